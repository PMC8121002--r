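# Built-in synthetic demonstration community.
#
# Emulates a methanol-fed activated-sludge metagenome from a landfill
# leachate treatment plant: species-resolved PHB, acetoin and
# 2,3-butanediol producers on a background community whose pooled gene
# complement also completes ectoine, zeaxanthin and astaxanthin (but not
# lutein). All counts are designed, not measured: the per-gene community
# hit numbers below are the study conditions the screen is demonstrated
# on, and the remaining mass is spread over single-gene filler taxa so
# that no filler can complete any pathway on its own.

# community hit-number totals per gene symbol
demo_targets <- c(
  lysC = 12563, asd = 9000, ectB = 3000, ectA = 177, ectC = 800,
  phaA = 2532, phaB = 2476, phaC = 14491,
  `E2.2.1.6L` = 25556, `E2.2.1.6S` = 1500, ilvM = 2000, alsD = 115,
  BDH = 1800, butA = 2200, budC = 900,
  dxs = 4000, dxr = 3500, ispD = 2800, ispE = 2600, ispF = 2400,
  ispG = 2200, ispH = 2000,
  ispA = 6000, crtE = 3000, crtB = 2500, crtI = 10000, crtY = 1500,
  crtZ = 1100, crtW = 1300)

# named species and their designed gene complements (counts)
demo_named_taxa <- function() {
  tri <- function(name, lineage, bg = 0L) {
    tibble::tibble(name = name, lineage = lineage, background = bg)
  }
  taxa <- dplyr::bind_rows(
    tri("Methyloceanibacter caenitepidi",
        "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae;Methyloceanibacter;Methyloceanibacter caenitepidi",
        bg = 500L),
    tri("Rhodopseudomonas palustris",
        "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Nitrobacteraceae;Rhodopseudomonas;Rhodopseudomonas palustris",
        bg = 350L),
    tri("Candidatus Filomicrobium marinum W",
        "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae;Filomicrobium;Candidatus Filomicrobium marinum W"),
    tri("Janthinobacterium sp. Marseille",
        "Bacteria;Proteobacteria;Gammaproteobacteria;Burkholderiales;Oxalobacteraceae;Janthinobacterium;Janthinobacterium sp. Marseille"),
    tri("Candidatus Promineofilum breve",
        "Bacteria;Chloroflexi;Ardenticatenia;Ardenticatenales;Ardenticatenaceae;Promineofilum;Candidatus Promineofilum breve"),
    tri("Caldilinea aerophila",
        "Bacteria;Chloroflexi;Caldilineae;Caldilineales;Caldilineaceae;Caldilinea;Caldilinea aerophila"),
    tri("Lonsdalea britannica",
        "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Pectobacteriaceae;Lonsdalea;Lonsdalea britannica"),
    tri("Orrella dioscoreae",
        "Bacteria;Proteobacteria;Gammaproteobacteria;Burkholderiales;Alcaligenaceae;Orrella;Orrella dioscoreae"))
  taxa$n_contigs <- 5L
  taxa
}

demo_named_counts <- function() {
  cnt <- function(taxon, ...) {
    v <- c(...)
    tibble::tibble(taxon = taxon, symbol = names(v),
                   count = as.integer(v))
  }
  dplyr::bind_rows(
    cnt("Methyloceanibacter caenitepidi", phaA = 400, phaB = 380,
        phaC = 520),
    cnt("Rhodopseudomonas palustris", lysC = 600, asd = 400),
    cnt("Candidatus Filomicrobium marinum W", phaA = 300, phaB = 300,
        phaC = 350),
    cnt("Janthinobacterium sp. Marseille", phaA = 250, phaB = 240,
        phaC = 300),
    cnt("Candidatus Promineofilum breve", `E2.2.1.6L` = 400, ilvM = 300,
        alsD = 30),
    cnt("Caldilinea aerophila", `E2.2.1.6L` = 350, ilvM = 280, alsD = 30,
        butA = 320, BDH = 250),
    cnt("Lonsdalea britannica", `E2.2.1.6L` = 330, ilvM = 260, alsD = 30,
        butA = 300, BDH = 230),
    cnt("Orrella dioscoreae", `E2.2.1.6L` = 310, ilvM = 240, alsD = 25,
        butA = 280, BDH = 220))
}

# residual hit mass goes to single-gene filler taxa (<= cap records each),
# so no filler can complete any multi-gene pathway; background-only fillers
# then pad the community to the designed total record count
demo_filler_counts <- function(named_counts, total_records = 150000L,
                               cap = 1200L) {
  assigned <- stats::setNames(rep(0L, length(demo_targets)),
                              names(demo_targets))
  agg <- tapply(named_counts$count, named_counts$symbol, sum)
  assigned[names(agg)] <- as.integer(agg)
  over <- assigned > demo_targets
  if (any(over)) {
    stop(sprintf("designed counts exceed the community target for '%s'",
                 names(demo_targets)[over][1L]), call. = FALSE)
  }
  residual <- demo_targets - assigned
  rows <- list()
  k <- 0L
  for (sym in names(residual)) {
    left <- residual[[sym]]
    while (left > 0L) {
      k <- k + 1L
      take <- min(left, cap)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        taxon = sprintf("Sludgea bacterium SB%03d", k),
        symbol = sym, count = take)
      left <- left - take
    }
  }
  filler_counts <- dplyr::bind_rows(rows)
  n_pad_total <- total_records - sum(demo_targets) -
    sum(demo_named_taxa()$background)
  stopifnot(n_pad_total >= 0L)
  n_full <- n_pad_total %/% cap
  pad_bg <- c(rep(cap, n_full),
              if (n_pad_total %% cap > 0L) n_pad_total %% cap)
  pads <- sprintf("Sludgea bacterium SB%03d", k + seq_along(pad_bg))
  filler_taxa <- tibble::tibble(
    name = c(unique(filler_counts$taxon), pads),
    background = c(rep(0L, length(unique(filler_counts$taxon))),
                   as.integer(pad_bg)))
  filler_taxa$lineage <- paste0(
    "Bacteria;CandidatusSludgimonadota;Sludgimonadia;Sludgimonadales;",
    "Sludgimonadaceae;Sludgea;", filler_taxa$name)
  filler_taxa$n_contigs <- 2L
  list(counts = filler_counts, taxa = filler_taxa)
}

#' Built-in demonstration community (synthetic)
#'
#' A fully designed activated-sludge-like community for examples, tests
#' and the worked analysis: three species (led by *Methyloceanibacter
#' caenitepidi* at 1.2% of records, with *Rhodopseudomonas palustris*
#' second at 0.9%) each carry a complete PHB gene set; four species carry
#' complete acetoin gene sets, three of which extend to 2,3-butanediol;
#' ectoine, zeaxanthin and astaxanthin are completed only by the pooled
#' community; lutein-specific genes are absent. Designed community hit
#' numbers include ectA 177 vs lysC 12,563 (min/max ratio 0.014), phaA
#' 2,532 / phaB 2,476 / phaC 14,491 (0.175 and 0.171 against phaC), alsD
#' 115, and carotenoid extremes 1,100 vs 10,000 (0.11). The seed only
#' disperses records over contigs; counts and classifications are fixed by
#' design. This is a synthetic stand-in for a real annotated metagenome,
#' not measured data.
#'
#' @param seed Integer seed for contig dispersal.
#' @return List with `bundle` (the [generate_community()] output),
#'   `community` (the bundle parsed back through the annotation readers)
#'   and `catalog` (the packaged default).
#' @examples
#' demo <- demo_community()
#' screen_community(demo$catalog, demo$community)
#' @export
demo_community <- function(seed = 20180720) {
  catalog <- default_catalog()
  named_counts <- demo_named_counts()
  filler <- demo_filler_counts(named_counts)
  taxa <- dplyr::bind_rows(demo_named_taxa(), filler$taxa)
  design <- synthetic_design(
    taxa = taxa,
    counts = dplyr::bind_rows(named_counts, filler$counts),
    unclassified_fraction = 0)
  bundle <- generate_community(design, catalog, seed = seed)
  list(bundle = bundle,
       community = bundle_community(bundle),
       catalog = catalog)
}
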