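#' Design a synthetic annotated community
#'
#' Declares the ground truth from which [generate_community()] emits
#' annotation and taxonomy tables: which taxa exist, which gene complements
#' they carry per product, how per-gene hit counts are drawn, and what
#' fraction of contigs is withheld from the taxonomy table (emulating
#' classifier dropout). The emitted bundle carries a manifest of the
#' realized truth, so every downstream screening behavior can be checked
#' without external data.
#'
#' @param taxa Tibble (or data frame) with columns `name` (unique species
#'   name), `lineage` (semicolon-delimited, domain first); optional
#'   `weight` (positive count multiplier, default 1), `n_contigs`
#'   (default 3), `background` (count of unannotated gene records,
#'   default 0).
#' @param complements Named list: taxon name -> named list of product ->
#'   either `"complete"` or `list(missing = <symbols>)`. Products not named
#'   contribute no genes for that taxon. A taxon's realized gene set is the
#'   union over its products of the granted symbols.
#' @param counts Optional explicit tibble `(taxon, symbol, count)`
#'   overriding `complements` + `count_model` (fully designed counts).
#' @param count_model List with `family` (`"log-uniform"` or `"uniform"`),
#'   `min`, `max`. The default log-uniform on \[50, 15000\] spans the
#'   dynamic range typical of deeply sequenced sludge metagenomes.
#' @param unclassified_fraction Fraction of contigs (in `[0, 1)`) omitted
#'   from the taxonomy table.
#' @return A `synthetic_design`.
#' @export
synthetic_design <- function(taxa, complements = list(), counts = NULL,
                             count_model = list(family = "log-uniform",
                                                min = 50, max = 15000),
                             unclassified_fraction = 0) {
  taxa <- tibble::as_tibble(taxa)
  stopifnot(all(c("name", "lineage") %in% names(taxa)))
  if (!"weight" %in% names(taxa)) taxa$weight <- 1
  if (!"n_contigs" %in% names(taxa)) taxa$n_contigs <- 3L
  if (!"background" %in% names(taxa)) taxa$background <- 0L
  if (anyDuplicated(taxa$name)) {
    stop("taxon names must be unique", call. = FALSE)
  }
  if (any(taxa$weight <= 0)) stop("abundance weights must be positive",
                                  call. = FALSE)
  if (unclassified_fraction < 0 || unclassified_fraction >= 1) {
    stop("unclassified_fraction must be in [0, 1)", call. = FALSE)
  }
  if (!count_model$family %in% c("log-uniform", "uniform")) {
    stop("count_model$family must be 'log-uniform' or 'uniform'",
         call. = FALSE)
  }
  structure(list(taxa = taxa, complements = complements, counts = counts,
                 count_model = count_model,
                 unclassified_fraction = unclassified_fraction),
            class = "synthetic_design")
}

validate_design <- function(design, catalog) {
  syms <- catalog_symbols(catalog)
  prods <- catalog_products(catalog)
  for (tx in names(design$complements)) {
    if (!tx %in% design$taxa$name) {
      stop(sprintf("complement for unknown taxon '%s'", tx), call. = FALSE)
    }
    for (p in names(design$complements[[tx]])) {
      if (!p %in% prods) {
        stop(sprintf("design references unknown product '%s'", p),
             call. = FALSE)
      }
      spec <- design$complements[[tx]][[p]]
      if (is.list(spec) && !is.null(spec$missing)) {
        bad <- setdiff(spec$missing, syms)
        if (length(bad)) {
          stop(sprintf("design references unknown symbol '%s'", bad[1L]),
               call. = FALSE)
        }
      }
    }
  }
  if (!is.null(design$counts)) {
    bad <- setdiff(design$counts$symbol, syms)
    if (length(bad)) {
      stop(sprintf("design counts reference unknown symbol '%s'", bad[1L]),
           call. = FALSE)
    }
  }
  invisible(design)
}

draw_count <- function(model, n) {
  u <- stats::runif(n)
  x <- switch(model$family,
    "log-uniform" = exp(log(model$min) + u * (log(model$max) -
                                                log(model$min))),
    "uniform" = model$min + u * (model$max - model$min))
  pmax(1L, as.integer(round(x)))
}

design_counts <- function(design, catalog) {
  if (!is.null(design$counts)) {
    cnt <- tibble::as_tibble(design$counts)
    return(cnt[cnt$count > 0, ])
  }
  rows <- lapply(seq_len(nrow(design$taxa)), function(i) {
    tx <- design$taxa$name[i]
    comp <- design$complements[[tx]]
    syms <- unique(unlist(lapply(names(comp), function(p) {
      all_syms <- product_symbols(catalog, p)
      spec <- comp[[p]]
      if (identical(spec, "complete")) all_syms
      else setdiff(all_syms, spec$missing)
    })))
    if (!length(syms)) return(NULL)
    tibble::tibble(
      taxon = tx, symbol = syms,
      count = pmax(1L, as.integer(round(
        design$taxa$weight[i] * draw_count(design$count_model,
                                           length(syms))))))
  })
  dplyr::bind_rows(rows)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic community bundle
#'
#' Realizes a [synthetic_design()]: draws (or copies) per-(taxon, gene)
#' hit counts, spreads the gene records uniformly over each taxon's
#' contigs, withholds the designed fraction of contigs from the taxonomy
#' table, and emits canonical-dialect annotation and taxonomy TSV content
#' together with a manifest of the realized truth (per-symbol counts by
#' species, expected classification per product, abundance fractions).
#' Deterministic for a fixed design and seed.
#'
#' @param design A `synthetic_design`.
#' @param catalog The catalog the design refers to (default
#'   [default_catalog()]).
#' @param seed Integer RNG seed.
#' @return A `synthetic_bundle`: list with `annotation_lines`,
#'   `taxonomy_lines` (character vectors of TSV rows), `manifest` (list:
#'   `community_counts`, `taxon_counts`, `classification`, `abundance`,
#'   `n_records`, `seed`), and the `design`.
#' @export
generate_community <- function(design, catalog = default_catalog(),
                               seed = 1L) {
  stopifnot(inherits(design, "synthetic_design"))
  validate_design(design, catalog)
  seed <- as.integer(seed)
  with_seed(seed, {
    counts <- design_counts(design, catalog)
    taxa <- design$taxa
    # symbol -> emitted KO (first map entry for the symbol)
    map <- read_symbol_map()
    sym_ko <- map$ko[match(counts$symbol, map$symbol)]
    if (anyNA(sym_ko)) {
      stop(sprintf("no KO in the symbol map for symbol '%s'",
                   counts$symbol[is.na(sym_ko)][1L]), call. = FALSE)
    }
    ord <- match(counts$taxon, taxa$name)
    if (anyNA(ord)) {
      stop(sprintf("counts reference unknown taxon '%s'",
                   counts$taxon[is.na(ord)][1L]), call. = FALSE)
    }
    # one record per hit, plus unannotated background records per taxon
    records <- tibble::tibble(
      taxon = c(rep(counts$taxon, counts$count),
                rep(taxa$name, taxa$background)),
      ko = c(rep(sym_ko, counts$count),
             rep(NA_character_, sum(taxa$background))))
    # contigs and uniform record placement
    taxa$tid <- sprintf("T%03d", seq_len(nrow(taxa)))
    contigs <- tibble::tibble(
      contig_id = unlist(lapply(seq_len(nrow(taxa)), function(i) {
        sprintf("%s_c%02d", taxa$tid[i], seq_len(taxa$n_contigs[i]))
      })),
      taxon = rep(taxa$name, taxa$n_contigs))
    idx <- match(records$taxon, taxa$name)
    cnum <- integer(nrow(records))
    for (i in seq_len(nrow(taxa))) {
      sel <- which(idx == i)
      if (length(sel)) {
        cnum[sel] <- sample.int(taxa$n_contigs[i], length(sel),
                                replace = TRUE)
      }
    }
    records$contig_id <- sprintf("%s_c%02d", taxa$tid[idx], cnum)
    records <- records[order(records$contig_id), ]
    records$gene_id <- stats::ave(
      records$contig_id, records$contig_id,
      FUN = function(x) sprintf("%s_%d", x, seq_along(x)))
    # withhold contigs from the taxonomy table
    n_drop <- floor(design$unclassified_fraction * nrow(contigs))
    dropped <- if (n_drop > 0) {
      sample(contigs$contig_id, n_drop)
    } else character()
    tax_tbl <- contigs[!contigs$contig_id %in% dropped, ]
    tax_tbl$taxon_id <- taxa$tid[match(tax_tbl$taxon, taxa$name)]
    tax_tbl$lineage <- taxa$lineage[match(tax_tbl$taxon, taxa$name)]
    manifest <- build_manifest(records, dropped, taxa, catalog, seed)
    structure(list(
      annotation_lines = paste0(records$gene_id, "\t",
                                ifelse(is.na(records$ko), "", records$ko)),
      taxonomy_lines = paste0(tax_tbl$contig_id, "\t", tax_tbl$taxon_id,
                              "\t", tax_tbl$lineage),
      manifest = manifest,
      design = design,
      seed = seed), class = "synthetic_bundle")
  })
}

# realized truth, computed from the generator's internal record table
build_manifest <- function(records, dropped, taxa, catalog, seed) {
  map <- read_symbol_map()
  records$species <- ifelse(records$contig_id %in% dropped,
                            "unclassified", records$taxon)
  hits <- records[!is.na(records$ko), c("ko", "species")]
  hits <- dplyr::inner_join(hits, map, by = "ko",
                            relationship = "many-to-many")
  taxon_counts <- dplyr::count(hits, .data$species, .data$symbol,
                               name = "count")
  community_counts <- dplyr::count(hits, .data$symbol, name = "count")
  complements <- split(taxon_counts$symbol, taxon_counts$species)
  complements <- complements[names(complements) != "unclassified"]
  pooled <- unique(hits$symbol)
  classification <- dplyr::bind_rows(lapply(catalog$products, function(pw) {
    producers <- sort(names(complements)[vapply(complements, function(s) {
      pathway_complete(pw, s)$complete
    }, logical(1))])
    cc <- pathway_complete(pw, pooled)$complete
    tibble::tibble(
      product = pw$product,
      classification = if (length(producers)) "SINGLE_MICROBE"
                       else if (cc) "MIXED_COMMUNITY" else "NONE",
      community_complete = cc,
      producers = list(producers))
  }))
  ab <- dplyr::count(records, .data$species, name = "count")
  ab$fraction <- ab$count / sum(ab$count)
  list(community_counts = community_counts,
       taxon_counts = taxon_counts,
       classification = classification,
       abundance = ab,
       n_records = nrow(records),
       seed = seed)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>\n")
  cat(sprintf("  %d gene records, %d classified contigs, seed %d\n",
              length(x$annotation_lines), length(x$taxonomy_lines),
              x$seed))
  invisible(x)
}

#' Write a bundle's tables to a directory
#'
#' Emits `annotations.tsv`, `taxonomy.tsv` and `manifest.yaml`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_lines(bundle$annotation_lines,
                     file.path(dir, "annotations.tsv"))
  readr::write_lines(bundle$taxonomy_lines, file.path(dir, "taxonomy.tsv"))
  m <- bundle$manifest
  yaml::write_yaml(list(
    seed = m$seed, n_records = m$n_records,
    community_counts = stats::setNames(as.list(m$community_counts$count),
                                       m$community_counts$symbol),
    classification = stats::setNames(
      as.list(m$classification$classification), m$classification$product)),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Parse a bundle back through the annotation readers
#'
#' Round-trips the emitted TSV content through [read_ko_table()],
#' [read_taxonomy_table()] and [join_community()] — the same path a user's
#' real annotator/classifier outputs take.
#'
#' @param bundle A `synthetic_bundle`.
#' @param symbol_map Symbol map used for the join.
#' @return An `annotated_community`.
#' @export
bundle_community <- function(bundle, symbol_map = read_symbol_map()) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  ann_file <- tempfile(fileext = ".tsv")
  tax_file <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(ann_file, tax_file)))
  readr::write_lines(bundle$annotation_lines, ann_file)
  readr::write_lines(bundle$taxonomy_lines, tax_file)
  join_community(read_ko_table(ann_file),
                 read_taxonomy_table(tax_file),
                 symbol_map = symbol_map,
                 contig_regex = "_[0-9]+$")
}
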