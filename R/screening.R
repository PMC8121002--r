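#' Screen a community for biosynthetic potential
#'
#' The core gene-centric screen. For every product in the catalog it
#' evaluates pathway completeness against (i) the pooled community gene
#' complement and (ii) each taxon-at-rank's own complement, and classifies
#' the product:
#' \describe{
#'   \item{`SINGLE_MICROBE` (Case I)}{at least one taxon at the chosen rank
#'     carries a full gene set on its own contigs.}
#'   \item{`MIXED_COMMUNITY` (Case II)}{only the pooled community carries a
#'     full set — production would need syntrophy between taxa.}
#'   \item{`NONE` (Case III)}{even the pooled community lacks required
#'     genes.}
#' }
#' Precedence is I over II over III. Records on contigs unclassified at the
#' rank count toward the community complement but never toward any single
#' taxon (conservative for Case I claims).
#'
#' @param catalog A `pathway_catalog`.
#' @param community An `annotated_community`.
#' @param rank Rank at which "a single microbe" is evaluated (default
#'   `"species"`).
#' @return A `screening_result`: tibble with one row per product and
#'   columns `product`, `classification`, `community_complete`,
#'   `missing_steps` (list column; step ids unsatisfied by the pooled
#'   complement), `single_producers` (list column of tibbles with `taxon`
#'   and ancestral `lineage`), `n_single_producers`; attribute `rank`.
#' @examples
#' demo <- demo_community()
#' screen_community(default_catalog(), demo$community)
#' @export
screen_community <- function(catalog, community, rank = "species") {
  stopifnot(inherits(catalog, "pathway_catalog"),
            inherits(community, "annotated_community"))
  check_rank(rank)
  pooled <- gene_complement(community)
  if (community$stats$n_annotated == 0L) {
    warning("community has no annotated genes; every product classified NONE",
            call. = FALSE)
  }
  complements <- complements_at_rank(community, rank)
  rows <- lapply(catalog$products, function(pw) {
    cc <- pathway_complete(pw, pooled)
    producer <- names(complements)[vapply(complements, function(sym) {
      pathway_complete(pw, sym)$complete
    }, logical(1))]
    producer <- sort(producer)
    classification <- if (length(producer)) "SINGLE_MICROBE"
      else if (cc$complete) "MIXED_COMMUNITY" else "NONE"
    tibble::tibble(
      product = pw$product,
      classification = classification,
      community_complete = cc$complete,
      missing_steps = list(cc$missing_steps),
      single_producers = list(producer_lineages(community, rank, producer)),
      n_single_producers = length(producer))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "rank") <- rank
  class(out) <- c("screening_result", class(out))
  out
}

# ancestral lineage (ranks above `rank`) for each producer taxon
producer_lineages <- function(community, rank, taxa) {
  ranks <- taxonomic_ranks()
  upto <- ranks[seq_len(match(rank, ranks))]
  above <- utils::head(upto, -1L)
  genes <- community$genes
  lin <- vapply(taxa, function(tx) {
    row <- genes[!is.na(genes[[rank]]) & genes[[rank]] == tx, above,
                 drop = FALSE]
    if (!nrow(row)) return(NA_character_)
    compose_lineage(row[1L, , drop = FALSE])
  }, character(1))
  tibble::tibble(taxon = taxa, lineage = unname(lin))
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> rank = %s\n", attr(x, "rank")))
  for (i in seq_len(nrow(x))) {
    mark <- if (x$community_complete[i]) "+" else "-"
    extra <- switch(x$classification[i],
      SINGLE_MICROBE = paste0(" by ",
        paste(x$single_producers[[i]]$taxon, collapse = "; ")),
      "")
    cat(sprintf("  %-14s %s  %s%s\n", x$product[i], mark,
                x$classification[i], extra))
  }
  invisible(x)
}

#' Presence/absence classification matrix
#'
#' Reshapes a [screen_community()] result into the familiar report layout:
#' one row per product, a `+`/`-` column for the mixed culture, and the
#' single-producer lineages and taxa (newline-collapsed) where Case I
#' holds.
#'
#' @param result A `screening_result`.
#' @return Tibble with columns `product`, `mixed_culture`, `lineage`,
#'   and the single-taxon column named after the screening rank.
#' @export
classification_matrix <- function(result) {
  stopifnot(inherits(result, "screening_result"))
  rank <- attr(result, "rank")
  out <- tibble::tibble(
    product = result$product,
    mixed_culture = ifelse(result$community_complete, "+", "-"),
    lineage = vapply(result$single_producers, function(sp) {
      if (!nrow(sp)) "-" else paste(sp$lineage, collapse = " | ")
    }, character(1)),
    single = vapply(result$single_producers, function(sp) {
      if (!nrow(sp)) "-" else paste(sp$taxon, collapse = " | ")
    }, character(1)))
  names(out)[names(out) == "single"] <- rank
  out
}

#' Hit-number profile of one product
#'
#' Collects the community hit number of every gene referenced by the
#' product's step requirements, plus per-step totals (the sum over the
#' step's genes). The extremes `min_gene` / `max_gene` are taken over the
#' product's *active* genes — the requirement tree pruned so that a
#' satisfied alternative (`any`) branch hides its unused siblings (see
#' [active_symbols()]); ties are broken by lexicographic symbol order.
#'
#' @inheritParams screen_community
#' @param product Product name in the catalog.
#' @return A `hit_profile`: list with `product`, `per_gene` (named counts
#'   over all referenced genes), `per_step` (named by step id),
#'   `active` (character vector), `min_gene`, `max_gene`.
#' @examples
#' demo <- demo_community()
#' hit_profile(default_catalog(), demo$community, "ectoine")
#' @export
hit_profile <- function(catalog, community, product) {
  stopifnot(inherits(catalog, "pathway_catalog"),
            inherits(community, "annotated_community"))
  pw <- get_product(catalog, product)
  symbols <- product_symbols(catalog, product)
  per_gene <- hit_count(community, symbols = symbols)
  present <- gene_complement(community)
  per_step <- vapply(pw$steps, function(s) {
    sum(per_gene[expr_symbols(s$expr)])
  }, numeric(1))
  names(per_step) <- vapply(pw$steps, `[[`, character(1), "id")
  active <- sort(unique(unlist(lapply(pw$steps, function(s) {
    active_symbols(s$expr, present)
  }))))
  act <- per_gene[active]
  # ties broken by lexicographic symbol order for both extremes
  ord_min <- order(act, names(act))
  ord_max <- order(-act, names(act))
  structure(list(product = product,
                 per_gene = per_gene,
                 per_step = per_step,
                 active = active,
                 min_gene = names(act)[ord_min[1L]],
                 max_gene = names(act)[ord_max[1L]]),
            class = "hit_profile")
}

#' @export
print.hit_profile <- function(x, ...) {
  cat(sprintf("<hit_profile> %s\n", x$product))
  for (s in names(x$per_gene)) {
    tag <- if (!s %in% x$active) " (inactive route)" else ""
    cat(sprintf("  %-10s %8d%s\n", s, as.integer(x$per_gene[[s]]), tag))
  }
  cat(sprintf("  min %s, max %s\n", x$min_gene, x$max_gene))
  invisible(x)
}

#' Rate-limiting hit-number ratio
#'
#' The ratio of the lowest to the highest per-gene hit number within one
#' product's (active) gene set. A low value flags the low-hit gene's step
#' as a candidate biosynthetic bottleneck; e.g. ectoine with `ectA` at 177
#' hits against `lysC` at 12,563 gives 0.014. The ratio is a rough genetic
#' indicator only — expression differences and pseudogenes are invisible to
#' it. When any active gene has zero hits the quantity is a completeness
#' problem, not a rate, and the summary is flagged undefined.
#'
#' @param profile A [hit_profile()].
#' @param digits Decimal places for half-away-from-zero rounding
#'   (default 3).
#' @return A `rate_limiting_summary`: list with `product`, `ratio` (`NA`
#'   when undefined), `min_gene`, `max_gene`, `defined`.
#' @export
rate_limiting_ratio <- function(profile, digits = 3) {
  stopifnot(inherits(profile, "hit_profile"))
  act <- profile$per_gene[profile$active]
  if (length(act) < 2L) {
    stop("rate-limiting ratio needs a profile with at least two genes",
         call. = FALSE)
  }
  lo <- as.numeric(act[[profile$min_gene]])
  hi <- as.numeric(act[[profile$max_gene]])
  defined <- lo > 0 && hi > 0
  structure(list(product = profile$product,
                 ratio = if (defined) round_half_up(lo / hi, digits)
                         else NA_real_,
                 min_gene = profile$min_gene,
                 max_gene = profile$max_gene,
                 defined = defined),
            class = "rate_limiting_summary")
}

#' @export
print.rate_limiting_summary <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("%s: min/max hit ratio %s (%s/%s)\n", x$product,
                format(x$ratio), x$min_gene, x$max_gene))
  } else {
    cat(sprintf("%s: ratio undefined (a required gene has zero hits)\n",
                x$product))
  }
  invisible(x)
}

#' Ratio between two named genes of a profile
#'
#' @inheritParams rate_limiting_ratio
#' @param numerator_gene,denominator_gene Gene symbols present in the
#'   profile.
#' @return Rounded numerator/denominator hit-count ratio.
#' @examples
#' demo <- demo_community()
#' p <- hit_profile(default_catalog(), demo$community, "PHB")
#' pairwise_ratio(p, "phaA", "phaC")
#' @export
pairwise_ratio <- function(profile, numerator_gene, denominator_gene,
                           digits = 3) {
  stopifnot(inherits(profile, "hit_profile"))
  for (g in c(numerator_gene, denominator_gene)) {
    if (!g %in% names(profile$per_gene)) {
      stop(sprintf("gene '%s' is not in the %s profile", g,
                   profile$product), call. = FALSE)
    }
  }
  den <- as.numeric(profile$per_gene[[denominator_gene]])
  if (den <= 0) {
    stop(sprintf("denominator gene '%s' has zero hits", denominator_gene),
         call. = FALSE)
  }
  round_half_up(as.numeric(profile$per_gene[[numerator_gene]]) / den,
                digits)
}

#' Ratio summaries for every catalog product
#'
#' @inheritParams screen_community
#' @param digits Rounding places for the ratio.
#' @return Tibble with `product`, `min_gene`, `max_gene`, `ratio`,
#'   `defined`.
#' @export
ratio_summary <- function(catalog, community, digits = 3) {
  rows <- lapply(catalog_products(catalog), function(p) {
    r <- rate_limiting_ratio(hit_profile(catalog, community, p),
                             digits = digits)
    tibble::tibble(product = r$product, min_gene = r$min_gene,
                   max_gene = r$max_gene, ratio = r$ratio,
                   defined = r$defined)
  })
  dplyr::bind_rows(rows)
}

#' Relative abundance of taxa at a rank
#'
#' Fractions are gene records of a taxon over all gene records (classified
#' plus unclassified), mirroring read-based community composition profiles.
#' Classified taxa are sorted by descending count then name and truncated
#' to `top_n` with an aggregate `"other"` remainder row; records on contigs
#' unclassified at the rank form a final `"unclassified"` row. Fractions
#' always sum to 1.
#'
#' @inheritParams hit_table
#' @param top_n Number of classified taxa to keep (default all).
#' @return Tibble with `taxon`, `count`, `fraction`; attribute `rank`.
#' @export
relative_abundance <- function(community, rank, top_n = Inf) {
  stopifnot(inherits(community, "annotated_community"))
  check_rank(rank)
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  genes <- community$genes
  tx <- genes[[rank]]
  tx[is.na(tx)] <- "unclassified"
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(taxon = tx, weight = genes$weight),
                    .data$taxon),
    count = sum(.data$weight), .groups = "drop")
  total <- sum(agg$count)
  uncls <- agg[agg$taxon == "unclassified", ]
  cls <- agg[agg$taxon != "unclassified", ]
  cls <- cls[order(-cls$count, cls$taxon), ]
  truncated <- is.finite(top_n) && nrow(cls) > top_n
  if (truncated) {
    rest <- cls[-seq_len(top_n), ]
    cls <- cls[seq_len(top_n), ]
    cls <- dplyr::bind_rows(cls, tibble::tibble(
      taxon = "other", count = sum(rest$count)))
  }
  out <- dplyr::bind_rows(cls, uncls)
  out$fraction <- out$count / total
  attr(out, "rank") <- rank
  attr(out, "truncated") <- truncated
  out
}

#' Ratio of two taxa's relative abundances
#'
#' @param abundance Tibble from [relative_abundance()].
#' @param taxon_a,taxon_b Taxon names in the table.
#' @param digits Rounding places (default 1, half away from zero).
#' @return `fraction(taxon_a) / fraction(taxon_b)`, rounded.
#' @export
abundance_ratio <- function(abundance, taxon_a, taxon_b, digits = 1) {
  f <- function(tx) {
    i <- match(tx, abundance$taxon)
    if (is.na(i)) stop(sprintf("taxon '%s' not in abundance table", tx),
                       call. = FALSE)
    abundance$fraction[i]
  }
  round_half_up(f(taxon_a) / f(taxon_b), digits)
}
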