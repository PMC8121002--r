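#' Read a gene-to-KO annotation table
#'
#' Consumes the two-column TSV emitted by GhostKOALA-style annotators:
#' gene id in column 1, KEGG Orthology id (possibly blank for unannotated
#' genes) in column 2. The `three-column-with-score` dialect additionally
#' carries a numeric score in column 3, which is retained but unused. Blank
#' KO rows are kept as unannotated (`NA`); a malformed KO token or a
#' duplicated gene id is an error naming the offending row.
#'
#' @param file Path to the TSV (a header line `gene_id<TAB>ko...` is
#'   detected and skipped).
#' @param dialect `"two-column"` (default) or `"three-column-with-score"`.
#' @return Tibble with columns `gene_id`, `ko` (and `score` for the
#'   three-column dialect).
#' @export
read_ko_table <- function(file,
                          dialect = c("two-column",
                                      "three-column-with-score")) {
  dialect <- match.arg(dialect)
  ncol_exp <- if (dialect == "two-column") 2L else 3L
  lines <- readr::read_lines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("empty annotation file: %s", file),
                           call. = FALSE)
  header <- grepl("^gene_id\t", lines[1L])
  if (header) lines <- lines[-1L]
  if (!length(lines)) stop(sprintf("annotation file has only a header: %s",
                                   file), call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  bad <- which(n < 1L | n > ncol_exp)
  if (length(bad)) {
    stop(sprintf("row %d of %s: expected at most %d tab-separated fields",
                 bad[1L] + header, file, ncol_exp), call. = FALSE)
  }
  gene_id <- vapply(parts, `[[`, character(1), 1L)
  ko <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
               character(1))
  ko <- trimws(ko)
  if (anyDuplicated(gene_id)) {
    stop(sprintf("duplicated gene_id '%s' in %s",
                 gene_id[duplicated(gene_id)][1L], file), call. = FALSE)
  }
  malformed <- which(nzchar(ko) & !grepl(ko_pattern, ko))
  if (length(malformed)) {
    stop(sprintf("row %d of %s: malformed KO token '%s'",
                 malformed[1L] + header, file, ko[malformed[1L]]),
         call. = FALSE)
  }
  out <- tibble::tibble(gene_id = gene_id,
                        ko = ifelse(nzchar(ko), ko, NA_character_))
  if (dialect == "three-column-with-score") {
    out$score <- as.numeric(vapply(parts, function(p) {
      if (length(p) >= 3L) p[[3L]] else NA_character_
    }, character(1)))
  }
  out
}

#' Read a contig taxonomy table
#'
#' Adapters for common classifier outputs, each yielding the same canonical
#' shape. Dialects:
#' \describe{
#'   \item{`centrifuge`}{`contig_id<TAB>taxon_id<TAB>lineage`, the lineage
#'     semicolon-delimited from domain down (the canonical dialect).}
#'   \item{`kraken2`}{`C/U<TAB>contig_id<TAB>taxon_id<TAB>lineage`, the
#'     lineage `|`-delimited with `x__` rank prefixes; `U` rows become
#'     unclassified sentinels.}
#'   \item{`plain-lineage`}{`contig_id<TAB>lineage` with no taxon id.}
#' }
#' Contigs absent from the table are treated as unclassified downstream.
#'
#' @param file Path to the TSV (a `contig_id...` header is skipped).
#' @param dialect One of `"centrifuge"`, `"kraken2"`, `"plain-lineage"`.
#' @return Tibble with `contig_id`, `taxon_id`, `lineage`, plus one parsed
#'   column per taxonomic rank.
#' @export
read_taxonomy_table <- function(file,
                                dialect = c("centrifuge", "kraken2",
                                            "plain-lineage")) {
  dialect <- match.arg(dialect)
  lines <- readr::read_lines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("empty taxonomy file: %s", file),
                           call. = FALSE)
  header <- grepl("^contig_id\t|^status\t", lines[1L])
  if (header) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) p[[i]] else ""
  }, character(1))
  tbl <- switch(dialect,
    "centrifuge" = tibble::tibble(contig_id = get(1L), taxon_id = get(2L),
                                  lineage = get(3L)),
    "kraken2" = {
      status <- get(1L)
      tibble::tibble(contig_id = get(2L), taxon_id = get(3L),
                     lineage = ifelse(status == "U", "unclassified",
                                      get(4L)))
    },
    "plain-lineage" = tibble::tibble(contig_id = get(1L),
                                     taxon_id = NA_character_,
                                     lineage = get(2L)))
  if (any(!nzchar(tbl$contig_id))) {
    stop(sprintf("row %d of %s: missing contig id",
                 which(!nzchar(tbl$contig_id))[1L] + header, file),
         call. = FALSE)
  }
  empty <- which(!nzchar(trimws(tbl$lineage)))
  if (length(empty)) {
    stop(sprintf(
      "row %d of %s: empty lineage (use the sentinel 'unclassified' for unassigned contigs)",
      empty[1L] + header, file), call. = FALSE)
  }
  if (anyDuplicated(tbl$contig_id)) {
    stop(sprintf("duplicated contig_id '%s' in %s",
                 tbl$contig_id[duplicated(tbl$contig_id)][1L], file),
         call. = FALSE)
  }
  ranks <- parse_lineage(tbl$lineage)
  tbl$lineage <- compose_lineage(ranks)
  dplyr::bind_cols(tbl, ranks)
}

#' Read a KO-to-gene-symbol map
#'
#' Two-column TSV (`ko<TAB>symbol`, header required) linking KEGG Orthology
#' ids to the catalog's gene symbols. The map may be many-to-many: a KO
#' mapping to several symbols (e.g. K00626 as both `phaA` and the MVA-route
#' thiolase `atoB`) contributes a hit to each. The packaged default covers
#' the seven-product catalog and is editable data, not ground truth.
#'
#' @param file Path to the map; `NULL` loads the packaged default.
#' @return Tibble with columns `ko`, `symbol`.
#' @export
read_symbol_map <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "ko_symbol_map.tsv",
                        package = "metascreen", mustWork = TRUE)
  }
  map <- readr::read_tsv(file, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("ko", "symbol") %in% names(map))) {
    stop("symbol map needs columns 'ko' and 'symbol'", call. = FALSE)
  }
  bad <- !grepl(ko_pattern, map$ko)
  if (any(bad)) {
    stop(sprintf("malformed KO id '%s' in symbol map", map$ko[bad][1L]),
         call. = FALSE)
  }
  if (anyDuplicated(map[c("ko", "symbol")])) {
    stop("duplicated (ko, symbol) pair in symbol map", call. = FALSE)
  }
  map[c("ko", "symbol")]
}

#' Join annotations, taxonomy and the symbol map into one community
#'
#' Links phylogeny with function: every annotated gene is tied to its
#' contig's lineage (or to the unclassified sentinel when the contig is
#' absent from the taxonomy table), and KOs are resolved to catalog gene
#' symbols through the map. The result answers every downstream query —
#' per-symbol hit counts at the community level or restricted to one taxon
#' at any rank, observed gene complements, and relative abundances.
#'
#' @param annotations Tibble from [read_ko_table()]; an optional `contig_id`
#'   column overrides derivation from the gene id, and an optional numeric
#'   `weight` column replaces the default per-record weight of 1 (e.g. to
#'   emulate read-depth weighting).
#' @param assignments Tibble from [read_taxonomy_table()].
#' @param symbol_map Tibble from [read_symbol_map()] (packaged default).
#' @param contig_regex Pattern stripped from `gene_id` to recover the contig
#'   id when no `contig_id` column is present; the default removes a
#'   trailing `_<n>` ORF index.
#' @return An `annotated_community` object.
#' @export
join_community <- function(annotations, assignments,
                           symbol_map = read_symbol_map(),
                           contig_regex = "_[0-9]+$") {
  stopifnot(is.data.frame(annotations), is.data.frame(assignments))
  genes <- tibble::as_tibble(annotations)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id in annotations", call. = FALSE)
  }
  if (!"contig_id" %in% names(genes)) {
    genes$contig_id <- sub(contig_regex, "", genes$gene_id)
  }
  if (!"weight" %in% names(genes)) genes$weight <- 1L
  ranks <- taxonomic_ranks()
  tax <- tibble::as_tibble(assignments)[c("contig_id", "taxon_id",
                                          "lineage", ranks)]
  genes <- dplyr::left_join(genes, tax, by = "contig_id")
  genes$lineage[is.na(genes$lineage)] <- "unclassified"
  hits <- genes[!is.na(genes$ko), c("gene_id", "ko")]
  hits <- dplyr::inner_join(hits, symbol_map, by = "ko",
                            relationship = "many-to-many")
  structure(list(
    genes = genes,
    hits = hits,
    symbol_map = symbol_map,
    stats = list(
      n_genes = nrow(genes),
      n_annotated = sum(!is.na(genes$ko)),
      n_symbol_hits = nrow(hits),
      n_unclassified_contigs = sum(is.na(genes$taxon_id) &
                                     genes$lineage == "unclassified"))
  ), class = "annotated_community")
}

#' @export
print.annotated_community <- function(x, ...) {
  s <- x$stats
  cat("<annotated_community>\n")
  cat(sprintf("  %d gene records (%d KO-annotated, %d catalog-symbol hits)\n",
              s$n_genes, s$n_annotated, s$n_symbol_hits))
  cat(sprintf("  %d contigs, %d records on unclassified contigs\n",
              length(unique(x$genes$contig_id)),
              sum(is.na(x$genes$taxon_id))))
  invisible(x)
}

restrict_genes <- function(community, rank = NULL, taxon = NULL) {
  genes <- community$genes
  if (!is.null(taxon)) {
    check_rank(rank)
    genes <- genes[!is.na(genes[[rank]]) & genes[[rank]] == taxon, ]
  }
  genes
}

#' Per-symbol hit counts
#'
#' The hit number of a gene symbol is the total weight (by default, the
#' number) of annotated gene records whose KO maps to that symbol —
#' community-wide, or restricted to the records of one taxon at a given
#' rank.
#'
#' @param community An `annotated_community`.
#' @param symbols Symbols to report (default: all symbols in the map, in
#'   map order); absent symbols report 0.
#' @param rank,taxon Optional restriction to records whose lineage at
#'   `rank` is `taxon`.
#' @return Named numeric vector of counts (integer-valued under unit
#'   weights).
#' @export
hit_count <- function(community, symbols = NULL, rank = NULL,
                      taxon = NULL) {
  stopifnot(inherits(community, "annotated_community"))
  if (is.null(symbols)) symbols <- unique(community$symbol_map$symbol)
  genes <- restrict_genes(community, rank, taxon)
  hits <- community$hits[community$hits$gene_id %in% genes$gene_id, ]
  w <- genes$weight[match(hits$gene_id, genes$gene_id)]
  counts <- tapply(w, factor(hits$symbol, levels = symbols), sum,
                   default = 0)
  out <- as.numeric(counts)
  names(out) <- symbols
  out
}

#' Long-format hit count table
#'
#' @inheritParams hit_count
#' @param rank `NULL` for community totals, or a rank to split counts by
#'   taxon at that rank (records on contigs unclassified at the rank are
#'   grouped under `"unclassified"`).
#' @return Tibble with `symbol`, `count` and, when `rank` is given,
#'   `taxon`.
#' @export
hit_table <- function(community, rank = NULL) {
  stopifnot(inherits(community, "annotated_community"))
  if (is.null(rank)) {
    counts <- hit_count(community)
    return(tibble::tibble(symbol = names(counts), count = counts))
  }
  check_rank(rank)
  genes <- community$genes
  tx <- genes[[rank]]
  tx[is.na(tx)] <- "unclassified"
  joined <- dplyr::inner_join(
    community$hits,
    tibble::tibble(gene_id = genes$gene_id, taxon = tx,
                   weight = genes$weight),
    by = "gene_id")
  out <- dplyr::summarise(dplyr::group_by(joined, .data$symbol, .data$taxon),
                          count = as.numeric(sum(.data$weight)),
                          .groups = "drop")
  dplyr::arrange(out, .data$symbol, .data$taxon)
}

#' Observed gene complement
#'
#' The set of catalog gene symbols with at least one hit — community-wide
#' or for one taxon at a rank. Records on contigs unclassified at the
#' queried rank never contribute to any taxon's complement (but always to
#' the community's).
#'
#' @inheritParams hit_count
#' @return Character vector of symbols.
#' @export
gene_complement <- function(community, rank = NULL, taxon = NULL) {
  counts <- hit_count(community, rank = rank, taxon = taxon)
  names(counts)[counts > 0]
}

#' All per-taxon gene complements at a rank
#'
#' @inheritParams hit_table
#' @return Named list: taxon name -> character vector of symbols observed in
#'   that taxon's records (the `"unclassified"` pool excluded).
#' @export
complements_at_rank <- function(community, rank) {
  check_rank(rank)
  tbl <- hit_table(community, rank = rank)
  tbl <- tbl[tbl$taxon != "unclassified" & tbl$count > 0, ]
  split(tbl$symbol, tbl$taxon)
}

#' Write canonical annotation / taxonomy TSVs
#'
#' Inverse of [read_ko_table()] and [read_taxonomy_table()] (centrifuge
#' dialect): reading a canonical-dialect file and writing it back is
#' byte-identical.
#'
#' @param annotations,assignments Tibbles in canonical shape.
#' @param file Output path.
#' @export
write_ko_table <- function(annotations, file) {
  lines <- paste0(annotations$gene_id, "\t",
                  ifelse(is.na(annotations$ko), "", annotations$ko))
  readr::write_lines(lines, file)
  invisible(file)
}

#' @rdname write_ko_table
#' @export
write_taxonomy_table <- function(assignments, file) {
  lines <- paste0(assignments$contig_id, "\t", assignments$taxon_id, "\t",
                  assignments$lineage)
  readr::write_lines(lines, file)
  invisible(file)
}
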