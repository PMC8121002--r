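#' Fixed taxonomic rank vocabulary
#'
#' Lineages are slotted into this ordered vocabulary, domain first. Queries
#' at any other rank name are rejected.
#'
#' @return Character vector of the seven ranks.
#' @export
taxonomic_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

check_rank <- function(rank) {
  if (!is.character(rank) || length(rank) != 1L ||
      !rank %in% taxonomic_ranks()) {
    stop(sprintf("rank must be one of: %s",
                 paste(taxonomic_ranks(), collapse = ", ")), call. = FALSE)
  }
  rank
}

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimal places: ties go away
#' from zero (0.0145 -> 0.015 at 3 places), unlike [base::round()]'s
#' round-half-even. Used for all reported hit-number ratios.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (>= 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  stopifnot(is.numeric(digits), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # nudge by an ulp-scale epsilon so that decimal ties survive binary
  # representation (0.0145 * 1000 is stored fractionally below 14.5)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Parse lineage strings into ranked columns
#'
#' Splits semicolon-delimited (or `|`-delimited) lineage strings and slots
#' the tokens by position into the fixed rank vocabulary
#' ([taxonomic_ranks()]). Tokens carrying Kraken-style `x__` prefixes are
#' stripped. Truncated lineages leave deeper ranks `NA`; the sentinel
#' string `"unclassified"` (or an empty string treated as an error by the
#' readers) yields all-`NA` ranks. Lineages longer than seven ranks emit a
#' warning and keep the first seven tokens.
#'
#' @param lineage Character vector of lineage strings.
#' @return Tibble with one column per rank, `NA` where unassigned.
#' @export
parse_lineage <- function(lineage) {
  ranks <- taxonomic_ranks()
  rows <- lapply(lineage, function(x) {
    out <- rep(NA_character_, length(ranks))
    if (is.na(x) || !nzchar(trimws(x)) ||
        identical(tolower(trimws(x)), "unclassified")) {
      return(out)
    }
    tokens <- trimws(strsplit(x, "[;|]")[[1L]])
    tokens <- sub("^[a-z]__", "", tokens)
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) > length(ranks)) {
      warning(sprintf(
        "lineage '%s' has %d ranks; keeping the first %d (positional slotting)",
        x, length(tokens), length(ranks)), call. = FALSE)
      tokens <- tokens[seq_along(ranks)]
    }
    out[seq_along(tokens)] <- tokens
    out
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- ranks
  tibble::as_tibble(mat)
}

compose_lineage <- function(rank_tbl) {
  apply(as.matrix(rank_tbl), 1L, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) "unclassified" else paste(r, collapse = ";")
  })
}
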