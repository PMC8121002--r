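# shared fixtures and independent oracles

# the demonstration community is expensive enough to build once per run
.fixture_env <- new.env(parent = emptyenv())
get_demo <- function() {
  if (is.null(.fixture_env$demo)) .fixture_env$demo <- demo_community()
  .fixture_env$demo
}

# independent truth-table oracle: renders the requirement tree as a base-R
# logical expression over backticked symbol variables and eval()s it, so the
# evaluation engine (R's `&`/`|`) is not the recursive evaluator under test
expr_to_r_code <- function(expr) {
  if (expr$op == "leaf") return(sprintf("`%s`", expr$symbol))
  glue_op <- if (expr$op == "all") " & " else " | "
  paste0("(", paste(vapply(expr$children, expr_to_r_code, character(1)),
                    collapse = glue_op), ")")
}

oracle_eval <- function(expr, present) {
  syms <- expr_symbols(expr)
  env <- list2env(stats::setNames(as.list(syms %in% present), syms))
  eval(parse(text = expr_to_r_code(expr)), envir = env)
}

# random expression over the given symbols, bounded depth and leaf count
random_expr <- function(symbols, max_depth = 3) {
  if (max_depth == 0 || stats::runif(1) < 0.35) {
    return(req_gene(sample(symbols, 1L)))
  }
  n <- sample(1:3, 1L)
  kids <- replicate(n, random_expr(symbols, max_depth - 1L),
                    simplify = FALSE)
  if (stats::runif(1) < 0.5) do.call(req_all, kids) else
    do.call(req_any, kids)
}

all_subsets <- function(symbols) {
  n <- length(symbols)
  lapply(seq_len(2^n) - 1L, function(mask) {
    symbols[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
  })
}

# a minimal single-product catalog document
tiny_catalog_text <- function() {
  paste(
    "catalog_name: tiny",
    "genes:",
    "  - {symbol: gA, ko: K00001, ec: ['1.1.1.1'], name: enzyme A}",
    "products:",
    "  - product: widget",
    "    entry_metabolite: pyruvate",
    "    steps:",
    "      - {id: s1, substrate: pyruvate, product: widget, requires: gA}",
    sep = "\n")
}

# build an annotated community from in-memory tables by writing canonical
# TSVs and passing them through the package's own readers
community_from_tables <- function(ann, tax_lines,
                                  symbol_map = read_symbol_map()) {
  ann_file <- withr::local_tempfile(fileext = ".tsv",
                                    .local_envir = parent.frame())
  tax_file <- withr::local_tempfile(fileext = ".tsv",
                                    .local_envir = parent.frame())
  readr::write_lines(paste0(ann$gene_id, "\t",
                            ifelse(is.na(ann$ko), "", ann$ko)), ann_file)
  readr::write_lines(tax_lines, tax_file)
  join_community(read_ko_table(ann_file), read_taxonomy_table(tax_file),
                 symbol_map = symbol_map)
}

# random synthetic design against the default catalog: small counts so a
# full generate/parse/screen cycle stays well under a second
random_design <- function(catalog) {
  n_taxa <- sample(3:5, 1L)
  taxa <- tibble::tibble(
    name = sprintf("Synthetica species%02d", seq_len(n_taxa)),
    lineage = sprintf(
      "Bacteria;Synthphyla;Synthclass;Synthorder;Synthfamily;Synthetica;Synthetica species%02d",
      seq_len(n_taxa)),
    n_contigs = sample(1:4, n_taxa, replace = TRUE),
    background = sample(0:10, n_taxa, replace = TRUE))
  products <- sample(catalog_products(catalog), sample(2:4, 1L))
  complements <- lapply(seq_len(n_taxa), function(i) {
    per <- list()
    for (p in sample(products, sample(seq_along(products), 1L))) {
      syms <- product_symbols(catalog, p)
      per[[p]] <- if (stats::runif(1) < 0.4) "complete" else
        list(missing = sample(syms, sample(seq_along(syms), 1L)))
    }
    per
  })
  names(complements) <- taxa$name
  synthetic_design(
    taxa = taxa, complements = complements,
    count_model = list(family = "uniform", min = 1, max = 20),
    unclassified_fraction = stats::runif(1, 0, 0.3))
}
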