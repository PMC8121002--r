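#' Pathway catalogs
#'
#' A pathway catalog declares the functional genes (symbol, optional KEGG
#' Orthology id, EC numbers, enzyme name) and, per product, an ordered list
#' of reaction steps, each with a [req_expr] gene requirement. The packaged
#' default ([default_catalog()]) covers seven products: ectoine, PHB,
#' lutein, zeaxanthin, astaxanthin, acetoin and 2,3-butanediol, with the
#' terpenoid backbone encoded as mevalonate-route OR
#' methylerythritol-phosphate-route alternatives.
#'
#' @name pathway_catalog
NULL

ko_pattern <- "^K[0-9]{5}$"

new_gene_requirement <- function(symbol, ko = "", ec = character(),
                                 name = "") {
  if (!nzchar(symbol)) stop("gene symbol must be non-empty", call. = FALSE)
  if (nzchar(ko) && !grepl(ko_pattern, ko)) {
    stop(sprintf("gene '%s': malformed KO id '%s' (expected K + 5 digits)",
                 symbol, ko), call. = FALSE)
  }
  structure(list(symbol = symbol, ko = ko, ec = as.character(ec),
                 name = name),
            class = "gene_requirement")
}

new_reaction_step <- function(id, substrate, product, expr) {
  if (!nzchar(id)) stop("step id must be non-empty", call. = FALSE)
  if (!nzchar(substrate) || !nzchar(product)) {
    stop(sprintf("step '%s': substrate and product names must be non-empty",
                 id), call. = FALSE)
  }
  structure(list(id = id, substrate = substrate, product = product,
                 expr = expr),
            class = "reaction_step")
}

new_product_pathway <- function(product, entry_metabolite, steps,
                                notes = "") {
  if (length(steps) < 1L) {
    stop(sprintf("product '%s' needs at least one step", product),
         call. = FALSE)
  }
  ids <- vapply(steps, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("product '%s': duplicated step id '%s'", product,
                 ids[duplicated(ids)][1L]), call. = FALSE)
  }
  structure(list(product = product, entry_metabolite = entry_metabolite,
                 steps = steps, notes = notes),
            class = "product_pathway")
}

validate_catalog <- function(catalog) {
  symbols <- names(catalog$genes)
  if (anyDuplicated(symbols)) {
    stop(sprintf("duplicated gene symbol '%s' in catalog",
                 symbols[duplicated(symbols)][1L]), call. = FALSE)
  }
  prods <- vapply(catalog$products, `[[`, character(1), "product")
  if (anyDuplicated(prods)) {
    stop(sprintf("duplicated product '%s' in catalog",
                 prods[duplicated(prods)][1L]), call. = FALSE)
  }
  for (pw in catalog$products) {
    for (st in pw$steps) {
      missing <- setdiff(expr_symbols(st$expr), symbols)
      if (length(missing)) {
        stop(sprintf(
          "product '%s', step '%s': unresolved gene symbol '%s' (not declared under genes:)",
          pw$product, st$id, missing[1L]), call. = FALSE)
      }
    }
  }
  invisible(catalog)
}

#' Read a pathway catalog from its YAML document
#'
#' The schema is `genes:` (a list of `{symbol, ko, ec, name}` records) and
#' `products:` (each with `product`, `entry_metabolite`, optional `notes`,
#' and `steps:` of `{id, substrate, product, requires}` where `requires` is
#' a bare gene symbol or nested `all:` / `any:` lists). Every symbol used in
#' a requirement must be declared under `genes:`; product names and gene
#' symbols must be unique.
#'
#' @param file Path to a catalog document, or `NULL` when `text` is given.
#' @param text Catalog document as a single string (overrides `file`).
#' @return A validated `pathway_catalog`.
#' @seealso [default_catalog()], [write_catalog()], [pathway_complete()]
#' @export
read_catalog <- function(file = NULL, text = NULL) {
  doc <- tryCatch(
    if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(file),
    error = function(e) {
      stop(sprintf("catalog syntax error: %s", conditionMessage(e)),
           call. = FALSE)
    })
  if (!is.list(doc) || is.null(doc$genes) || is.null(doc$products)) {
    stop("catalog document must contain 'genes:' and 'products:' sections",
         call. = FALSE)
  }
  genes <- lapply(doc$genes, function(g) {
    if (is.null(g$symbol)) stop("gene record without a symbol", call. = FALSE)
    new_gene_requirement(g$symbol, ko = g$ko %||% "",
                         ec = g$ec %||% character(), name = g$name %||% "")
  })
  names(genes) <- vapply(genes, `[[`, character(1), "symbol")
  products <- lapply(doc$products, function(p) {
    if (is.null(p$product)) stop("product record without a name", call. = FALSE)
    steps <- lapply(p$steps, function(s) {
      new_reaction_step(
        id = as.character(s$id %||% ""),
        substrate = as.character(s$substrate %||% ""),
        product = as.character(s$product %||% ""),
        expr = expr_from_list(s$requires,
                              where = sprintf("product '%s', step '%s'",
                                              p$product, s$id %||% "?")))
    })
    new_product_pathway(p$product, p$entry_metabolite %||% "", steps,
                        notes = p$notes %||% "")
  })
  names(products) <- vapply(products, `[[`, character(1), "product")
  catalog <- structure(
    list(name = doc$catalog_name %||% "", genes = genes,
         products = products),
    class = "pathway_catalog")
  validate_catalog(catalog)
}

#' @rdname read_catalog
#' @param als_large_only If `TRUE`, relax the acetolactate-synthase step of
#'   acetoin and 2,3-butanediol to require the large subunit only (catabolic
#'   ALS enzymes can be single-subunit); the default additionally requires a
#'   small subunit (`E2.2.1.6S` or `ilvM`).
#' @export
default_catalog <- function(als_large_only = FALSE) {
  path <- system.file("extdata", "valuable_products_catalog.yaml",
                      package = "metascreen", mustWork = TRUE)
  catalog <- read_catalog(path)
  if (isTRUE(als_large_only)) {
    for (p in c("acetoin", "2,3-butanediol")) {
      ids <- vapply(catalog$products[[p]]$steps, `[[`, character(1), "id")
      catalog$products[[p]]$steps[[which(ids == "act1")]]$expr <-
        req_gene("E2.2.1.6L")
    }
  }
  catalog
}

#' Serialize a catalog back to its YAML document
#'
#' `catalog_to_yaml()` returns the document as a string; `write_catalog()`
#' writes it to a file. Re-reading the result yields an equivalent catalog.
#'
#' @param catalog A `pathway_catalog`.
#' @param file Output path.
#' @export
catalog_to_yaml <- function(catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  doc <- list(
    catalog_name = catalog$name,
    genes = unname(lapply(catalog$genes, function(g) {
      list(symbol = g$symbol, ko = g$ko, ec = as.list(g$ec), name = g$name)
    })),
    products = unname(lapply(catalog$products, function(p) {
      out <- list(product = p$product,
                  entry_metabolite = p$entry_metabolite)
      if (nzchar(p$notes)) out$notes <- p$notes
      out$steps <- lapply(p$steps, function(s) {
        list(id = s$id, substrate = s$substrate, product = s$product,
             requires = expr_to_list(s$expr))
      })
      out
    })))
  yaml::as.yaml(doc)
}

#' @rdname catalog_to_yaml
#' @export
write_catalog <- function(catalog, file) {
  writeLines(catalog_to_yaml(catalog), file)
  invisible(file)
}

#' Catalog accessors
#'
#' @param catalog A `pathway_catalog`.
#' @param product Product name.
#' @return `catalog_products()`: character vector of product names;
#'   `catalog_symbols()`: declared gene symbols; `product_symbols()`: the
#'   unique gene symbols referenced by one product's step requirements.
#' @export
catalog_products <- function(catalog) names(catalog$products)

#' @rdname catalog_products
#' @export
catalog_symbols <- function(catalog) names(catalog$genes)

#' @rdname catalog_products
#' @export
product_symbols <- function(catalog, product) {
  pw <- get_product(catalog, product)
  unique(unlist(lapply(pw$steps, function(s) expr_symbols(s$expr))))
}

get_product <- function(catalog, product) {
  pw <- catalog$products[[product]]
  if (is.null(pw)) {
    stop(sprintf("unknown product '%s' (catalog has: %s)", product,
                 paste(names(catalog$products), collapse = ", ")),
         call. = FALSE)
  }
  pw
}

#' Is a biosynthesis pathway complete for an observed gene complement?
#'
#' A pathway is complete when every reaction step's gene requirement is
#' satisfied by the observed symbols — the gene complement carries a full
#' set of functional genes from the entry metabolite to the product.
#'
#' @param pathway A `product_pathway` (an element of `catalog$products`).
#' @param present Character vector of observed gene symbols.
#' @return List with `complete` (logical) and `missing_steps` (character
#'   vector of step ids whose requirement is unsatisfied; empty iff
#'   complete).
#' @examples
#' cat <- default_catalog()
#' pathway_complete(cat$products$PHB, c("phaA", "phaB", "phaC"))
#' @export
pathway_complete <- function(pathway, present) {
  stopifnot(inherits(pathway, "product_pathway"))
  ok <- vapply(pathway$steps, function(s) evaluate_expr(s$expr, present),
               logical(1))
  ids <- vapply(pathway$steps, `[[`, character(1), "id")
  list(complete = all(ok), missing_steps = ids[!ok])
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat(sprintf("<pathway_catalog> %s\n", x$name))
  cat(sprintf("  %d products, %d genes\n", length(x$products),
              length(x$genes)))
  for (p in x$products) {
    cat(sprintf("  - %s (%d steps, entry: %s)\n", p$product,
                length(p$steps), p$entry_metabolite))
  }
  invisible(x)
}

#' @export
print.product_pathway <- function(x, ...) {
  cat(sprintf("<product_pathway> %s (entry: %s)\n", x$product,
              x$entry_metabolite))
  for (s in x$steps) {
    cat(sprintf("  %s: %s -> %s   [%s]\n", s$id, s$substrate, s$product,
                format_expr(s$expr)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
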