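#' Gene-requirement expressions
#'
#' A requirement expression encodes which functional genes are needed for a
#' reaction step (or a whole route) as a boolean tree: a leaf names one gene
#' symbol; `req_all()` is a conjunction (every child required); `req_any()` is
#' a disjunction (alternative genes or alternative routes, such as the MVA vs
#' MEP terpenoid-backbone pathways). Completeness of a step then reduces to
#' evaluating the tree against the set of gene symbols observed in a
#' community or in one taxon.
#'
#' @param symbol Gene symbol string (e.g. `"ectA"`).
#' @param ... Child expressions, or bare strings which are promoted to leaves.
#' @return A `req_expr` object.
#' @examples
#' e <- req_all("lysC", "asd", "ectB", "ectA", "ectC")
#' evaluate_expr(e, c("lysC", "asd", "ectB", "ectA", "ectC"))
#' @name req_expr
NULL

#' @rdname req_expr
#' @export
req_gene <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nzchar(symbol))
  structure(list(op = "leaf", symbol = symbol), class = "req_expr")
}

new_node <- function(op, children) {
  children <- lapply(children, function(x) {
    if (is.character(x)) return(req_gene(x))
    if (!inherits(x, "req_expr")) {
      stop("requirement children must be req_expr objects or symbol strings",
           call. = FALSE)
    }
    x
  })
  if (length(children) < 1L) {
    stop(sprintf("'%s' node needs at least one child", op), call. = FALSE)
  }
  structure(list(op = op, children = children), class = "req_expr")
}

#' @rdname req_expr
#' @export
req_all <- function(...) new_node("all", list(...))

#' @rdname req_expr
#' @export
req_any <- function(...) new_node("any", list(...))

#' Evaluate a requirement expression against observed genes
#'
#' @param expr A [req_expr] tree.
#' @param present Character vector of gene symbols observed (with at least
#'   one annotated hit) in the gene complement being tested.
#' @param known Optional character vector of symbols declared in the owning
#'   catalog; when supplied, a leaf outside it raises an error rather than
#'   silently evaluating to `FALSE`.
#' @return Single logical: `TRUE` iff the expression is satisfied.
#' @export
evaluate_expr <- function(expr, present, known = NULL) {
  stopifnot(inherits(expr, "req_expr"))
  present <- as.character(present)
  switch(expr$op,
    leaf = {
      if (!is.null(known) && !expr$symbol %in% known) {
        stop(sprintf("unknown gene symbol in expression: '%s'", expr$symbol),
             call. = FALSE)
      }
      expr$symbol %in% present
    },
    all = all(vapply(expr$children, evaluate_expr, logical(1),
                     present = present, known = known)),
    any = any(vapply(expr$children, evaluate_expr, logical(1),
                     present = present, known = known)),
    stop("corrupt expression node", call. = FALSE)
  )
}

#' List the gene symbols referenced by an expression
#'
#' @inheritParams evaluate_expr
#' @return Character vector of unique leaf symbols, in first-appearance order.
#' @export
expr_symbols <- function(expr) {
  stopifnot(inherits(expr, "req_expr"))
  if (expr$op == "leaf") return(expr$symbol)
  unique(unlist(lapply(expr$children, expr_symbols)))
}

#' Gene symbols actively required given an observed complement
#'
#' Prunes the expression against `present`: an `any` node with at least one
#' satisfied alternative contributes only the leaves of its satisfied
#' branches (an unused alternative route is not "required"); an unsatisfied
#' `any` node, and every `all` node, contribute all their leaves. The result
#' is the gene set over which rate-limiting extremes are meaningful: when the
#' expression is satisfied, every active symbol is present.
#'
#' @inheritParams evaluate_expr
#' @return Character vector of active leaf symbols.
#' @export
active_symbols <- function(expr, present) {
  stopifnot(inherits(expr, "req_expr"))
  present <- as.character(present)
  if (expr$op == "leaf") return(expr$symbol)
  kids <- expr$children
  if (expr$op == "any") {
    sat <- vapply(kids, evaluate_expr, logical(1), present = present)
    if (any(sat)) kids <- kids[sat]
  }
  unique(unlist(lapply(kids, active_symbols, present = present)))
}

format_expr <- function(expr) {
  switch(expr$op,
    leaf = expr$symbol,
    all = paste0("ALL(", paste(vapply(expr$children, format_expr,
                                      character(1)), collapse = ", "), ")"),
    any = paste0("ANY(", paste(vapply(expr$children, format_expr,
                                      character(1)), collapse = ", "), ")")
  )
}

#' @export
format.req_expr <- function(x, ...) format_expr(x)

#' @export
print.req_expr <- function(x, ...) {
  cat(format_expr(x), "\n")
  invisible(x)
}

# expression <-> plain list (for the YAML catalog schema)
expr_to_list <- function(expr) {
  switch(expr$op,
    leaf = expr$symbol,
    all = list(all = lapply(expr$children, expr_to_list)),
    any = list(any = lapply(expr$children, expr_to_list))
  )
}

expr_from_list <- function(x, where = "requirement") {
  if (is.character(x) && length(x) == 1L) return(req_gene(x))
  if (is.list(x) && length(x) == 1L && !is.null(names(x))) {
    op <- names(x)
    kids <- x[[1L]]
    if (op %in% c("all", "any")) {
      if (is.character(kids)) kids <- as.list(kids)
      if (!is.list(kids) || length(kids) == 0L) {
        stop(sprintf("%s: '%s' needs a non-empty list of children",
                     where, op), call. = FALSE)
      }
      children <- lapply(kids, expr_from_list, where = where)
      return(new_node(op, children))
    }
  }
  stop(sprintf(
    "%s: cannot parse requirement (expected a symbol string or one all:/any: mapping)",
    where), call. = FALSE)
}
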