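#' Run the full screening workflow and write reports
#'
#' Ties the stages together: read the annotation and taxonomy tables,
#' join them with the symbol map, screen every catalog product, and write
#' four TSV reports plus a machine-readable run manifest to `out_dir`:
#' \describe{
#'   \item{`classification.tsv`}{product-by-source presence/absence matrix
#'     (mixed culture `+`/`-`, single-producer lineages and taxa).}
#'   \item{`hit_profiles.tsv`}{per product, step and gene: hit counts and
#'     step totals.}
#'   \item{`ratios.tsv`}{per product: min/max genes, rate-limiting ratio,
#'     defined flag.}
#'   \item{`abundance.tsv`}{relative abundances at the screening rank,
#'     truncated to `top_n`.}
#' }
#' `run_manifest.json` logs the package version, input digests and all
#' parameters, so a run is reproducible from its manifest. Reports contain
#' no timestamps and are byte-identical across reruns on identical inputs.
#'
#' @param annotations Path to the gene-to-KO TSV.
#' @param taxonomy Path to the contig taxonomy TSV.
#' @param out_dir Output directory (created if needed).
#' @param catalog A `pathway_catalog`, a path to a catalog YAML, or `NULL`
#'   for the packaged default.
#' @param rank Rank for single-taxon screening and abundances.
#' @param top_n Abundance rows kept.
#' @param digits Rounding places for ratios (>= 1).
#' @param dialect_annotations,dialect_taxonomy Input dialects (see
#'   [read_ko_table()], [read_taxonomy_table()]).
#' @param symbol_map Path to a KO-to-symbol map TSV, or `NULL` for the
#'   packaged default.
#' @return Invisibly, a list with the screening result, profiles, ratio
#'   and abundance tables, and the report paths.
#' @export
run_screen <- function(annotations, taxonomy, out_dir,
                       catalog = NULL, rank = "species", top_n = 50,
                       digits = 3,
                       dialect_annotations = "two-column",
                       dialect_taxonomy = "centrifuge",
                       symbol_map = NULL) {
  if (digits < 1) stop("digits must be >= 1", call. = FALSE)
  catalog <- resolve_catalog(catalog)
  for (f in c(annotations, taxonomy)) {
    if (!file.exists(f)) stop(sprintf("input file not found: %s", f),
                              call. = FALSE)
  }
  message(sprintf("reading annotations from %s", annotations))
  ann <- read_ko_table(annotations, dialect = dialect_annotations)
  message(sprintf("reading taxonomy from %s", taxonomy))
  tax <- read_taxonomy_table(taxonomy, dialect = dialect_taxonomy)
  map <- read_symbol_map(symbol_map)
  community <- join_community(ann, tax, symbol_map = map)
  message(sprintf("joined %d gene records (%d KO-annotated)",
                  community$stats$n_genes, community$stats$n_annotated))
  result <- screen_community(catalog, community, rank = rank)
  profiles <- dplyr::bind_rows(lapply(catalog_products(catalog),
                                      function(p) {
    prof <- hit_profile(catalog, community, p)
    pw <- get_product(catalog, p)
    dplyr::bind_rows(lapply(pw$steps, function(s) {
      genes <- expr_symbols(s$expr)
      tibble::tibble(product = p, step = s$id, gene = genes,
                     count = as.numeric(prof$per_gene[genes]),
                     step_count = as.numeric(prof$per_step[[s$id]]))
    }))
  }))
  ratios <- ratio_summary(catalog, community, digits = digits)
  abundance <- relative_abundance(community, rank = rank, top_n = top_n)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(classification = file.path(out_dir, "classification.tsv"),
             hit_profiles = file.path(out_dir, "hit_profiles.tsv"),
             ratios = file.path(out_dir, "ratios.tsv"),
             abundance = file.path(out_dir, "abundance.tsv"),
             manifest = file.path(out_dir, "run_manifest.json"))
  readr::write_tsv(classification_matrix(result), paths[["classification"]],
                   progress = FALSE)
  readr::write_tsv(profiles, paths[["hit_profiles"]], progress = FALSE)
  readr::write_tsv(ratios, paths[["ratios"]], progress = FALSE)
  readr::write_tsv(abundance, paths[["abundance"]], progress = FALSE)
  write_run_manifest(paths[["manifest"]], list(
    tool = "metascreen",
    version = as.character(utils::packageVersion("metascreen")),
    command = "screen",
    inputs = list(
      annotations = input_digest(annotations),
      taxonomy = input_digest(taxonomy)),
    params = list(rank = rank, top_n = top_n, digits = digits,
                  dialect_annotations = dialect_annotations,
                  dialect_taxonomy = dialect_taxonomy)))
  message(sprintf("reports written to %s", out_dir))
  invisible(list(result = result, profiles = profiles, ratios = ratios,
                 abundance = abundance, paths = paths))
}

resolve_catalog <- function(catalog) {
  if (is.null(catalog)) return(default_catalog())
  if (inherits(catalog, "pathway_catalog")) return(catalog)
  if (is.character(catalog)) return(read_catalog(catalog))
  stop("catalog must be NULL, a pathway_catalog, or a file path",
       call. = FALSE)
}

input_digest <- function(path) {
  list(path = path, md5 = unname(tools::md5sum(path)),
       bytes = file.size(path))
}

write_run_manifest <- function(path, manifest) {
  writeLines(jsonlite_or_yaml(manifest), path)
}

# jsonlite is a light runtime convenience; fall back to YAML if absent
jsonlite_or_yaml <- function(x) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::as.yaml(x)
  }
}

#' Read a synthetic-community design document
#'
#' YAML schema: `taxa:` (list of `{name, lineage, weight, n_contigs,
#' background}`), `complements:` (taxon -> product -> `complete` or
#' `{missing: [symbols]}`), optional `count_model:` (`{family, min, max}`)
#' and `unclassified_fraction`.
#'
#' @param file Path to the design YAML.
#' @return A [synthetic_design()].
#' @export
read_design <- function(file) {
  doc <- yaml::read_yaml(file)
  if (is.null(doc$taxa)) stop("design needs a 'taxa:' section",
                              call. = FALSE)
  taxa <- dplyr::bind_rows(lapply(doc$taxa, function(t) {
    tibble::tibble(name = t$name, lineage = t$lineage,
                   weight = t$weight %||% 1,
                   n_contigs = as.integer(t$n_contigs %||% 3L),
                   background = as.integer(t$background %||% 0L))
  }))
  complements <- lapply(doc$complements %||% list(), function(per_taxon) {
    lapply(per_taxon, function(spec) {
      if (identical(spec, "complete")) "complete"
      else list(missing = as.character(spec$missing))
    })
  })
  cm <- doc$count_model %||% list(family = "log-uniform", min = 50,
                                  max = 15000)
  synthetic_design(taxa = taxa, complements = complements,
                   count_model = cm,
                   unclassified_fraction =
                     doc$unclassified_fraction %||% 0)
}

#' Generate a synthetic bundle from a design file and write it out
#'
#' @param design Path to a design YAML, or a `synthetic_design`.
#' @param out_dir Output directory for `annotations.tsv`, `taxonomy.tsv`
#'   and `manifest.yaml`.
#' @param catalog Catalog (as in [run_screen()]).
#' @param seed Integer seed (logged in the manifest).
#' @return Invisibly, the generated `synthetic_bundle`.
#' @export
run_simulate <- function(design, out_dir, catalog = NULL, seed = 1L) {
  catalog <- resolve_catalog(catalog)
  if (is.character(design)) design <- read_design(design)
  bundle <- generate_community(design, catalog, seed = seed)
  write_bundle(bundle, out_dir)
  message(sprintf("bundle written to %s (seed %d, %d records)", out_dir,
                  seed, bundle$manifest$n_records))
  invisible(bundle)
}
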