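simple_design <- function(unclassified_fraction = 0) {
  synthetic_design(
    taxa = tibble::tibble(
      name = c("Alpha producer", "Beta half", "Gamma half"),
      lineage = sprintf("Bacteria;P;C;O;F;G;%s",
                        c("Alpha producer", "Beta half", "Gamma half")),
      n_contigs = c(3L, 2L, 2L),
      background = c(5L, 0L, 2L)),
    complements = list(
      "Alpha producer" = list(PHB = "complete"),
      "Beta half" = list(ectoine = list(missing = c("ectA", "ectC"))),
      "Gamma half" = list(ectoine = list(missing = c("lysC", "asd",
                                                     "ectB")))),
    count_model = list(family = "uniform", min = 1, max = 15),
    unclassified_fraction = unclassified_fraction)
}

test_that("designs are validated against the catalog", {
  cat <- default_catalog()
  taxa <- tibble::tibble(name = "A", lineage = "Bacteria;P;C;O;F;G;A")
  expect_error(
    generate_community(synthetic_design(
      taxa, complements = list(A = list(unobtainium = "complete"))), cat),
    "unknown product 'unobtainium'")
  expect_error(
    generate_community(synthetic_design(
      taxa, complements = list(A = list(PHB = list(missing = "xyzQ")))),
      cat),
    "unknown symbol 'xyzQ'")
  expect_error(synthetic_design(taxa, unclassified_fraction = 1),
               "unclassified_fraction")
  expect_error(synthetic_design(dplyr::bind_rows(taxa, taxa)), "unique")
  expect_error(
    synthetic_design(taxa, count_model = list(family = "poisson",
                                              min = 1, max = 2)),
    "count_model")
})

test_that("generation is byte-identical for a fixed design and seed", {
  d <- simple_design(unclassified_fraction = 0.2)
  cat <- default_catalog()
  b1 <- generate_community(d, cat, seed = 11)
  b2 <- generate_community(d, cat, seed = 11)
  expect_identical(b1$annotation_lines, b2$annotation_lines)
  expect_identical(b1$taxonomy_lines, b2$taxonomy_lines)
  expect_identical(b1$manifest, b2$manifest)
  b3 <- generate_community(d, cat, seed = 12)
  expect_false(identical(b1$annotation_lines, b3$annotation_lines))
})

test_that("generation does not disturb the session RNG stream", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(generate_community(simple_design(), default_catalog(),
                               seed = 5))
  expect_identical(stats::runif(1), before)
})

test_that("a designed single producer and a designed split are recovered", {
  cat <- default_catalog()
  bundle <- generate_community(simple_design(), cat, seed = 3)
  res <- screen_community(cat, bundle_community(bundle))
  expect_identical(res$classification[res$product == "PHB"],
                   "SINGLE_MICROBE")
  expect_identical(res$single_producers[[which(res$product == "PHB")]]$taxon,
                   "Alpha producer")
  expect_identical(res$classification[res$product == "ectoine"],
                   "MIXED_COMMUNITY")
  expect_identical(res$classification[res$product == "lutein"], "NONE")
  # MISSING symbols are never emitted for their taxon
  expect_identical(
    unname(hit_count(bundle_community(bundle), "ectA", rank = "species",
                     taxon = "Beta half")), 0)
})

test_that("parsing an emitted bundle recovers the manifest exactly", {
  cat <- default_catalog()
  bundle <- generate_community(simple_design(unclassified_fraction = 0.25),
                               cat, seed = 21)
  comm <- bundle_community(bundle)
  m <- bundle$manifest
  # community counts
  counts <- hit_count(comm)
  for (i in seq_len(nrow(m$community_counts))) {
    expect_identical(unname(counts[m$community_counts$symbol[i]]),
                     as.numeric(m$community_counts$count[i]))
  }
  # per-species counts, including records displaced to 'unclassified'
  tbl <- hit_table(comm, rank = "species")
  tbl <- tbl[tbl$count > 0, ]
  expect_identical(
    dplyr::arrange(tbl, .data$symbol, .data$taxon)$count,
    as.numeric(dplyr::arrange(
      dplyr::rename(m$taxon_counts, taxon = "species"),
      .data$symbol, .data$taxon)$count))
  # abundances
  ab <- relative_abundance(comm, "species")
  for (i in seq_len(nrow(m$abundance))) {
    expect_identical(ab$fraction[ab$taxon == m$abundance$species[i]],
                     m$abundance$fraction[i])
  }
  # classifications
  res <- screen_community(cat, comm)
  expect_identical(res$classification, m$classification$classification)
})

test_that("the generator can realize all three cases for any product", {
  cat <- default_catalog()
  pivots <- c(ectoine = "ectA", zeaxanthin = "crtZ",
              "2,3-butanediol" = "E2.2.1.6L")   # each essential to its product
  for (product in names(pivots)) {
    syms <- product_symbols(cat, product)
    pivot <- pivots[[product]]
    lin <- function(n) sprintf("Bacteria;P;C;O;F;G;%s", n)
    one <- synthetic_design(
      taxa = tibble::tibble(name = "Owner", lineage = lin("Owner")),
      complements = list(Owner = stats::setNames(list("complete"),
                                                 product)),
      count_model = list(family = "uniform", min = 1, max = 5))
    split2 <- synthetic_design(
      taxa = tibble::tibble(name = c("Left", "Right"),
                            lineage = lin(c("Left", "Right"))),
      complements = stats::setNames(list(
        stats::setNames(list(list(missing = pivot)), product),
        stats::setNames(list(list(missing = setdiff(syms, pivot))),
                        product)),
        c("Left", "Right")),
      count_model = list(family = "uniform", min = 1, max = 5))
    nobody <- synthetic_design(
      taxa = tibble::tibble(name = "Empty", lineage = lin("Empty"),
                            background = 4L))
    got <- vapply(list(one, split2, nobody), function(d) {
      res <- suppressWarnings(screen_community(
        cat, bundle_community(generate_community(d, cat, seed = 2))))
      res$classification[res$product == product]
    }, character(1))
    expect_identical(got, c("SINGLE_MICROBE", "MIXED_COMMUNITY", "NONE"),
                     info = product)
  }
})

test_that("random designs round-trip their manifests end to end", {
  cat <- default_catalog()
  set.seed(601)
  designs <- replicate(5, random_design(cat), simplify = FALSE)
  for (i in seq_along(designs)) {
    for (seed in 1:2) {
      bundle <- generate_community(designs[[i]], cat, seed = seed)
      comm <- bundle_community(bundle)
      res <- suppressWarnings(screen_community(cat, comm))
      expect_identical(res$classification,
                       bundle$manifest$classification$classification,
                       info = sprintf("design %d seed %d", i, seed))
      counts <- hit_count(comm)
      m <- bundle$manifest$community_counts
      expect_identical(unname(counts[m$symbol]), as.numeric(m$count),
                       info = sprintf("design %d seed %d", i, seed))
    }
  }
})
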