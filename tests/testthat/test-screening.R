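# hand-built five-taxon community: one species owns a complete PHB set,
# ectoine genes are split so only the pooled community completes them, and
# no lutein-specific gene occurs anywhere
small_screen_community <- function() {
  ann <- tibble::tibble(
    gene_id = c("c1_1", "c1_2", "c1_3",          # S1: phaA phaB phaC
                "c2_1", "c2_2", "c2_3",          # S2: lysC asd ectB
                "c3_1", "c3_2",                  # S3: ectA ectC
                "c4_1"),                         # S4: lysC only
    ko = c("K00626", "K00023", "K03821",
           "K00928", "K00133", "K00836",
           "K06718", "K06720",
           "K00928"))
  tax <- c("c1\tT1\tBacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae;Methyloceanibacter;Methyloceanibacter caenitepidi",
           "c2\tT2\tBacteria;P;C;O;F;G;Ectoine splitter one",
           "c3\tT3\tBacteria;P;C;O;F;G;Ectoine splitter two",
           "c4\tT4\tBacteria;P;C;O;F;G;Bystander")
  community_from_tables(ann, tax)
}

test_that("screening classifies Case I, II and III with their invariants", {
  cat <- default_catalog()
  res <- screen_community(cat, small_screen_community())
  row <- function(p) res[res$product == p, ]
  phb <- row("PHB")
  expect_identical(phb$classification, "SINGLE_MICROBE")
  expect_identical(phb$single_producers[[1]]$taxon,
                   "Methyloceanibacter caenitepidi")
  expect_match(phb$single_producers[[1]]$lineage, "Alphaproteobacteria")
  ect <- row("ectoine")
  expect_identical(ect$classification, "MIXED_COMMUNITY")
  expect_true(ect$community_complete)
  expect_identical(ect$n_single_producers, 0L)
  lut <- row("lutein")
  expect_identical(lut$classification, "NONE")
  expect_false(lut$community_complete)
  expect_true(length(lut$missing_steps[[1]]) > 0)
  # exactly one class per product, and the class-specific implications
  expect_true(all(res$classification %in%
                    c("SINGLE_MICROBE", "MIXED_COMMUNITY", "NONE")))
  expect_true(all(res$community_complete[res$classification ==
                                           "SINGLE_MICROBE"]))
  expect_true(all(res$n_single_producers[res$classification ==
                                           "MIXED_COMMUNITY"] == 0L))
  expect_true(all(!res$community_complete[res$classification == "NONE"]))
})

test_that("removing one required gene demotes a single producer", {
  cat <- default_catalog()
  ann <- tibble::tibble(
    gene_id = c("c1_1", "c1_2", "c1_3", "c2_1"),
    ko = c("K00626", "K00023", "K03821", "K03821"))
  tax <- c("c1\tT1\tBacteria;P;C;O;F;G;Producer",
           "c2\tT2\tBacteria;P;C;O;F;G;Helper")
  full <- screen_community(cat, community_from_tables(ann, tax))
  expect_identical(full$classification[full$product == "PHB"],
                   "SINGLE_MICROBE")
  # drop the producer's phaB record: the union still has phaA, phaC from
  # elsewhere? no phaB remains anywhere, so PHB falls to NONE
  demoted <- screen_community(cat, community_from_tables(ann[-2, ], tax))
  expect_identical(demoted$classification[demoted$product == "PHB"], "NONE")
  # drop only the producer's phaC: the helper still supplies it pooled
  mixed <- screen_community(cat, community_from_tables(ann[-3, ], tax))
  expect_identical(mixed$classification[mixed$product == "PHB"],
                   "MIXED_COMMUNITY")
})

test_that("an empty community warns and classifies everything NONE", {
  ann <- tibble::tibble(gene_id = "c1_1", ko = NA_character_)
  comm <- community_from_tables(ann, "c1\tT1\tBacteria;P;C;O;F;G;S1")
  expect_warning(res <- screen_community(default_catalog(), comm),
                 "no annotated genes")
  expect_true(all(res$classification == "NONE"))
})

test_that("hit-profile extremes match a brute-force scan", {
  cat <- default_catalog()
  demo <- get_demo()
  set.seed(501)
  for (p in c("ectoine", "PHB", "acetoin")) {
    prof <- hit_profile(cat, demo$community, p)
    act <- prof$per_gene[prof$active]
    expect_identical(unname(act[prof$min_gene]), min(act))
    expect_identical(unname(act[prof$max_gene]), max(act))
  }
  # random counts against an exhaustive scan, via a designed community
  for (i in 1:5) {
    counts <- sample(1:500, 5)
    design <- synthetic_design(
      taxa = tibble::tibble(name = "Solo species",
                            lineage = "Bacteria;P;C;O;F;G;Solo species"),
      counts = tibble::tibble(
        taxon = "Solo species",
        symbol = c("lysC", "asd", "ectB", "ectA", "ectC"),
        count = counts))
    comm <- bundle_community(generate_community(design, cat, seed = i))
    prof <- hit_profile(cat, comm, "ectoine")
    expect_identical(unname(prof$per_gene[prof$min_gene]),
                     as.numeric(min(counts)))
    expect_identical(unname(prof$per_gene[prof$max_gene]),
                     as.numeric(max(counts)))
  }
})

test_that("uniform counts tie-break lexicographically", {
  cat <- default_catalog()
  design <- synthetic_design(
    taxa = tibble::tibble(name = "Solo species",
                          lineage = "Bacteria;P;C;O;F;G;Solo species"),
    counts = tibble::tibble(
      taxon = "Solo species",
      symbol = c("phaA", "phaB", "phaC"), count = c(5L, 5L, 5L)))
  comm <- bundle_community(generate_community(design, cat, seed = 1))
  prof <- hit_profile(cat, comm, "PHB")
  expect_identical(prof$min_gene, "phaA")
  expect_identical(prof$max_gene, "phaA")
  r <- rate_limiting_ratio(prof)
  expect_identical(r$ratio, 1)
})

test_that("rate-limiting ratios reproduce the worked examples", {
  demo <- get_demo()
  ect <- rate_limiting_ratio(hit_profile(demo$catalog, demo$community,
                                         "ectoine"))
  expect_identical(ect$ratio, 0.014)
  expect_identical(ect$min_gene, "ectA")
  expect_identical(ect$max_gene, "lysC")
  phb <- hit_profile(demo$catalog, demo$community, "PHB")
  expect_identical(rate_limiting_ratio(phb)$ratio, 0.171)
  expect_identical(pairwise_ratio(phb, "phaA", "phaC"), 0.175)
  expect_identical(pairwise_ratio(phb, "phaB", "phaB"), 1)
})

test_that("ratios are scale-invariant and bounded", {
  cat <- default_catalog()
  set.seed(502)
  base_counts <- sample(1:300, 5)
  mk <- function(k) {
    design <- synthetic_design(
      taxa = tibble::tibble(name = "Solo species",
                            lineage = "Bacteria;P;C;O;F;G;Solo species"),
      counts = tibble::tibble(
        taxon = "Solo species",
        symbol = c("lysC", "asd", "ectB", "ectA", "ectC"),
        count = base_counts * k))
    bundle_community(generate_community(design, cat, seed = 7))
  }
  r1 <- rate_limiting_ratio(hit_profile(cat, mk(1L), "ectoine"), digits = 6)
  for (k in c(2L, 13L)) {
    rk <- rate_limiting_ratio(hit_profile(cat, mk(k), "ectoine"),
                              digits = 6)
    expect_identical(rk$ratio, r1$ratio)
  }
  expect_true(r1$ratio > 0 && r1$ratio <= 1)
  expect_identical(r1$ratio == 1, min(base_counts) == max(base_counts))
})

test_that("a zero-hit required gene yields an undefined ratio, not zero", {
  cat <- default_catalog()
  demo <- get_demo()
  lut <- rate_limiting_ratio(hit_profile(cat, demo$community, "lutein"))
  expect_false(lut$defined)
  expect_true(is.na(lut$ratio))
  # but an unused alternative route does not poison the ratio
  zea <- rate_limiting_ratio(hit_profile(cat, demo$community, "zeaxanthin"))
  expect_true(zea$defined)
  expect_identical(zea$ratio, 0.11)
  expect_false("mvaS" %in% hit_profile(cat, demo$community,
                                       "zeaxanthin")$active)
})

test_that("pairwise ratio rejects unknown genes and zero denominators", {
  demo <- get_demo()
  phb <- hit_profile(demo$catalog, demo$community, "PHB")
  expect_error(pairwise_ratio(phb, "lysC", "phaC"), "not in the PHB")
  lut <- hit_profile(demo$catalog, demo$community, "lutein")
  expect_error(pairwise_ratio(lut, "crtB", "lcyE"), "zero hits")
})

test_that("rounding is half away from zero", {
  expect_identical(round_half_up(0.0145, 3), 0.015)
  expect_identical(round_half_up(0.1745, 3), 0.175)
  expect_identical(round_half_up(-0.0145, 3), -0.015)
  expect_identical(round_half_up(1.333333, 1), 1.3)
  expect_identical(round_half_up(177 / 12563, 3), 0.014)
  expect_identical(round_half_up(2476 / 14491, 3), 0.171)
  expect_identical(round_half_up(2532 / 14491, 3), 0.175)
})

test_that("relative abundance fractions are exact and sum to one", {
  ann <- tibble::tibble(gene_id = sprintf("c%d_1", 1:10),
                        ko = rep(NA_character_, 10))
  tax <- c(sprintf("c%d\tT1\tBacteria;P;C;O;F;G;Majority", 1:6),
           sprintf("c%d\tT2\tBacteria;P;C;O;F;G;Minority", 7:9))
  comm <- community_from_tables(ann, tax)   # c10 left unclassified
  ab <- relative_abundance(comm, "species")
  expect_identical(ab$fraction[ab$taxon == "Majority"], 0.6)
  expect_identical(ab$fraction[ab$taxon == "Minority"], 0.3)
  expect_identical(ab$fraction[ab$taxon == "unclassified"], 0.1)
  expect_equal(sum(ab$fraction), 1, tolerance = 1e-9)
  # single-taxon community
  solo <- community_from_tables(
    tibble::tibble(gene_id = "c1_1", ko = NA_character_),
    "c1\tT1\tBacteria;P;C;O;F;G;Solo")
  expect_identical(relative_abundance(solo, "species")$fraction, 1)
})

test_that("top-n truncation adds a remainder row and keeps the total", {
  demo <- get_demo()
  ab <- relative_abundance(demo$community, "species", top_n = 3)
  expect_identical(ab$taxon[1], "Methyloceanibacter caenitepidi")
  expect_identical(ab$taxon[2], "Rhodopseudomonas palustris")
  expect_true("other" %in% ab$taxon)
  expect_equal(sum(ab$fraction), 1, tolerance = 1e-9)
  expect_identical(ab$fraction[1], 0.012)
  expect_identical(ab$fraction[2], 0.009)
  expect_identical(
    abundance_ratio(ab, "Methyloceanibacter caenitepidi",
                    "Rhodopseudomonas palustris"), 1.3)
})

test_that("the classification matrix mirrors the screening result", {
  demo <- get_demo()
  res <- screen_community(demo$catalog, demo$community)
  mat <- classification_matrix(res)
  expect_identical(names(mat), c("product", "mixed_culture", "lineage",
                                 "species"))
  expect_identical(sum(mat$mixed_culture == "+"), 6L)
  expect_identical(mat$mixed_culture[mat$product == "lutein"], "-")
  expect_match(mat$species[mat$product == "PHB"], "Methyloceanibacter")
  expect_identical(mat$species[mat$product == "ectoine"], "-")
})
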