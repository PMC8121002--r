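Package: metascreen
Title: Gene-Centric Screening of Metagenomes for Biosynthetic Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-centric screening of shotgun-metagenome annotations for the
    genetic potential to synthesize valuable products (ectoine,
    polyhydroxybutyrate, carotenoids, acetoin, 2,3-butanediol) in mixed
    microbial communities such as activated sludge. Joins KEGG Orthology
    gene annotations with contig-level taxonomy, evaluates boolean
    gene-requirement expressions for pathway completeness at the community
    and single-taxon level, classifies each product as producible by a
    single taxon, only by the pooled community, or by nobody, and flags
    candidate rate-limiting steps from per-gene hit-number ratios. Includes
    a ground-truth synthetic community generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
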