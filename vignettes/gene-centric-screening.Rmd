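---
title: "Gene-centric screening of metagenomes for biosynthetic potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric screening of metagenomes for biosynthetic potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metascreen)
```

## The screening problem

Engineered microbial systems — activated sludge treating landfill leachate,
methanol-fed denitrifying reactors, and similar mixed-culture bioprocesses —
harbor large, mostly uncultured communities whose genetic repertoire may
already contain everything needed to synthesize industrially valuable
compounds: the compatible solute ectoine, the biodegradable polyester
polyhydroxybutyrate (PHB), carotenoids such as zeaxanthin and astaxanthin,
and the platform chemicals acetoin and 2,3-butanediol. Before investing in
enrichment, isolation, or process retrofits, an engineer wants a cheap
primary screen: *does anything in this biomass carry a complete biosynthesis
gene set for product X — and if so, does a single organism carry it, or
only the community as a whole?*

`metascreen` implements that screen gene-centrically, i.e. without genome
binning. Its inputs are the two tables a standard shotgun-metagenome
workflow already produces: a gene-to-KEGG-Orthology (KO) annotation table
(GhostKOALA/KofamScan style) and a contig-to-taxonomy table
(Centrifuge/Kraken style). Joining the two through the contig id links each
annotated gene to a ranked lineage, which is all the taxonomic resolution
the method needs.

## The model

### Pathway completeness as a boolean expression

Each product is modeled as an ordered list of reaction steps from an entry
metabolite to the product. Each step carries a *gene-requirement
expression*: a boolean tree whose leaves are gene symbols, with `ALL` nodes
for conjunctions (every subunit/enzyme needed) and `ANY` nodes for
alternatives (isofunctional genes, or whole alternative routes such as the
mevalonate (MVA) versus methylerythritol-phosphate (MEP) terpenoid
backbones). A gene complement $G$ (the set of symbols with at least one
annotated hit) completes a step when its expression evaluates true under
"leaf is true iff its symbol is in $G$", and completes the pathway when
every step does:

$$\mathrm{complete}(P, G) \;=\; \bigwedge_{s \in \mathrm{steps}(P)} \mathrm{eval}(\mathrm{expr}_s, G).$$

Evaluation is monotone: adding genes can never make a complete pathway
incomplete. This single primitive is evaluated against two complements —
the pooled community's, and each taxon's own — to classify every product:

* **Case I (`SINGLE_MICROBE`)** — some taxon at the chosen rank is complete
  on its own contigs;
* **Case II (`MIXED_COMMUNITY`)** — only the union of all complements is
  complete, so production would require syntrophic division of labor;
* **Case III (`NONE`)** — even the pooled community is missing required
  genes; no amount of enrichment of this biomass can help.

Precedence is I over II over III, so exactly one case holds per product.
Records on contigs that the classifier left unassigned at the query rank
count toward the community complement but never toward any single taxon —
deliberately conservative for Case I claims.

### Hit numbers and the rate-limiting ratio

The *hit number* of a gene symbol is the number of annotated gene records
whose KO maps to it (an optional per-record weight column lets users
emulate read-depth weighting instead). Within one product's gene set, the
ratio

$$r \;=\; \frac{\min_g \mathrm{hits}(g)}{\max_g \mathrm{hits}(g)} \in (0, 1]$$

flags a candidate rate-limiting step: a gene carried by far fewer community
members than the rest of the pathway. In the packaged demonstration
community, ectoine has `ectA` at 177 hits against `lysC` at 12,563, giving
$r = 0.014$ — a strong bottleneck signal — while PHB's three genes are
comparatively even (0.171).

Two numerical decisions matter here:

* **Active genes.** The extremes are taken over the *active* leaves of the
  product's expressions: a satisfied `ANY` node contributes only its
  satisfied branches. Without this, every carotenoid ratio would be
  poisoned by the zero hits of whichever backbone route (usually MVA) the
  community does not use, although that route is not required. If a truly
  required gene has zero hits, the ratio is reported as *undefined* rather
  than 0 — absence is a completeness question, not a rate question.
* **Rounding.** Ratios are rounded half away from zero (default 3
  decimals), the convention under which 2532/14491 prints as 0.175. An
  epsilon guard keeps decimal ties stable against binary floating-point
  representation.

The ratio is scale-invariant (multiplying all counts by a constant leaves
it unchanged) and equals 1 exactly when all per-gene counts are equal; ties
for the extremes are broken by lexicographic symbol order so reports are
deterministic.

The hit number is a rough proxy: it ignores gene expression, enzyme
kinetics, and pseudogenes, any of which can decouple genetic potential from
realized flux. The ratio ranks candidate bottlenecks for follow-up; it does
not predict rates.

## The packaged catalog

The default catalog covers seven products. Ectoine (aspartate →
`lysC asd ectB ectA ectC`), PHB (acetyl-CoA → `phaA phaB phaC`), and the
acetoin/2,3-butanediol family are taken from the standard bacterial
pathways. Three encodings were genuinely open and are resolved as follows:

* **Acetolactate synthase (ALS).** The catalog requires
  `ALL(E2.2.1.6L, ANY(E2.2.1.6S, ilvM))` — a large subunit plus either
  small subunit. Catabolic ALS enzymes can function as a single large
  subunit, so `default_catalog(als_large_only = TRUE)` relaxes the step to
  the large subunit alone.
* **Acetoin and 2,3-butanediol.** Acetoin formation accepts either the
  decarboxylase `alsD` or a diacetyl-reductase route
  (`ANY(alsD, BDH, butA, budC)`); 2,3-butanediol additionally requires a
  butanediol dehydrogenase (`ANY(BDH, butA, budC)`).
* **Carotenoids.** The terpenoid backbone is
  `ANY(ALL(MVA chain), ALL(MEP chain))` followed by the standard crt
  ladder (GGPP → phytoene → lycopene → β-carotene → zeaxanthin, plus the
  `crtW` ketolase for astaxanthin). Lutein additionally needs ε-ring
  cyclization (`ALL(lcyE, crtY)`) and the plant cytochrome-P450 ring
  hydroxylases (`ALL(cyp97A, cyp97C)`), which bacteria essentially lack.
  These routes are a curated reconstruction of the standard KEGG reference
  pathways; the YAML catalog is packaged as editable data precisely so
  users with organism-specific knowledge can amend it.

Steps upstream of each entry metabolite (aspartate, acetyl-CoA, pyruvate)
are assumed present, on the standard grounds that all eubacteria run
central carbon metabolism. The KO-to-symbol map is likewise packaged,
editable data: KO ids are a curation of KEGG Orthology, not ground truth,
and the map may be many-to-many (K00626 is both `phaA` in PHB context and
the MVA-entry thiolase `atoB`; a K00626 record contributes a hit to both
symbols, while record counts for abundance stay at gene grain).

```{r catalog}
catalog <- default_catalog()
catalog
catalog$products$ectoine
```

## Key parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `rank` | `screen_community()` | `"species"` | rank at which "a single microbe" is evaluated; coarser ranks (genus, family) answer "could an enrichable clade do it" instead |
| `digits` | ratio functions | 3 | decimal places, half-away-from-zero |
| `top_n` | `relative_abundance()` | all | classified taxa kept before the `other` remainder row |
| `als_large_only` | `default_catalog()` | `FALSE` | relax the ALS step to the large subunit |
| `weight` column | annotations | 1 per record | per-record hit weight (e.g. read depth) |

Rank choice is the one that changes conclusions: a product with no
species-level producer may have a genus-level one once sibling species'
complements pool. Both behaviors are legitimate questions; the default is
the stricter species-level claim, with the producer's ancestral lineage
reported alongside.

## The synthetic generator and what passing tests mean

`synthetic_design()` + `generate_community()` produce annotation and
taxonomy TSVs with a fully known manifest: designed taxa with designed
per-product gene complements, per-gene hit counts drawn from a log-uniform
model on [50, 15000] (spanning the dynamic range seen in deeply sequenced
sludge metagenomes) or supplied exactly, genes spread uniformly over each
taxon's contigs, and a designed fraction of contigs withheld from the
taxonomy table to emulate classifier dropout. The manifest is written from
the same internal draw as the tables, so parsing the tables back through
the package must recover its counts, abundances, and classifications
exactly — the end-to-end property the test suite asserts over randomized
designs and seeds (20 designs × 5 seeds in the acceptance suite, smaller
batches elsewhere; each cycle runs in well under a second).

`demo_community()` is a fixed, fully designed instance emulating a
methanol-fed activated-sludge community: 150,000 gene records, three
species carrying complete PHB sets, four carrying acetoin sets (three
extending to 2,3-butanediol), ectoine and the carotenoids completed only by
the pooled community, lutein genes absent, and designed community hit
numbers (ectA 177, lysC 12,563, phaA 2,532, phaB 2,476, phaC 14,491, alsD
115, carotenoid extremes 1,100/10,000) chosen to exercise the ratio
statistic at realistic magnitudes. Residual hit mass lives on single-gene
filler taxa, so no filler can complete any pathway; the two most abundant
species sit at exactly 1.2% and 0.9% of records. Only record-to-contig
dispersal is random; every reported number is fixed by design.

What the generator does *not* emulate, and hence what green tests do not
establish about real data: sequencing error and annotation noise (wrong or
missing KO calls), chimeric contigs (records attached to the wrong
lineage), classifier disagreement between ranks, strain-level heterogeneity
within a species bin, and any correlation between gene presence and
abundance. On real data those errors propagate directly into complements
and hit numbers; the screen is only as good as the upstream annotator and
classifier.

## Degenerate inputs and edge behavior

* An empty or all-unannotated community classifies every product `NONE`
  with a warning, not an error.
* Lineages are slotted positionally into the fixed rank vocabulary
  (domain…species); truncated lineages leave deeper ranks unassigned, and
  over-long lineages are truncated with a warning.
* Contigs absent from the taxonomy table are an expected condition (the
  unclassified sentinel), but an empty lineage string in the table is a
  parse error — silent coercion would blur the two meanings.
* Duplicate gene ids, duplicate contig ids, and malformed KO tokens are
  rejected with the offending row, since each breaks a counting invariant.

## Known limitations

Beyond the generator's idealizations above: the screen is
presence/absence at the gene level, so it cannot see regulation, operon
completeness, or enzyme activity; "single microbe" is really "single
taxon bin at the chosen rank", which on real classifier output can merge
strains; and the packaged carotenoid/terpenoid routes are a reconstruction
that users should review before drawing conclusions about those products.
The worked numbers this vignette cites are exactly those computed by the
package's own test suite and acceptance script on the packaged
demonstration community.
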