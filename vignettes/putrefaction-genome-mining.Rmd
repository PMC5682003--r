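---
title: "Mining bacterial genomes for putrefaction pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bacterial genomes for putrefaction pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(putrescan)
library(dplyr)
```

## The problem

Bacterial putrefaction — fermentation of undigested dietary protein in the
large intestine — releases metabolites (ammonia, the polyamines putrescine,
spermidine, spermine and cadaverine, cresol, indole, phenol, hydrogen
sulfide) that are implicated in damage to the colonic epithelium and in
colorectal cancer. putrescan predicts which bacteria can run the pathways
that make these compounds, directly from genome annotations, and connects
those predictions to cohort-level microbiome comparisons.

Naive homology mapping of pathway enzymes over-predicts: several
putrefaction steps are catalyzed by enzyme families with generic activity,
so the presence of a lone homolog is weak evidence. The engine therefore
combines **domain homology** (profile-search hits on Pfam-style domains)
with **genomic proximity** of the component genes, the operon-like
organization reported for these pathways in experimentally characterized
organisms.

## The catalog and its prediction categories

The built-in catalog (`default_catalog()`) holds 10 pathways covering 9
product metabolites; `catalog_overview()` prints the full table. Each
sub-pathway (an alternative enzymatic route) carries a prediction category:

* **Category I** — experimental work located *all* component genes in one
  cluster (histidine degradation and THF production via the *hut* locus;
  the ornithine-decarboxylase and agmatinase routes to putrescine). The
  pathway is called only when some gene cluster covers every component.
* **Category II** — proximity is documented for a *subset* of components
  (glutamate degradation's methylaspartate pair; the *aguBA* operon of the
  agmatine deiminase route; *speD*/*speE* for spermidine). The core must
  co-cluster and every remaining (distal) component needs a homolog
  somewhere in the genome — any replicon, including the cluster's own.
* **Category III** — single-reaction pathways with substrate-specific
  enzymes (indole, phenol, cadaverine, H2S): one hit anywhere suffices.
  Alternative enzymes for one step (the five H2S-producing enzymes; the
  formiminoglutamase *versus* glutamate-formyltransferase options in
  histidine degradation) are grouped so that any one member satisfies the
  step.

Cresol is special: the small subunit of 4-hydroxyphenylacetate
decarboxylase has no characterized Pfam domain, so the pathway is flagged
`evidence_only` and predicted from curated external evidence lists rather
than domain hits.

A pathway is present when **any** of its sub-pathways is satisfied; the
putrescine pathway is one pathway with three routes, spanning categories I
and II. Because category is a property of the route, the catalog stores it
per sub-pathway (the pathway-level view reports the set).

### Domain accessions are curation slots

Exact Pfam accessions per EC number belong to a curation layer the package
deliberately leaves editable: the shipped catalog uses deterministic
per-EC placeholder accessions (`PDOM_4_3_1_3`, ...) which users replace
with curated accessions via `write_catalog()`/`load_catalog()`. Two
domains are hard-coded by name because the fused-gene analysis depends on
them: `Arginase` and `OKR_DC_1`, the domain pair of the ornithine
decarboxylase route. A known consequence of per-EC placeholders is that
real domain sharing across enzymes (lysine decarboxylase shares the
`OKR_DC_1` clan with ornithine decarboxylase, for example) is not
reflected until accessions are curated; the engine itself supports shared
domains across components and pathways.

The identities of the five H2S-producing enzymes are cited to external
literature; the catalog carries five named slots (cystathionine
beta-synthase, cystathionine gamma-lyase, 3-mercaptopyruvate
sulfurtransferase, cysteine synthase, cysteine aminotransferase) in one
alternative group, again with placeholder accessions.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `evalue_threshold` | `1e-06` | full-sequence E-value gate on hmmscan-style hits; **inclusive** (`<=`), the common tool convention |
| `max_gap` | `2` | maximum intervening genes between consecutive cluster members |
| `max_bp` | `5000` | alternative base-pair proximity mode (`bp_mode = TRUE`) |
| `same_strand` | `FALSE` | optionally require strand agreement within clusters |
| `p_threshold` | `0.05` | raw significance cutoff for differential genera |

Proximity is measured on **gene ranks** (counts of intervening genes), not
base pairs, because rank gaps are robust to annotation density; the
literature describing these gene clusters rarely quantifies distance, so
"at most 2 intervening genes" is this package's documented
operationalization, config-exposed rather than hard-coded. Strand
agreement is not required by default because operonic organization is
reported, not proven, for every component. Clusters are built by
single-linkage chaining on sorted ranks, which is deterministic, order
independent, and equal to connected components of the pairwise proximity
graph (the test suite verifies this equivalence against a brute-force
oracle).

Only full-sequence E-values are compared; per-domain conditional E-values
are ignored. No bit-score or coverage filter is applied beyond the E-value
gate.

## The Pfacs score

Metagenomic profiling rarely resolves strains, so per-strain predictions
are aggregated to genus or phylum level. For taxon *j* and pathway *i*:

    Pfacs_ij = S * alpha

where *S* is the proportion of the taxon's sequenced strains predicted to
carry the pathway and *alpha* in 1..5 is a confidence rank derived from the
percentile of the taxon's sequenced-strain count across all taxa in the
panel — more sequenced representatives, more trust in *S*. Scores range 0
to 5; a taxon with half its strains positive at top confidence scores 2.5.

The percentile uses the strictly-less convention
(`100 * #smaller / #taxa`) and the quintile map
`alpha = min(5, floor(percentile / 20) + 1)`; ties share percentiles and
ranks. The literature defining the score states neither formula precisely,
so both are explicit, tested choices here. The rank panel is the full
strain set supplied, not only putrefiers.

```{r pfacs}
confidence_ranks(tibble::tibble(taxon = c("A", "B", "C", "D", "E"),
                                strain_count = c(1, 2, 3, 4, 100)))
compute_pfacs(S = 0.5, alpha = 5)
```

## Cohort comparison

Genus abundance tables (one row per sample) are normalized to relative
abundances per sample, then tested per genus: Welch's unequal-variance
*t*-test for two cohorts (healthy vs carcinoma), Kruskal–Wallis for three
(healthy, adenoma, carcinoma). P-values are deliberately **unadjusted** —
the selection rule this analysis mirrors is a raw p ≤ 0.05 — with an
optional Benjamini–Hochberg flag (`adjust = "BH"`). The enriched cohort is
the one with the highest mean relative abundance; this direction rule is a
documented choice.

Occurrence summaries report, per cohort and pathway, the percentage of
differentially abundant genera whose Pfacs is positive, both as an exact
fraction and as a round-half-away-from-zero integer (published roundings
of such percentages are not internally consistent under any single rule,
so the exact fraction is always retained). Genera are also classified by
oxygen requirement (aerobe, anaerobe, microaerophile, facultative
anaerobe, obligate anaerobe); when a genus's strains disagree but all fall
among anaerobic subtypes it is collapsed to a generic "anaerobe", other
conflicts are flagged ambiguous rather than guessed.

## The synthetic-data generators

The package is fully testable without downloads: `generate_genome()`
emulates an annotated genome (default 2 replicons × 60 genes) with planted
pathway gene clusters, and `generate_cohort()` emulates genus abundance
tables with planted effects.

Planting modes map to expected outcomes: `intact`, `fused` (two
components' domains on one protein, as in the *Fusobacterium* fused
arginase/decarboxylase gene), `distal-split` (category II layout) and
`evidence` are recoverable; `partial` (a required component omitted) and
`scrambled` (components separated by at least 12 ranks, defeating any
proximity window up to 10 intervening genes) are not. True hits get
E-values log-uniform on [1e-30, 1e-8] — safely inside the 1e-06 gate —
while decoy hits on non-catalog domains (rate 0.15 per gene) span
[1e-30, 1e-2], so decoys probe mapping robustness rather than threshold
placement.

The truth table is derived by brute-force evaluation of the category rules
over the planted layout (pairwise proximity graph, not the pipeline's
sorted-chain clustering, and no file I/O), so it is an independent check
on the whole scan path. This evaluation — rather than the planting-mode
labels alone — is what handles cross-pathway domain sharing honestly: a
planted THF-production operon genuinely implies histidine degradation,
because the THF route contains the *hut* core and glutamate
formyltransferase completes the glutamate-producing branch.

Cohort baselines are log-normal (meanlog `log(1000)`, sdlog 1), a standard
right-skewed stand-in for genus abundances, with an optional dropout
probability for zero inflation (default 0); planted effects are
multiplicative on one cohort's expected abundance. What the generators do
**not** emulate: realistic protein sequences, phylogenetic correlation
between strains, compositional sequencing depth variation, and the sparse,
heavy-tailed structure of real 16S profiles. Passing the planted-recovery
and calibration suites therefore demonstrates correctness of the engine's
logic under its stated assumptions, not field performance on real
annotation pipelines.

## Numerical and degenerate-input choices

* The E-value gate is inclusive (`evalue <= threshold`); boundary hits at
  exactly 1e-06 are retained.
* Rank ties in the gene table break by end coordinate, then gene id, so
  ranking is a deterministic permutation 0..n-1 per replicon.
* A strain with zero genes yields an all-absent profile except for
  evidence-list overrides; an all-zero abundance sample is an error naming
  the sample; a genus with zero variance and equal means in all cohorts is
  untestable and excluded (p treated as 1).
* Kruskal–Wallis uses the tie-corrected statistic with the chi-square
  approximation (`stats::kruskal.test`); exact small-sample p-values are
  out of scope.
* Percentile ties in confidence ranking share alphas; percentages round
  half away from zero.

## Problem sizes used by the test suite

The suites run on sizes chosen to exercise every code path while staying
desk-scale: cluster-oracle equivalence on 500 random instances of up to 12
genes across four gap settings; planted-pathway recovery on a 100-strain
panel spanning all planting modes; null calibration on 100 genera × 200
replicates of a three-cohort design at 20 samples per cohort (the
rank-based test is the calibration target because the *t*-test's size on
raw log-normal abundances is conservative, which is a property of the
test, not of the implementation); and power checks of a five-pooled-SD
planted shift at 20 samples per cohort. Genome-wide survey percentages
reported for thousands of real genomes are not reproducible at this scale
and are not asserted anywhere.

## Known limitations

* Placeholder domain accessions must be curated against Pfam before use on
  real hmmscan output; predictions on real genomes are only as good as the
  domain curation.
* Plasmids and chromosomes are treated uniformly as replicons.
* Pathway presence is genomic capability, not expression or flux.
* The evidence-list mechanism (cresol and any user-flagged pathway) is
  only as complete as the supplied lists.

## End-to-end run

```{r pipeline, message = FALSE}
td <- file.path(tempdir(), "demo")
res <- run_all(td, n_strains = 12, seed = 1)
glance(res$profiles)
head(tidy(res$scores))
```

`autoplot(res$scores)` renders the taxa-by-pathway Pfacs heatmap;
`plot_occurrence()` shows pathway occurrence among differential genera per
cohort.
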