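---
title: "Measuring embryonic recapitulation in insect metamorphosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring embryonic recapitulation in insect metamorphosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devrecap)
library(dplyr)
```

## The question and the model

Holometabolous development runs embryo → larva → pupa → adult. During the
pupal stage the larval body is dismantled and the adult one is built, partly
from imaginal primordia — pluripotent cells set aside during embryogenesis.
If organ formation in the pupa reuses embryonic differentiation programs,
two transcriptome-level signatures should follow:

1. **Reversion**: pupal expression profiles should resemble embryonic ones
   more than the intervening larval profiles do, interrupting the otherwise
   gradual decay of similarity with time.
2. **Recapitulation of transitions**: per-gene expression *changes* across
   the pupa→adult transition should correlate positively with the changes
   across the embryo→larva transition — the same program being switched
   through twice.

`devrecap` measures both on a gene-by-sample FPKM matrix. Every similarity
statistic is a Spearman rank correlation of `log2(FPKM + 1)` values:
rank-based because FPKM distributions are heavy-tailed and
platform-dependent, log-transformed so that fold changes rather than
absolute levels drive the ranks.

### Fold changes and the recapitulation coefficient

Stage profiles are arithmetic means of log2 expression over each stage's
samples (`stage_average()`). For a transition $s \to t$ the per-gene log
fold change is

$$\mathrm{lfc}_g = \bar{x}_{g,t} - \bar{x}_{g,s}, \qquad
  \bar{x}_{g,s} = \text{mean log2 expression of gene } g
  \text{ in stage } s,$$

with $|\mathrm{lfc}| > 1.5$ (log2 units) flagging a substantial change. The
recapitulation coefficient is the correlation over genes between the
embryo→larva and pupa→adult lfc vectors; Spearman by default (consistent
with the rest of the analysis), Pearson available. Positive values mean the
two transitions move genes in the same directions.

### Resampling nulls for functional subsets

Whether a functional gene set (say, development-associated genes) carries
*more* of a signal than the transcriptome at large is judged against random
gene sets of the same size: `resample_metric()` draws $B$ subsets uniformly
without replacement from the matrix's gene universe, recomputes the
statistic on each, and reports

$$\text{quantile} = \frac{\#\{m_b \le m_{\mathrm{obs}}\}}{B}, \qquad
  p = \frac{1 + \#\{m_b \ge m_{\mathrm{obs}}\}}{B + 1}.$$

Ties count toward the quantile (≤) and toward the p-value (≥); the add-one
estimator never returns zero and is exact for the null hypothesis that the
subset is exchangeable with a random draw. $B$ defaults to 999. Sampling is
from all genes in the matrix; the positively expressed reference can be
passed instead when consistency with the enrichment background matters.

### Trajectory templates and zigzag genes

With only the four major stages there are three transitions, each of which
can go up, stay level, or go down: $3^3 = 27$ canonical trajectories. Each
template's level vector is the cumulative sum of its steps, e.g. `+-+` →
$(0, 1, 0, 1)$. A gene is assigned to the template with the highest Pearson
correlation between its 4-point stage profile and the template's levels.
Pearson rather than Spearman on 4 points: Spearman ranks of 4 values are too
coarse to separate 26 templates, many of which share a rank ordering.

Two templates are strictly alternating — `+-+` and `-+-` — and define the
zigzag genes: expression departs from the embryonic level in the larva and
reverts at metamorphosis. A looser criterion (`embryo_pupa_return`) accepts
the six templates whose first two steps cancel, leaving the pupa→adult
direction free; both are implemented because the third transition's
direction is not constrained by "reverts to the embryonic state", and the
strict pair is the default.

Numerical choices: the constant template `000` has zero variance, so
correlation against it is undefined. Genes whose stage-profile variance is
below `var_tol` ($10^{-10}$) are assigned to `000` directly; all other genes
compete among the 26 directional templates. Correlation ties (within
$10^{-9}$) are broken by fewest non-zero steps, then canonical template
order — preferring the simplest explanation of a profile.

Datasets with more than four time points carry more information than four
stage means; they are clustered agglomeratively (`cluster_profiles()`) with
distance $1 - \rho_{\mathrm{Spearman}}$ between gene profiles (average
linkage by default) and the tree cut to $K$ clusters. Constant profiles have
no rank ordering, hence no defined distance: they are excluded and reported
rather than silently placed. Zigzag-like clusters are then selected on
standardized stage means: $|z_{\mathrm{embryo}} - z_{\mathrm{pupa}}| <
\delta$ (default 0.5) and $|z_{\mathrm{larva}} - z_{\mathrm{embryo}}| >
\varepsilon$ (default 1.0).

### Ontology handling and enrichment

`parse_obo()` reads OBO 1.2 stanzas (`is_a` always, `part_of` by default —
which relations a closure should traverse is a genuine modelling choice, so
it is exposed as an argument), drops obsolete terms, resolves `alt_id`s and
rejects cyclic graphs. A term's gene subset is defined by its **descendant
closure**: the term plus every term below it; a gene directly annotated to
any member belongs to the subset. The development- and metabolism-associated
subsets use GO:0032502 and GO:0008152 as roots.

Enrichment (`fisher_enrichment()`) first propagates annotations upward (a
gene annotated to a term is annotated to all its ancestors), then tests each
term with at least one study gene by the one-sided Fisher exact test
(hypergeometric upper tail) against the positively expressed reference —
genes with FPKM > 0 in at least one sample — and adjusts with
Benjamini–Hochberg at $\alpha = 0.05$. Only terms with a study gene enter
the BH family: terms that cannot possibly be enriched would only dilute the
correction.

### Sample QC

Two metadata-driven rules, applied before anything else (`qc_filter()`):

* **Female exclusion.** Gravid females carry eggs; whole-body adult-female
  transcriptomes therefore contain genuine embryonic signal and correlate
  spuriously with the embryo. Only explicit `sex == "female"` samples are
  removed; `mixed`/`unknown` are retained, since removing them would discard
  most pooled datasets.
* **Duplicate removal.** Exact equality of expression columns is used as the
  observable proxy for technical duplication (the analysis never sees raw
  reads); the first column in input order is kept.

Filtering that would empty any of the four major stages is a hard error —
every downstream statistic needs all four.

The pipeline order is fixed: QC → log transform → stage averaging. Averaging
commutes with the log transform only when every stage has a single sample,
and all downstream statistics are defined on the log scale, so means are
taken on log2 values.

## The synthetic-data generator

`simulate_dataset()` is the package's test bed: it emulates the structure
the analysis assumes so that every statistic can be checked against planted
truth.

Per gene: a latent 4-stage log2 trajectory (class-determined), a baseline
drawn uniformly from 2–8 log2 units (≈ 3–250 FPKM, a realistic expressed
range), and i.i.d. Gaussian replicate noise on the log2 scale — i.e.
multiplicative log-normal noise on FPKM, the simplest model consistent with
a log-scale analysis. Observations are back-transformed as
`2^x − pseudocount` floored at 0; the floor means latent values below 0
log2 are not recoverable, which mimics the detection limit of real data.

Defaults, chosen once as a plausible mid-size insect time course:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | transcriptome slice |
| class fractions | 0.15/0.15 monotone up/down, 0.10/0.10 zigzag up/down, 0.20 constant, 0.30 random | mixture of gradual, reverting, silent-structure and unstructured genes |
| `stage_replicates` | 3 per stage | a typical replicated design |
| `noise_sd` | 0.2 log2 | replicate scatter of well-expressed genes |
| `effect_size` | 2 log2 | a 4-fold developmental excursion |
| `shared_program_rho` | 0 | no cross-transition program unless planted |
| `female_contamination` | 0 | confounder off unless studied |

The `random` class draws its three transition steps from normals with sd
`effect_size/2`; when `shared_program_rho` is set, the embryo→larva and
pupa→adult steps come from a bivariate normal with that correlation — a
recapitulation program of known strength whose recovery the tests measure.
With `female_contamination = f > 0`, half the adult replicates are labelled
female and observed as a $(1-f, f)$ FPKM mixture with the mean embryonic
profile, reproducing the egg-signal confounder that female exclusion is
designed to remove. A seven-term miniature ontology (development and
metabolism subtrees under one root) and annotations concentrating zigzag
genes in the development subtree accompany each dataset.

What the generator does **not** emulate: count-level noise
(negative-binomial overdispersion at low expression), within-stage temporal
structure, tissue composition shifts, batch effects, or annotation bias
beyond the planted concentration. Tests passing on this generator therefore
demonstrate the statistics' correctness and calibration on data satisfying
the model's assumptions — not robustness to everything real RNA-seq does.

Two behaviours of the generator are worth knowing when interpreting tests.
First, planted *monotone* genes recapitulate by construction (their
embryo→larva and pupa→adult steps are equal), which is faithful — a gene
rising throughout development genuinely shares its program across
transitions — so detection tests for a planted subset use an unstructured
(`random`, ρ = 0) background. Second, constant-class genes observed with
replicate noise have non-constant stage profiles, so maximal-correlation
assignment places them on some directional template; template-recovery
rates are therefore measured on the classes with a planted directional
template.

## Problem sizes and determinism

The test suite and the acceptance script run on simulated datasets of
400–2000 genes with 12 samples, resampling with $B$ = 99–199 and null
calibration at 500 repetitions — sizes at which every planted effect is
comfortably detectable and a full run stays in the tens of seconds. All
randomness flows through explicit integer seeds (`withr::with_seed`), so
every result in the README, the tests and the acceptance JSON is exactly
reproducible.

A worked end-to-end run:

```{r pipeline, eval = FALSE}
sim <- simulate_dataset(seed = 1)
res <- run_pipeline(sim$expression, sim$samples, sim$ontology,
                    sim$annotations, out_dir = "recap-run", seed = 1)
res$recapitulation$rho
glance(res$enrichment)
autoplot(res$similarity)
```

## Known limitations

* Stage means flatten within-stage dynamics; for dense time courses the
  hierarchical route retains them, but template assignment always sees four
  points.
* Spearman similarity between samples is dominated by the bulk of
  moderately expressed genes; a small reverting module can be invisible in
  the global matrix while still detectable via subsets and templates.
* The duplicate-sample rule detects only *exact* duplication; resequenced
  libraries with independent noise will not be caught.
* Enrichment p-values inherit annotation sparsity: with few annotated
  genes (1% is common for non-model species from sequence-based
  prediction), power is limited and the BH family is small.
* The `LCF > 1.5` flag is a log2-unit convention; it feeds only the flags
  and plots, never the correlation statistics.
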