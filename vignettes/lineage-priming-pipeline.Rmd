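---
title: "Sorted-lineage signatures and priming: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorted-lineage signatures and priming: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineageprime)
```

This vignette is the package's own account of its statistics: the model
behind every call, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be made.

## The data model

The pipeline consumes a log2 expression matrix (transcript clusters ×
arrays), a sample sheet assigning each array a lineage (supporting,
interstitial/stromal, germ, endothelial), a sex (XX/XY), a stage, and a
replicate number, and an annotation table mapping clusters to gene symbols
with an annotation grade. "Interstitial/stromal" is treated as a single
lineage: in XY gonads these are interstitial cells (including fetal Leydig
cells), in XX gonads stromal cells — the sex label carries that
distinction, so no separate lineage code is needed.

Before any analysis, `filter_clusters()` drops clusters that lack
best-grade annotation, lack a gene symbol, or never exceed a log2 intensity
of 6 (strictly) in at least 2 of the 3 replicates of some (lineage, sex,
stage) group. With replicate counts other than 3 the rule generalises to
`ceiling(2/3 * n)`, preserving the original proportion. Quality and
expression conditions commute, so filter order is irrelevant; the quality
filter is applied first. The filter is idempotent and never touches
retained values.

## The atomic comparison

All list recipes compose one operation: a two-sided two-sample t-test on
the log2 replicate values of two groups, with the fold change reported on
the linear scale in the signed convention (FC = 2^Δ for Δ ≥ 0, −2^(−Δ)
otherwise, so |FC| ≥ 1 always). A difference call needs p < 0.05 *and*
|FC| ≥ 1.5; an identity call needs p > 0.05 *and* |FC| < 1.5; boundary
cases are "neither" and never enter a list. Identity is therefore a
deliberately weak claim — roughly 5% of truly identical genes fail it by
chance — and that property propagates: every recipe containing *k* identity
steps loses about 1 − 0.95^k of its true members. This is the binding
sensitivity constraint of the whole pipeline and the reason the planted
recovery rates below sit near 0.95 rather than 1.

The test is pooled-variance by default with a Welch option
(`threshold_config(var_equal = FALSE)`). The underlying array software's
contrast test is not documented at this level of detail; pooled variance is
the conventional choice for a balanced 3v3 log-scale contrast and the two
options rarely disagree at these sample sizes. Zero-variance degenerate
rows follow the t-statistic's limits: equal means give p = 1, unequal means
p = 0, so the call is decided by the fold change alone.

No per-gene multiple-testing correction is applied — deliberately. Error is
controlled at the list level by permutation (below), which respects the
intersection structure of the recipes in a way per-gene corrections cannot.

## Recipes as data

Recipes are first-class objects (`recipe()`, `step_compare()`,
`step_exclude()`, `step_subtract()`) rather than hard-coded call chains, so
the permutation machinery and the cross-platform variant re-run exactly the
recipe that produced a list. Intersection steps commute; exclusion steps
(the "if the gene was also higher … it was removed" constructions) and
list subtractions apply afterwards. Subtraction steps — the removal of the
E13.5 Leydig list from the XY endothelial lists, and the
interstitial/stromal removal in the cross-platform analysis — are ignored
during permutation re-runs, since they reference a fixed external list
whose permutation null is not meaningful; comparison-based exclusions, by
contrast, are part of the recipe and are re-evaluated under permutation.
The Leydig list computed at E13.5 is the default removal list for both
E12.5 and E13.5 endothelial signatures (it is the larger of the two and
removes the maximum number of co-sorting steroidogenic genes); the stage is
configurable.

## Priming and its denominators

A gene is primed when the progenitor expresses it identically in both
sexes and differentiation resolves it asymmetrically: one sex represses,
the other maintains or activates. Three methods are implemented —
`all_primed` (the four-step core), `enriched_primed` (adding
lineage-specificity at both stages), and `depleted_primed` (the mirror
image for genes held *off* in one sex) — for both sexes, for any lineage
and stage pair. Defaults follow the study design: germ cells E11.5 → E13.5,
supporting cells E11.5 → E12.5 (supporting-cell differentiation is
essentially complete by E12.5).

Primed genes are tagged by progenitor level relative to the retaining sex:
**similar** (identical call between start and end), **intermediate**
(significantly higher at the end stage — or at the start stage for the
depleted method), **other** (neither). Duplicate transcript clusters are
resolved at the gene level: a symbol with clusters in both the similar and
intermediate categories counts as "other"; a symbol with one categorised
and one uncategorised cluster keeps its category. Set operations always run
at the cluster level; reported counts are gene-level deduplicated.

Percentages of primed genes are computed against method-matched marker
denominators (end-stage dimorphism alone; dimorphism plus end-stage
enrichment; reversed dimorphism plus end-stage depletion), so that a bias
in primed counts can be separated from a bias in marker-list sizes — the
2×2 independence test below makes that comparison exact.

## Model tests

With n primed genes of which k are female-primed, three models are tested:
female and male extreme models (the progenitor is committed to one
program: 90% of primed genes belong to that sex) with one-tailed exact
binomial tests at p₀ = 0.9, and the balanced model (50/50) with a
two-tailed exact binomial test. Models with p < 0.05 are excluded; if all
three fall, an intermediate (biased) model is selected with its direction
given by the majority sex; if exactly one survives it is selected; if
several survive the result is reported as indeterminate with the survivors
listed — small lists genuinely cannot discriminate the models.

Two definitional choices here were open and are fixed as follows:

- **Two-tailed exact binomial** = the sum of all outcome probabilities not
  exceeding the observed outcome's (with the standard 1 + 1e−7 relative
  tolerance), capped at 1 — the same definition the reference
  implementation (`binom.test`) uses, verified to 1e−12 against it over
  every table with n ≤ 30.
- **One-tailed direction** = toward the observed side of p₀: the
  scientifically meaningful rejection is "the data are too far from the
  model's prediction on the side where they lie". An observation exactly at
  p₀ takes the lower tail; either tail exceeds 0.5 there, so the choice
  can never flip an exclusion.

The sex × priming independence test on the 2×2 table of primed/not-primed
versus male/female markers is the two-sided exact test on the
hypergeometric null (Fisher's exact test, probability-mass method), again
implemented by direct summation and verified against `fisher.test` to
1e−12 on all tables with total ≤ 30.

## Permutation FDR

For a recipe using a set of arrays, the (lineage, sex, stage) assignment of
exactly those arrays is permuted uniformly (group sizes preserved — a
label permutation against a fixed design), the comparison and exclusion
steps re-run, and the list size recorded; 200 draws with replacement from
the permutation space by default. FDR = mean permuted gene count / observed
gene count, with medians and cluster-level counts reported alongside;
observed count 0 yields an undefined (NA) FDR. Each named recipe derives
its own RNG stream from the base seed, so adding recipes to an analysis
never reshuffles existing results.

Calibration: on a pure-noise study the FDR of any recipe should be ≈ 1,
but its Monte-Carlo precision depends on the absolute counts. A
single-difference recipe on 5000 null genes yields only ~10 genes, making
the ratio a wide Poisson quotient; the calibration checks in the test suite
therefore use an identity recipe (thousands of null members), where the
ratio concentrates tightly around 1. Both are computed in the analysis
drivers; the distinction is statistical, not substantive.

## The synthetic generator

`simulation_spec()` defines the study conditions used throughout: 5000
genes; 4 lineages × 2 sexes × 3 stages × 3 replicates = 72 arrays; per-gene
baselines N(8, 1) log2 units; homoscedastic Gaussian replicate noise with
sd 0.25; planted effects of 2 log2 units; 100 genes (~2%) per pattern; 10%
of genes carrying a duplicate transcript cluster (same symbol and group
means, independent noise). Planted genes draw baselines from N(9, 0.5)
truncated at 8: templates emulate well-expressed marker genes, which keeps
depleted templates above the expression floor in their reference groups —
a planted signal that the inclusion filter deletes would measure the
filter, not the recipe.

Eleven templates cover every downstream consumer, from single-group
sex-specific enrichment through the Leydig co-sorting contaminant (elevated
in XY interstitial *and* XY endothelial fractions at the late stages) to
the primed shapes. Primed templates place the full 2-log2 effect on every
divergence arm: "similar" genes start at the retained level and the losing
sex falls by δ; "intermediate" genes start midway between final levels
separated by 2δ, so the retaining sex activates by δ while the losing sex
represses by δ. Factor-structure offsets (per-gene lineage/sex/stage level
shifts) are available for studies of global structure and are switched off
in the default spec: the list-recovery benchmark needs a clean null for its
false-positive rate, while the structure benchmark needs dense global
signal — one default cannot honestly serve both, so the structure analyses
declare their own condition (sd 1.0 / 0.5 / 0.25 for lineage / sex /
stage).

What the generator does **not** emulate: probe-level artefacts and
normalisation residue (inputs are assumed RMA-normalised), heteroscedastic
or heavy-tailed noise, correlated genes (co-regulation), partial FACS
contamination gradients, or symbols re-annotated between platform
generations. Passing recovery benchmarks on this generator therefore
demonstrates the correctness of the list algebra and its calibration under
the stated noise model — not robustness to every failure mode of real
sorted-cell arrays.

Recovery scoring is gene-level. Sensitivity and FPR for detection are
computed against planted and null genes respectively; genes planted with
*other* patterns are excluded from both sides, because several templates
genuinely belong to more than one list. Level-tag accuracy is reported
conditional on detection: it measures how well recovered primed genes are
classified, which is the property the tags add; unconditional tag recovery
would simply re-multiply the two independent ~0.95 identity-call
probabilities already accounted for in detection.

## Problem sizes and runtime

The test suite and the acceptance script run the full default study
(5000 × 72) for recovery, model selection, and permutation FDR (200
permutations), and a 2000-gene study for the structure diagnostics; the
exact-test oracle sweeps cover every binomial and 2×2 configuration up to
n = 30. The complete suite runs in well under a minute on one CPU; each
analysis driver in `analysis/` takes seconds.

## Known limitations

- The identity call inherits the raw-p convention: its 5% miss rate per
  step bounds recipe sensitivity (≈ 0.95 per identity step), and recipes
  stacking several identity steps pay multiplicatively.
- Permutation draws are with replacement from the permutation space; for
  small participating-array sets (6 arrays → 20 assignments) the same
  assignment recurs, which inflates nothing but wastes draws.
- The model tests treat primed-gene counts as independent Bernoulli trials;
  co-regulated gene modules violate that assumption in real data, making
  the binomial p-values anti-conservative there.
- Cross-platform integration is membership-only by symbol; expression
  levels are never compared across platforms, and symbols with conflicting
  annotations are dropped with a logged count.
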