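---
title: "Cell-type-resolved age program enrichment: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved age program enrichment: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspen)
library(dplyr)
```

`aspen` asks a simple question of an annotated single-cell expression
cohort: *in which cell types does the activity of a gene program track donor
age?* Donor age is treated as a continuous covariate, never dichotomized,
and every statement is made at the resolution of an annotated cell type.
This vignette is the package's own account of the statistical machinery: the
two arms of the enrichment framework, the companion composition,
interactome and spatial procedures, what every tunable parameter means, what
the synthetic generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## The dual-arm enrichment model

### Arm 1: correlation-ranked gene set enrichment

For each cell type that survives the eligibility filter (below), we form a
**pseudobulk** profile per donor: the arithmetic mean of log-normalized
expression (`log1p(count / cell_total * 10^4)`, natural log) over that
donor's cells of the type. Each gene's pseudobulk means are correlated with
donor age (Pearson), and genes are ranked from most positively to most
negatively age-correlated. Genes whose correlation is exactly zero
(numerically, |r| < 1e-15) or undefined (no variance across donors) are
dropped to a ledger rather than placed arbitrarily; remaining ties are
broken lexicographically by gene id so a ranking is a pure function of its
inputs.

A gene set is scored against this ranking with the weighted
Kolmogorov–Smirnov running-sum statistic: walking down the ranking, a member
gene ("hit") raises the running sum by `|r|^p` normalized over the member
total, a non-member lowers it by `1/(N - N_set)`, and the **enrichment score
(ES)** is the signed maximum absolute excursion. The default weight exponent
`p = 1` weights hits by correlation magnitude; an exact tie between the
largest positive and negative excursion resolves to the positive one. The
implementation computes the extremum from hit positions alone; a brute-force
cumulative-sum oracle in the test suite confirms exact agreement (to 1e-12)
over hundreds of random instances.

Significance is assessed twice, and a pair must pass both:

* **Permutation test.** The null is gene sampling: `n_permutations` random
  same-size gene sets drawn from the ranking universe. The p-value is
  sign-conditional, `p = (1 + #{same-sign nulls at least as extreme}) /
  (1 + #{same-sign nulls})`, so its resolution floor is
  `1/(n_permutations + 1)`. The **NES** divides the observed ES by the mean
  magnitude of same-sign null scores, making scores comparable across set
  sizes; its sign encodes direction (positive = activity rises with age).
  We deliberately use the plainly specified sampling null rather than any
  multilevel approximation of extreme p-values: every quantity is exactly
  testable, at the cost of a p floor that `n_permutations` controls.
* **Parametric set test.** A two-sided Welch two-sample t-test of the
  member genes' correlation statistics against the non-members', with
  Welch–Satterthwaite degrees of freedom. Cited parametric gene set tests
  of this family admit one-sample and rank-based variants; we fix the
  set-versus-complement two-sample form because it is fully determined by
  the ranking statistic already in hand.

Within each cell type, each family of p-values is Benjamini–Hochberg
adjusted across the gene sets tested — separately for the permutation and
parametric tests, never pooled across cell types — and the **dual gate**
declares a (cell type, gene set) pair significant only when both adjusted
p-values fall below `alpha` (default 0.05). Requiring two different test
geometries to agree is a deliberate guard against the known excesses of
either test alone.

### Arm 2: signature scoring against age

Independently of the ranking arm, every cell receives a per-gene-set
**signature score**: the mean log-normalized expression of the set's matched
genes minus the mean over a pool of control genes drawn from
expression-matched bins. Genes are ordered by dataset-wide mean expression
and cut into `n_bins = 24` equal-occupancy bins; each signature gene draws
`n_ctrl = 100` controls from its own bin (the whole bin when it is smaller),
and the control pool excludes the signature's own genes by default so the
score responds one-for-one to a shift in signature expression. Ties in the
binning are resolved by gene id — never by random jitter — and all control
draws come from one seeded stream, so identical inputs give bitwise
identical score matrices. Scores are averaged per (cell type, donor) over
the same retained donors as arm 1 and correlated with age (Pearson, t-based
two-sided p with n−2 degrees of freedom). Arm 2 carries no significance
gate: the magnitude |r| accompanies each row (it sizes the points in the
bubble plot) and its p-value is reported for completeness only.

### Eligibility

A donor is retained for a cell type iff it contributes at least one cell of
that type; a cell type is analyzed iff its retained donors are at least
`min_donor_fraction` (default 0.5) of all donors. The boundary is
inclusive: a type present in exactly half the donors is analyzed, matching
the convention that only types in *fewer than* half the donors are excluded.
Excluded types are returned in a ledger with the reason, never silently
dropped. Correlation against age needs at least 3 retained donors with
distinct ages.

## Companion procedures

**Composition.** Within each donor and major cell type, minor-type
proportions are computed over that donor's cells of the major type; a donor
with zero cells of a major type contributes *no observation* for its minors
(a proportion over an empty denominator is undefined, not zero). Proportions
are correlated with age per minor type and BH-adjusted within — never
across — the major group, since minors of one major are algebraically
coupled (they sum to one). The correlation is Pearson by default with a
`method` flag for Spearman, the underlying routine's two options.

**Interactome prioritization.** Given cohort-stratified ligand–receptor
interaction tables (cohorts `young`/`old`; one probability and p-value per
pathway × ligand–receptor pair × source × target), cell types are first
screened by total interaction strength: per role (source/target), the
threshold is the *sum of the two cohorts' mean-over-cell-types strengths*,
and a type qualifies by strictly exceeding the role threshold in either
cohort for either role. The published criterion admits more than one
arithmetic reading; this one — per-role means summed over cohorts — yields a
single threshold per dataset and is stated here precisely because the
ambiguity exists. Thresholds are always data-derived, never constants.
Manual exclusions apply after qualification and are recorded with reasons.
For each pathway, mean probabilities over the analyzed source–target
combinations are regressed against cohort membership (univariate binomial
GLM fit by IRLS, 25-iteration / 1e-8 defaults, Wald p); pathways with
`p < 0.05` appearing in at least 15 combinations are selected. Observations
are the rows actually present: a pathway–combination absent from a cohort's
table is missing data, not zero, because upstream communication tools omit
non-significant probabilities and imputing zeros would manufacture
separation. Perfect separation and non-convergence are flagged
(`separation`, `nonconvergent`) instead of surfacing as enormous
coefficients. Finally, signaling nodes are classified per cohort
significance at `p < 0.01`: exclusive to the single significant cohort,
biased toward the larger-probability cohort when significant in both with a
fold difference ≥ 1.2, `shared` when significant in both below that fold,
and `not_significant` when significant in neither — the last label is ours,
since the published class set only partitions significant nodes.

**Spatial proximity.** Imaged-cell tables are filtered twice before any
distance is measured: region-inconsistent cells (stromal classes inside
tumor regions, tumor cells inside stroma) are removed and ledgered, and
cores with stromal fraction outside [0.10, 0.90] are dropped (inclusive
boundaries retained). The proximity statistic is the fraction of query
cells with at least one reference cell within `radius = 30` µm — Euclidean,
boundary inclusive, a cell never its own neighbor (identity-based, so
coincident distinct cells count). The neighbor search buckets reference
cells into radius-sized grid tiles and inspects the 3×3 neighborhood; this
is an exact algorithm, and the suite verifies it against all-pairs brute
force on every fixture. Core fractions are summarized per patient by the
median, groups compared by a two-sided Wilcoxon rank-sum test (exact when
total n ≤ 12 and tie-free; otherwise normal approximation with tie and
continuity correction), and BH adjustment spans the comparisons tested in
one invocation — a run is the correction family, which callers should keep
in mind when splitting analyses.

## The synthetic cohort generator

The generator exists so that every stage can be exercised, calibrated and
power-tested without any external download. Its defaults emulate the shape
of a small annotated tumor atlas: 8 donors with ages uniform on 35–85
years, 6 minor cell types nested in 3 majors, ~30 cells per donor and type,
2000 genes with lognormal baseline abundances, negative-binomial counts with
shared dispersion 0.5 and mild lognormal library-size variation. A planted
age program multiplies the expected expression of one gene set's members,
in one cell type, by `exp(beta * z(age))` with `z` the standardized age —
the log-linear form makes the induced pseudobulk–age relationship
approximately linear, which is what a Pearson-based detection arm should be
tested against. The planted effect size used in the recovery studies,
`beta = 0.6`, was calibrated once with the generator itself so the planted
genes' pseudobulk–age correlation averages ≈ 0.9; recovery runs use 20
seeded cohorts and expect detection by the dual gate, with concordant NES
and score–age signs, in at least 18.

Companion generators produce interaction tables (lognormal baseline
probabilities shared across cohorts, one pathway optionally biased by a
stated factor with p-values consistent with the bias) and imaged cores
(reference cells as a homogeneous Poisson process; query cells independent
under the null, or Gaussian-scattered offspring of reference parents under
attraction). The core generator accepts a padding margin for the reference
process so the closed-form null adjacency `1 - exp(-lambda * pi * r^2)` can
be checked free of edge effects; realistic cores use no padding.

What the generator does **not** emulate: gene–gene covariance beyond the
planted programs, doublets, ambient RNA, batch structure, cell-type
misannotation, or the heavy-tailed library-size distributions of real
droplet data. Passing recovery tests therefore demonstrates that the
machinery detects what it claims to detect under its stated noise model —
not that real-data discoveries at these sample sizes are guaranteed, and
not that the eligibility and dual-gate conventions are optimal for any
particular tissue.

## Numerical choices and degenerate inputs

* Natural-log normalization with scale factor 10⁴; the log base is a
  parameter.
* Correlation coefficients are clamped to [−1, 1] after computation to
  absorb floating-point excess.
* `|r| < 1e-15` is the floating-point realization of "a correlation
  coefficient of zero" for ranking exclusion.
* A gene set covering the whole ranking universe is an error (the miss
  decrement is undefined); an empty intersection is a flagged, untested
  row.
* When no same-sign permutation null exists, NES and p are flagged
  undefined rather than extrapolated.
* BH adjustment propagates NAs and uses the number of defined p-values as
  the family size.
* Seeds: one integer seed governs an entire run (`aspen_config(seed = )`);
  the permutation null is cached per set size within a cell type, so sets
  of equal size share one null sample per ranking.

## Problem sizes used in the checks

The package's own calibration and recovery checks run at desk scale by
design: 500 random instances for the ES oracle, 1000 draws (499 nulls each)
for permutation-null uniformity, 20 seeded cohorts of 8 donors × 6 cell
types × 2000 genes × 10 gene sets at 1000 permutations for program
recovery, and 20 seeded interaction tables for interactome recovery. The
default `n_permutations = 10000` remains the recommendation for real
analyses; the recovery studies use 1000, which already places the
permutation p floor at 1e-3, an order below the BH-adjusted decision
boundary at these set counts.

## Known limitations

* The permutation arm's p floor means very small `n_permutations` cannot
  produce small adjusted p-values over many sets; raise it rather than
  loosening `alpha`.
* Pseudobulk means ignore within-donor cell-count differences; a donor with
  3 cells and one with 300 carry equal weight in the age correlation.
* The Pearson arms assume roughly linear age trends; strongly non-monotone
  age programs will be missed by design.
* The interactome module consumes upstream probability tables as given; it
  inherits whatever biases the upstream communication inference carries.
* The spatial fraction statistic ignores edge effects at core boundaries;
  with a fixed 30 µm radius and ~600 µm cores this biases all groups
  equally and cancels in between-group comparisons.
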