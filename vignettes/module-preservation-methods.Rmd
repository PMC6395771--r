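---
title: "Methods: differential expression and coexpression module preservation"
author: "modpres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and coexpression module preservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modpres)
```

# Scope and model

`modpres` analyzes small case–control bulk RNA-seq cohorts along two arms
that answer different questions about the same count matrix:

* **Differential expression** — per-gene changes in *mean* expression,
  modelled as negative-binomial counts with a log link;
* **Module preservation** — changes in *co-variation*: a weighted gene
  coexpression network is built in the control group (the reference), its
  modules are mapped gene-for-gene onto the case data, and each module's
  connectivity is scored against a permutation null to find the module that
  lost its network structure.

Both arms share the preprocessing contract: integer counts in, filtered and
normalized log2 expression out, with hidden structure estimated and either
adjusted for (DE) or diagnosed (sample weights).

# Preprocessing

**Expression filter.** A gene is kept when at least `min_frac` (default 0.5)
of the samples of at least one group reach `min_cpm` (default 0.3 CPM). The
boundary is inclusive: exactly 50% of a group qualifies. The filter is
monotone in the threshold, which the tests exploit as a property check.

**Normalization.** Each sample is scaled by its median-of-ratios size factor
(the median, over genes positive in all samples, of the count divided by the
gene's geometric mean), the factors are rescaled to geometric mean 1, and
the matrix is put on a common counts-per-million scale before
`log2(x + 0.5)`. This is a variance-reasonable log transform, not an
empirical-Bayes shrinkage transform: the downstream network needs a log-scale
matrix whose correlations are meaningful, and a transparent deterministic
transform is preferred over a model-internal one. Scaling one sample's
counts by a constant leaves its normalized values unchanged (exactly — the
common scale constant absorbs the factor), which is the property a
size-factor normalization must have.

**Hidden covariates.** Surrogate variables are estimated in two steps:
regress every gene on the full known model (group plus adjustment
variables), then take the right singular vectors of the residual matrix.
The number of components is chosen by permutation parallel analysis: each
gene's values are permuted independently across samples, the permuted matrix
is residualized on the *same* design, and the k-th observed singular value
must exceed the 95th percentile of the permuted k-th singular values
(20 permutations, fixed seed; counting stops at the first failure).
Permuting the expression and re-residualizing — rather than permuting the
residuals — is essential: observed residuals live in the (n − p)-dimensional
residual subspace, and a null spectrum computed in a different subspace is
systematically biased (both directions were observed while developing the
parallel-analysis step; only the matched construction is calibrated, with a
~5% per-dataset false-positive rate inherent to the 95th-percentile rule).
Because the primary variable is part of the regression, surrogate variables
are near-orthogonal to the case/control contrast by construction.

**Sample weights.** The per-sample weight is the inverse mean squared
residual about the fitted gene-wise model, normalized to geometric mean 1.
This is a per-sample *diagnostic* (the pipeline reports a two-sample
Kolmogorov–Smirnov comparison of the weight distributions with and without
surrogate variables), not an observation-level precision weight entering the
likelihood. If all residuals vanish (degenerate identical samples) the
weights are defined as exactly 1.

# Differential expression

Per gene, a negative-binomial GLM with log link is fitted by IRLS
(`glm.fit`, at most 50 iterations) with the gene's dispersion held fixed and
`log(size factor)` as offset. The group coefficient, oriented case over
control, is reported as `log2fc`; the Wald statistic `coef/se` gets a
two-sided normal p-value, BH-adjusted across genes. Zero-count genes and
non-converged fits are flagged (`p = 1`) and excluded from DEG sets.

Dispersion is estimated by method of moments on normalized counts,
`max(0, (s² − μ)/μ²)`, then shrunk 50/50 toward a `a₀ + a₁/μ` trend fitted
across genes by least squares. This is deliberately simpler than
empirical-Bayes MAP shrinkage: the testable contracts are the type-I rate
under the null and power/sign fidelity on planted effects, and the
method-of-moments blend meets both (see `de_calibration()`); genes with zero
sample variance get dispersion 0 since they carry no overdispersion
evidence. The multiple-testing procedure is Benjamini–Hochberg; where only
an "adjusted p" is required the step-up is the standard choice.

DEGs are called at two thresholds: strict `p_adj ≤ 0.05` and relaxed
`p ≤ 0.01` without adjustment — the latter an exploratory set appropriate to
severely underpowered cohorts, always reported as such. Cross-region
summaries count exclusive/shared DEGs per region combination and the
fraction of shared genes whose fold changes agree in sign everywhere they
appear; zero fold changes are counted as neither direction.

# Network construction

The network is **unsigned**: `a_ij = |cor_ij|^β`. The soft threshold β is
the smallest power whose connectivity distribution fits a power law with
R² ≥ 0.8 on a log–log regression of bin frequency against mean bin
connectivity, over 10 **equal-width** connectivity bins. Equal-width binning
is load-bearing: with equal-count (quantile) bins every bin has the same
frequency by construction, the regression response is constant, and the fit
index is degenerate — this was verified numerically (slope ≈ 1e-16) and is
why the implementation bins `k`, not quantiles of `log k`.

Topological overlap is
`TOM_ij = (l_ij + a_ij)/(min(k_i, k_j) + 1 − a_ij)` with
`l_ij = Σ_{u≠i,j} a_iu a_uj`; it is computed by one matrix product with a
zeroed diagonal, and the test suite pins it to a brute-force triple loop at
1e-12 on random adjacencies.

**Module detection** is average-linkage hierarchical clustering of
`1 − TOM` with a deterministic static cut. Candidate heights are the tree's
merge heights capped at 0.99 of the tallest merge; at each height the
clusters of size ≥ `min_size` are candidate modules. The chosen height
*maximizes the number of such modules*, with ties broken by covered genes
and then by the larger height. Maximizing coverage alone was rejected after
it provably merged distinct planted modules: near the top of the tree a
single background-inflated cluster covers more genes than the separated
modules, so a coverage objective collapses the partition. Counting modules
first keeps the partition at its finest stable resolution; background genes
that merge above the cap stay unassigned (label 0). Ties in exact-tie
dendrograms are guarded by clamping sub-epsilon height inversions
(`cummax`), and three degenerate inputs have defined behaviour: all-identical
genes form one module, `min_size > n` leaves everything unassigned with a
warning, and constant genes cannot join modules because their correlations
are set to 0.

Module eigengenes are first principal components of the gene-standardized
module submatrix, sign-oriented so the mean member kME is non-negative;
`kME[g, m]` is the Pearson correlation of gene g with eigengene m.

A practical floor: with fewer than about 15 samples per group the
correlation sampling noise (sd ≈ `1/√(n−1)`) lets background genes form
spurious clusters and planted modules merge; the pipeline examples and tests
therefore use 15+ per group for the network stages, while the DE arm runs at
any n. This is the main caveat when applying the package at the 6-vs-8 scale
typical of postmortem cohorts: the network arm is reported there too, but
its stability should be judged by the preservation permutation Z, not by the
module count.

# Module preservation

The reference (control) partition is applied to the case data gene-for-gene.
Seven statistics are computed per module: four **density** statistics on the
test data (mean within-module correlation, mean adjacency at β, eigengene
variance explained, mean signed kME) and three **connectivity** statistics
comparing reference and test (correlations of intramodular connectivity, of
kME, and of the vectorized within-module correlation matrices). The
permutation null draws random gene sets of the module's size from the full
analyzed universe (not label shuffles — the null asks "how would an
arbitrary same-size gene set score", matching the permutation construction
of reference-based preservation), recomputes all statistics per draw, and
standardizes: `Z = (obs − mean)/sd`, 100 permutations by default,
deterministic given the seed. Zero permutation sd yields a flagged infinite
Z excluded from medians.

`Zsummary` is the mean of the median density Z and the median connectivity
Z. On this scale ≈ 2 means little preservation and ≥ 10 strong preservation.
`medianRank` ranks modules per statistic (rank 1 = most preserved, average
ranks on ties) and takes the per-module median across statistics, so the
least preserved module has the *highest* medianRank; being rank-based it is
invariant to monotone rescaling of any statistic and insensitive to module
size.

**Selection.** If the module with the highest medianRank is also the one
with the lowest Zsummary, it is selected outright. Otherwise the *union* of
the three least preserved modules under each criterion (at most six
candidates) is tie-broken by the control-vs-case correlation of own-module
kME: the candidate with |r| closest to 0 — the most neutral membership
correlation — is selected, and the rationale records both criteria and all
candidate correlations. The union is the permissive reading of a
three-candidates-per-criterion rule; an intersection could be empty exactly
when the criteria disagree, which is the one situation the tie-break exists
for. The kME correlation p-value is the standard correlation t-test.

Hubs are genes with |kME| ≥ 0.9 against their module's eigengene, computed
separately per condition with the case eigengene recomputed on case data, so
hub loss reflects case connectivity rather than a projected control pattern.
The phrase "correlation between a gene's expression and the kME value" is
read as correlation with the module eigengene (hub ⇔ |kME| ≥ 0.9), the
standard convention; a literal correlation against a kME vector indexed by
genes is dimensionally incoherent.

# Enrichment

ORA uses the exact hypergeometric upper tail `P(X ≥ k)` with BH across sets
(one shared BH implementation package-wide) and FDR ≤ 0.05 as the default
significance level. The randomization test (MSET-style) samples gene lists
of the query's size uniformly *without replacement* from the background and
reports the add-one-corrected empirical p, `(1 + #{overlap ≥ obs})/(n_iter + 1)`,
which is a valid permutation p-value (never 0) and converges to the
hypergeometric tail. Gene ids are harmonized by case-folding and stripping
trailing ".N" version suffixes; no ortholog mapping is attempted.
Association tables are filtered at strictly `p < 1e-5`.

# Cohort tables

Categorical variables use the Wald test on the log odds ratio:
`OR = ad/bc`, `se = √(1/a + 1/b + 1/c + 1/d)`, two-sided normal p (doubled
tail, capped at 1). A zero cell triggers the Haldane–Anscombe +0.5
correction on all cells, flagged in the result, keeping the estimator
finite. Continuous variables use Mood's median test with values equal to
the grand median assigned to the "at or below" side and an exact Fisher
p-value on the resulting 2×2 — appropriate at single-digit group sizes; an
all-tied sample is degenerate and returns p = 1 with a warning. Whether an
exact rather than Wald test was intended for the categorical rows is
ambiguous in some published tables; the Wald form reproduces the
sex/alcohol/tobacco worked examples to two decimals, and the remaining
discrepancies (e.g. a printed 0.05 where the Wald value is 0.055) are left
as documented observations rather than fitted.

# The synthetic-data generator

`simulate_dataset()` draws counts `NB(μ, α)` with

```
log μ[g, s] = baseline[g] + loading[m] · f[s, m] + DEG shift (cases)
            + batch[g, batch(s)] + log library-size offset[s]
```

Latent factors `f` are standard normal per sample and module; baselines are
log-uniform over `base_mean_log_range` (default 10–1000); batch shifts are
gene-specific `N(0, batch_effect_sd)` (default 0.2 on the natural-log scale,
a modest laboratory effect); library sizes are log-uniform over 5–15
million, entering only through their ratios; DEG shifts of `deg_log2fc`
log2 units are applied to case samples of `n_deg` genes drawn from outside
the planted modules when possible, so mean and wiring perturbations stay
separable. Under `break_correlation` the disrupted module's case samples
receive i.i.d. per-gene factors: variance is preserved and only co-variation
is destroyed, so the disruption is connectivity-only and marginal means
match between groups (a tested invariant); `attenuate` instead halves the
loading in cases. Defaults mirror a small postmortem cohort: 6 cases, 8
controls, NB dispersion 0.05 (a typical bulk-brain value; the real data's
dispersion is not characterized, so this is an artifact choice exposed in
the design).

What the generator does *not* emulate: read-level sampling (FASTQ),
isoforms, gene length and GC effects, correlated DEG/module structure,
outlier samples, or mean–variance trends beyond a single global dispersion.
Passing recovery tests therefore demonstrates that the statistics behave as
designed under their own generative assumptions — not that real tissue data
satisfies those assumptions.

## Benchmark conditions

The standard disruption benchmark (`disruption_benchmark_design()`) uses
2000 genes, planted modules of 100/150/200 genes at loading 0.8 with the
size-150 module disrupted, 20 samples per group, dispersion 0.05, β = 6,
minimum module size 30, and 100 permutations — the demonstration scale at
which preservation statistics are stable; postmortem-cohort sizes (6 vs 8)
are the generator's defaults for pipeline demos. The benchmark design sets
`batch_effect_sd = 0`: it plants correlation structure only. With a nonzero
gene-specific batch effect the background genes genuinely co-vary through
their shared batch response and form real batch-driven modules — that is a
different (and interesting) condition, and it is exactly what the
surrogate-variable step exists to absorb in the DE arm. Recovery counts a
seed as successful when the selected module is the detected module carrying
the majority of the planted disrupted genes; calibration additionally
requires every intact planted module's detected host to exceed Zsummary 10
while the disrupted one falls below 2. DE calibration uses 2000 genes at 20
samples per group with a batch covariate in both generator and model.

# Numerical and degenerate-input conventions

* All randomness flows through explicit integer seeds (`withr::with_seed`),
  and every stochastic stage is byte-reproducible; the pipeline derives
  per-region, per-stage seeds from the global seed.
* Correlations on constant vectors are defined as 0 with a flag, never NA.
* BH validates its input lies in [0, 1]; TOM validates symmetry; adjacency
  requires β ≥ 1; permutation nulls require ≥ 20 permutations.
* Non-converged GLM fits are excluded from DEG sets rather than reported
  with unstable estimates.
* Size factors are rescaled to geometric mean 1, so only their ratios are
  identified — individual factors are not scale-equivariant under this
  convention (the ratio form is, and is what the tests assert).

# Known limitations

* The static tree cut trades the adaptivity of dynamic hybrid cutting for
  determinism; diffuse modules that only separate at varying heights may be
  merged or dropped.
* Reference-based preservation inherits the reference network's detection
  errors: background genes accreted into a module dilute its density
  statistics (visible as intact-module Zsummary shrinking toward the weak
  end at small n).
* The DE arm's dispersion shrinkage is a fixed blend, slightly conservative
  for genes whose true dispersion sits far from the trend.
* Sample weights are diagnostics only; no observation-level weighting enters
  the GLM.
* Enrichment ships format support and the tests' synthetic collections only;
  curated pathway databases are user-supplied.
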