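---
title: "Betti-0 curves of functional connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Betti-0 curves of functional connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The filtration model

A subject's functional connectome is the matrix of Pearson correlations
*r* between regional signals. `betticonn` studies it under the
correlation distance *d = 1 − r*, which maps perfect correlation to 0,
independence to 1 and perfect anticorrelation to 2. For a filtration
value ε ≥ 0, the ε-graph connects every node pair with *d ≤ ε*; the
zeroth Betti number B₀(ε) is its number of connected components. As ε
grows from 0 the graph is nested, B₀ falls monotonically from *n* to 1,
and the whole curve is determined by the *n − 1* values at which two
components merge. Those merge values equal the sorted edge weights of a
minimum spanning tree of *d* (equivalently, single-linkage dendrogram
heights); `b0_curve()` computes them with Kruskal's algorithm over a
union-find forest in compiled code.

Three conventions fix the curve exactly:

- **Edge rule.** An edge exists at *d ≤ ε* (non-strict), making B₀
  right-continuous. At ε = 0 only exactly duplicated nodes are joined,
  so generic data give B₀(0) = *n*.
- **Ties.** Coincident merge values are kept with their multiplicity —
  no jittering. Tie order cannot change B₀, only which tied edge is
  recorded as the merger; edges are processed in ascending weight with a
  stable (i, j) order so results are reproducible bit for bit.
- **Negative correlations** are kept: the distance simply extends to 2.
  Truncating them would discard the anticorrelation structure, and the
  1 − r form needs no truncation to be a well-defined filtration.

## Curve features

`b0_features()` reduces a curve to three scalars.

**AUC** is the exact integral of the step function over the *fixed*
domain [0, 2] (units: components × distance): the sum of interval widths
between consecutive breakpoints times the component count on each
interval. Fixing the domain — rather than stopping at the last merge —
makes areas comparable across subjects and node subsets: the flat B₀ = 1
tail contributes the same constant to everyone, so group contrasts are
unaffected while subjects with late merges are not artificially
truncated. Lower AUC means the connectome fuses at lower filtration
values: less segregation.

**Slope** (components per distance unit, always negative in practice) is
the ordinary least-squares slope of the staircase points (ε_k, B₀(ε_k))
sampled at 0 and at every merge value up to and including the last. The
plausible alternative — the secant (1 − n)/ε_last — uses only the
endpoints; we prefer OLS because a "rate of change" of the whole curve
should see the whole curve shape, and because the secant is driven
entirely by the single largest merge, the noisiest order statistic. The
choice is isolated in `b0_slope()` so a secant variant can be swapped in.

**Kurtosis** is the bias-uncorrected excess kurtosis m₄/m₂² − 3 of the
merge-value distribution (unitless). Treating the merges as a sample
over ε reads "how tailed the distribution is" literally: merges
concentrated around one filtration value give high kurtosis and a fast,
switch-like transition. The other defensible reading — kurtosis of the
curve's ordinate values — depends heavily on the fixed domain tail and
is not used; it too is isolated behind `b0_kurtosis()`.

Degenerate inputs are errors, not silent numbers: fewer than 2 nodes for
the slope, fewer than 5 nodes (4 merges) or zero merge variance for the
kurtosis.

## Rewiring null model

To show that the features reflect topology rather than the weight
distribution, `rewire()` redistributes the off-diagonal weights over the
complete graph while preserving the weight multiset exactly (hence every
moment of the weight distribution). On a complete weighted graph,
degree-preserving rewiring reduces to permuting weights over edge slots;
the default performs 10·E seeded pairwise transpositions of the upper
triangle, mirrored below, staying close to rewiring semantics, and a
`"shuffle"` mode draws one uniform permutation — the two are
statistically equivalent here. `null_features()` repeats this `n_perm`
times (1000 in routine use) and `empirical_p()` applies the add-one rule
p = (1 + #{at least as extreme}) / (1 + n_perm), never below
1/(1 + n_perm). Per-subject p-values are the primitive; a pooled rate
across subjects can be formed by the caller, and both readings are
deliberately exposed rather than hidden behind one aggregate.

## Group inference

`fit_group_model()` fits, by maximum likelihood,

```
group ~ auc + kurtosis + slope + sex + age + motion
```

with the dimensional variables (features, age in years, motion in mm)
standardized to z-scores over the full analysis sample and sex entering
as an unstandardized binary indicator; cases are coded 1. Each term is
reported as an odds ratio with a 95% Wald interval and two-sided Wald p,
the standard summary for per-term logistic effects. Non-convergence and
separation are flagged on the returned object instead of silently
reported. The three features are strongly correlated, so the per-term
coefficients are conditional effects; this is intentional — the model
asks what each curve summary adds given the others.

`subnetwork_scan()` re-runs the whole machinery on every intranetwork
subset (one network's nodes) and internetwork subset (the union of two
networks' nodes, so both members' internal edges participate in the
filtration) — k(k+1)/2 cells for k networks. Features are re-computed on
each principal submatrix and re-standardized within the model, once per
cell over the full sample; covariates are not re-standardized per cell
differently from the whole-brain model. Networks with fewer than 5 nodes
make their cells unevaluable rather than producing unstable fits, and
per-cell failures are recorded without aborting the scan.

**Family-wise error.** `fwe_correct()` transliterates the network-based
statistic to the cell grid: cells with AUC-term p < 0.05 (two-sided) are
supra-threshold; networks are vertices, significant internetwork cells
edges and intranetwork cells self-loops; clusters are connected
components and the cluster statistic is its cell count. The null
distribution of the maximum cluster statistic comes from permuting the
diagnosis across subjects — covariates stay attached to their subjects,
i.e. a simple permutation of the outcome, which is the exchangeable
quantity in this model — and re-fitting every cell; 10,000 permutations
in routine use. Cluster p-values again use the add-one rule.

`edge_proportion_test()` compares, per edge and per filtration value
(defaults 0.35, 0.5, 0.75, 1.0), the proportion of subjects in each
group showing the edge (*d ≤ ε*), with the pooled two-proportion z-test,
flagged at p < 0.01 uncorrected; edges with zero pooled variance report
p = 1. `cohens_d_summary()` and `odds_ratio_2x2()` (cross-product, with
the Haldane–Anscombe +0.5 correction when a cell is zero) cover the
descriptive effect sizes of the phenotype table.

## Concordance across parcellations

`kendalls_w()` measures agreement of m parcellations over n subjects by
Kendall's W on mid-ranks with the standard tie correction; continuous
features make ties rare, but file rounding can create them. Significance
uses the large-sample χ² approximation χ² = m(n − 1)W on n − 1 degrees
of freedom, matching how such coefficients are reported at cohort sizes
near 180; an exact permutation option exists for small n.
`kcc_critical()` inverts the approximation (for two raters and 176
degrees of freedom the 5% threshold is W ≈ 0.59), and `pairwise_kcc()`
builds the feature-by-parcellation-pair grid with m = 2.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the pipeline targets: two
diagnostic groups (81 cases, 96 controls by default), 105 nodes in 7
communities, 172 time points per subject. Node signals follow a factor
model — community factor times `within_load` (0.6), a global factor
times `between_load` (0.2), unit Gaussian noise — which guarantees a
positive semi-definite population correlation matrix and realistic
sampling noise at finite scan length. Cases receive `effect_between`
added to the global loading, raising between-community connectivity and
thereby lowering the B₀ AUC ("decreased segregation"). The default
0.03 was calibrated once, by sweeping the loading and measuring the
case-control AUC gap over repeated cohorts, to implant a shift of about
−0.5 pooled SD — the effect size the recovery analyses are designed
around; it was then frozen. Effects meant to stay confined to one
community use `effect_within` on `target_networks` instead: raising the
*global* loading of a node subset necessarily leaks into every
internetwork pair containing it, whereas raising the community loading
touches only that community's internal edges, which is what
"localized effect" should mean.

Covariates copy the magnitudes of a typical pediatric case-control
table: sex odds near 3 (female fractions 51/96 vs 22/81), an age gap of
1.76 years (12.26 ± 3.07 vs 10.5 ± 2.48), a motion gap of 0.005 mm
(0.067 ± 0.054 vs 0.072 ± 0.041, truncated at zero). They are drawn
independently of the connectomes: they exercise the confound-adjustment
code paths but do not confound, so tests of the group effect are tests
of the implanted effect only. Subject i draws from sub-seed
`derive_seed(seed, i)` (a counter-based scheme), making cohorts
bit-reproducible and subjects generatable in any order.

What the generator does *not* emulate: hemodynamic autocorrelation,
motion artifacts and their spatial structure, atlas geometry,
heavy-tailed or spatially smooth noise, and real between-site
heterogeneity. Passing tests therefore demonstrate internal statistical
correctness — calibration, power against implanted effects,
reproducibility — not that real cohorts carry effects of this size or
cleanliness.

One structural property of the generator deserves emphasis. Because
subjects differ only through correlation sampling noise around one
population matrix per group, the three curve features are strongly
coupled across subjects, and any mechanism that lowers the mean of the
merge-value distribution (the area, which equals 2 plus the sum of the
merges over the fixed domain) also steepens the zero-anchored OLS slope
in the same standardized direction. The six-term model estimates the
*conditional* AUC effect given slope and kurtosis, so part of an
implanted AUC shift is absorbed by the co-shifted slope term, and the
conditional test is less powerful against this generator's effects than
a marginal AUC test would be. We explored several alternative implants —
a variance-compensated uniform translation factor, subject-level
integration heterogeneity, within-community loadings, and node-level
loading heterogeneity — and the co-shifting persists in each, because
the slope's anchor at the origin makes it location-sensitive by
construction. Real cohorts, whose subjects vary along many more axes
than sampling noise, need not show this degree of coupling; the
conditional model is kept because it is the inferential model the
package exists to provide, and the recovery analyses in the test suite
report its behaviour against this generator honestly rather than
against a generator engineered to decouple the features.

`refine_partition()` splits communities into random sub-labels to mimic
parcellations of different granularity over the same sources; combined
with `parcellate_timeseries()` (label-wise signal averaging) it lets
concordance analyses run on "two atlases" of one cohort.

## Numerical choices and problem sizes

- Symmetry tolerance on file input: entries differing by ≤ 1e-6 are
  averaged; anything larger is corrupt, not noise, and errors.
  Diagonals in files are ignored and forced to r = 1 / d = 0.
- Files reference nodes by label, never by position, so reordered files
  remain valid; internally indexing is positional.
- All permutation p-values use the add-one rule; permutation streams are
  seeded per replicate via `derive_seed()` and never disturb the
  caller's RNG state.
- Logistic fits in the permutation inner loop reuse the fixed design
  matrix (only the outcome is permuted) through `glm.fit`, with Wald
  p-values from the weighted QR decomposition.
- The test suite runs the statistical analyses at reduced but still
  informative sizes chosen for a laptop-scale run: 500 null cohorts for
  type-I error, 100 cohorts at 200 permutations for FWE false-positive
  rate, 200 cohorts for effect recovery, 100 for scan localization, and
  100–200 rewirings where routine use would take 1000–10,000. The
  fitted-model sample size (177 subjects) is never scaled down.

## Known limitations

Only H₀ is computed: cavities (Betti-1 and higher), persistence
diagrams beyond merge values, and landscape vectorizations are out of
scope. The χ² approximation for Kendall's W is a large-n device; use
the permutation option below a few dozen subjects. The cluster FWE
procedure tests the global null via the maximum cluster statistic, so
cluster-level p-values are corrected for the grid but say nothing about
which *cell* inside a cluster drives it. Wald intervals degrade under
separation; the fit flags it rather than switching estimators.
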