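---
title: "Methods: stability-selected co-expression communities and their classification screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-selected co-expression communities and their classification screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis in one paragraph

Given a genes x samples expression matrix with case/control labels, the
package (1) links every gene pair whose Pearson correlation is significant at
the 1% level into a weighted co-expression network, (2) cuts that network
into *stable* gene communities by running the Leiden algorithm many times per
(resolution, randomness) configuration and recursing until all communities
hold 4-100 genes, (3) asks, for every community separately, how well a Random
Forest discriminates cases from controls under repeated stratified
cross-validation with Boruta feature selection nested inside each training
fold, and (4) explains the retained classifiers with exact interventional
Shapley values and tests communities for annotation over-representation. The
unit of discovery is therefore not a single gene signature but a set of
co-regulated gene groups, each small enough to interpret and each judged by
its own out-of-sample classification performance.

# Preprocessing

Three steps, each exposed on its own and composed by
`preprocessExpression()`:

* `log2Transform(se, offset = 1)` — the offset guards intensities near zero;
  it is configurable because synthetic intensities can be arbitrarily small.
* `batchAdjustOnControls(se)` — per (gene, batch), a location and a scale
  coefficient are estimated from that batch's *control* samples only (batch
  control mean/SD against the pooled control mean/SD) and the affine
  correction is applied to all samples of the batch. Anchoring on controls
  means the case/control contrast can never be absorbed into the batch
  model. A full empirical-Bayes batch correction is deliberately out of
  scope: the essential convention — coefficients from controls only — is
  preserved by this simpler estimator, which is exactly testable. A
  degenerate control SD (< 1e-12) sets the scale to 1 for that gene/batch.
* `quantileNormalize(se)` — every column is mapped onto the across-sample
  mean of order statistics; ties receive the mean of the reference values at
  their tied ranks (the standard convention, which makes the operation
  permutation-equivariant). On tie-free data the operation is exactly
  idempotent.

The default order is log2 → batch → quantile. Applying the location-scale
batch correction on the raw intensity scale can produce negative intensities
(an affine map applied to skewed positive data), so the correction is run on
the log scale where additive/multiplicative batch artifacts live; the order
remains configurable since the field has no single convention.

One consequence of quantile normalization worth knowing when validating
against planted ground truth: forcing all samples onto a common distribution
*redistributes* a strong class-dependent mean shift across the other genes —
case samples get a small compensatory shift in every unshifted gene. On real
data this is a mild, well-known side effect; on synthetic data with a large
planted effect it can make "null" genes weakly class-informative. The
ground-truth classification checks in the test suite therefore run on
log2-only data.

# Network construction

For each gene pair the two-sided p-value of the Pearson correlation is
computed from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
freedom; a pair is linked iff `p < alpha` with `alpha = 0.01` — equivalent to
the 99% confidence interval excluding zero. No multiple-testing correction is
applied across pairs, matching the method's convention. The clustering
weight is `|r|` (the community detection backend's quality function needs
nonnegative weights); the signed correlation is kept as an edge attribute.
Whether a signed quality function should be used instead is left as a
flagged extension — the implemented objective is modularity on `|r|`.
Constant genes cannot be tested and are dropped with a warning rather than
an error, to tolerate degenerate synthetic draws.

# Community detection

## Stability selection

For one configuration (gamma, beta), the Leiden algorithm (modularity
objective, igraph backend) runs `L = 100` times, run `j` seeded with
`baseSeed + j`. Ensemble agreement is scored by the mean pairwise normalized
mutual information over all L(L-1)/2 pairs; NMI uses the "sum" normalization
`2 I / (H_p + H_q)` with natural-log entropies. Degenerate conventions: two
zero-entropy (single-community) partitions compare as 1 if equal; exactly one
zero entropy gives 0. The majority partition is the most frequent canonical
partition, ties broken by highest average NMI against the ensemble, then by
lexicographic order of the canonical assignment vector — fully deterministic.

A configuration is *retained* when three criteria hold: **stability**
(mean pairwise NMI >= 0.80), **substantiality** (at least two communities)
and **non-fragmentation** (no community below `ceiling(0.05 * n)` nodes,
where `n` is the size of the network currently being partitioned). The 5%
floor is evaluated per current (sub)network: 5% of the full network would
forbid any community under the size cap in realistically sized networks.

## Choosing among configurations

Among retained configurations the highest mean NMI wins. Exact NMI ties are
common on cleanly modular data — many configurations are perfectly stable at
NMI 1.0 — and the tie-break matters: a coarser but equally stable partition
merges planted structure into communities that already fit the size band,
and the recursion never revisits them, whereas the extra fragments of a finer
partition are simply dropped by the size floor. Ties therefore break towards
the **larger** resolution (then the smaller beta). When no configuration is
retained at all (typical when background genes form tiny stable fragments,
so non-fragmentation can never pass), the same ordering picks a fallback
configuration and a prominent warning is logged; silently discarding a large
subnetwork would lose its genes.

## Hierarchical recursion

Communities larger than 100 genes are re-partitioned on their induced
subgraph (edge attributes are *not* recomputed); communities under 4 genes
are discarded with a log entry; everything in between becomes a final
record. Each recursion node derives its ensemble seed from the master seed
and its hierarchy path, so sibling ensembles are independent yet the whole
tree is byte-reproducible. A subnetwork whose selected partition has a
single community cannot be subdivided; it is recorded as non-final with a
warning rather than looping. Recursion depth is capped (default 20).

# Classification screen

Every final community is scored by `evaluateCommunity()`: stratified 5-fold
cross-validation repeated (by default) 100 times; within each training fold,
Boruta selects genes and a Random Forest with `M = 300` trees and
`s = S` features per split (all features; the square-root rule is available
but not the default) is trained on the confirmed genes; accuracy, AUC
(rank-based, on the forest's vote-fraction scores) and F1 (case = positive)
are computed on the held-out fold. Stratification is used because imbalanced
cohorts make unstratified 5-fold splits occasionally single-class. Reported
errors are the SD of the repetition-level means (a documented reading of
"mean +/- error over repetitions"; SEM would be SD/10). When Boruta confirms
nothing in a fold the forest falls back to all community genes — discarding
folds would bias the aggregates. Communities with mean accuracy above 85%
pass the screen.

The per-community gene ranking follows the frequency rule: `N` is the mean
number of confirmed genes per fold x repetition, and the top-`round(N)` genes
by selection frequency (ties by mean importance, then gene id) form the
community's reduced signature.

## The forest and Boruta internals

No Random Forest, Boruta or tree-Shapley implementation is available in the
package's dependency environment, so all three are implemented here (the
forest in C++): CART trees grown on bootstrap rows with Gini splits,
vote-fraction prediction (an exactly tied leaf votes control), and mean
weighted impurity decrease as importance. All randomness flows from one
explicit seed — results do not depend on R's RNG state.

Boruta follows the shadow-feature scheme: each iteration shuffles every
remaining feature into a shadow copy, fits a forest on real + shadow
columns, and scores a *hit* for each feature beating the best shadow's
importance; hits are tested two-sided against Binomial(iter, 1/2) with
Bonferroni correction over the original feature count. Rejected features
leave the model; features still tentative at the iteration cap are
conservatively not confirmed. The selector's internal forest uses the
square-root mtry rule (the selector standard) with 64 trees and at most 30
iterations by default — a desk-scale choice: the planted effects this
package is validated against are decided well within those budgets, and the
caps keep a full repeated-CV screen inside minutes rather than hours. Both
are configurable for heavier data.

## Independent validation

`validateOnIndependent()` reruns the identical repeated-CV procedure on a
second dataset restricted to the community's genes present there (>= 50%
overlap required, missing genes reported). Re-running the full CV on the
independent set — rather than freezing the training-set gene list — follows
the reading that the independent-set metrics are themselves CV aggregates.

# Enrichment

Over-representation is the upper-tail hypergeometric probability
`P(X >= k)` of the observed overlap, with the annotation set intersected
with the universe first. The universe is the set of network genes (after
constant-gene filtering): communities can only draw from network genes, so
that is the correct sampling frame; using the full array would overstate
significance. Two conventions are reported per test: the raw p at the 1%
level (the single risk-gene-list test) and Bonferroni-corrected p at 5%
(multi-set collections, corrected within community by the number of sets).

# Shapley attribution

The model explained is one forest per screened community, retrained on the
full dataset restricted to the community's top-N genes (the summary plots
this mirrors show one model per community). The explanation target is the
forest's case vote fraction, so attributions are continuous.

Two routes are implemented and cross-checked:

* `shapExact()` — the brute-force subset enumeration of the Shapley weight
  formula, with `f_x(F)` defined by interventional background averaging
  (features outside `F` replaced by background rows). Enumeration is capped
  at 12 features.
* `shapTree()` — exact polynomial-time attribution for the forest: for each
  background row, a tree restricted to a coalition is a multilinear product
  game over the leaf-path interval constraints, whose Shapley values have a
  closed form; summing over leaves, trees and background rows reproduces the
  brute force to numerical precision. Local accuracy
  (`base + sum(phi) = f(x)`) is enforced by the class validity check on
  every explained sample.

The background is a seeded subsample of the data capped at 100 rows — the
conditioning convention (interventional, fixed background) is a documented
choice. Feature ranking uses mean |phi| (ties by gene id); the direction
summary is the sign of the correlation between a feature's values and its
attributions, so a planted risk gene whose *low* values drive case calls
reports a negative direction.

# The synthetic world

`simulateCoexpression()` generates the stated world the tests rely on:

* module gene `g` in module `m`: `x = sqrt(rho) F_m + sqrt(1 - rho) eps_g`
  with standard-normal factor and noise, so the expected within-module
  correlation is exactly `rho` and the marginal SD is 1; background genes
  are pure noise;
* class signal: a mean shift of `effectSize` (in marginal-SD units, i.e.
  Cohen's d per gene) on the informative fraction of each discriminative
  module's genes — on the genes, not the latent factor, so informative and
  uninformative genes within one module remain distinguishable by the
  selector;
* batch effects per (batch, gene): additive shift ~ N(0, batchShiftSd^2)
  and log-scale factor ~ N(0, batchScaleSd^2), applied as
  `x * exp(lambda) + delta`;
* an annotation set of `annotationSize` genes, `annotationOverlap` of them
  inside the first discriminative module, the rest background;
* values are written as intensities `2^(x + 8)` so the log2 step is
  genuinely exercised.

All draws happen in a fixed order regardless of parameter values, so
matched-seed comparisons isolate single parameters (e.g. accuracy as a
function of effect size). `simulateHierarchicalCoexpression()` adds a
two-level variant (super-blocks containing sub-blocks) for the recursion
tests.

What the generator does **not** emulate: probe-level artifacts, dye effects,
missing values, heavy-tailed noise, correlated batch/class confounding, or
realistic gene-gene correlation topology (scale-free degree distributions,
overlapping modules). A green test therefore establishes algorithmic
correctness on block-structured worlds, not robustness to every microarray
pathology.

# Numerical and degenerate-input choices

* Correlations are clamped to [-1, 1] before the t statistic; `|r| = 1`
  yields p = 0 and is always linked.
* `N` (the top-gene count) is rounded to the nearest integer; `round(N) = 0`
  yields an empty top list, and the attribution stage then falls back to the
  full community.
* F1 is 0 when the denominator vanishes; AUC requires both classes in the
  test fold (guaranteed by stratification).
* Derived seeds (per fold, repetition, community, recursion node) are hashed
  into [0, 2^31) so they remain valid R integers.
* Edge-list TSVs are written with 15 significant digits (round-trip to at
  least 12); the synthetic expression TSV uses 17, which round-trips doubles
  exactly.

# Known limitations

* The screen's 85% accuracy threshold is applied to CV means whose folds
  share samples across repetitions; the SD bars understate sampling
  variability accordingly (a property of the design being mirrored, not a
  bug).
* Boruta's binomial decision ignores the correlation between iterations
  induced by re-using the same training split; at desk scale this makes the
  selector slightly conservative.
* `shapTree()` cost grows with samples x background x total leaf count;
  explaining hundreds of samples against a 100-row background with a
  300-tree forest takes seconds-to-minutes, not milliseconds.
* The signed-network variant (negative-weight-aware quality function) is not
  implemented; `|r|` weighting treats strong negative co-expression as
  strong similarity at the clustering stage while the sign is preserved for
  inspection.
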