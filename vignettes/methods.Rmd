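---
title: "Methods: iterative random forests for ZIP-level case-control risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative random forests for ZIP-level case-control risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(zipforest)
```

## The problem

Suicide-attempt risk (or any rare binary outcome) is modelled here from
*areal* covariates: every patient carries the climatic and sociodemographic
profile of the ZIP code they live in, not individual measurements. Such data
have three structural properties that drive every design choice in this
package:

* **rows repeat** — thousands of patients share each ZIP's feature vector;
* **outcomes are rare** — prevalences of a few percent, so ranking metrics
  must be prevalence-aware (precision-recall, not ROC);
* **features are massively redundant** — census tables and monthly climate
  grids contain near-duplicate columns that dilute any split-based
  importance measure.

## The model

### Regression trees on 0/1 labels

The core learner is a CART-style regression tree minimising the weighted sum
of squared errors. With labels encoded case = 1 / control = 0, a leaf
predicts the mean of the labels that reached it — an estimated case
proportion — so forest scores live in [0, 1] and are directly comparable to
prevalences. The split objective for a node with label sum $S$ and size $n$
splitting into $(S_L, n_L)$ and $(S_R, n_R)$ is the SSE decrease

$$\Delta = \frac{S_L^2}{n_L} + \frac{S_R^2}{n_R} - \frac{S^2}{n},$$

maximised over candidate features and thresholds; ties break toward the
lower feature index, then the lower threshold (on exactly equal doubles).

### Split-threshold placement and binning

Candidate thresholds for a feature with at most `max_bins` (default 256)
distinct values are exactly the midpoints between consecutive distinct
values — the classic exhaustive CART search. Denser features are quantised
to weighted-quantile bins, a standard accuracy/cost trade for forests at
scale; `max_bins` is configurable when exactness matters more than speed.
The test suite verifies node-by-node, against an independent exhaustive
searcher, that every chosen split attains the optimal SSE decrease on small
instances.

### Collapsed rows

Because patients sharing a ZIP have byte-identical feature rows, trees are
grown over distinct rows carrying aggregated (count, $\sum y$, $\sum y^2$)
statistics; the bootstrap draws *patients* and re-aggregates per row. This
is numerically identical to expanding the matrix (a test asserts it) and is
what makes a 50,000-patient cohort over 2,000 ZIPs cheap to fit. `min_leaf`
always counts patients, not ZIPs.

### Iterative reweighting (iRF)

Iteration 1 draws split candidates uniformly ($w^{(1)} = 1/F$). Iteration
$t+1$ draws candidate sets (of size $\lceil \sqrt F \rceil$ by default,
without replacement) with probability proportional to

$$w^{(t+1)} \propto \mathrm{importance}^{(t)} + \varepsilon,
\qquad \varepsilon = \tfrac{1}{100F},$$

where importance is the per-feature total SSE decrease across all splits of
all trees, normalized to sum to one. The literature describes the
reweighting idea without fixing the exact rule; proportional candidate
sampling with an $\varepsilon$ floor is this package's choice — the floor
keeps every feature samplable, so a feature unlucky in early iterations can
recover. Five iterations are the default for the cohort risk model, and the
final iteration's importance vector is the feature ranking. The random
intersection trees (interaction discovery) component of the original iRF
method is intentionally not implemented: only the importance ranking is
consumed downstream.

## Preprocessing

**Correlation pruning.** Features whose pairwise $|r| \ge 0.90$ (computed
over ZIP rows — features are ZIP-level quantities, so ZIP rows are the
natural sample; the boundary is inclusive) are grouped as connected
components of the correlation graph. Components are the minimal
deterministic grouping consistent with "groups of mutually correlated
features" and guarantee the retained set has no pair at or above the
threshold. The retained representative is the highest-variance member
(most informative under variance-reduction splitting), with lexicographic
tie-break; zero-variance columns are dropped outright (their correlation is
undefined and no tree can split on them). Pruning an already-pruned table is
a no-op.

**Age split.** The cohort is split at 60 years (boundary inclusive to the
older stratum), reflecting the regime change in attempt rates around that
age; each stratum is modelled separately because risk factors act
differently by age.

## Evaluation

**Group-shuffled cross-validation.** ZIP codes are the grouping factor: each
of 5 repeats randomly permutes the ZIPs and cuts at the prefix whose
cumulative patient count is closest to 20%, so no ZIP contributes to both
training and test and geospatial leakage is impossible (a hard assertion in
the tests). A test fold containing zero cases — possible at desk scale with
1.6% prevalence — is redrawn with a warning, at most 10 times.

**AUPRC.** The precision-recall curve is computed at every distinct score
threshold (ties processed as one block) and summarised by the
average-precision step sum $\sum_k (r_k - r_{k-1})\,p_k$. Trapezoidal
interpolation is deliberately avoided: linear interpolation in PR space is
known to be optimistic. The expected AUPRC of a random ranking equals the
prevalence, which is the "random chance" baseline reported next to every
result.

**Reduced model.** The top 20 features of the full-design ranking are united
with the forced vendor-rate covariates (≤ 22 features) and cross-validated
against the all-features model. The ranking is fitted on the full stratum
rather than re-fitted inside each CV split — this mirrors how the selection
is used in practice, and carries a mild optimistic bias for the reduced
model's absolute AUPRC; the all-vs-reduced *comparison* is still meaningful
because both models see the same folds' structure.

## Directionality

The method's explainability claim rests on reading effect direction from
the trees themselves. Every split on a feature contributes two points —
each child's (mean feature value, mean outcome), weighted by child size —
from the final iteration's forest (the one that produced the ranking). A
weighted least-squares line through these points gives a slope whose sign
classifies the feature as risk (positive: higher values predict cases) or
protective (negative), plus a weighted $R^2$ measuring how linear the
relationship is. The per-split child-mean construction is this package's
concretisation of "averaging the result of each split"; it uses all the
information a forest exposes about a feature without refitting anything. A
feature never split on, or one whose split points share a single x value,
is `undetermined` rather than assigned an arbitrary sign.

## iRF-LOOP

For each feature as a regression target, a forest predicts it from all
other features over ZIP rows; the target model's normalized importance
vector becomes directed predictor→target edges, so each fitted target's
incoming weights sum to one, and the network is filtered to the top
`floor(0.01 · F(F−1))` edges — 1% of *candidate ordered pairs*, the
interpretation recorded in the run manifest (the alternative, 1% of nonzero
edges, would make the cut depend on forest sparsity).

Two deliberate defaults differ from the cohort model:

* **20 trees per target** — the loop fits F models; at desk scale this
  keeps the full all-against-all pass in seconds while edge weights remain
  stable enough for a top-1% filter.
* **1 iRF iteration per target** (configurable). Iterative reweighting is a
  ratchet: on a target with *no* real predictors it concentrates importance
  on an arbitrary feature, manufacturing strong spurious edges. Measured on the
  planted-dependency fixtures in the test suite, 5-iteration LOOP floods the
  top-1% filter with a majority of edges between mutually independent
  features, while single-pass importance keeps such edges below 10% and
  still recovers at least 4 of 5 planted links. Single-pass forest importance is also the convention of
  all-against-all forest network inference (GENIE3). The per-target
  iteration count for the original analysis is not documented; this default
  is the package's own calibration and is exposed as `loop_n_iterations`.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated; real patient-level data of this kind are protected health
information.

* **Sizes.** Defaults n_zips = 2,000, n_demo_features = 200,
  n_patients = 50,000 preserve the shape of the production data
  (many ZIPs, wide feature table, rare outcome) at 1–2 orders of magnitude
  reduction. The full-scale column structure (1,606 census-style columns +
  density + water/land ratio + 174 climate + 2 vendor rates = 1,784) is
  reproduced exactly when `n_demo_features = 1606`.
* **Climate block.** 12 measurement types × 12 months; columns of one type
  share a latent ZIP effect (same-type correlation ≈ 0.5, safely below the
  0.90 pruning boundary) plus a seasonal mean cycle; 30 static columns
  include log-normal elevation and beta-distributed urban cover.
* **Demographics.** Logit-normal proportions in (0, 1), base rates drawn
  per column.
* **Vendor rates.** Zero-inflated gamma per 10,000 residents — business
  counts are skewed with many zero-vendor ZIPs.
* **Correlated groups.** Planted as noised, sign-flipped copies of a latent
  seed column: member pairwise correlation is controlled exactly via
  $\sigma = \sqrt{1/r - 1}$, and the linear min-max rescale into [0, 1]
  preserves Pearson correlation, so group membership is known ground truth
  for pruning tests. Targets below 0.90 are rejected — the groups exist to
  exercise the pruning boundary.
* **Ages and labels.** Ages ramp up toward 60 and decay exponentially above
  it (about two thirds of the cohort at or above 60, mirroring an older
  veteran-like population). Labels are Bernoulli with
  $\mathrm{logit}\,p = b_{\text{band}} + \sum_j \beta_j z_j$ on standardized
  ZIP features; the per-band intercept is solved numerically so the realized
  prevalence matches the configured 7.2% (under 60) and 1.6% (60+). Planted
  coefficients (|β| between 0.5 and 0.9) give ZIP-level risk variation
  strong enough to be recoverable yet far from separable.
* **What it does not emulate.** No spatial autocorrelation between ZIPs, no
  real census variable semantics, no multi-ZIP residential histories, and
  feature marginals are convenient stand-ins — the real features' joint
  distribution is unknown. Passing tests therefore demonstrate that the
  *machinery* recovers planted structure under realistic shapes and rates,
  not that any particular real-world association would be recovered.

## Numerical and reproducibility choices

* All randomness descends from one base seed through named substreams
  (generation, per-iteration and per-tree forest seeds, CV repeats and
  redraws, per-LOOP-target seeds), so every stage is independently
  reproducible and pipeline reruns are byte-identical.
* A node is pure (leaf) when its SSE is at or below
  $10^{-12}(|\sum y^2| + 1)$; splits require strictly positive gain.
* Weighted-quantile bin edges, the ε importance floor, and the
  highest-variance pruning representative are all deterministic given the
  data, so results never depend on evaluation order.
* Degenerate inputs fail loudly: empty designs, all-zero feature weights,
  single-group CV, curves without positives, constant LOOP targets
  (skipped with a warning), unknown patient ZIPs (reported by id).
* Desk-scale forest defaults (50 trees, `min_leaf = 250`, √F candidate
  fraction) keep a full two-stratum pipeline run on one CPU in minutes;
  `min_leaf = 250` holds the leaf-occupancy ratio at a 50,000-patient cohort
  within a factor of two of the production configuration (1,000-patient
  leaves in a ~405k cohort). Production-scale values (1,000 trees,
  1,000-patient leaves) are plain `run_config()` settings.

## Known limitations

* Importance is split-mass (mean decrease in impurity); it shares that
  family's bias toward high-cardinality features. Correlation pruning
  removes the worst redundancy-driven dilution but sub-threshold correlation
  still spreads importance across related columns.
* The reduced model's feature list is selected on the full stratum, so its
  CV estimate is mildly optimistic (documented above).
* Directionality summarises a possibly non-monotone response by a single
  slope; the $R^2$ column is the honesty check — low values flag features
  whose effect is not well captured by a line.
* LOOP edges are predictive, not causal; direction means "source helps
  predict target", nothing more.
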