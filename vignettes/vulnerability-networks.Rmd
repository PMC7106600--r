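---
title: "Recognizing psychological vulnerability with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing psychological vulnerability with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvqnet)
```

## The problem

Clinical services screen for suicidal behavior (SB) with short
questionnaires, but a sum score hides *which* configuration of answers put
a given patient at risk. pvqnet implements a pipeline that treats the
problem as probabilistic state recognition: a 25-item instrument (five
OQ-45.2 items, six Depressive Experiences Questionnaire items, fourteen
Reasons for Living items) plus eight sociodemographic fields is reduced to
a small set of discrete features, a Bayesian network is learned over those
features under expert constraints, and each patient's answers become
evidence for an exact posterior probability of membership in the
with-SB group, together with an attribution of which answers pushed the
posterior up (risk factors) or down (protective factors).

## The model

A discrete Bayesian network is a directed acyclic graph $G$ over random
variables $X_1,\dots,X_p$ plus one conditional probability table (CPT) per
node; the joint distribution factorizes as

$$P(x_1,\dots,x_p) \;=\; \prod_{i=1}^{p} P\!\left(x_i \mid \mathrm{pa}(x_i)\right).$$

Three modelling commitments follow the method under study:

* **Expert-constrained structure.** Search starts from a whitelist (the
  expert initial graph, arcs that must stay) and never adds blacklisted
  arcs. The shipped default blacklist (`default_constraints()`) makes the
  sociodemographic variables exogenous and the group node a sink. This is
  not a convenience: with a binary outcome whose conditional distribution
  is close to additive-logistic in its parents, partial reversals of the
  outcome's arcs can represent the same joint distribution with fewer
  parameters, so an unconstrained penalized-likelihood search will
  systematically prefer a reversed structure. Orientation of the outcome's
  neighborhood is domain knowledge, not something the data can decide.
* **Score-based search.** Greedy hill-climbing and tabu search over single
  arc additions, deletions and reversals, scored by BIC (default) or BDeu
  (`score_spec()`). Both scores decompose over families, so moves are
  evaluated from local differences with a per-family cache. Tabu search
  keeps a FIFO of the inverses of recent moves (length 10 by default),
  accepts the best non-improving admissible move at a local optimum (up to
  `max_tabu_escapes` consecutive times), applies an aspiration rule, and
  returns the best structure visited. Ties between equal-scoring moves are
  broken lexicographically by (child, parent, add < delete < reverse), so
  both searches are fully deterministic. Hill-climbing demonstrably sticks
  in single-move local optima even on three-variable problems (see
  `test-bayesnet.R`); tabu search reaches the exhaustively enumerated
  optimum there, which is why it is the default.
* **Bayesian parameters.** CPT rows are Dirichlet posterior means with a
  total equivalent sample size `ess = 1` spread uniformly over each
  child-by-parent table: $\hat p(k \mid j) = (n_{jk} + \mathrm{ess}/(rq)) /
  (n_j + \mathrm{ess}/q)$. Unseen parent configurations return the uniform
  row; as $\mathrm{ess} \to 0$ the estimate approaches maximum likelihood.

Inference is exact variable elimination with a min-degree elimination
order; the networks here (a dozen nodes, cardinalities 2–9) make
approximate inference unnecessary. `predict_risk()` thresholds the
posterior of the group node at 0.5 (boundary classified as with-SB), both
configurable.

## Feature construction

* **OQ block.** Items 13, 24 and 31 are positively worded and printed with
  a reversed answer scale; they are scored $4 - \text{position}$. The mean
  of items 3, 13, 24, 31 becomes `oq_mean` (0–4, higher = more distress);
  item 8, the suicidal-ideation screen, stays a standalone ordinal
  variable `oq8`.
* **RFL block.** All fourteen items share the protective direction; the
  mean of thirteen of them becomes `rfl_mean` (1–6), while item 25 ("I'm
  too stable to kill myself") is kept separate as `rfl25` because it is
  informative on its own.
* **DEQ block.** The six items are only weakly inter-correlated, so a mean
  would destroy information. Instead the items are standardized and the
  first two eigenvectors of their correlation matrix are retained — a "low
  self-esteem" and an "interpersonal sensitivity" component. Exactly two
  components are kept as a fixed design choice, not via a variance cutoff.
  Sign indeterminacy is resolved by orienting each component so item 19
  ("I become terrified when I feel alone") loads non-negatively, which
  matches the published orientation where that item is positive on both
  components. A patient's two scores are coded into a quadrant `00/01/10/11`
  (first digit: component 1 at or above 0), the boundary going to the
  "high" side; with centered scores the four quadrants each hold about a
  quarter of a cohort.
* **Discretization.** The two continuous composites enter the discrete
  network as `k = 3` training-quantile levels. The interior edges are
  tie-aware empirical quantiles: a mean of four Likert items takes at most
  17 distinct values, and an interpolated quantile that lands on such an
  atom would reassign the whole tied block at once, so each edge is
  snapped to the boundary between distinct observed values whose
  cumulative share is closest to $j/k$. On tie-free data this coincides
  with ordinary sample quantiles to within one observation.

All transforms are fitted on training data only and serialize to JSON
(`transforms_to_json()`), so held-out scoring is reproducible across
processes.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 3 | quantile levels for each composite |
| `score_spec()` | BIC | structure score; BDeu with configurable `ess` available |
| `ess` (CPTs) | 1 | Dirichlet equivalent sample size for parameter fitting |
| `tabu_length` / `max_tabu_escapes` | 10 / 10 | tabu memory and escape budget |
| `threshold` | 0.5 | posterior cut for the predicted group |
| `structure_mode` | `"per_fold"` | re-learn structure inside every CV fold (honest) vs `"fixed"` |
| `age_bands` | `"table7"` | instrument band coding; `"table3"` enrollment coding also supported |

The two age-band codings are both in circulation for this instrument and
are not mutually consistent; neither is asserted as canonical. Band
intervals are left-closed, with the open-ended top band strictly above its
lower bound.

## Evaluation

`loocv()` refits everything — PCA, discretizer edges, structure (unless
`structure_mode = "fixed"`), CPTs — on the other $N-1$ cases before
predicting case $i$; no parameter used to score a case is ever fitted on
it. `repeated_kfold()` uses stratified folds from a seeded generator and
pools per-repeat accuracy $(tp+tn)/N$. `metrics()` produces the standard
eleven-metric set (sensitivity, specificity, predictive values, F1,
prevalence, detection rate/prevalence, balanced accuracy), reporting
undefined ratios as `NaN` with a warning rather than silently zero.
`select_algorithm()` compares search algorithms by mean cross-validated
classification error (ties by error variance) under a shared fold
assignment; the constraint-based algorithms sometimes named alongside
(Grow-Shrink, the IAMB family, MMPC) are registered but deliberately
unsupported and raise an error rather than silently substituting.

## The synthetic cohort generator

The study's patient-level data is controlled-access, so the package ships
a generator (`generate_cohort()`) whose cohorts have the statistical
structure the analysis assumes *and* a known ground truth, making every
stage testable against an analytic answer.

The generator samples feature-level truth first from a known network
(`default_truth_network()`): gender and age band from the published
marginals, the DEQ quadrant mildly dependent on gender, reasons-for-living
level increasing with age, and the SB label from a logistic-style CPT over
quadrant, RFL level, OQ level and the ideation item, with interaction
terms (ideation amplifies distress; reasons for living buffer the
low-self-esteem quadrants) and an intercept solved so the marginal group
rate is a balanced 0.5015. The interactions matter structurally: they make
the conditional genuinely table-valued, so the full parent set is
identifiable; a purely additive CPT would be representable by smaller
reversed families and no score could prefer the truth.

Items are then rendered from the sampled features: a shared block factor
per instrument (standardized loading 0.93, giving the "highly
inter-correlated" OQ and RFL blocks), two orthogonal components with the
published loading pattern for the DEQ, and Likert discretization. Two
rendering choices serve the generator's design goal that preprocessing
provably inverts the rendering: composite-level latents leave a margin
(22% of the band width) around the quantile boundaries, and component
magnitudes keep a margin (0.6 component SD) away from the quadrant
boundary. The DEQ component variances are scaled to 65% of the published
eigenvalues: the published spectrum implies a mean absolute inter-item
correlation of ~0.32, which would contradict the weak-correlation
structure the block must exhibit; the scaled spectrum gives ~0.21 while
preserving the loading pattern.

Two auxiliary truth networks support specific checks:
`strong_truth_network()` (SB depends only on the two composite levels,
with large effects and every conditional row kept at least 0.45 logits
from the decision boundary, so the classification ceiling is stable under
resampling) and `null_truth_network()` (SB independent of everything — any
cross-validated result materially above 0.5 balanced accuracy would
indicate leakage).

What the generator does **not** emulate: missing or careless responding,
item-level idiosyncrasies beyond a single block factor, dependence of
diagnosis or the remaining demographics on the outcome, measurement drift,
or the real (unpublished) network among the study's variables. Passing the
recovery suite therefore shows the *pipeline* is correct and calibrated on
data satisfying its assumptions — it does not certify performance on real
cohorts.

## Problem sizes and numerical choices in the test suite

The suite checks exact inference against full-joint enumeration on 200
random networks of up to 8 nodes (agreement to 1e-9); tabu search against
the exhaustively scored 25-DAG space on three-node strong-signal problems
(≥95% of 100 datasets); CPT recovery on the strong network at
$n = 20{,}000$ (max absolute error < 0.05 — assessed there because every
row receives ~2,000 observations, whereas the default network's 180-row
outcome table gets ~40 per row, where such a bound is statistically
unattainable for any estimator); structure recovery under the default
expert blacklist at $n = 20{,}000$ over 20 seeds (structural Hamming
distance 0 to the truth CPDAG in ≥90%); and the end-to-end pipeline via
leave-one-out cross-validation on strong-signal cohorts of $n = 500$,
which must land within 0.05 balanced accuracy of the generator's
analytically enumerated Bayes ceiling, with the chance-level control at
0.5. A single $n = 500$ cohort's balanced accuracy carries roughly 0.02
standard deviation from the label draw alone, so the acceptance script
averages three independent cohorts for its reported value.

## Per-patient profiles

`render_profile()` scores one raw record, reports the posterior risk, and
attributes it: for each evidence variable in the Markov blanket of the
group node, the strength is the leave-one-variable-out log risk ratio
$\log P(\text{with} \mid e) - \log P(\text{with} \mid e \setminus v)$ —
positive states are currently pushing the patient toward the risk group,
negative states protect. Variables whose current state is a risk factor
are mapped to intervention focus areas (satisfaction with life,
satisfaction with oneself and achievements, reasons to live) via an
editable dictionary, and `attribute_roles()` carries the three-way
taxonomy of network variables (impacting vulnerability / coexisting and
stable / part of the state). The computation behind "protective/risk
factor" is a package definition — the construct is standard, the formula
is documented in the report itself. Every report ends with a fixed
disclaimer that the output is a research artifact, not a diagnostic
instrument.

## Known limitations

* Validation is synthetic-only; the published headline fit (balanced
  accuracy ≈ 0.70 under leave-one-out cross-validation on the real cohort)
  depends on controlled-access data and is not reproduced here.
* Only score-based structure search is implemented; the constraint-based
  family is intentionally absent.
* Continuous or hybrid networks, latent-variable learning and ROC/AUC
  machinery are out of scope.
* The shipped constraints and truth networks are illustrative defaults,
  not published expert graphs.
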