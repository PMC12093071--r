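---
title: "Forecasting subjective cognitive decline with discrete dynamic Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting subjective cognitive decline with discrete dynamic Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`scdforecast` implements a lifestyle risk calculator for subjective
cognitive decline (SCD) — self-rated worsening of memory, learning and
concentration — built on a discrete, time-homogeneous dynamic Bayesian
network (DBN). The schema has 17 categorical variables per 5-year time
slice: age group (40–80 in 5-year steps), gender, education, six
modifiable lifestyle factors (fruit/vegetable consumption, smoking,
alcohol consumption, leisure-time physical activity, insomnia symptoms,
BMI), five health factors (hypertension, high cholesterol, diabetes,
mental disorders, pain) and the three binary SCD outcomes.

Two kinds of edges are distinguished:

* **Temporal self-edges** are hardwired for the dynamic variables (age and
  the six lifestyle factors): each carries its own value at slice $t-1$ as
  a parent at slice $t$. These edges represent developmental paths and are
  not subject to search.
* **Intra-slice edges** are learned. Nodes are placed in a fixed expert
  ordering (putative causes precede effects; outcomes come last), and each
  node's parent set is chosen from the variables earlier in the ordering.
  This makes acyclicity hold by construction and decomposes the search
  into an independent subset choice per node.

## The qNML score

Parent sets are scored with the quotient normalized maximum likelihood
(qNML) criterion. For a family with child $X$, parents
$\mathbf{P}$ and $n$ complete records, both the joint column over
$\{X\} \cup \mathbf{P}$ and the parent column over $\mathbf{P}$ are
treated as one-dimensional categoricals over their full product domains,
and

$$
\mathrm{qNML}(X,\mathbf{P}) \;=\;
\log \mathrm{NML}\!\left(X\!\times\!\mathbf{P}\right)
\;-\; \log \mathrm{NML}\!\left(\mathbf{P}\right),
\qquad
\log \mathrm{NML}(\cdot) = \sum_j n_j \log\frac{n_j}{n} - \log C(n, k),
$$

where $C(n,k)$ is the parametric complexity (regret) of the $k$-category
multinomial. The score is decomposable, so the network score is the sum
of family scores, and an exhaustive search over all subsets of size
$\le 3$ (the parent cap) per node is exact. Ties are broken toward the
smaller subset, then lexicographically.

$C(n,k)$ is computed **exactly** rather than by the Szpankowski
asymptotic: $C(n,1) = 1$, $C(n,2)$ via its explicit binomial sum, and
$C(n,k) = C(n,k-1) + \tfrac{n}{k-2}\,C(n,k-2)$ for larger $k$, all
carried in log space so that the computation is overflow-safe for any
$n$, $k$ encountered (family sizes here are at most a few hundred
thousand records over a few hundred configurations). Exactness lets the
test suite compare the recurrence against a brute-force sum over all
compositions of $n$ into $k$ parts. Regret values are cached per $n$
across the search.

Two choices the criterion itself does not fix:

* **Configuration-space size.** Unobserved parent/child configurations
  count as structural zeros in the likelihood term, but $k$ in the regret
  is the full *declared* product-space size: the criterion is defined on
  the model's domain, not the observed support.
* **Available-case scoring.** Each candidate family is scored on the
  person-phase records complete for that family, pooled across phases
  (the model is time-homogeneous). This mirrors the available-case CPT
  estimation and avoids imputation, but it means NML scores computed at
  different $n$ are compared: a candidate whose parents have heavy item
  nonresponse is scored on fewer records, which shrinks the magnitude of
  the log-likelihood term and can dominate the comparison. This is a
  documented limitation of the design. Consequently, the structure- and
  effect-recovery checks in the test suite run on synthetic cohorts with
  fully observed covariates (cognitive outcomes still observed only in
  the last two phases, as in the emulated survey design), which keeps
  every candidate for a given node on a common $n$.

## Parameters

CPTs are estimated on family-wise available cases with Bayesian smoothing
under a per-cell Dirichlet$(\tfrac12,\dots,\tfrac12)$ prior (posterior
mean, $p = (n_{\text{cell}} + \tfrac12)/(n_{\text{row}} + \tfrac{k}{2})$),
so every probability is strictly positive. Each node has an
initial-slice CPT (parents: its learned intra-slice parents); each
temporal variable additionally has a transition CPT whose parent set
prepends its own previous-slice value. Transition counts use only
consecutive-phase pairs of the same person; phase gaps contribute
nothing. The age-group transition is not estimated: ageing is exogenous
bookkeeping, fixed to a deterministic +1 category per slice and absorbing
in the top group. Non-temporal nodes (health factors, outcomes) are
regenerated each slice from their intra-slice parents.

# Inference and the calculator

Per-slice inference is **exact** (variable elimination with a greedy
min-size ordering), replacing the approximate expectation-propagation
scheme sometimes used for such models: the slice network has at most 17
discrete nodes with at most three learned parents each, so exact
marginals are cheap, and exactness allows oracle testing against full
joint enumeration (the suite requires agreement to $10^{-9}$ on networks
of up to 10 nodes).

Forecasts unroll the two-slice template: slice-0 posteriors condition on
the user's evidence (age group is mandatory — it is the clock); when
moving to slice $t$, the per-variable **MAP states** (marginal modes,
ties toward the lower category index) of slice $t-1$ feed the transition
CPTs. Propagating modal states rather than full distributions is the
deliberate design of this calculator: it keeps each slice exact and
prevents the overpropagation of uncertainty across slices. MAP here is
per-variable, not joint; a joint-MAP variant would be a different
estimator. Evidence supplied for a future slice overrides anything
propagated into it — this is how intervention targets enter.

The what-if calculator (`compare_scenarios()`) contrasts a current and a
target evidence set that agree at slice 0, reporting the outcome
probabilities, their absolute difference in percentage points, and the
odds ratio $\frac{p_t/(1-p_t)}{p_c/(1-p_c)}$.

**Credible intervals.** The interval construction is the package's own
choice (the quantity is standard, its construction rarely reported):
every estimated CPT row is resampled from its Dirichlet posterior
(observed counts plus the smoothing pseudo-counts), both forecasts are
recomputed under each sampled model, and the equal-tailed quantiles of
the sampled odds ratios form the interval. The default is 500 draws at
the 95% level; draws are seeded and reproducible. The deterministic age
clock is excluded from resampling.

**Decision heatmap.** For each modifiable factor and each attainable
level, the heatmap reports the outcome risk one slice ahead when that
factor is set to that level on top of any committed choices, and the
change (in percentage points) versus keeping the factor at its
status-quo level — the committed level if one exists, otherwise the
current value. Because a cell's delta is measured against its own row's
status-quo cell, the status-quo delta is exactly zero by construction.
Committing a choice re-bases the whole matrix, which is what makes the
heatmap dynamic. The text rendering bins deltas at ±1 and ±5 percentage
points; this is presentation only.

# Evaluation

`cross_validate()` partitions **individuals** (never person-phases) into
$k$ folds with a seeded shuffle, so the repeated measures of one person
never straddle the train/test split. Per fold the full pipeline
(structure search + CPT fitting) is rerun on the training individuals;
each held-out person-phase with an observed outcome is scored with the
posterior probability of the adverse state given its observed same-slice
covariates, excluding the other two SCD outcomes from the conditioning
set (the conditioning set is a package choice; it mimics what a
calculator user could supply). AUROC uses the Mann–Whitney formulation
with ties half-credited, reported pooled over folds and per fold.

# The synthetic cohort generator

No individual-level data from the emulated survey are distributable, so
the generator is the package's only data source and is itself tested
code. It emulates a five-phase occupational cohort at 5-year steps:

* baseline ages 40–60 (five groups), 80% women, three education levels;
* lifestyle and health factors evolving by *sticky Markov* kernels:
  with probability $p$ (default 0.8 for lifestyle, 0.9 for health
  factors) the previous category is retained, otherwise a fresh value is
  drawn from an innovation distribution solved so that the implied
  marginal tracks per-phase targets digitized from published descriptive
  tables (shipped as a labelled emulation-target CSV in `extdata`, not
  real data). Where the solved innovation would be negative it is clamped
  and renormalized, so marginals are tracked approximately there —
  `marginal_check()` reports all deviations beyond three binomial
  standard errors;
* outcomes drawn per phase from an additive category-log-odds (logistic)
  model over age, gender and the six lifestyle factors, with a per-phase
  intercept calibrated by root-finding so the expected prevalence equals
  the target exactly. The defaults plant a mildly protective physical
  activity effect (log-odds $\log 0.76$) and a U-shaped alcohol profile.
  The outcome model is deliberately *not* a Bayesian network, so ground
  truth is analytic and independent of the estimator under test;
* per-variable, per-phase item missingness (cognitive outcomes observed
  only in the last two phases, as in the emulated design) and monotone
  dropout (once out, always out), optionally dependent on the
  previous-phase memory state.

What passing tests do **not** show: the generator reproduces marginals
and a few stylized dependencies, not the joint distribution of any real
cohort; real response processes are not missing-completely-at-random;
and the true phase-1→2 interval of the emulated study was seven years,
which the generator (like the model) treats as one 5-year step.

# Numerical and design choices

* BMI uses three levels (underweight merged with healthy weight), the
  resolution at which descriptive tables are published, although
  four-level codings exist.
* "No answer" education is treated as missing; no imputation anywhere.
* Probability rows must sum to 1 within $10^{-12}$; regret values are
  reproducible to $10^{-9}$ relative; serialization stores full double
  precision (round trips are lossless).
* Degenerate inputs: empty count rows fall back to the prior mean;
  evidence with zero probability under the model raises an
  impossible-evidence error; a horizon that would push age beyond its top
  group is truncated with a warning; constant indicators in correlation
  reports yield `NA`, not errors.
* Effect-recovery scenarios pin every other modifiable factor at the
  target slice (the heatmap-cell semantics), so the estimated odds ratio
  targets the planted conditional effect rather than a partially
  marginalized one.

Problem sizes used by the test suite are package choices balancing
statistical resolution against desk-scale runtimes: effect recovery at
20,000 individuals, structure recovery at 5,000, null calibration at
2,000–5,000, oracle equivalence on networks of up to 10 nodes and count
grids up to $n = 50$, $k = 20$.

# Known limitations

* Available-case scoring couples structure selection to differential
  item nonresponse (see above); with strongly unequal missingness the
  selected parents can reflect response patterns rather than dependence.
* MAP propagation is a point approximation between slices; probabilities
  more than one slice ahead are conditional on modal trajectories, not
  full filtering distributions.
* The scenario odds ratio is a model output, not a causal effect
  estimate; like any observational model, planted or real confounding
  passes straight through.
* Credible intervals reflect CPT parameter uncertainty only, not
  structure uncertainty.
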