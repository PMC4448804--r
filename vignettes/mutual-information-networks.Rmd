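---
title: "Mutual information networks for clinical prognosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual information networks for clinical prognosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cox proportional-hazards regression is the standard tool for prognostic
modelling in cardiology: it estimates a hazard ratio (HR) per clinical
variable and selects the significant ones.  When the variables are strongly
interdependent -- as risk factors, prior history, therapy and
stress-echocardiography readouts are in coronary artery disease (CAD)
cohorts -- collinearity blurs the regression view, and associations that do
not survive model selection disappear from the analysis entirely.

`minprog` implements a complementary, network-based view for cohorts of
binary clinical indicators with a survival endpoint.  Every pair of
variables gets a non-parametric dependence score, the mutual information

$$I(X;Y) = H(X) + H(Y) - H(X,Y),$$

estimated on the 2x2 contingency table; statistically significant pairs
become edges of an undirected weighted graph (the mutual information
network, MIN) with edge weight $I$ and edge length $1/I$.  Indirect
associations are pruned with the data-processing-inequality (DPI) rule used
by ARACNE-style network inference.  The endpoint ("death") is a node like
any other, so prognosis becomes graph geometry: the shortest inverse-MI path
from a variable to the endpoint, centralities, and map-equation modules.
A hand-rolled Cox baseline (univariate screen plus multivariate fit) and a
per-method z-score table let the two views be compared on equal footing.

The package is modelled on a stress-echocardiography cohort of 4313
patients with known or suspected CAD (median follow-up 19 months, 146
deaths, 29 binary indicators); `clinical_variables()` carries that cohort's
variable dictionary, marginal counts and binarization rules.  Patient-level
data from such studies are not public, so a synthetic cohort generator with
planted, known structure stands in for them everywhere the pipeline is
exercised.

## Entropy and MI estimation

`entropy_plugin()` is the maximum-likelihood estimator
$-\sum_i \hat p_i \ln \hat p_i$ (nats).  It is biased downward at finite
$n$; `entropy_mm()` adds the Miller-Madow first-order correction
$(m-1)/(2n)$, with $m$ the number of occupied cells.  `mi_mm()` combines
three MM entropies.  Because the three corrections do not cancel, the MM MI
can be slightly negative for a near-independent table (for the exactly
factorizing 4-observation table the residual is $-1/8$); values are
reported as computed, and the plug-in MI is stored alongside for bound
checks.  Natural logarithms are used throughout; only the permutation
ranks, not the unit, drive significance, and the inverse-MI distances are
non-normalized by design.

Missing entries are handled pairwise-complete per pair, with a guard
(`min_n`, default 10) on the remaining sample size.  Constant columns give
MI 0 with a degeneracy flag rather than an error.

## Permutation significance and the choice of B

Each pair's p-value comes from a seeded Monte Carlo permutation test:
compare the observed MM MI with its value under `B` uniformly random
permutations of the second variable, counting ties as exceedances.
Permuting a binary vector leaves both margins of the 2x2 table fixed, so
the permuted MI depends only on the joint count
$a = \#\{x = 1, y = 1\}$, whose exact permutation distribution is
hypergeometric.  `permutation_pvalue()` therefore draws each replicate as
one `rhyper()` variate -- identical in distribution to an explicit shuffle
(the test suite proves the identity by enumerating all permutations at
small $n$) and O(1) per replicate.  Every pair derives its own RNG stream
from the root seed and the ordered variable names, so matrix results do not
depend on evaluation order.

Two p-value estimators are offered.  The default `add_one`,
$(r+1)/(B+1)$, is the standard valid Monte Carlo estimator and never
returns 0.  `empirical`, $r/B$, can return 0.  The distinction matters
once Bonferroni control enters: with $k$ variables there are
$m = k(k-1)/2$ tests, and an edge needs raw $p \le T/m$.  With the
`add_one` floor $1/(B+1)$ this is attainable only when

$$B \ge m / T,$$

i.e. $B \ge 8120$ for $k = 29$ and $T = 0.05$.  Below that, no edge can
ever be significant under `add_one` (and under `empirical` the null
rate of exact zeros, about $1/(B+1)$ per pair, exceeds the Bonferroni
budget, so false edges appear instead).  `run_pipeline()` warns when its
`B` cannot resolve its own threshold.  The package's end-to-end tests and
the acceptance script use `B = 16000`, which both clears the bound and
keeps the familywise null clean; with the hypergeometric reduction this
costs a few seconds per 406-pair matrix.

## Network construction

`significant_edges()` keeps exactly the pairs with Bonferroni-adjusted
$p \le T$ (default 0.05), MI $\ge D$ (default 0) and MI strictly positive
(a zero-MI edge has no defined length).  Significance filtering happens
*before* DPI pruning: that is the only composition in which both thresholds
are well-typed, since the DPI tolerance compares MI values while $T$
compares p-values.  `dpi_prune()` then examines every triangle of the
candidate graph and marks its weakest edge for removal when its MI is below
$(1-\varepsilon)$ times the smaller of the other two (default
$\varepsilon = 0$, i.e. any strict minimum is removed).  All marks are
computed against the pre-pruning graph and applied simultaneously, so the
result is independent of edge order; exact ties on the minimum are broken
by lexicographic pair order and, with $\varepsilon = 0$, a fully tied
triangle keeps all three edges (no strict inequality).  `build_network()`
assembles the surviving edges into an `igraph` graph, retaining declared
isolated nodes, with `weight` = MI and `length` = 1/MI.

## Network analysis

* `shortest_paths_to()` runs Dijkstra on the inverse-MI lengths with a
  deterministic lexicographic tie-break on predecessors; unreachable nodes
  get an infinite-distance sentinel and are flagged, never zero-filled.
* `centralities()` reports degree, betweenness and PageRank.  Betweenness
  uses the same inverse-MI lengths as the path analysis (consistent with
  the MIN's distance definition); PageRank runs on the MI weights with
  damping 0.85 and uniform teleportation.  Both parameters are exposed and
  documented because the choice between weighted and unweighted variants is
  a genuine free parameter of this analysis style.
* `detect_modules()` minimizes the two-level map equation
  $L(M) = q\,H(Q) + \sum_m p_m H(P_m)$ (bits), with node visit
  probabilities proportional to weighted degree, by greedy agglomeration
  (best pair-merge first, then single-node moves) over seeded restarts
  (default 10).  The test suite requires the greedy optimum to match
  exhaustive minimization over all partitions on small fixtures, and the
  returned partition never scores worse than the all-singleton or
  one-module partitions.
* `classify_edge_strength()` bins edges by the mid-rank percentile
  $(\mathrm{rank}-0.5)/n$ of their MI into the four strength classes used
  to colour MIN figures (top 20%, 60-80%, 40-60%, below 40%); ties share
  the mean rank, so an all-tied network sits in the middle bin.

## The Cox baseline

`fit_cox()` maximizes the Cox partial likelihood by Newton-Raphson with
step-halving, gradient max-norm tolerance $10^{-9}$, at most 50 iterations;
standard errors come from the inverse observed information and 95%
intervals are Wald intervals on the log scale.  Ties use the Breslow
approximation by default (the simplest well-defined choice); Efron is
available behind a flag, and both are cross-checked against an independent
implementation in the test suite.  Monotone likelihoods (complete
separation) raise an error naming the covariate; the pipeline's
multivariate stage therefore pre-drops binary covariates with zero events
in one arm -- at a 3.4% event rate a 1.3%-prevalence variable frequently
has none -- and records the exclusion.  No stepwise or penalized selection
is attempted: only the univariate screen and the full multivariate fit on
the declared panel are in scope.

The score test at $\beta = 0$ equals the log-rank statistic on untied
two-group data; this classical identity is asserted numerically.

## Cross-method comparison

`method_scores()` assembles, per variable, the multivariate HR, the
pairwise MI to the endpoint, and the shortest MIN distance.
`zscore_table()` standardizes each method over its available variables
using the population standard deviation, with the distance negated by
default so that larger z always reads "stronger association"; raw signed
values remain available (`orient_distance = FALSE`), and a `log_hr` flag
standardizes log HRs instead of raw HRs (raw is the default).
`rank_concordance()` reports orientation-corrected Spearman correlations
per method pair.  Variables missing a score -- an unreachable node, a
failed fit -- are flagged unavailable and excluded from standardization.

The 16-variable restricted panel (`restricted_variables()`), which yields
the 17-node network configuration next to the full 29-node one, was defined
by the cohort's earlier regression analysis; the shipped default
reconstructs it from the variables the comparison discusses and is
configurable wherever it is consumed.

## The synthetic cohort generator

`default_spec()` emulates the reference cohort: $n = 4313$, the 29
indicators with prevalences equal to the reported positive counts over
4313, and a 20-edge dependency DAG grouping variables the way a
cardiologist would: prior history (known CAD driving prior infarction and
revascularization, which drives CABG/PCI), risk factors (age driving
hypertension, hypertension driving hypercholesterolemia), therapy flags,
and the stress-test cascade (resting wall-motion abnormality through
rest/peak/delta WMSI; vessel disease driving ischemia, which drives angina
and ECG changes; CFR driving resting LAD velocity).  Non-endpoint edges
carry log-odds effects of 1.5-2.5 (odds ratios ~4.5-12, strong clinical
associations); these sizes are the generator's own calibration, chosen once
so that planted direct dependencies sit clearly above the permutation null
at the cohort's $n$, as the recovery properties assume.

Variables are sampled in topological order from logistic models whose
intercepts are found by bisection (tolerance $10^{-6}$) so that the mean of
the sigmoid over the realized parent configurations equals the target
prevalence -- marginals therefore match the dictionary up to Bernoulli
noise regardless of the planted structure.  Each variable has its own RNG
stream derived from the root seed and the variable name by a stable string
hash, so editing one variable never perturbs another, and identical
spec + seed gives bit-identical cohorts.

The endpoint is *not* a logistic node: survival times are exponential
proportional hazards with linear predictor
$\sum_v \beta_v X_v$ over four hazard covariates (age, LBBB, low CFR,
stress-echo ischemia; HRs 2-2.5), administratively censored at 19 months,
the cohort's median follow-up -- with a 3.4% event rate almost every
follow-up ends at the horizon, so the administrative choice reproduces the
reported median, and the censoring mechanism is deliberately
non-informative.  The baseline hazard $6.1156 \times 10^{-4}$ per month was
solved once, by exact enumeration over the joint distribution of the
(mutually independent) hazard covariates, so that the expected event
fraction equals $146/4313$; it is a frozen constant of the default spec,
never re-fit at generation time.  DAG edges into the endpoint record these
log HRs, so the ground-truth edge set (`truth$direct_edges`) remains the
undirected closure of the DAG.

What the generator does *not* emulate: the real cohort's full joint
distribution (only the planted margins and pairwise structure),
informative censoring, staggered entry, continuous measurements beyond the
age/CFR columns used to exercise `binarize()`, and any latent confounding
beyond the declared DAG.  Passing recovery tests therefore show that the
pipeline finds the kind of structure it assumes, at the cohort's scale and
event rate -- not that it would recover the true dependency structure of
real patients.

## Problem sizes and numerical choices

The test suite and acceptance script use: all $2\times2$ tables with
$n \le 12$ for the estimator oracle; 2000 independent pairs at $n = 2000$,
$B = 199$ for type-I calibration (at much smaller $n$ the discrete 2x2
permutation null is visibly conservative through ties, which is why the
calibration is run at cohort-like scale); 200 random graphs of at most 8
nodes for the DPI and shortest-path oracles; exhaustive partition
enumeration (Bell(8) = 4140) for the map-equation oracle; 1000 simulated
cohorts of $n = 5000$ for Cox recovery of $\beta = \ln 2$; and 20 null
plus 10 planted full-pipeline runs at $n = 4313$, $B = 16000$.  Degenerate
inputs follow fixed rules: zero-MI edges are never admitted, unreachable
distances are infinite sentinels, sd-zero z-scores raise errors naming the
method, and all ties break lexicographically or by mean rank as documented
above.

## Known limitations

Binary indicators only (binarization loses dose-response information, and
the 2x2 MI saturates at $\ln 2$); no edge-stability assessment
(bootstrap) beyond the permutation screen; two-level (not hierarchical)
map equation; Breslow/Efron but no exact tie handling; no time-varying
covariates or stratified baselines; plots are best-effort companions, not
tested artifacts.
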