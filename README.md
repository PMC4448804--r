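# minprog — mutual information networks for clinical prognosis

`minprog` is an R package for exploring the prognostic structure of binary
clinical cohort data with **mutual information networks (MINs)**, side by
side with the standard **Cox proportional-hazards** analysis.

It is aimed at biostatisticians and systems-medicine researchers working
with cohorts like the motivating one: ~4300 patients with known or
suspected coronary artery disease, 29 binary indicators (risk factors,
prior history, therapy, stress-echocardiography readouts) and all-cause
death as the endpoint.  Cox regression ranks variables by hazard ratio but
blurs under collinearity and discards what it does not select; the MIN
keeps every statistically supported pairwise association and turns
prognosis into graph geometry.

## The method

For variables $X, Y$ binarized per the cohort's clinical rules, dependence
is scored by mutual information estimated with the Miller–Madow
bias-corrected entropy estimator (natural log),

$$\hat I(X;Y) = \hat H_{MM}(X) + \hat H_{MM}(Y) - \hat H_{MM}(X,Y),
\qquad \hat H_{MM} = \hat H_{plug} + \frac{m-1}{2n}.$$

Each pair gets a seeded Monte Carlo permutation p-value (B permutations of
one variable; for binary data the permutation null of the 2×2 table is
exactly hypergeometric, which the implementation exploits), Bonferroni
correction over the $k(k-1)/2$ tests, and a significance threshold
$T = 0.05$ plus an MI floor $D = 0$.  Surviving edges are pruned by the
ARACNE data-processing-inequality rule — in every triangle the weakest
edge is removed (tolerance $\varepsilon$) — and assembled into an
undirected graph with edge weight $\hat I$ and length $1/\hat I$.  The
package then computes shortest prognostic paths to the endpoint,
degree / betweenness / PageRank centralities, two-level map-equation
(Infomap-style) modules, and edge-strength quintile classes; a
hand-implemented Cox baseline (Breslow/Efron partial likelihood,
Newton–Raphson) and per-method z-scores support the cross-method
comparison.  A synthetic cohort generator with planted dependency
structure and a proportional-hazards endpoint makes the whole pipeline
reproducible and testable without patient-level data.

See `vignettes/mutual-information-networks.Rmd` for the full methods
account and design rationale.

## Worked example

```r
library(minprog)

cfg <- list(synthetic = default_spec(seed = 1),      # 4313-patient cohort
            perm = perm_config(B = 16000, seed = 1)) # B >= n_tests / T
bundle <- run_pipeline(cfg, quiet = TRUE)
print(bundle)
#> MIN pipeline: 4313 patients, 29 variables (endpoint 'death')
#>   edges: 406 candidates -> 31 significant -> 19 after DPI; 13 modules
```

406 variable pairs were tested; 31 passed the Bonferroni-corrected
permutation screen and 19 direct associations survive DPI pruning.  The
shortest inverse-MI paths to death rank the prognostic variables:

```r
paths <- bundle$paths[bundle$paths$reachable, ]
head(paths[order(paths$distance), c("variable", "distance", "path")], 5)
#>      variable distance                         path
#>           CFR 263.5960                 CFR -> death
#>  Rest_vel_LAD 282.4376 Rest_vel_LAD -> CFR -> death
#>           age 467.8811                 age -> death
#>       Isch_SE 479.3942             Isch_SE -> death
#>        hypert 488.0395       hypert -> age -> death
```

Reduced coronary flow reserve (CFR) is death's nearest neighbour; resting
LAD velocity reaches death *through* CFR — exactly the kind of mediated
prognostic path the network view adds over regression.  The Cox baseline
on the same cohort agrees on the direct drivers:

```r
cm <- bundle$cox_multi$coefficients
head(cm[order(cm$wald_p), c("variable", "hr", "ci_low", "ci_high", "wald_p")], 4)
#>  variable   hr ci_low ci_high   wald_p
#>       CFR 2.50  1.796    3.48 5.70e-08
#>       age 2.16  1.511    3.10 2.51e-05
#>      LBBB 2.52  1.628    3.91 3.48e-05
#>   Isch_SE 2.16  1.448    3.24 1.67e-04
```

and the z-score table aligns the three metrics (HR, MI to death, negated
MIN distance) for the dot-chart comparison; variables without a score
(e.g. unreachable in the network, like LBBB here) stay `NA` rather than
being zero-filled:

```r
head(bundle$zscores[order(-bundle$zscores$z_mi), ], 4)
#>  variable z_hr z_mi z_dist
#>       CFR 2.44 3.83  1.955
#>       age 1.78 1.98 -0.264
#>   Isch_SE 1.78 1.93 -0.389
#>      LBBB 2.48 1.06     NA
```

Since the cohort is synthetic, the recovered edges can be checked against
the planted ground truth (`bundle$cohort$truth$direct_edges`); across the
shipped acceptance runs the pipeline recovers ~90% of planted direct
dependencies with no false edges.  Lower-level entry points (`mi_mm`,
`permutation_pvalue`, `significant_edges`, `dpi_prune`, `build_network`,
`detect_modules`, `fit_cox`, ...) expose every stage individually, and
`run_pipeline(list(input = "patients.csv", ...))` accepts a raw delimited
patient table binarized by the cohort's clinical rules
(`default_rules()`); a small example file ships in `inst/extdata/`.

A thin command-line wrapper is available after installation:

```sh
Rscript exec/minprog run --seed 1 --B 16000 --out minprog_out
Rscript exec/minprog simulate --n 4313 --seed 1 --out cohort_out
```

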