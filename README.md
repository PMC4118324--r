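# risksetmatch

Matched-pair survival analysis when the exposure is an event occurring
over time.

## The problem

In many clinical cohorts the "exposure" whose prognostic effect is of
interest — a pregnancy after breast-cancer treatment, a transplant, a
treatment switch — happens at a subject-specific time during follow-up,
not at baseline. A popular design matches each exposed subject to an
unexposed one with the same prognostic profile, hoping the pair also
shares unmeasured prognosis (controlling the "healthy mother effect":
only subjects in good health undertake the exposure). But forming the
pairs *a posteriori* (Method 1), with controls required to remain
unexposed over their entire follow-up, conditions on the future and
biases the estimated exposure effect. Matching *in real time* (Method 2)
instead draws the control, at each exposure time, from the risk set of
subjects not yet exposed; such a control may later become exposed
("imperfect" pair) and is then censored within her pair and may head a
new pair of her own.

`risksetmatch` implements both matching methods and the two
semi-parametric analyses for the resulting correlated censored data:

* **Stratified Cox model** (Holt–Prentice): one baseline hazard per
  pair, `λ_i(t) = λ_{0,pair}(t) exp{γ(t) E_i(t)}`, fitted by the
  stratified partial likelihood;
* **Marginal Cox models** (Lee–Wei–Amato): a common baseline with pairs
  as clusters and a robust sandwich covariance, unadjusted
  (`γ(t)E_i(t)`), adjusted (`+ β'Z_i`), or with exposure-by-covariate
  interactions (`+ α'(t) Z_i E_i(t)`), so the exposure hazard ratio per
  profile is `exp{γ_l + α_l'z}` on each time interval `I_l`.

Around these it provides the full simulation laboratory used to compare
the Method × Model combinations: an illness-death cohort generator
(initial state → exposure → final event, plus the direct path, all timed
from the origin), a truth engine that computes the
left-truncation-corrected true average hazard ratio `HR̄(t)` by
discretizing the convolution of the exposure-entry density with the
post-exposure event density, and a replication framework reporting the
bias and RMSE of every combination against that truth.

## Worked example

```r
library(risksetmatch)

cfg  <- reference_scenario()            # the healthy-exposure benchmark design
coh  <- simulate_cohort(cfg, seed = 1)  # 2000 subjects, 250 per profile
p2   <- match_cohort(coh, method = 2, seed = 2)
nrow(p2); sum(p2$perfect == 0)
#> [1] 854          # pairs formed in real time
#> [1] 488          # of which imperfect (control exposed later)

grid <- default_interval_grid(coh, L = 4)
grid
#> <interval grid: L = 4, boundaries = [0, 162.261, 338.507, 547.032, 1000]>

tab  <- build_counting_process(p2, "lwa", grid)
fit  <- fit_marginal_cox(tab, grid, "adjusted")
fit
#> <LWA fit (adjusted): 854 pairs, 1017 events>
#>                e1         e2         e3        e4
#> log HR -0.5799344 0.07920403 0.05786995 0.1386964
#> se      0.2243970 0.12354611 0.11635742 0.1348562
```

The four `e` coefficients are the covariate-adjusted exposure log hazard
ratios on the four time intervals: early after diagnosis the exposed
appear protected (few have spent enough time in the exposed state to be
at risk of a post-exposure event), later the effect is near null in this
population — the increasing-then-decreasing pattern the benchmark design
builds in. The matching covariates' effects and the pair-clustered
robust variance are in `fit$beta` and `fit$vcov_robust`;
`profile_loghr(fit, c(0,0,0))` gives the per-profile curve for an
interaction fit.

The corresponding truth:

```r
tr <- truth_curves(cfg, K = 2000)
tr
#> <truth curves: K = 2000 over [0, 1000]; HR range 0.007 - 1.036>
```

and a full replication study, comparing both matching methods and all
four models against it:

```r
res <- run_study(cfg, reps = 200, seed = 1)
res   # per-combination overall bias and RMSE tables
```

A command-line front end with `simulate`, `match`, `fit`, `truth` and
`study` subcommands is installed at `inst/cli/risksetmatch.R`.

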