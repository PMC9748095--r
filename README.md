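# mzipmod

Moderation analysis for zero-inflated count outcomes in two-arm randomized
trials, built around the **marginalized zero-inflated Poisson (MZIP)**
model.

## The problem

Count outcomes such as "number of drinks in a typical week" often carry far
more zeros than a Poisson model allows, because a subset of participants
does not engage in the behavior at all. The classical zero-inflated Poisson
(ZIP) model handles this with a two-component mixture,

```
Y_i ~  0            with probability pi_i
       Poisson(mu_i) with probability 1 - pi_i
logit(pi_i) = z_i' gamma,      log(mu_i) = x_i' beta_ZIP,
```

but its `beta_ZIP` coefficients describe only the latent "engaged"
subpopulation. When a trial asks *does the intervention reduce consumption
in the population as a whole?*, the estimand is the overall mean
`nu_i = E(Y_i) = (1 - pi_i) mu_i`. The MZIP model reparameterizes the same
mixture so that covariates act directly on that overall mean,

```
log(nu_i) = x_i' beta,
```

making `exp(beta)` a population **rate ratio (RR)** and `exp(gamma)` an
**odds ratio (OR)** for a structural (behavioral) zero.

`mzipmod` implements:

- maximum-likelihood MZIP and ZIP fits (BFGS with analytic gradients;
  observed-information standard errors) with Wald rate-/odds-ratio tables;
- a moderation pipeline for a binary effect modifier: full interaction
  model, Wald test and trimming of a nonsignificant interaction,
  conditional rate ratios per moderator stratum with percent-change
  phrasing, g-computed (marginally standardized) group means, and
  nonparametric bootstrap percentile intervals;
- a seeded synthetic-study generator emulating a two-arm brief alcohol
  intervention trial (brief motivational intervention, BMI, vs personalized
  feedback intervention, PFI) among mandated college students, with a
  high-school drinking moderator, zero-inflated drinks-per-week outcomes at
  two follow-ups, and 2% missingness in the moderator;
- a simulation driver measuring bias, RMSE, confidence-interval coverage
  and interaction-test calibration.

## Worked example

```r
library(mzipmod)

tab <- generate_study(generator_config(n_participants = 2000, seed = 1))
report <- run_moderation_analysis(tab, "4m", B = 500, seed = 2)
print(report)
#> Moderation analysis, 4m follow-up
#>   analyzed n = 1952 (48 excluded for missing moderator)
#>   interaction Wald p = 0.0000 -> retained (significant moderation)
#>   BMI vs PFI | no high-school drinking: RR 1.52 (52% higher)
#>   BMI vs PFI | high-school drinking:    RR 0.93 (7% lower)
#>   g-computed group means (bootstrap 95% CI):
#>     hs_drink=0 arm=0: 2.63 [2.30, 2.95]
#>     hs_drink=1 arm=0: 5.21 [4.93, 5.47]
#>     hs_drink=0 arm=1: 4.00 [3.67, 4.35]
#>     hs_drink=1 arm=1: 4.85 [4.64, 5.03]
```

Reading the output: 48 of 2000 simulated participants had a missing
moderator and were excluded. The moderator-by-arm interaction on the
overall mean is significant, so it is retained. Among participants who did
not drink in high school, the counseled arm (BMI) has a 52% *higher* mean
drinks-per-week than written feedback alone (PFI); among high-school
drinkers it is 7% *lower* — close to the generating rate ratios 1.49 and
1.49 × 0.61 = 0.91. The four g-computed cell means fix each participant's
moderator and arm at the cell's values while keeping their other
covariates, then average the predicted overall mean; error bars are
bootstrap 95% percentile intervals (`plot_group_means(report)` draws the
bar chart).

Lower-level entry points: `mzip_fit()` / `zip_fit()` on design matrices,
`coefficient_table()` for RR/OR tables, `conditional_rr()`,
`gcomp_group_means()`, `bootstrap_group_means()`, `run_recovery_study()`
for simulation studies, and `read_study_csv()` / `write_study_csv()` for
data exchange. A thin command-line wrapper lives in
`inst/cli/mzip-cli.R` (`simulate`, `fit`, `moderate`, `recover`).

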