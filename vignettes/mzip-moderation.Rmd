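---
title: "Marginalized zero-inflated Poisson moderation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginalized zero-inflated Poisson moderation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzipmod)
```

## The model

A zero-inflated count outcome is modeled as the two-component mixture

$$
Y_i \sim \begin{cases} 0 & \text{with probability } \pi_i \\
\mathrm{Poisson}(\mu_i) & \text{with probability } 1 - \pi_i, \end{cases}
\qquad \mathrm{logit}\,\pi_i = z_i'\gamma .
$$

The structural-zero probability $\pi_i$ captures participants who do not
engage in the behavior at all; the Poisson component still produces
"chance" zeros with probability $e^{-\mu_i}$. The two parameterizations in
this package differ only in the mean model:

* **ZIP** (`zip_fit()`): $\log \mu_i = x_i'\beta_{\mathrm{ZIP}}$ — effects
  on the latent engaged subpopulation;
* **MZIP** (`mzip_fit()`): $\log \nu_i = x_i'\beta$ with
  $\nu_i = E(Y_i) = (1-\pi_i)\mu_i$ — effects on the *overall* mean, so
  $e^\beta$ is a population rate ratio (RR) and $e^\gamma$ an odds ratio
  (OR) for a structural zero.

Internally the MZIP likelihood uses
$\log \mu_i = x_i'\beta + \mathrm{softplus}(z_i'\gamma)$, since
$1/(1-\pi_i) = 1 + e^{z_i'\gamma}$. Zero observations contribute
$\log\{\pi_i + (1-\pi_i)e^{-\mu_i}\}$, evaluated as a log-sum-exp of
`plogis(eta, log.p = TRUE)` terms so that extreme linear predictors do not
underflow. Positive observations use $\log\Gamma(y+1)$ for the factorial,
so non-integer outcomes (which single imputation can produce) are accepted;
only exact zeros are treated as zeros, values in $(0, 0.5)$ are *not*
rounded, and `strict_integer = TRUE` refuses fractional counts outright.

Assumptions worth keeping in view: counts are conditionally ZIP given
covariates (no overdispersion beyond zero inflation — no negative-binomial
tail), observations are independent, and both submodels are log/logit
linear. The default design uses the same predictor set in both submodels
($X = Z$), configurable via `design_spec()`.

## Estimation and inference

`mzip_fit()` maximizes the likelihood by BFGS with analytic gradients.
Starting values are a Poisson log-linear fit for $\beta$ and a logistic fit
of the zero indicator $1\{y=0\}$ for $\gamma$: cheap and directionally
consistent. The relative objective tolerance is $10^{-12}$ with up to 1000
iterations; convergence additionally requires a small gradient norm. The
tight tolerance costs little with analytic gradients and makes
reparameterization checks (below) sharp.

Standard errors are model-based: the observed information is computed by
central finite differences of the analytic gradient at the optimum (step
$\varepsilon^{1/3}\max(|\theta_j|,1)$), symmetrized and inverted.
Confidence intervals are Wald on the log scale,
$\exp(\hat\theta \pm 1.959964\,\mathrm{SE})$ at the default 95% level — no
small-sample $t$ correction, mirroring standard ML practice — so interval
bounds are always log-symmetric around the point estimate and positive.

Degenerate inputs: an outcome with no zeros leaves the zero submodel weakly
identified and triggers a warning (perfect-separation risk); if the
optimizer drives any $|\gamma_j| > 15$, the fit is retried with a tiny
L2 penalty ($10^{-6}$) on $\gamma$ and a warning, never a silent
divergence. A singular information matrix warns and returns `NA` standard
errors; `coefficient_table()` refuses non-converged fits.

### When are ZIP and MZIP the same model?

The two fits are *not* reparameterizations of each other in general: MZIP's
Poisson-part mean is $\exp\{x_i'\beta + \mathrm{softplus}(z_i'\gamma)\}$,
and the softplus offset lies inside the ZIP family only when it is in the
column span of $X$ over the observed rows. That holds for intercept-only
models and for designs saturated over discrete covariates (e.g.
$X = Z = [1, x_1, x_2, x_1x_2]$ with binary $x_1, x_2$, where any function
of the four cells is in the span). On such designs the package's test suite
requires the two independently parameterized fitters to reach the same
maximized log-likelihood to $10^{-6}$ — a genuine dual-route check of the
optimizer and both likelihoods. On generic designs (e.g. with a continuous
baseline-drinks covariate) the families differ and so, slightly, do their
maxima; the suite does not pretend otherwise.

## The moderation pipeline

`run_moderation_analysis()` reproduces a standard moderation workflow per
follow-up wave:

1. **Exclusion.** Rows with a missing moderator are dropped and counted;
   moderator missingness is assumed MCAR, so dropping is unbiased.
2. **Full model.** MZIP with moderator, arm, their interaction and all
   covariates, in both submodels.
3. **Trimming.** If the overall-mean-submodel interaction's two-sided Wald
   p-value is $\ge \alpha$ (default 0.05; ties trim), the interaction is
   removed from *both* submodels and the model refit. The overall-mean
   submodel drives the decision because the intervention effect on the
   overall mean is the primary estimand; the logit-submodel interaction is
   secondary.
4. **Conditional rate ratios.** RR(BMI vs PFI | moderator $=0$)
   $= e^{\beta_{\mathrm{arm}}}$ and RR | moderator $=1$
   $= e^{\beta_{\mathrm{arm}} + \beta_{\mathrm{int}}}$ (equal when
   trimmed). Prose phrasing is $100\,(RR-1)$ percent "higher" when
   $RR \ge 1$, else $100\,(1-RR)$ percent "lower", rounded to whole
   percents in report text while tables keep full precision.
5. **G-computation.** For each (moderator, arm) cell, those two columns are
   counterfactually fixed for every participant, all other covariates stay
   observed, and the predicted overall means $\nu_i$ are averaged. Because
   the mean model is log-linear, cell-mean ratios across arms collapse
   exactly to coefficient products — the suite checks this to $10^{-12}$.
6. **Bootstrap.** Nonparametric case resampling (rows with replacement,
   resample size $n$, default $B = 1000$), refitting the model and
   recomputing the g-computed means per resample; 95% percentile
   intervals. The trimming decision is **frozen** at the original-sample
   decision rather than re-tested per resample: the reported intervals
   then describe the selected model's group means, not model-selection
   uncertainty. Non-converged resamples are dropped and counted; more than
   5% is an error.

## What the synthetic generator emulates

`generator_config()` defaults encode the study conditions the pipeline
targets — a two-arm randomized brief alcohol intervention trial among
mandated college students:

| quantity | default | rationale |
|---|---|---|
| n | 348 | trial size |
| P(BMI arm) | 180/348 | coin-flip randomization, realized split |
| P(moderator = 1) | 0.80 | high-school drinking prevalence |
| P(male), P(White), P(first-year) | 0.601, 0.733, 0.615 | sample margins |
| baseline drinks | intercept-only MZIP, mean 7.32, $\pi_0 = 0.049$ | pooled baseline moments (mean ≈ 7.3, ≈ 5% zeros) |
| 4m outcome | RRs 0.90, 1.51, 2.04, 1.13, 1.03, 1.94, 1.49, 0.61; ORs 1.50, 0.62, 0.38, 1.07, 0.96, 0.69, 0.56, 1.13 | reference effect sizes with moderation |
| 15m outcome | RRs 2.38, 1.60, 1.42, 1.37, 1.05, 1.11, 0.77; ORs 1.31, 0.61, 0.41, 1.26, 0.91, 0.39, 1.37 | reference effect sizes, no interaction |
| P(missing moderator) | 0.02 | MCAR missingness, ≈ 7–8 of 348 |

Covariates are mutually independent Bernoulli draws and the arm is drawn
independently of everything (randomization): the simplest structure
consistent with reported margins. Baseline drinks come from an
intercept-only MZIP so all generators stay in one family. The two
follow-up outcomes are conditionally independent given covariates, because
the waves are analyzed separately. Counts are generated as integers.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: outcome-dependent attrition (real follow-up
rates were far below 100%; only MCAR moderator missingness is generated),
arm-specific baseline differences (a real randomized sample can show
chance imbalance at baseline; the generator's baseline distribution is
arm-independent by construction), covariate correlation, overdispersion
beyond zero inflation, and recall error in the retrospective moderator.

## Validation design and problem sizes

The test suite validates each stage at the scale its Monte-Carlo error
supports, keeping the default run a few minutes long:

* likelihood values against a naive per-row mixture oracle ($n = 50$,
  $10^{-10}$); analytic gradients against finite differences;
* simulator marginalization ($\bar y \to \overline{\nu}$, $n = 10^5$,
  1% relative) and closed-form zero fractions; a $\chi^2$ goodness-of-fit
  against the pure Poisson limit;
* parameter recovery: 200 replicates at $n = 1000$ from the 4-month
  reference effect sizes — per-coefficient bias on the log scale under
  0.02 and 95% CI coverage within $[0.92, 0.975]$ (the ±2.5-SE binomial
  band for 200 replicates); with the interaction nulled in truth, the
  interaction test rejects at a rate inside the corresponding band around
  0.05;
* the Poisson limit: with the structural-zero mass switched off, MZIP
  $\hat\beta$ matches a Poisson GLM within $10^{-2}$ at $n = 10^4$;
* exact identities: conditional-RR arithmetic, percent phrasing,
  g-computation collapse, $\nu = (1-\pi)\mu$ to machine precision.

`scripts/acceptance.R` re-runs the pipeline end to end on seeded synthetic
studies ($n = 20000$ per wave for precise effect recovery, plus a
trial-sized $n = 348$ run with $B = 300$ bootstrap) and writes every
recomputed quantity as JSON.

## Known limitations

* No negative-binomial or marginalized ZINB extension; overdispersed data
  will show it in goodness of fit, not in inflated standard errors
  (variances are model-based observed-information, not robust/sandwich).
* The bootstrap freezes the trimming decision; model-selection uncertainty
  is deliberately out of scope.
* Wald inference can be optimistic for the logit submodel when zeros are
  scarce; the separation fallback stabilizes the point fit but does not
  repair weak identification.
* No multiple-testing correction across follow-up waves, matching the
  single-wave reporting convention the pipeline mirrors.
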