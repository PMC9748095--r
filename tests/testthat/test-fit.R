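test_that("fitted rate ratios recover the generating values", {
  tab <- small_study(20000, 1234)
  prep <- prepare_analysis_sample(tab, "4m")
  fit <- mzip_fit(prep$y, prep$X, prep$Z)
  expect_true(fit$converged)
  truth <- default_mzip_params("4m")$beta
  se <- sqrt(diag(fit$vcov))[seq_along(truth)]
  # every coefficient within 3 asymptotic SEs of truth ...
  expect_true(all(abs(fit$params$beta - truth) <= 3 * se))
  # ... and the precisely-estimated covariate RRs within 5% relative error
  for (nm in c("male", "white", "firstyear", "baseline_drinks"))
    expect_equal(exp(fit$params$beta[[nm]]), exp(truth[[nm]]),
                 tolerance = 0.05)
})

test_that("optimum is stable under perturbed starting values", {
  tab <- small_study(1500, 5)
  prep <- prepare_analysis_sample(tab, "4m")
  fit <- mzip_fit(prep$y, prep$X, prep$Z)
  start <- c(fit$params$beta, fit$params$gamma) * 1.3 + 0.05
  refit <- mzip_fit(prep$y, prep$X, prep$Z, start = start)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("ZIP intercept-only MLE satisfies the moment identity", {
  set.seed(21)
  n <- 2000
  y <- ifelse(rbinom(n, 1, 0.3) == 1, 0, rpois(n, 5))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- zip_fit(y, X, X)
  pi_hat <- plogis(fit$params$gamma[[1]])
  mu_hat <- exp(fit$params$beta[[1]])
  expect_equal((1 - pi_hat) * mu_hat, mean(y), tolerance = 1e-6)
})

test_that("ZIP and MZIP coincide on a saturated binary design", {
  d <- saturated_instance(400, 31)
  f_m <- mzip_fit(d$y, d$X, d$Z)
  f_z <- zip_fit(d$y, d$X, d$Z)
  expect_equal(f_m$loglik, f_z$loglik, tolerance = 1e-6)
  # shared zero-model parameterization: gamma estimates coincide
  expect_equal(f_m$params$gamma, f_z$params$gamma, tolerance = 1e-4)
})

test_that("degenerate outcomes are flagged", {
  set.seed(77)
  X <- cbind("(Intercept)" = rep(1, 60))
  w <- capture_warnings(mzip_fit(rpois(60, 20) + 1, X, X))
  expect_true(any(grepl("no zeros", w)))
  expect_error(mzip_fit(c(0.5, 1.2, rep(1, 58)), X, X,
                        strict_integer = TRUE), "non-integer")
  expect_error(mzip_fit(c(0, 1, 2), cbind("(Intercept)" = rep(1, 3),
                                          a = 1:3, b = 3:1)),
               "more observations")
})

test_that("coefficient table has Wald geometry and refuses bad fits", {
  tab <- small_study(1200, 8)
  prep <- prepare_analysis_sample(tab, "4m")
  fit <- mzip_fit(prep$y, prep$X, prep$Z)
  ct <- coefficient_table(fit)
  expect_equal(nrow(ct), 16)
  expect_true(all(ct$conf_low < ct$ratio & ct$ratio < ct$conf_high))
  expect_true(all(ct$ratio > 0))
  # CI bounds are exp(est +/- 1.959964 * se): symmetric on the log scale
  expect_equal(log(ct$conf_high) - log(ct$ratio),
               log(ct$ratio) - log(ct$conf_low), tolerance = 1e-10)
  expect_equal(log(ct$conf_high) - ct$estimate,
               qnorm(0.975) * ct$se, tolerance = 1e-10)
  bad <- structure(list(converged = FALSE, gradient_norm = 1),
                   class = c("mzip_fit", "zi_fit"))
  expect_error(coefficient_table(bad), "did not converge")
})

test_that("predictions honor the marginalization identity", {
  tab <- small_study(500, 13)
  prep <- prepare_analysis_sample(tab, "4m")
  fit <- mzip_fit(prep$y, prep$X, prep$Z)
  nu <- predict_overall_mean(fit, prep$X)
  pi <- structural_zero_prob(fit, prep$Z)
  mu <- predict(fit, prep$X, prep$Z, type = "poisson_mean")
  expect_lt(max(abs(nu - (1 - pi) * mu)), 1e-12)

  # intercept-only fit: nu constant at exp(beta0)
  X1 <- matrix(1, 500, 1, dimnames = list(NULL, "(Intercept)"))
  f1 <- mzip_fit(prep$y, X1, X1)
  expect_equal(predict_overall_mean(f1, X1),
               rep(exp(f1$params$beta[[1]]), 500))

  # toggling the arm column multiplies nu by exp(b_arm + b_int * hs) per row
  d1 <- prep$data; d1$arm <- 1
  d0 <- prep$data; d0$arm <- 0
  ratio <- predict_overall_mean(fit, d1) / predict_overall_mean(fit, d0)
  expected <- exp(fit$params$beta[["arm"]] +
                  fit$params$beta[["hs_drink:arm"]] * prep$data$hs_drink)
  expect_equal(ratio, expected, tolerance = 1e-12)

  expect_error(predict_overall_mean(fit, prep$Z[, 1:3]),
               "do not match")
})
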