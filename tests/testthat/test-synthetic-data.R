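test_that("covariate generator honors configured prevalences", {
  # degenerate probability
  cfg <- generator_config(n_participants = 10, p_hs_drink = 1, seed = 1)
  expect_true(all(generate_covariates(cfg)$hs_drink == 1))
  # law of large numbers at n = 1e5 (band ~ 8 binomial SEs)
  cfg <- generator_config(n_participants = 1e5, seed = 2)
  cov <- generate_covariates(cfg)
  expect_lt(abs(mean(cov$hs_drink) - 0.80), 0.01)
  expect_lt(abs(mean(cov$arm) - 180 / 348), 0.01)
  expect_lt(abs(mean(cov$male) - 0.601), 0.01)
})

test_that("configuration is validated", {
  expect_error(generator_config(p_bmi = 1.2), "probabilities")
  expect_error(generator_config(n_participants = 0), "positive integer")
})

test_that("seeded generation is reproducible bit-for-bit", {
  cfg <- generator_config(n_participants = 500, seed = 11)
  expect_identical(generate_study(cfg), generate_study(cfg))
  expect_identical(generate_covariates(cfg), generate_covariates(cfg))
})

test_that("simulator reduces to plain Poisson when the zero mass is off", {
  n <- 1e5
  tab <- data.frame(id = seq_len(n))
  p <- mzip_params(c("(Intercept)" = log(5)), c("(Intercept)" = -40))
  y <- simulate_mzip_outcome(tab, design_spec(character(0)), p, seed = 4)
  expect_lt(abs(mean(y) - 5), 3 * sqrt(5 / n))
  # chi-square goodness of fit against the Poisson(5) pmf on binned counts
  brk <- 0:12
  obs <- tabulate(pmin(y, 12) + 1, nbins = 13)
  expected <- c(dpois(0:11, 5), ppois(11, 5, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(obs, p = expected))
  expect_gt(gof$p.value, 0.01)
})

test_that("zero fraction matches the closed form for intercept-only draws", {
  n <- 1e5
  tab <- data.frame(id = seq_len(n))
  # pi = 0.5, nu = 2 -> mu = 4; P(Y = 0) = pi + (1 - pi) e^{-mu}
  p <- mzip_params(c("(Intercept)" = log(2)), c("(Intercept)" = 0))
  y <- simulate_mzip_outcome(tab, design_spec(character(0)), p, seed = 5)
  p0 <- 0.5 + 0.5 * exp(-4)
  expect_lt(abs(mean(y == 0) - p0), 4 * sqrt(p0 * (1 - p0) / n))
})

test_that("simulated outcomes marginalize to the model overall mean", {
  cfg <- generator_config(n_participants = 1e5, p_missing_moderator = 0,
                          seed = 6)
  tab <- generate_study(cfg)
  d <- build_design(default_design_spec(TRUE), tab)
  nu <- exp(drop(d$X %*% default_mzip_params("4m")$beta))
  expect_lt(abs(mean(tab$drinks_4m) - mean(nu)) / mean(nu), 0.01)
})

test_that("study generator applies MCAR missingness only to the moderator", {
  tab <- generate_study(generator_config(seed = 7))
  expect_equal(nrow(tab), 348)
  n_miss <- sum(is.na(tab$hs_drink))
  expect_true(n_miss >= 1 && n_miss <= 16)  # 2% of 348, wide MC band
  expect_false(anyNA(tab[setdiff(names(tab), "hs_drink")]))
  tab0 <- generate_study(generator_config(p_missing_moderator = 0,
                                          seed = 7))
  expect_false(anyNA(tab0))
})

test_that("default calibration lands in the plausible descriptive bands", {
  tab <- generate_study(generator_config(n_participants = 5e4,
                                         p_missing_moderator = 0, seed = 8))
  z4 <- mean(tab$drinks_4m == 0)
  expect_true(z4 > 0.15 && z4 < 0.30)
  expect_lt(abs(mean(tab$baseline_drinks) - 7.32), 0.3)
  expect_lt(abs(mean(tab$baseline_drinks == 0) - 0.05), 0.02)
})

test_that("simulation errors name the offending row", {
  tab <- data.frame(id = 1:3, x = c(0, 50, 0))
  p <- mzip_params(c("(Intercept)" = 0, x = 0),
                   c("(Intercept)" = 0, x = 2))
  expect_error(
    simulate_mzip_outcome(tab, design_spec("x"), p, seed = 1),
    "row 2")
})
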