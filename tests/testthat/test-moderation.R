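test_that("analysis sample excludes rows with a missing moderator", {
  tab <- small_study(348, 2)
  tab$hs_drink[c(3, 10, 40, 77, 120, 200, 280, 340)] <- NA
  prep <- prepare_analysis_sample(tab, "4m")
  expect_equal(length(prep$y), 340)
  expect_equal(prep$n_excluded, 8)
  expect_true("hs_drink:arm" %in% colnames(prep$X))

  prep0 <- prepare_analysis_sample(small_study(50, 3), "15m")
  expect_equal(prep0$n_excluded, 0)

  tab$hs_drink <- NA
  expect_error(prepare_analysis_sample(tab, "4m"), "no analyzable rows")
  expect_error(prepare_analysis_sample(small_study(20, 1), "9m"))
})

test_that("full moderation model requires the interaction design", {
  prep <- prepare_analysis_sample(small_study(900, 4), "4m")
  noint <- prep$X[, colnames(prep$X) != "hs_drink:arm"]
  expect_error(fit_moderation_model(prep$y, noint, noint), "interaction")
  fit <- fit_moderation_model(prep$y, prep$X, prep$Z)
  expect_s3_class(fit, "mzip_fit")
})

test_that("trimming follows the overall-mean interaction Wald test", {
  # truth without moderation: trimming decision must track the p-value
  p0 <- default_mzip_params("4m")
  p0$beta[["hs_drink:arm"]] <- 0
  p0$gamma[["hs_drink:arm"]] <- 0
  for (seed in 1:3) {
    cfg <- generator_config(n_participants = 1500, outcome_params_4m = p0,
                            p_missing_moderator = 0, seed = seed)
    prep <- prepare_analysis_sample(generate_study(cfg), "4m")
    full <- fit_moderation_model(prep$y, prep$X, prep$Z)
    tr <- trim_if_nonsignificant(full, prep$y, prep$X, prep$Z)
    expect_equal(tr$trimmed, tr$p_interaction >= 0.05)
    if (tr$trimmed) {
      expect_false("hs_drink:arm" %in% tr$fit$design$mean)
      expect_false("hs_drink:arm" %in% tr$fit$design$zero)
    }
    # ties trim: alpha exactly equal to the observed p-value
    tie <- trim_if_nonsignificant(full, prep$y, prep$X, prep$Z,
                                  alpha = tr$p_interaction)
    expect_true(tie$trimmed)
    # p below alpha keeps the full model
    keep <- trim_if_nonsignificant(full, prep$y, prep$X, prep$Z,
                                   alpha = min(1, tr$p_interaction * 2))
    expect_false(keep$trimmed)
    expect_identical(keep$fit, full)
  }
})

test_that("conditional rate ratios and phrasing follow the coefficients", {
  rr <- conditional_rr(default_mzip_params("4m"))
  expect_equal(rr$rr_hs0, 1.49)
  expect_equal(rr$rr_hs1, 1.49 * 0.61)
  expect_equal(rr$phrase_hs0$text, "49% higher")
  expect_equal(rr$phrase_hs1$text, "9% lower")

  trimmed <- mzip_params(c("(Intercept)" = 0, arm = log(0.77)),
                         c("(Intercept)" = 0, arm = 0))
  rr15 <- conditional_rr(trimmed)
  expect_false(rr15$interaction_present)
  expect_equal(rr15$rr_hs0, rr15$rr_hs1)
  expect_equal(rr15$phrase_hs0$text, "23% lower")

  expect_error(conditional_rr(mzip_params(c("(Intercept)" = 0),
                                          c("(Intercept)" = 0))),
               "'arm' coefficient")
  expect_error(percent_change(-1), "positive")
})

test_that("percent phrasing always reports 100*|RR - 1| with direction", {
  for (r in c(0.2, 0.61, 0.9089, 1, 1.49, 2.7)) {
    pc <- percent_change(r)
    expect_equal(pc$percent, round(100 * abs(r - 1)))
    expect_equal(pc$direction, if (r >= 1) "higher" else "lower")
  }
})

test_that("g-computed cell means collapse to coefficient products", {
  prep <- prepare_analysis_sample(small_study(800, 6), "4m")
  fit <- fit_moderation_model(prep$y, prep$X, prep$Z)
  gm <- gcomp_group_means(fit, prep$data)
  cell <- function(h, a) gm$mean[gm$hs_drink == h & gm$arm == a]
  b <- fit$params$beta
  expect_equal(cell(1, 1) / cell(1, 0),
               exp(b[["arm"]] + b[["hs_drink:arm"]]), tolerance = 1e-12)
  expect_equal(cell(0, 1) / cell(0, 0), exp(b[["arm"]]), tolerance = 1e-12)
  expect_equal(cell(1, 0) / cell(0, 0), exp(b[["hs_drink"]]),
               tolerance = 1e-12)
  # high-school drinkers sit above abstainers in both arms (b_hs > 0,
  # b_hs + b_int > 0 under the reference effect sizes)
  expect_gt(cell(1, 0), cell(0, 0))
  expect_gt(cell(1, 1), cell(0, 1))

  # intercept-only model: all four cells equal exp(beta0)
  X1 <- matrix(1, length(prep$y), 1, dimnames = list(NULL, "(Intercept)"))
  f1 <- mzip_fit(prep$y, X1, X1)
  gm1 <- gcomp_group_means(f1, prep$data)
  expect_equal(gm1$mean, rep(exp(f1$params$beta[[1]]), 4))
})

test_that("bootstrap group means are seeded, bracketing and consistent", {
  tab <- small_study(600, 14)
  prep <- prepare_analysis_sample(tab, "4m")
  bt <- bootstrap_group_means(prep$data, "4m", trimmed = FALSE, B = 200,
                              seed = 99)
  expect_true(all(bt$ci_low <= bt$mean & bt$mean <= bt$ci_high))
  bt2 <- bootstrap_group_means(prep$data, "4m", trimmed = FALSE, B = 200,
                               seed = 99)
  expect_identical(bt, bt2)
  expect_error(bootstrap_group_means(prep$data, "4m", B = 50), "at least 200")

  # precision grows with n: median interval width shrinks from n=500 to 2000
  w <- sapply(c(500, 2000), function(n) {
    prep_n <- prepare_analysis_sample(small_study(n, 15), "4m")
    b <- bootstrap_group_means(prep_n$data, "4m", trimmed = FALSE, B = 200,
                               seed = 1)
    median(b$ci_high - b$ci_low)
  })
  expect_lt(w[2], w[1])
})

test_that("full pipeline report recovers the generating moderation", {
  tab <- small_study(2000, 16)
  rep4 <- run_moderation_analysis(tab, "4m", B = 200, seed = 3)
  expect_false(rep4$trimmed)   # strong true interaction at n = 2000
  expect_lt(abs(log(rep4$conditional_rr$rr_hs0 / 1.49)), 0.35)
  expect_lt(abs(log(rep4$conditional_rr$rr_hs1 / 0.91)), 0.30)
  expect_equal(rep4$n + rep4$n_excluded, 2000)
  expect_output(print(rep4), "BMI vs PFI")

  # byte-identical regeneration from the same inputs and seed
  rep4b <- run_moderation_analysis(tab, "4m", B = 200, seed = 3)
  expect_identical(as.character(report_json(rep4)),
                   as.character(report_json(rep4b)))

  expect_error(run_moderation_analysis(tab[0, ], "4m"), "no analyzable")
})
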