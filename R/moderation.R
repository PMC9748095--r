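# Moderation-analysis pipeline for one follow-up wave: exclusion of rows
# with a missing moderator, full interaction model, significance-based
# trimming, conditional rate ratios with percent-change phrasing, and
# g-computed (marginally standardized) group means with nonparametric
# bootstrap percentile intervals.

#' Build the analysis sample for one follow-up wave
#'
#' Drops participants with a missing high-school drinking moderator
#' (reporting the exclusion count), then builds the full-model design
#' matrices including the moderator-by-arm interaction in both submodels.
#'
#' @param table a study data frame (see [generate_study()] or
#'   [read_study_csv()]).
#' @param wave `"4m"` or `"15m"`.
#' @return List with `y`, `X`, `Z`, the retained `data`, `n_excluded` and
#'   `wave`.
#' @export
prepare_analysis_sample <- function(table, wave = c("4m", "15m")) {
  wave <- match.arg(wave)
  outcome <- paste0("drinks_", wave)
  if (!outcome %in% names(table))
    stop("outcome column '", outcome, "' not present in the table")
  keep <- !is.na(table$hs_drink)
  n_excluded <- sum(!keep)
  data <- table[keep, , drop = FALSE]
  if (nrow(data) == 0L)
    stop("no analyzable rows: every participant has a missing moderator")
  d <- build_design(default_design_spec(interaction = TRUE), data)
  y <- as.numeric(data[[outcome]])
  if (anyNA(y)) stop("missing outcome values in column '", outcome, "'")
  list(y = y, X = d$X, Z = d$Z, data = data, n_excluded = n_excluded,
       wave = wave)
}

#' Fit the full moderation model
#'
#' MZIP fit with the moderator, arm, their interaction and all covariates
#' in both submodels. Errors if the design lacks the interaction parents.
#'
#' @param y,X,Z outcome and full-model design matrices from
#'   [prepare_analysis_sample()].
#' @param ... passed to [mzip_fit()].
#' @return An [mzip_fit()].
#' @export
fit_moderation_model <- function(y, X, Z, ...) {
  int <- grep(":", colnames(X), value = TRUE)
  if (!length(int) || !length(grep(":", colnames(Z))))
    stop("design must contain the moderator-by-arm interaction ",
         "in both submodels")
  parents <- strsplit(int[1], ":", fixed = TRUE)[[1]]
  if (!all(parents %in% colnames(X)))
    stop("interaction parents missing from the design: ",
         paste(setdiff(parents, colnames(X)), collapse = ", "))
  mzip_fit(y, X, Z, ...)
}

interaction_p_value <- function(fit) {
  int <- grep(":", fit$design$mean, value = TRUE)
  if (!length(int)) stop("fit has no interaction term")
  nm <- paste0("mean_", int[1])
  est <- fit$coefficients[[nm]]
  se <- sqrt(fit$vcov[nm, nm])
  2 * stats::pnorm(-abs(est / se))
}

#' Trim a nonsignificant interaction
#'
#' Wald-tests the overall-mean-submodel interaction coefficient; if its
#' two-sided p-value is at or above `alpha` (ties trim), the model is refit
#' with the interaction removed from both submodels and flagged as
#' trimmed. The overall-mean submodel drives the decision because the
#' intervention effect on the overall mean is the primary estimand.
#'
#' @param full_fit converged full-model [mzip_fit()].
#' @param y,X,Z the data and full-model design used for `full_fit`.
#' @param alpha trimming threshold (default 0.05, two-sided).
#' @return List with the final `fit`, logical `trimmed` and
#'   `p_interaction`.
#' @export
trim_if_nonsignificant <- function(full_fit, y, X, Z, alpha = 0.05) {
  stopifnot(inherits(full_fit, "mzip_fit"))
  if (!full_fit$converged)
    stop("full model did not converge; cannot test the interaction")
  p <- interaction_p_value(full_fit)
  if (p >= alpha) {
    int <- grep(":", colnames(X), value = TRUE)[1]
    fit <- mzip_fit(y, X[, colnames(X) != int, drop = FALSE],
                    Z[, colnames(Z) != int, drop = FALSE])
    list(fit = fit, trimmed = TRUE, p_interaction = p)
  } else {
    list(fit = full_fit, trimmed = FALSE, p_interaction = p)
  }
}

#' Percent-change phrasing for a ratio
#'
#' Renders a rate or odds ratio as the percent change reported in prose:
#' `100 * (ratio - 1)` percent "higher" when the ratio is at least 1,
#' `100 * (1 - ratio)` percent "lower" otherwise, rounded to a whole
#' percent.
#'
#' @param ratio a positive rate or odds ratio.
#' @return List with `ratio`, integer `percent`, `direction`
#'   (`"higher"`/`"lower"`) and the assembled `text` (e.g. `"49% higher"`).
#' @examples
#' percent_change(1.49)$text   # "49% higher"
#' percent_change(0.77)$text   # "23% lower"
#' @export
percent_change <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0)
    stop("ratio must be a single positive number")
  direction <- if (ratio >= 1) "higher" else "lower"
  pct <- as.integer(round(100 * abs(ratio - 1)))
  list(ratio = ratio, percent = pct, direction = direction,
       text = sprintf("%d%% %s", pct, direction))
}

#' Conditional rate ratios for the arm contrast within moderator strata
#'
#' From the overall-mean coefficients, the BMI-vs-PFI rate ratio is
#' \eqn{e^{\beta_{arm}}} among participants without high-school drinking
#' and \eqn{e^{\beta_{arm} + \beta_{int}}} among those with it (equal when
#' the interaction was trimmed), each phrased as a percent change.
#'
#' @param fit an [mzip_fit()] (or an [mzip_params()]) whose overall-mean
#'   coefficients contain `arm` and optionally `hs_drink:arm`.
#' @return List with `rr_hs0`, `rr_hs1`, `interaction_present`, and
#'   [percent_change()] phrasings `phrase_hs0`, `phrase_hs1`.
#' @examples
#' conditional_rr(default_mzip_params("4m"))$rr_hs1   # 1.49 * 0.61
#' @export
conditional_rr <- function(fit) {
  beta <- if (inherits(fit, "mzip_params")) fit$beta
          else if (inherits(fit, "zi_fit")) fit$params$beta
          else stop("fit must be an mzip_fit or mzip_params")
  if (!"arm" %in% names(beta))
    stop("model does not contain an 'arm' coefficient")
  b_arm <- beta[["arm"]]
  has_int <- "hs_drink:arm" %in% names(beta)
  b_int <- if (has_int) beta[["hs_drink:arm"]] else 0
  rr0 <- exp(b_arm)
  rr1 <- exp(b_arm + b_int)
  list(rr_hs0 = rr0, rr_hs1 = rr1, interaction_present = has_int,
       phrase_hs0 = percent_change(rr0), phrase_hs1 = percent_change(rr1))
}

#' G-computed (marginally standardized) group means
#'
#' For each of the four (moderator, arm) cells, every participant's
#' moderator and arm are set to the cell's values while all other
#' covariates keep their observed values; the cell mean is the average
#' predicted overall mean \eqn{\nu_i}. Because the mean model is
#' log-linear, the ratio of g-computed cell means across arms collapses
#' exactly to the coefficient-product rate ratio.
#'
#' @param fit a converged [mzip_fit()].
#' @param data the analysis data frame (complete covariates).
#' @return Data frame with columns `hs_drink`, `arm`, `mean`.
#' @export
gcomp_group_means <- function(fit, data) {
  stopifnot(inherits(fit, "mzip_fit"))
  cells <- expand.grid(hs_drink = 0:1, arm = 0:1)
  cells$mean <- vapply(seq_len(nrow(cells)), function(i) {
    nd <- data
    nd$hs_drink <- cells$hs_drink[i]
    nd$arm <- cells$arm[i]
    mean(predict_overall_mean(fit, nd))
  }, numeric(1))
  cells
}

#' Bootstrap percentile intervals for the g-computed group means
#'
#' Nonparametric case bootstrap: participants are resampled with
#' replacement, the MZIP model is refit on each resample and the four
#' g-computed cell means recomputed; 95% percentile intervals are taken
#' across resamples. The trimming decision is held fixed at the
#' original-sample decision (pass `trimmed`), so every resample fits the
#' same model shape. Non-converged resamples are dropped and counted; more
#' than `max_fail` of them is an error.
#'
#' @param data analysis data frame (missing moderator already excluded).
#' @param wave `"4m"` or `"15m"`.
#' @param trimmed logical; fit the design without the interaction.
#' @param B number of resamples (at least 200; default 1000).
#' @param seed optional seed for the resampling.
#' @param level confidence level for the percentile interval.
#' @param max_fail maximum tolerated fraction of non-converged resamples.
#' @return Data frame `hs_drink`, `arm`, `mean`, `ci_low`, `ci_high`, with
#'   attributes `B`, `n_failed`, `draws`.
#' @export
bootstrap_group_means <- function(data, wave = c("4m", "15m"),
                                  trimmed = FALSE, B = 1000, seed = NULL,
                                  level = 0.95, max_fail = 0.05) {
  wave <- match.arg(wave)
  if (B < 200) stop("B must be at least 200")
  if (!is.null(seed)) set.seed(seed)
  spec <- default_design_spec(interaction = !trimmed)
  y <- as.numeric(data[[paste0("drinks_", wave)]])
  d <- build_design(spec, data)
  fit0 <- mzip_fit(y, d$X, d$Z)
  point <- gcomp_group_means(fit0, data)

  n <- nrow(data)
  draws <- matrix(NA_real_, B, 4)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    db <- data[idx, , drop = FALSE]
    fitb <- tryCatch(suppressWarnings({
      dd <- build_design(spec, db)
      mzip_fit(y[idx], dd$X, dd$Z)
    }), error = function(e) NULL)
    if (is.null(fitb) || !fitb$converged) {
      n_failed <- n_failed + 1L
      next
    }
    draws[b, ] <- gcomp_group_means(fitb, db)$mean
  }
  if (n_failed > max_fail * B)
    stop("bootstrap failed: ", n_failed, " of ", B,
         " resamples did not converge")
  a <- (1 - level) / 2
  ok <- stats::complete.cases(draws)
  point$ci_low <- apply(draws[ok, , drop = FALSE], 2, stats::quantile, a)
  point$ci_high <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                         1 - a)
  attr(point, "B") <- B
  attr(point, "n_failed") <- n_failed
  attr(point, "draws") <- draws
  point
}

#' Run the full moderation analysis for one follow-up wave
#'
#' Composes the pipeline: exclusion of rows with a missing moderator, full
#' interaction model, Wald test and trimming of a nonsignificant
#' interaction, conditional rate ratios with percent phrasing,
#' structural-zero odds ratios with percent phrasing, and g-computed group
#' means with bootstrap percentile intervals.
#'
#' @param table a study data frame.
#' @param wave `"4m"` or `"15m"`.
#' @param B bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap.
#' @param alpha trimming threshold.
#' @return An object of class `moderation_report`.
#' @examples
#' \donttest{
#' tab <- generate_study(generator_config(seed = 1))
#' rep4 <- run_moderation_analysis(tab, "4m", B = 200, seed = 2)
#' print(rep4)
#' }
#' @export
run_moderation_analysis <- function(table, wave = c("4m", "15m"), B = 1000,
                                    seed = NULL, alpha = 0.05) {
  wave <- match.arg(wave)
  prep <- prepare_analysis_sample(table, wave)
  full_fit <- fit_moderation_model(prep$y, prep$X, prep$Z)
  tr <- trim_if_nonsignificant(full_fit, prep$y, prep$X, prep$Z, alpha)
  rr <- conditional_rr(tr$fit)
  ct <- coefficient_table(tr$fit)
  zt <- ct[ct$submodel == "logit_zero" & ct$term != "(Intercept)", ]
  zero_phrases <- lapply(stats::setNames(zt$ratio, zt$term), percent_change)
  gm <- bootstrap_group_means(prep$data, wave, trimmed = tr$trimmed, B = B,
                              seed = seed)
  structure(list(
    wave = wave, n = length(prep$y), n_excluded = prep$n_excluded,
    full_fit = full_fit, final_fit = tr$fit,
    p_interaction = tr$p_interaction, trimmed = tr$trimmed,
    conditional_rr = rr, coefficient_table = ct,
    zero_model_phrases = zero_phrases, group_means = gm,
    alpha = alpha, B = B, seed = seed),
    class = "moderation_report")
}

#' @export
print.moderation_report <- function(x, ...) {
  cat(sprintf("Moderation analysis, %s follow-up\n", x$wave))
  cat(sprintf("  analyzed n = %d (%d excluded for missing moderator)\n",
              x$n, x$n_excluded))
  cat(sprintf("  interaction Wald p = %.4f -> %s\n", x$p_interaction,
              if (x$trimmed) "trimmed (interaction removed)"
              else "retained (significant moderation)"))
  rr <- x$conditional_rr
  cat(sprintf("  BMI vs PFI | no high-school drinking: RR %.2f (%s)\n",
              rr$rr_hs0, rr$phrase_hs0$text))
  cat(sprintf("  BMI vs PFI | high-school drinking:    RR %.2f (%s)\n",
              rr$rr_hs1, rr$phrase_hs1$text))
  cat("  g-computed group means (bootstrap 95% CI):\n")
  gm <- x$group_means
  for (i in seq_len(nrow(gm)))
    cat(sprintf("    hs_drink=%d arm=%d: %.2f [%.2f, %.2f]\n",
                gm$hs_drink[i], gm$arm[i], gm$mean[i], gm$ci_low[i],
                gm$ci_high[i]))
  invisible(x)
}

#' Serialize a moderation report to JSON
#'
#' Machine-readable counterpart of the printed report. Regeneration from
#' the same table and seed is byte-identical.
#'
#' @param report a `moderation_report`.
#' @param path optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "moderation_report"))
  gm <- report$group_means
  out <- list(
    wave = report$wave, n = report$n, n_excluded = report$n_excluded,
    p_interaction = report$p_interaction, trimmed = report$trimmed,
    conditional_rr = list(
      rr_hs0 = unname(report$conditional_rr$rr_hs0),
      rr_hs1 = unname(report$conditional_rr$rr_hs1),
      phrase_hs0 = report$conditional_rr$phrase_hs0$text,
      phrase_hs1 = report$conditional_rr$phrase_hs1$text),
    zero_model = lapply(report$zero_model_phrases,
                        function(p) list(or = unname(p$ratio),
                                         phrase = p$text)),
    coefficients = report$coefficient_table,
    group_means = data.frame(hs_drink = gm$hs_drink, arm = gm$arm,
                             mean = gm$mean, ci_low = gm$ci_low,
                             ci_high = gm$ci_high),
    B = report$B, seed = report$seed)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = 10)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Bar plot of the g-computed group means
#'
#' Four bars (moderator stratum by arm) with bootstrap percentile error
#' bars, the standard display for a significant moderator-by-arm
#' interaction on a count outcome.
#'
#' @param report a `moderation_report` (or the data frame returned by
#'   [bootstrap_group_means()]).
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_group_means <- function(report, ...) {
  gm <- if (inherits(report, "moderation_report")) report$group_means
        else report
  hts <- matrix(gm$mean[order(gm$hs_drink, gm$arm)], nrow = 2,
                dimnames = list(c("PFI", "BMI"),
                                c("No HS drinking", "HS drinking")))
  lo <- gm$ci_low[order(gm$hs_drink, gm$arm)]
  hi <- gm$ci_high[order(gm$hs_drink, gm$arm)]
  mid <- graphics::barplot(hts, beside = TRUE, ylim = c(0, max(hi) * 1.1),
                           ylab = "Predicted drinks in a typical week",
                           legend.text = rownames(hts), ...)
  graphics::arrows(mid, lo, mid, hi, angle = 90, code = 3, length = 0.05)
  invisible(mid)
}
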