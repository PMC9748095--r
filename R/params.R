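#' MZIP coefficient set
#'
#' Container for the two coefficient vectors of a marginalized zero-inflated
#' Poisson model: `beta` acts on the log overall mean
#' \eqn{\log \nu_i = x_i'\beta} and `gamma` on the log-odds of a structural
#' zero \eqn{\mathrm{logit}\,\pi_i = z_i'\gamma}. Exponentiated `beta`
#' entries are rate ratios (RR) on the overall mean; exponentiated `gamma`
#' entries are odds ratios (OR) for the excess-zero component.
#'
#' @param beta numeric vector of log-rate-ratio coefficients, usually named
#'   after design columns (with `"(Intercept)"` first).
#' @param gamma numeric vector of log-odds-ratio coefficients for the
#'   structural-zero submodel.
#' @return An object of class `mzip_params`.
#' @examples
#' mzip_params(beta = c("(Intercept)" = log(5), arm = log(0.8)),
#'             gamma = c("(Intercept)" = stats::qlogis(0.2), arm = 0))
#' @export
mzip_params <- function(beta, gamma) {
  if (!is.numeric(beta) || !is.numeric(gamma))
    stop("beta and gamma must be numeric vectors")
  if (any(!is.finite(beta)) || any(!is.finite(gamma)))
    stop("all coefficients must be finite")
  structure(list(beta = beta, gamma = gamma), class = "mzip_params")
}

#' @export
print.mzip_params <- function(x, ...) {
  cat("MZIP coefficients\n")
  cat("  overall-mean submodel (log RR):\n")
  print(round(x$beta, 4))
  cat("  structural-zero submodel (log OR):\n")
  print(round(x$gamma, 4))
  invisible(x)
}

#' Design specification for the two MZIP submodels
#'
#' Records which study-table columns enter the overall-mean design matrix X
#' and the structural-zero design matrix Z, plus an optional two-way
#' interaction shared by both submodels. The intercept is always first; the
#' interaction column is the elementwise product of its parents.
#'
#' @param mean_terms character vector of column names for the overall-mean
#'   submodel (excluding the intercept).
#' @param zero_terms column names for the structural-zero submodel; defaults
#'   to `mean_terms` (both submodels share the predictor set in a typical
#'   moderation analysis).
#' @param interaction `NULL`, or a length-2 character vector naming the two
#'   parent columns of an interaction added to both submodels.
#' @return An object of class `design_spec`.
#' @seealso [build_design()], [default_design_spec()]
#' @export
design_spec <- function(mean_terms, zero_terms = mean_terms,
                        interaction = NULL) {
  mean_terms <- as.character(mean_terms)
  zero_terms <- as.character(zero_terms)
  if (!is.null(interaction)) {
    if (length(interaction) != 2L)
      stop("interaction must name exactly two parent columns")
    if (!all(interaction %in% mean_terms) || !all(interaction %in% zero_terms))
      stop("interaction parents must appear in both submodels: ",
           paste(interaction, collapse = ", "))
  }
  structure(list(mean_terms = mean_terms, zero_terms = zero_terms,
                 interaction = interaction),
            class = "design_spec")
}

#' Default trial design: covariates, moderator, arm, optional interaction
#'
#' The standard specification for the emulated trial: sex, race, first-year
#' status and baseline drinks as covariates, the high-school drinking
#' moderator, the randomized arm, and (optionally) the moderator-by-arm
#' interaction, identical in both submodels.
#'
#' @param interaction logical; include the `hs_drink:arm` interaction.
#' @return A [design_spec()].
#' @export
default_design_spec <- function(interaction = TRUE) {
  design_spec(c("male", "white", "firstyear", "baseline_drinks",
                "hs_drink", "arm"),
              interaction = if (interaction) c("hs_drink", "arm"))
}

#' Build design matrices from a study table
#'
#' @param spec a [design_spec()].
#' @param data a data frame with one row per participant.
#' @return A list with matrices `X` (overall mean) and `Z` (structural
#'   zero), each with an `"(Intercept)"` column first.
#' @export
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "design_spec"), is.data.frame(data))
  int_name <- if (!is.null(spec$interaction))
    paste(spec$interaction, collapse = ":")
  X <- matrix_from_names(c("(Intercept)", spec$mean_terms, int_name), data)
  Z <- matrix_from_names(c("(Intercept)", spec$zero_terms, int_name), data)
  list(X = X, Z = Z)
}

# reconstruct a design_spec from the coefficient names of an mzip_params
spec_from_params <- function(params) {
  nb <- setdiff(names(params$beta), "(Intercept)")
  ng <- setdiff(names(params$gamma), "(Intercept)")
  if (is.null(names(params$beta)) || is.null(names(params$gamma)))
    stop("parameter vectors must be named to derive a design")
  int <- grep(":", nb, fixed = FALSE, value = TRUE)
  if (length(int) > 1L) stop("at most one interaction term is supported")
  interaction <- if (length(int)) strsplit(int, ":", fixed = TRUE)[[1]]
  design_spec(setdiff(nb, int), setdiff(ng, int), interaction)
}
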