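# Mixture log-likelihoods for the ZIP and MZIP parameterizations.
#
# Both models share the observation density
#   y = 0:  pi + (1 - pi) exp(-mu)
#   y > 0:  (1 - pi) mu^y exp(-mu) / y!
# with logit(pi_i) = z_i' gamma. They differ in the mean model:
#   ZIP:   log mu_i = x_i' beta                     (Poisson-part mean)
#   MZIP:  log nu_i = x_i' beta,  mu_i = nu_i / (1 - pi_i)
# i.e. for MZIP log mu_i = x_i' beta + softplus(z_i' gamma), since
# 1/(1 - pi) = 1 + exp(eta). Zero contributions use a log-sum-exp;
# lgamma(y + 1) replaces the factorial so non-integer counts (e.g. from
# imputation) are accepted.

mixture_ll_vector <- function(beta, gamma, y, X, Z, marginalized) {
  eta <- drop(Z %*% gamma)
  lmu <- drop(X %*% beta) + if (marginalized) softplus(eta) else 0
  mu <- exp(lmu)
  lpi <- stats::plogis(eta, log.p = TRUE)
  l1m <- stats::plogis(-eta, log.p = TRUE)
  z0 <- y == 0
  ll <- numeric(length(y))
  ll[z0] <- log_add_exp(lpi[z0], l1m[z0] - mu[z0])
  ll[!z0] <- l1m[!z0] + y[!z0] * lmu[!z0] - mu[!z0] - lgamma(y[!z0] + 1)
  ll
}

check_ll_dims <- function(params, y, X, Z) {
  if (!is.matrix(X) || !is.matrix(Z))
    stop("X and Z must be numeric matrices")
  if (length(y) != nrow(X) || length(y) != nrow(Z))
    stop("dimension mismatch: length(y) = ", length(y), ", nrow(X) = ",
         nrow(X), ", nrow(Z) = ", nrow(Z))
  if (length(params$beta) != ncol(X))
    stop("dimension mismatch: length(beta) = ", length(params$beta),
         " but ncol(X) = ", ncol(X))
  if (length(params$gamma) != ncol(Z))
    stop("dimension mismatch: length(gamma) = ", length(params$gamma),
         " but ncol(Z) = ", ncol(Z))
  if (any(y < 0)) stop("y must be nonnegative")
}

#' MZIP log-likelihood
#'
#' Log-likelihood of the marginalized zero-inflated Poisson model at a given
#' coefficient set. Coefficients `beta` act on the log overall mean
#' \eqn{\nu_i = E(Y_i)}; internally the Poisson-part mean is
#' \eqn{\mu_i = \nu_i / (1 - \pi_i)}. Zero observations contribute
#' \eqn{\log\{\pi_i + (1-\pi_i) e^{-\mu_i}\}} via a numerically stable
#' log-sum-exp.
#'
#' @param params an [mzip_params()] (or list with `beta`, `gamma`).
#' @param y nonnegative outcome counts.
#' @param X,Z design matrices for the overall-mean and structural-zero
#'   submodels (intercept column included).
#' @return The scalar log-likelihood.
#' @export
mzip_loglik <- function(params, y, X, Z) {
  check_ll_dims(params, y, X, Z)
  ll <- mixture_ll_vector(params$beta, params$gamma, y, X, Z,
                          marginalized = TRUE)
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood contribution at row ",
         which(!is.finite(ll))[1])
  sum(ll)
}

#' ZIP log-likelihood
#'
#' Log-likelihood of the conventional zero-inflated Poisson model, in which
#' `beta` acts on the log Poisson-part mean \eqn{\mu_i} rather than the
#' overall mean.
#'
#' @inheritParams mzip_loglik
#' @return The scalar log-likelihood.
#' @export
zip_loglik <- function(params, y, X, Z) {
  check_ll_dims(params, y, X, Z)
  ll <- mixture_ll_vector(params$beta, params$gamma, y, X, Z,
                          marginalized = FALSE)
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood contribution at row ",
         which(!is.finite(ll))[1])
  sum(ll)
}

# Negative log-likelihood over a concatenated parameter vector, with an
# optional tiny L2 penalty on gamma (separation fallback). Non-finite values
# are capped so the line search can back off instead of aborting.
mixture_nll <- function(par, y, X, Z, marginalized, ridge = 0) {
  p <- ncol(X)
  ll <- mixture_ll_vector(par[seq_len(p)], par[-seq_len(p)], y, X, Z,
                          marginalized)
  val <- -sum(ll) + 0.5 * ridge * sum(par[-seq_len(p)]^2)
  if (!is.finite(val)) return(1e10)
  val
}

# Analytic gradient of mixture_nll. For y > 0:
#   d/d(x'b) = y - mu,  d/d(eta) = pi (y - 1 - mu)    [MZIP]
#                        d/d(eta) = -pi               [ZIP]
# For y = 0, with A = pi + (1-pi) e^{-mu} and w = (1-pi) e^{-mu} / A:
#   d/d(x'b) = -w mu
#   d/d(eta) = pi (1-pi) (1 - e^{-mu}) / A - [MZIP only] pi w mu
mixture_ngr <- function(par, y, X, Z, marginalized, ridge = 0) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  gamma <- par[-seq_len(p)]
  eta <- drop(Z %*% gamma)
  lmu <- drop(X %*% beta) + if (marginalized) softplus(eta) else 0
  mu <- exp(lmu)
  pi <- stats::plogis(eta)
  lpi <- stats::plogis(eta, log.p = TRUE)
  l1m <- stats::plogis(-eta, log.p = TRUE)
  z0 <- y == 0
  gb <- ge <- numeric(length(y))
  gb[!z0] <- y[!z0] - mu[!z0]
  ge[!z0] <- if (marginalized) pi[!z0] * (y[!z0] - 1 - mu[!z0]) else -pi[!z0]
  ll0 <- log_add_exp(lpi[z0], l1m[z0] - mu[z0])
  w <- exp(l1m[z0] - mu[z0] - ll0)
  gb[z0] <- -w * mu[z0]
  q <- exp(lpi[z0] + l1m[z0] - ll0)          # pi (1 - pi) / A
  ge[z0] <- q * (-expm1(-mu[z0])) -
    if (marginalized) pi[z0] * w * mu[z0] else 0
  g <- -c(drop(crossprod(X, gb)), drop(crossprod(Z, ge))) +
    c(numeric(p), ridge * gamma)
  g[!is.finite(g)] <- 0
  g
}

# Observed information at `par`: central finite differences of the analytic
# gradient of the unpenalized negative log-likelihood.
observed_information <- function(par, y, X, Z, marginalized) {
  k <- length(par)
  H <- matrix(0, k, k)
  h <- .Machine$double.eps^(1 / 3) * pmax(abs(par), 1)
  for (j in seq_len(k)) {
    e <- numeric(k)
    e[j] <- h[j]
    H[, j] <- (mixture_ngr(par + e, y, X, Z, marginalized) -
               mixture_ngr(par - e, y, X, Z, marginalized)) / (2 * h[j])
  }
  (H + t(H)) / 2
}
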