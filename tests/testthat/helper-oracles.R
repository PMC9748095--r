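# Independent oracles and small fixtures, built in code.

# Naive per-row mixture log-likelihood: no log-sum-exp, dpois for the
# Poisson density. Deliberately independent of the package's vectorized
# log-scale implementation.
brute_force_loglik <- function(beta, gamma, y, X, Z, marginalized = TRUE) {
  total <- 0
  for (i in seq_along(y)) {
    eta <- sum(Z[i, ] * gamma)
    pi <- 1 / (1 + exp(-eta))
    mu <- exp(sum(X[i, ] * beta)) * (if (marginalized) 1 / (1 - pi) else 1)
    total <- total + if (y[i] == 0)
      log(pi + (1 - pi) * exp(-mu))
    else
      log(1 - pi) + dpois(y[i], mu, log = TRUE)
  }
  total
}

# small synthetic study with complete moderator data
small_study <- function(n, seed, missing = 0) {
  generate_study(generator_config(n_participants = n,
                                  p_missing_moderator = missing,
                                  seed = seed))
}

# data on a saturated design over two binary covariates: the one setting
# where the ZIP and MZIP families are exact reparameterizations of each
# other (softplus of any zero-model linear predictor is itself a function
# of the four cells, hence lies in the span of the saturated X)
saturated_instance <- function(n, seed) {
  set.seed(seed)
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.6)
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2, "x1:x2" = x1 * x2)
  beta <- c(log(3), 0.4, -0.3, 0.5)
  gamma <- c(-0.4, 0.5, 0.3, -0.2)
  eta <- drop(X %*% gamma)
  pi <- plogis(eta)
  mu <- exp(drop(X %*% beta)) / (1 - pi)
  y <- ifelse(rbinom(n, 1, pi) == 1, 0, rpois(n, mu))
  list(y = y, X = X, Z = X)
}

# analysis-ready pieces for one wave of a simulated study
study_design <- function(tab, wave = "4m") {
  prepare_analysis_sample(tab, wave)
}
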