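# Independent numerical oracles used to check the model-fitting code.
# These are deliberately written from first principles (no lme4).

# Gauss-Hermite nodes/weights for weight exp(-x^2), by Golub-Welsch on the
# Jacobi matrix of the (physicists') Hermite recurrence.
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Marginal log-likelihood of a random-intercept logistic model, integrating
# the subject effect by fixed (non-adaptive) Gauss-Hermite quadrature.
gh_loglik_random_intercept <- function(y, eta_fixed, subject, sigma, n_nodes = 51) {
  gh <- gauss_hermite(n_nodes)
  b <- sqrt(2) * sigma * gh$nodes          # b ~ N(0, sigma^2)
  w <- gh$weights / sqrt(pi)
  sum(vapply(split(seq_along(y), subject), function(ix) {
    # log sum_k w_k * prod_j Bernoulli(y_j | plogis(eta_j + b_k))
    lp <- vapply(b, function(bk) {
      p <- stats::plogis(eta_fixed[ix] + bk)
      sum(stats::dbinom(y[ix], 1, p, log = TRUE))
    }, numeric(1))
    m <- max(lp)
    m + log(sum(w * exp(lp - m)))
  }, numeric(1)))
}

# Plain iteratively reweighted least squares for logistic regression.
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  beta
}

# A tiny battery design used by several tests: every count is the smallest
# that keeps the balanced cells intact.
tiny_config <- function(seed = 1L) {
  design_config(n_per_condition = 3, trials_per_training_session = 24,
                oddity_trials = 12, picture_id_trials = 12,
                repetition_words = 12, naming_pictures = 6,
                aptitude_trials = 24, continuum_repetitions = 10,
                seed = seed)
}
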