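# Independent oracles used by the tests: direct likelihood evaluation and
# general-purpose numerical maximisation, written without touching the
# package's EM code paths.

# Multivariate normal log density, straight from the definition.
oracle_mvn_logdens <- function(y, mean, cov) {
  d <- length(y)
  -0.5 * (d * log(2 * pi) + determinant(cov, logarithm = TRUE)$modulus +
            drop(t(y - mean) %*% solve(cov) %*% (y - mean)))
}

# LCA mixture log-likelihood from mixing proportions and item probabilities.
oracle_lca_loglik <- function(U, pi_c, probs) {
  n <- nrow(U); K <- length(pi_c)
  ll <- 0
  for (i in seq_len(n)) {
    li <- 0
    for (c in seq_len(K))
      li <- li + pi_c[c] * prod(probs[c, ]^U[i, ] * (1 - probs[c, ])^(1 - U[i, ]))
    ll <- ll + log(li)
  }
  ll
}

# Joint one-step log-likelihood (indicators + growth outcomes).
oracle_joint_loglik <- function(U, Y, pi_c, probs, growth_list, loadings) {
  n <- nrow(U); K <- length(pi_c)
  ll <- 0
  for (i in seq_len(n)) {
    li <- 0
    for (c in seq_len(K)) {
      g <- growth_list[[c]]
      psi <- matrix(c(g$var_intercept, g$cov_int_slope,
                      g$cov_int_slope, g$var_slope), 2, 2)
      mu <- drop(loadings %*% c(g$mean_intercept, g$mean_slope))
      cov <- loadings %*% psi %*% t(loadings) + diag(g$resid_var, nrow(loadings))
      li <- li + pi_c[c] *
        prod(probs[c, ]^U[i, ] * (1 - probs[c, ])^(1 - U[i, ])) *
        exp(oracle_mvn_logdens(Y[i, ], mu, cov))
    }
    ll <- ll + log(li)
  }
  ll
}

# Brute-force maximum of the 2-class LCA likelihood on a tiny dataset:
# multi-start quasi-Newton on the unconstrained (logit) scale.
oracle_lca_max <- function(U, n_starts = 40, seed = 99) {
  set.seed(seed)
  P <- ncol(U)
  negll <- function(v) {
    pi1 <- plogis(v[1])
    probs <- matrix(plogis(v[-1]), 2, P)
    -oracle_lca_loglik(U, c(pi1, 1 - pi1), probs)
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    v0 <- c(rnorm(1, 0, 1), rnorm(2 * P, 0, 1.5))
    res <- tryCatch(optim(v0, negll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(res) && res$value < best) best <- res$value
  }
  -best
}

# Brute-force maximum of the 2-class one-step joint likelihood on a tiny
# dataset: multi-start BFGS on an unconstrained parameterisation
# (logit pi, logit item probs, growth means, log-Cholesky Psi, log theta).
oracle_one_step_max <- function(U, Y, loadings, n_starts = 50, seed = 99) {
  set.seed(seed)
  P <- ncol(U)
  unpack_growth <- function(g6) {
    L <- matrix(c(exp(g6[3]), g6[4], 0, exp(g6[5])), 2, 2)
    psi <- L %*% t(L)
    list(mean_intercept = g6[1], mean_slope = g6[2],
         var_intercept = psi[1, 1], var_slope = psi[2, 2],
         cov_int_slope = psi[1, 2], resid_var = exp(g6[6]))
  }
  negll <- function(v) {
    pi1 <- plogis(v[1])
    probs <- matrix(plogis(v[2:(1 + 2 * P)]), 2, P, byrow = TRUE)
    g1 <- unpack_growth(v[(2 + 2 * P):(7 + 2 * P)])
    g2 <- unpack_growth(v[(8 + 2 * P):(13 + 2 * P)])
    val <- tryCatch(
      -oracle_joint_loglik(U, Y, c(pi1, 1 - pi1), probs, list(g1, g2), loadings),
      error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  H <- solve(crossprod(loadings), t(loadings))
  b <- Y %*% t(H)
  mu0 <- colMeans(b)
  best <- Inf
  for (s in seq_len(n_starts)) {
    g0 <- function() c(mu0 + rnorm(2, 0, 1), log(runif(1, 0.3, 2)),
                       rnorm(1, 0, 0.3), log(runif(1, 0.3, 2)),
                       log(runif(1, 0.3, 2)))
    v0 <- c(rnorm(1), rnorm(2 * P, 0, 1.5), g0(), g0())
    res <- tryCatch(optim(v0, negll, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-13)),
                    error = function(e) NULL)
    if (!is.null(res) && res$value < best) best <- res$value
  }
  -best
}
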