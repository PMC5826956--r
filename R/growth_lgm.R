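# Weighted maximum-likelihood estimation of a single-class linear growth
# model: the computational kernel shared by the one-step, three-step and
# case-weight approaches.  The marginal model is y ~ N(Lambda mu,
# Lambda Psi Lambda' + theta I) with a common residual variance theta.

#' Weighted sample of repeated outcomes
#'
#' @param outcomes n x T outcome matrix.
#' @param weights length-n vector of non-negative case weights (default all
#'   1); the effective sample size is their exact sum.
#' @return An object of class `"weighted_sample"` with fields `outcomes`,
#'   `weights`, `effective_n`.
#' @export
weighted_sample <- function(outcomes, weights = rep(1, nrow(outcomes))) {
  outcomes <- as.matrix(outcomes)
  weights <- as.numeric(weights)
  if (length(weights) != nrow(outcomes))
    stop("one weight per outcome row required")
  if (any(weights < 0)) stop("weights must be non-negative")
  effective_n <- sum(weights)
  if (effective_n <= 0) stop("effective sample size must be positive")
  structure(list(outcomes = outcomes, weights = weights,
                 effective_n = effective_n),
            class = "weighted_sample")
}

# Vectorised multivariate-normal log density of the rows of Y.
mvn_logdens <- function(Y, mean, cov) {
  Tt <- ncol(Y)
  R <- chol(cov)                              # t(R) %*% R = cov
  z <- forwardsolve(t(R), t(Y) - mean)
  -0.5 * Tt * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

#' Weighted log-likelihood of a linear growth model
#'
#' \eqn{\sum_i w_i \log \phi_T(y_i; \Lambda\mu, \Lambda\Psi\Lambda' +
#' \theta I)}, the weight-expanded marginal normal log-likelihood.
#'
#' @param params a [growth_params()].
#' @param sample a [weighted_sample()].
#' @param loadings T x 2 loading matrix.
#' @return scalar weighted log-likelihood.
#' @export
lgm_loglik <- function(params, sample, loadings = growth_loadings(ncol(sample$outcomes))) {
  stopifnot(inherits(params, "growth_params"),
            inherits(sample, "weighted_sample"))
  mom <- implied_outcome_moments(params, loadings)
  ev <- eigen(mom$cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("implied outcome covariance is not positive definite")
  sum(sample$weights * mvn_logdens(sample$outcomes, mom$mean, mom$cov))
}

# Unnormalised per-subject log density under a growth_params-style list
# (tolerant of non-PD matrices: returns NULL on failure).  Used by the EM
# inner loops where params are plain lists, not validated objects.
lgm_logdens_rows <- function(p, Y, loadings) {
  cov <- loadings %*% growth_psi(p) %*% t(loadings) +
    diag(p$resid_var, nrow(loadings))
  R <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  z <- forwardsolve(t(R), t(Y) - drop(loadings %*% growth_mu(p)))
  -0.5 * ncol(Y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

# Conditional moments of the growth factors given y under current params:
# posterior mean rows M (n x 2) and shared posterior covariance V (2 x 2).
lgm_factor_moments <- function(p, Y, loadings) {
  psi <- growth_psi(p); mu <- growth_mu(p)
  S <- loadings %*% psi %*% t(loadings) + diag(p$resid_var, nrow(loadings))
  B <- psi %*% t(loadings) %*% solve(S)       # 2 x T regression of eta on y
  resid <- t(Y) - drop(loadings %*% mu)       # T x n
  M <- t(mu + B %*% resid)                    # n x 2
  V <- psi - B %*% loadings %*% psi
  list(M = M, V = (V + t(V)) / 2)
}

# One closed-form weighted M-step update of (mu, Psi, theta) given the
# factor moments; weights w, total mass Wt.
lgm_m_step <- function(fm, Y, w, loadings) {
  Wt <- sum(w)
  Tt <- ncol(Y)
  mu <- colSums(w * fm$M) / Wt
  Mc <- sweep(fm$M, 2L, mu)
  psi <- crossprod(Mc * sqrt(w)) / Wt + fm$V
  E <- Y - fm$M %*% t(loadings)
  theta <- sum(w * rowSums(E^2)) / (Tt * Wt) +
    sum(diag(loadings %*% fm$V %*% t(loadings))) / Tt
  list(mean_intercept = mu[1], mean_slope = mu[2],
       var_intercept = psi[1, 1], var_slope = psi[2, 2],
       cov_int_slope = psi[1, 2], resid_var = theta)
}

# Deterministic method-of-moments starting values: per-subject OLS
# intercept/slope, their weighted moments, pooled residual variance.
lgm_moment_start <- function(Y, w, loadings) {
  Wt <- sum(w)
  H <- solve(crossprod(loadings), t(loadings))     # 2 x T
  B <- Y %*% t(H)                                  # n x 2 OLS coefficients
  mu <- colSums(w * B) / Wt
  E <- Y - B %*% t(loadings)
  df <- ncol(Y) - ncol(loadings)
  theta <- max(sum(w * rowSums(E^2)) / (Wt * df), 1e-4)
  Bc <- sweep(B, 2L, mu)
  covb <- crossprod(Bc * sqrt(w)) / Wt
  psi <- covb - theta * solve(crossprod(loadings))
  # project to comfortably positive definite for a safe start
  ed <- eigen((psi + t(psi)) / 2, symmetric = TRUE)
  ev <- pmax(ed$values, 0.05 * max(abs(ed$values), 1e-3))
  psi <- ed$vectors %*% diag(ev, 2L) %*% t(ed$vectors)
  list(mean_intercept = mu[1], mean_slope = mu[2],
       var_intercept = psi[1, 1], var_slope = psi[2, 2],
       cov_int_slope = psi[1, 2], resid_var = theta)
}

#' Fit a weighted linear growth model by maximum likelihood
#'
#' Maximises [lgm_loglik()] over the six growth parameters, with the
#' residual variance constrained equal across time points.  Two fitters are
#' provided and agree on regular problems: `"em"` (default) treats the
#' growth factors as missing data and iterates closed-form weighted updates;
#' `"optim"` runs BFGS on an unconstrained reparameterisation (means,
#' log-Cholesky of Psi, log residual variance).  Starting values are
#' deterministic method-of-moments values, so no multi-start is needed.
#'
#' A fit is flagged rather than erroring when the sample is degenerate
#' (positive weight on fewer than 3 subjects), when the effective sample
#' size is below `min_effective_n`, or when the fitted Psi lands on the
#' positive-definiteness boundary (smallest eigenvalue < 1e-8).
#'
#' @param sample a [weighted_sample()].
#' @param method `"em"` or `"optim"`.
#' @param tol relative log-likelihood change declaring convergence (EM).
#' @param max_iter iteration cap.
#' @param loadings T x 2 loading matrix.
#' @param min_effective_n minimum effective sample size (default 30 = 5 per
#'   parameter); smaller samples are fitted but flagged.
#' @param se_method `"none"`, `"naive_hessian"`, or `"sandwich"` — standard
#'   errors on the natural parameter scale via [estimate_ses()].
#' @param keep_trace if TRUE the EM log-likelihood trace is kept in
#'   `extra$trace`.
#' @return A [fit_result()] whose `params` is a [growth_params()].
#' @export
fit_weighted_lgm <- function(sample, method = c("em", "optim"), tol = 1e-8,
                             max_iter = 2000L,
                             loadings = growth_loadings(ncol(sample$outcomes)),
                             min_effective_n = 30,
                             se_method = c("none", "naive_hessian", "sandwich"),
                             keep_trace = FALSE) {
  stopifnot(inherits(sample, "weighted_sample"))
  method <- match.arg(method)
  se_method <- match.arg(se_method)
  Y <- sample$outcomes; w <- sample$weights
  pos <- sum(w > 1e-8)
  flags <- character(0)
  if (pos < 3L) {
    p0 <- lgm_moment_start(Y, pmax(w, 1e-8), loadings)
    return(fit_result(do.call(growth_params, p0), NA_real_, 6L,
                      n = max(1L, round(sample$effective_n)),
                      converged = FALSE, reason = "degenerate_sample"))
  }
  if (sample$effective_n < min_effective_n) flags <- "small_effective_n"

  p <- lgm_moment_start(Y, w, loadings)
  trace <- if (keep_trace) numeric(0)
  if (method == "em") {
    ll_old <- -Inf; iter <- 0L
    repeat {
      iter <- iter + 1L
      ld <- lgm_logdens_rows(p, Y, loadings)
      ll <- sum(w * ld)
      if (keep_trace) trace <- c(trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
      if (iter >= max_iter) break
      ll_old <- ll
      fm <- lgm_factor_moments(p, Y, loadings)
      p <- lgm_m_step(fm, Y, w, loadings)
    }
    hit_max <- iter >= max_iter
    n_iter <- iter
  } else {
    res <- lgm_optim_fit(Y, w, loadings, p, max_iter)
    p <- res$params; ll <- res$loglik
    hit_max <- !res$converged
    n_iter <- res$n_iterations
  }

  psi <- growth_psi(p)
  min_ev <- min(eigen((psi + t(psi)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (min_ev < 1e-8 || p$resid_var < 1e-8) flags <- c(flags, "boundary_psi")
  if (hit_max) flags <- c(flags, "max_iter")
  reason <- if (length(flags)) flags[[1L]] else "ok"

  # keep the returned object constructible even right at the boundary
  p$var_intercept <- max(p$var_intercept, 1e-10)
  p$var_slope <- max(p$var_slope, 1e-10)
  p$resid_var <- max(p$resid_var, 1e-10)
  if (p$cov_int_slope^2 >= p$var_intercept * p$var_slope)
    p$cov_int_slope <- sign(p$cov_int_slope) *
      sqrt(p$var_intercept * p$var_slope) * (1 - 1e-8)
  params <- do.call(growth_params, p)

  ses <- NULL
  if (se_method != "none") {
    obj <- lgm_objective(sample, loadings)
    est <- estimate_ses(obj$fn, growth_par_vector(params), method = se_method,
                        fn_i = obj$fn_i, weights = w)
    ses <- est$se
  }
  fit_result(params, ll, 6L, n = max(1L, round(sample$effective_n)),
             converged = reason == "ok", reason = reason,
             n_iterations = n_iter, estimated_ses = ses,
             extra = if (keep_trace) list(trace = trace) else list())
}

# BFGS fit on the unconstrained scale: (mu_I, mu_S, log l11, l21, log l22,
# log theta) with Psi = L L', L lower-triangular.
lgm_optim_fit <- function(Y, w, loadings, start, max_iter) {
  to_par <- function(p) {
    L <- t(chol(growth_psi(p)))
    c(p$mean_intercept, p$mean_slope, log(L[1, 1]), L[2, 1], log(L[2, 2]),
      log(p$resid_var))
  }
  from_par <- function(v) {
    L <- matrix(c(exp(v[3]), v[4], 0, exp(v[5])), 2L, 2L)
    psi <- L %*% t(L)
    list(mean_intercept = v[1], mean_slope = v[2],
         var_intercept = psi[1, 1], var_slope = psi[2, 2],
         cov_int_slope = psi[1, 2], resid_var = exp(v[6]))
  }
  negll <- function(v) {
    p <- from_par(v)
    ld <- lgm_logdens_rows(p, Y, loadings)
    if (is.null(ld)) return(1e10)
    -sum(w * ld)
  }
  res <- stats::optim(to_par(start), negll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  list(params = from_par(res$par), loglik = -res$value,
       converged = res$convergence == 0L, n_iterations = res$counts[["function"]])
}

# Objective factory for SE computation: fn(par) is the weighted
# log-likelihood, fn_i(par) the per-subject (unweighted) log densities, both
# on the natural parameter scale, NA-safe for non-PD perturbations.
lgm_objective <- function(sample, loadings = growth_loadings(ncol(sample$outcomes))) {
  Y <- sample$outcomes; w <- sample$weights
  as_plist <- function(v) list(mean_intercept = v[1], mean_slope = v[2],
                               var_intercept = v[3], var_slope = v[4],
                               cov_int_slope = v[5], resid_var = v[6])
  fn_i <- function(v) {
    ld <- lgm_logdens_rows(as_plist(v), Y, loadings)
    if (is.null(ld)) rep(NA_real_, nrow(Y)) else ld
  }
  list(fn = function(v) sum(w * fn_i(v)), fn_i = fn_i)
}

#' Standard errors from a numerical Hessian or a sandwich estimator
#'
#' `naive_hessian`: square roots of the diagonal of the inverse negative
#' Hessian of the objective (central differences, step
#' `max(1e-5, 1e-5 |par|)` per coordinate).  `sandwich`: \eqn{A^{-1} M
#' A^{-1}} with A the observed information and M the outer product of the
#' per-subject *weighted* scores — the pseudo-ML variance under case
#' weights; requires `fn_i` and `weights`.
#'
#' @param fn objective: parameter vector -> (weighted) log-likelihood.
#' @param par parameter vector at the (interior) maximum; names are carried
#'   to the SE vector.
#' @param method `"naive_hessian"` or `"sandwich"`.
#' @param fn_i per-subject log-density function (vector-valued), required
#'   for the sandwich.
#' @param weights case weights, required for the sandwich.
#' @return list with `se` (named vector, NA if the Hessian is not
#'   invertible), `vcov`, and `ok` flag.
#' @export
estimate_ses <- function(fn, par, method = c("naive_hessian", "sandwich"),
                         fn_i = NULL, weights = NULL) {
  method <- match.arg(method)
  H <- num_hessian(fn, par)
  p <- length(par)
  fail <- function() list(se = stats::setNames(rep(NA_real_, p), names(par)),
                          vcov = NULL, ok = FALSE)
  if (any(!is.finite(H))) return(fail())
  A <- -H
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(fail())
  V <- if (method == "naive_hessian") {
    Ainv
  } else {
    if (is.null(fn_i) || is.null(weights))
      stop("sandwich SEs need fn_i and weights")
    S <- num_jacobian(fn_i, par)              # n x p per-subject scores
    if (any(!is.finite(S))) return(fail())
    Sw <- S * weights
    Ainv %*% crossprod(Sw) %*% Ainv
  }
  d <- diag(V)
  if (any(d < 0)) return(fail())
  list(se = stats::setNames(sqrt(d), names(par)), vcov = V, ok = TRUE)
}

# Central-difference Hessian with per-coordinate steps h_j = max(1e-5,
# 1e-5 |par_j|).
num_hessian <- function(fn, par) {
  p <- length(par)
  h <- pmax(1e-5, 1e-5 * abs(par))
  H <- matrix(NA_real_, p, p)
  f0 <- fn(par)
  for (j in seq_len(p)) {
    ej <- replace(numeric(p), j, h[j])
    H[j, j] <- (fn(par + ej) - 2 * f0 + fn(par - ej)) / h[j]^2
    if (j < p) for (k in seq((j + 1L), p)) {
      ek <- replace(numeric(p), k, h[k])
      H[j, k] <- H[k, j] <-
        (fn(par + ej + ek) - fn(par + ej - ek) -
           fn(par - ej + ek) + fn(par - ej - ek)) / (4 * h[j] * h[k])
    }
  }
  H
}

# Central-difference Jacobian of a vector-valued function: n x p.
num_jacobian <- function(fn_i, par) {
  p <- length(par)
  h <- pmax(1e-5, 1e-5 * abs(par))
  cols <- vector("list", p)
  for (j in seq_len(p)) {
    ej <- replace(numeric(p), j, h[j])
    cols[[j]] <- (fn_i(par + ej) - fn_i(par - ej)) / (2 * h[j])
  }
  do.call(cbind, cols)
}
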