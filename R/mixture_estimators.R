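# The three linking approaches for the two-phase mixture model:
# one-step joint ML, bias-corrected three-step (ML correction with the
# classification-error matrix held fixed), and posterior-probability
# case weighting.

#' Two-phase fit container
#'
#' Common result type of [fit_one_step()], [fit_three_step()] and
#' [fit_case_weight()].  Classes are relabelled once, at construction, in
#' order of decreasing final mixing proportion (so class K is the smallest
#' class); all artifacts (posteriors, classification table, assignments)
#' are permuted consistently.
#'
#' @param method `"one_step"`, `"three_step"`, or `"case_weight"`.
#' @param lca an [lca_params()] (jointly estimated for one-step, the step-1
#'   estimate otherwise).
#' @param growth list of [growth_params()], one per class.
#' @param growth_ses optional list of named SE vectors, one per class.
#' @param mixing_props_final final class proportions (three-step
#'   re-estimates them; case-weight uses posterior column means).
#' @param loglik,n_params,n log-likelihood, free-parameter count and sample
#'   size for the BIC.
#' @param converged,reason convergence flag and reason code.
#' @param artifacts list of step artifacts (posteriors, q, assignments,
#'   entropy, effective_n, ...).
#' @param loglik_comparable FALSE when the recorded log-likelihood is a sum
#'   of separate weighted fits (case-weight) and must not be used for
#'   BIC-based selection across K.
#' @return An object of class `"two_phase_fit"`.
#' @export
two_phase_fit <- function(method, lca, growth, growth_ses = NULL,
                          mixing_props_final, loglik, n_params, n,
                          converged, reason = "ok", artifacts = list(),
                          loglik_comparable = TRUE) {
  K <- length(growth)
  perm <- order(mixing_props_final, decreasing = TRUE)
  growth <- growth[perm]
  if (!is.null(growth_ses)) growth_ses <- growth_ses[perm]
  mixing_props_final <- mixing_props_final[perm]
  lca <- lca_params(lca$thresholds[perm, , drop = FALSE],
                    lca$mixing_props[perm] / sum(lca$mixing_props[perm]))
  if (!is.null(artifacts$posteriors))
    artifacts$posteriors <- artifacts$posteriors[, perm, drop = FALSE]
  if (!is.null(artifacts$q))
    artifacts$q <- artifacts$q[perm, perm, drop = FALSE]
  if (!is.null(artifacts$assignments))
    artifacts$assignments <- match(artifacts$assignments, perm)
  if (!is.null(artifacts$effective_n))
    artifacts$effective_n <- artifacts$effective_n[perm]
  structure(list(method = method, lca = lca, growth = growth,
                 growth_ses = growth_ses,
                 mixing_props_final = mixing_props_final,
                 loglik = loglik, n_params = as.integer(n_params),
                 bic = -2 * loglik + n_params * log(n), n = as.integer(n),
                 converged = isTRUE(converged), reason = reason,
                 artifacts = artifacts,
                 loglik_comparable = isTRUE(loglik_comparable)),
            class = "two_phase_fit")
}

#' @export
print.two_phase_fit <- function(x, ...) {
  cat(sprintf("Two-phase fit (%s): %d classes, loglik %.3f, BIC %.2f, %s (%s)\n",
              x$method, length(x$growth), x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged", x$reason))
  cat("  mixing proportions:",
      paste(format(x$mixing_props_final, digits = 4), collapse = ", "), "\n")
  for (c in seq_along(x$growth)) {
    g <- growth_par_vector(x$growth[[c]])
    cat(sprintf("  class %d: ", c),
        paste(sprintf("%s=%.3f", names(g), g), collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- shared internals ------------------------------------------------------

# Per-class joint log component densities (indicators + outcomes) for the
# one-step model: n x K matrix, or NULL if a class covariance is non-PD.
os_class_loglik <- function(U, Y, probs, growth, loadings) {
  K <- nrow(probs)
  ind_part <- pattern_class_loglik(U, probs)
  out <- matrix(NA_real_, nrow(U), K)
  for (c in seq_len(K)) {
    ld <- lgm_logdens_rows(growth[[c]], Y, loadings)
    if (is.null(ld)) return(NULL)
    out[, c] <- ind_part[, c] + ld
  }
  out
}

# Growth-parameter starting values for multi-start EM: full-sample moments,
# jittered per class.
os_growth_start <- function(Y, loadings, K) {
  base <- lgm_moment_start(Y, rep(1, nrow(Y)), loadings)
  sds <- apply(Y %*% t(solve(crossprod(loadings), t(loadings))), 2L, stats::sd)
  lapply(seq_len(K), function(c) {
    p <- base
    p$mean_intercept <- p$mean_intercept + stats::rnorm(1, 0, 0.5 * sds[1])
    p$mean_slope <- p$mean_slope + stats::rnorm(1, 0, 0.5 * sds[2])
    p$var_intercept <- p$var_intercept * stats::runif(1, 0.6, 1.5)
    p$var_slope <- p$var_slope * stats::runif(1, 0.6, 1.5)
    p$resid_var <- p$resid_var * stats::runif(1, 0.6, 1.5)
    p
  })
}

# One EM run of the one-step joint model from given starting values.
os_em_run <- function(U, Y, loadings, pi0, probs0, growth0, tol, max_iter,
                      keep_trace = FALSE) {
  n <- nrow(U)
  pi_c <- pi0; probs <- probs0; growth <- growth0
  ll_old <- -Inf; iter <- 0L
  failed <- FALSE; trace <- if (keep_trace) numeric(0)
  w <- NULL; ll <- -Inf
  repeat {
    iter <- iter + 1L
    lcl <- os_class_loglik(U, Y, probs, growth, loadings)
    if (is.null(lcl)) { failed <- TRUE; break }
    lw <- sweep(lcl, 2L, log(pi_c), "+")
    lse <- row_logsumexp(lw)
    ll <- sum(lse)
    w <- exp(lw - lse)
    if (keep_trace) trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    if (iter >= max_iter) break
    ll_old <- ll
    mass <- colSums(w)
    if (any(mass < 1e-10)) { failed <- TRUE; break }
    pi_c <- mass / n
    probs <- t(w) %*% U / mass
    probs <- pmin(pmax(probs, item_response_prob(TAU_CLIP)),
                  item_response_prob(-TAU_CLIP))
    for (c in seq_along(growth)) {
      fm <- lgm_factor_moments(growth[[c]], Y, loadings)
      growth[[c]] <- lgm_m_step(fm, Y, w[, c], loadings)
    }
  }
  list(pi = pi_c, probs = probs, growth = growth, posteriors = w,
       loglik = if (failed) -Inf else ll, n_iterations = iter,
       hit_max_iter = iter >= max_iter, failed = failed, trace = trace)
}

# Reason code shared by the EM drivers.
mixture_reason <- function(run, n, check_items = TRUE) {
  if (run$failed) return("degenerate_posterior")
  if (run$hit_max_iter) return("max_iter")
  if (any(run$pi < 1 / n)) return("boundary_proportion")
  if (check_items &&
      any(run$probs < ITEM_PROB_EPS | run$probs > 1 - ITEM_PROB_EPS))
    return("boundary_item_probability")
  for (g in run$growth) {
    ev <- eigen(growth_psi(g), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8 || g$resid_var < 1e-8) return("boundary_psi")
  }
  K <- length(run$growth)
  if (K > 1L) {
    vecs <- lapply(seq_len(K), function(c)
      c(if (check_items) run$probs[c, ] else numeric(0),
        unlist(run$growth[[c]], use.names = FALSE)))
    for (a in seq_len(K - 1L)) for (b in seq((a + 1L), K))
      if (max(abs(vecs[[a]] - vecs[[b]])) < 1e-3) return("class_collapse")
  }
  "ok"
}

# Coerce a plain growth list to a constructible growth_params (nudging
# boundary values inward by a hair).
as_growth_params <- function(p) {
  p$var_intercept <- max(p$var_intercept, 1e-10)
  p$var_slope <- max(p$var_slope, 1e-10)
  p$resid_var <- max(p$resid_var, 1e-10)
  if (p$cov_int_slope^2 >= p$var_intercept * p$var_slope)
    p$cov_int_slope <- sign(p$cov_int_slope) *
      sqrt(p$var_intercept * p$var_slope) * (1 - 1e-8)
  growth_params(p$mean_intercept, p$mean_slope, p$var_intercept,
                p$var_slope, p$cov_int_slope, p$resid_var)
}

# ---- one-step --------------------------------------------------------------

#' One-step joint maximum-likelihood estimation
#'
#' Fits the K-class two-phase mixture model by maximising the joint
#' likelihood \eqn{\sum_i \log \sum_c \pi_c [\prod_p P(U_{ip}|c)]
#' \phi_T(y_i; \Lambda\mu_c, \Lambda\Psi_c\Lambda' + \theta_c I)} by EM:
#' the E-step forms posteriors from both indicator and outcome
#' contributions; the M-step updates the mixing proportions and item
#' probabilities in closed form and each class's growth parameters by the
#' closed-form weighted growth update.  Multi-start management runs
#' `n_starts` random starts for `burn_iter` iterations and polishes the
#' best `n_finish` to convergence.  K = 1 reduces exactly to the
#' closed-form item means plus one unweighted growth-model fit.
#'
#' @param dataset a [two_phase_dataset()].
#' @param K number of classes.
#' @param n_starts,burn_iter,n_finish multi-start schedule.
#' @param tol,max_iter EM convergence controls.
#' @param seed seed for the random starts.
#' @param se_method `"none"` or `"naive_hessian"` (observed information of
#'   the joint likelihood, SEs reported for the growth parameters).
#' @param keep_trace if TRUE all starts are run to convergence and their
#'   log-likelihood traces stored in `artifacts$traces`.
#' @return A [two_phase_fit()] with n_params = K P + (K - 1) + 6 K.
#' @export
fit_one_step <- function(dataset, K, n_starts = 16L, tol = 1e-7,
                         max_iter = 500L, seed = 1L,
                         se_method = c("none", "naive_hessian"),
                         burn_iter = 30L, n_finish = 4L, keep_trace = FALSE) {
  stopifnot(inherits(dataset, "two_phase_dataset"))
  se_method <- match.arg(se_method)
  U <- dataset$indicators; Y <- dataset$outcomes
  n <- nrow(U); P <- ncol(U)
  loadings <- growth_loadings(ncol(Y))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")

  if (K == 1L) {
    lres <- fit_lca(dataset, 1L)
    gres <- fit_weighted_lgm(weighted_sample(Y), tol = tol)
    ll <- lres$fit$loglik + gres$loglik
    return(two_phase_fit("one_step", lres$fit$params, list(gres$params),
                         growth_ses = NULL, mixing_props_final = 1,
                         loglik = ll, n_params = P + 6L, n = n,
                         converged = gres$converged, reason = gres$reason,
                         artifacts = list(posteriors = matrix(1, n, 1L))))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  starts <- lapply(seq_len(n_starts), function(s) {
    st <- lca_random_start(K, P)
    list(pi = st$pi, probs = st$probs,
         growth = os_growth_start(Y, loadings, K))
  })

  if (keep_trace) {
    runs <- lapply(starts, function(st)
      os_em_run(U, Y, loadings, st$pi, st$probs, st$growth, tol, max_iter,
                keep_trace = TRUE))
    best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
    start_lls <- vapply(runs, `[[`, numeric(1), "loglik")
    traces <- lapply(runs, `[[`, "trace")
  } else {
    burns <- lapply(starts, function(st)
      os_em_run(U, Y, loadings, st$pi, st$probs, st$growth, tol, burn_iter))
    burn_lls <- vapply(burns, `[[`, numeric(1), "loglik")
    top <- order(burn_lls, decreasing = TRUE)[seq_len(min(n_finish, n_starts))]
    finished <- lapply(burns[top], function(b) {
      if (b$failed) return(b)
      os_em_run(U, Y, loadings, b$pi, b$probs, b$growth, tol, max_iter)
    })
    start_lls <- vapply(finished, `[[`, numeric(1), "loglik")
    best <- finished[[which.max(start_lls)]]
    traces <- NULL
  }

  if (!is.finite(best$loglik))
    return(two_phase_fit("one_step",
                         lca_params(matrix(0, K, P), rep(1 / K, K)),
                         rep(list(do.call(growth_params, TRUE_GROWTH$class1)), K),
                         mixing_props_final = rep(1 / K, K),
                         loglik = NA_real_, n_params = K * P + (K - 1L) + 6L * K,
                         n = n, converged = FALSE,
                         reason = "degenerate_posterior"))

  reason <- mixture_reason(best, n)
  lca <- lca_params(prob_to_threshold(best$probs), best$pi / sum(best$pi))
  growth <- lapply(best$growth, as_growth_params)
  np <- K * P + (K - 1L) + 6L * K

  growth_ses <- NULL
  if (se_method == "naive_hessian") {
    obj <- os_objective(U, Y, loadings, K)
    est <- estimate_ses(obj$fn, obj$pack(best$pi, best$probs, growth),
                        method = "naive_hessian")
    growth_ses <- obj$extract_growth_ses(est$se)
  }

  ent <- if (K >= 2L) relative_entropy(best$posteriors) else NA_real_
  two_phase_fit("one_step", lca, growth, growth_ses = growth_ses,
                mixing_props_final = best$pi, loglik = best$loglik,
                n_params = np, n = n, converged = reason == "ok",
                reason = reason,
                artifacts = c(list(posteriors = best$posteriors,
                                   entropy = ent,
                                   n_iterations = best$n_iterations,
                                   start_logliks = start_lls),
                              if (keep_trace) list(traces = traces)))
}

# Natural-scale objective for the one-step joint likelihood (SEs):
# parameters (pi_1..pi_{K-1}, thresholds by class then item, 6 growth
# parameters per class).
os_objective <- function(U, Y, loadings, K) {
  P <- ncol(U)
  gnames <- c("mean_intercept", "mean_slope", "var_intercept", "var_slope",
              "cov_int_slope", "resid_var")
  nm <- c(if (K > 1L) paste0("pi", seq_len(K - 1L)),
          paste0("tau_c", rep(seq_len(K), each = P), "_p", rep(seq_len(P), K)),
          paste0("c", rep(seq_len(K), each = 6L), "_", rep(gnames, K)))
  pack <- function(pi_c, probs, growth) {
    v <- c(pi_c[-K], as.vector(t(prob_to_threshold(probs))),
           unlist(lapply(growth, function(g) growth_par_vector(as_growth_params(g))),
                  use.names = FALSE))
    stats::setNames(v, nm)
  }
  fn <- function(v) {
    pi_c <- c(v[seq_len(K - 1L)], 1 - sum(v[seq_len(K - 1L)]))
    if (any(pi_c <= 0)) return(NA_real_)
    tau <- matrix(v[K:(K - 1L + K * P)], K, P, byrow = TRUE)
    probs <- item_response_prob(tau)
    growth <- lapply(seq_len(K), function(c) {
      g <- v[(K - 1L + K * P + 6L * (c - 1L) + 1L):(K - 1L + K * P + 6L * c)]
      list(mean_intercept = g[1], mean_slope = g[2], var_intercept = g[3],
           var_slope = g[4], cov_int_slope = g[5], resid_var = g[6])
    })
    lcl <- os_class_loglik(U, Y, probs, growth, loadings)
    if (is.null(lcl)) return(NA_real_)
    sum(row_logsumexp(sweep(lcl, 2L, log(pi_c), "+")))
  }
  extract_growth_ses <- function(se) {
    lapply(seq_len(K), function(c)
      stats::setNames(se[paste0("c", c, "_", gnames)], gnames))
  }
  list(fn = fn, pack = pack, extract_growth_ses = extract_growth_ses)
}

# ---- three-step ------------------------------------------------------------

#' Bias-corrected three-step estimation
#'
#' Step 2 derives the modal assignment W and the classification-error table
#' q from the step-1 posteriors; step 3 maximises
#' \eqn{\sum_i \log \sum_c \pi_c \, q_{c,W_i} \,
#' \phi_T(y_i; \Lambda\mu_c, \Lambda\Psi_c\Lambda' + \theta_c I)} by EM over
#' the mixing proportions and the K growth-parameter sets, with q held
#' fixed (the ML correction: W acts as a single nominal indicator with known
#' measurement error).  Following the convergence bookkeeping of the study
#' design, the fit counts as converged only if step 1 and step 3 both
#' converged.
#'
#' @param dataset the [two_phase_dataset()] used in step 1.
#' @param step1 result of [fit_lca()] on the same dataset: a list with
#'   elements `fit` and `posteriors`.
#' @param tol,max_iter EM controls for step 3.
#' @param se_method `"none"` or `"naive_hessian"` (observed information of
#'   the step-3 likelihood).
#' @param keep_trace keep the step-3 EM log-likelihood trace.
#' @param q_override optional K x K matrix replacing the step-2
#'   classification-error table (diagnostics: e.g. the identity matrix
#'   gives classify-and-analyze, a uniform matrix removes all assignment
#'   information).
#' @return A [two_phase_fit()] with n_params = (K - 1) + 6 K.
#' @export
fit_three_step <- function(dataset, step1, tol = 1e-7, max_iter = 500L,
                           se_method = c("none", "naive_hessian"),
                           keep_trace = FALSE, q_override = NULL) {
  stopifnot(inherits(dataset, "two_phase_dataset"))
  se_method <- match.arg(se_method)
  Y <- dataset$outcomes
  n <- nrow(Y)
  loadings <- growth_loadings(ncol(Y))
  post1 <- posterior_table(step1$posteriors)
  K <- ncol(post1)
  W <- modal_assignment(post1)
  ct <- tryCatch(classification_table(post1, W), error = function(e) NULL)
  fallback <- function(reason) {
    two_phase_fit("three_step", step1$fit$params,
                  rep(list(do.call(growth_params, TRUE_GROWTH$class1)), K),
                  mixing_props_final = step1$fit$params$mixing_props,
                  loglik = NA_real_, n_params = (K - 1L) + 6L * K, n = n,
                  converged = FALSE, reason = reason,
                  artifacts = list(posteriors = post1))
  }
  if (is.null(ct)) return(fallback("degenerate_posterior"))
  q <- if (is.null(q_override)) ct$q else as.matrix(q_override)

  pi_c <- step1$fit$params$mixing_props
  growth <- lapply(seq_len(K), function(c)
    lgm_moment_start(Y, pmax(post1[, c], 1e-8), loadings))
  lq_w <- log(q)[, W, drop = FALSE]           # K x n, log q[c, W_i]

  ll_old <- -Inf; iter <- 0L; failed <- FALSE
  trace <- if (keep_trace) numeric(0)
  w <- NULL; ll <- -Inf
  repeat {
    iter <- iter + 1L
    dens <- matrix(NA_real_, n, K)
    for (c in seq_len(K)) {
      ld <- lgm_logdens_rows(growth[[c]], Y, loadings)
      if (is.null(ld)) { failed <- TRUE; break }
      dens[, c] <- ld
    }
    if (failed) break
    lw <- t(lq_w) + dens
    lw <- sweep(lw, 2L, log(pi_c), "+")
    lse <- row_logsumexp(lw)
    if (any(!is.finite(lse))) { failed <- TRUE; break }
    ll <- sum(lse)
    w <- exp(lw - lse)
    if (keep_trace) trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    if (iter >= max_iter) break
    ll_old <- ll
    mass <- colSums(w)
    if (any(mass < 1e-10)) { failed <- TRUE; break }
    pi_c <- mass / n
    for (c in seq_len(K)) {
      fm <- lgm_factor_moments(growth[[c]], Y, loadings)
      growth[[c]] <- lgm_m_step(fm, Y, w[, c], loadings)
    }
  }
  if (failed || !is.finite(ll)) return(fallback("degenerate_posterior"))

  run <- list(pi = pi_c, growth = growth, failed = FALSE,
              hit_max_iter = iter >= max_iter)
  reason3 <- mixture_reason(run, n, check_items = FALSE)
  step_ok <- step1$fit$converged
  converged <- step_ok && reason3 == "ok"
  reason <- if (!step_ok) paste0("step1_", step1$fit$reason) else reason3

  growth_ses <- NULL
  if (se_method == "naive_hessian") {
    obj <- ts_objective(Y, loadings, q, W, K)
    est <- estimate_ses(obj$fn, obj$pack(pi_c, growth),
                        method = "naive_hessian")
    growth_ses <- obj$extract_growth_ses(est$se)
  }

  two_phase_fit("three_step", step1$fit$params,
                lapply(growth, as_growth_params), growth_ses = growth_ses,
                mixing_props_final = pi_c, loglik = ll,
                n_params = (K - 1L) + 6L * K, n = n,
                converged = converged, reason = reason,
                artifacts = c(list(posteriors = post1, q = q,
                                   assignments = W,
                                   entropy = if (K >= 2L) relative_entropy(post1) else NA_real_,
                                   n_iterations = iter),
                              if (keep_trace) list(trace = trace)))
}

# Natural-scale objective of the step-3 likelihood (q, W fixed).
ts_objective <- function(Y, loadings, q, W, K) {
  gnames <- c("mean_intercept", "mean_slope", "var_intercept", "var_slope",
              "cov_int_slope", "resid_var")
  nm <- c(if (K > 1L) paste0("pi", seq_len(K - 1L)),
          paste0("c", rep(seq_len(K), each = 6L), "_", rep(gnames, K)))
  lq_w <- log(q)[, W, drop = FALSE]
  pack <- function(pi_c, growth) {
    stats::setNames(c(pi_c[-K],
                      unlist(lapply(growth, function(g)
                        growth_par_vector(as_growth_params(g))),
                        use.names = FALSE)), nm)
  }
  fn <- function(v) {
    pi_c <- c(v[seq_len(K - 1L)], 1 - sum(v[seq_len(K - 1L)]))
    if (any(pi_c <= 0)) return(NA_real_)
    lw <- matrix(NA_real_, nrow(Y), K)
    for (c in seq_len(K)) {
      g <- v[(K - 1L + 6L * (c - 1L) + 1L):(K - 1L + 6L * c)]
      ld <- lgm_logdens_rows(list(mean_intercept = g[1], mean_slope = g[2],
                                  var_intercept = g[3], var_slope = g[4],
                                  cov_int_slope = g[5], resid_var = g[6]),
                             Y, loadings)
      if (is.null(ld)) return(NA_real_)
      lw[, c] <- log(pi_c[c]) + lq_w[c, ] + ld
    }
    sum(row_logsumexp(lw))
  }
  extract_growth_ses <- function(se) {
    lapply(seq_len(K), function(c)
      stats::setNames(se[paste0("c", c, "_", gnames)], gnames))
  }
  list(fn = fn, pack = pack, extract_growth_ses = extract_growth_ses)
}

# ---- case-weight -----------------------------------------------------------

#' Case-weight estimation
#'
#' Fits the growth model once per class, weighting each subject by its
#' step-1 posterior probability of belonging to that class; the final class
#' proportions are the posterior column means and each class's effective
#' sample size is its posterior column sum.  No joint likelihood is formed:
#' the recorded log-likelihood is the sum of the per-class weighted
#' log-likelihoods and is flagged `loglik_comparable = FALSE` (model
#' selection for this approach happens at step 1).  Standard errors default
#' to the sandwich (pseudo-ML under case weights).
#'
#' @param dataset the [two_phase_dataset()] used in step 1.
#' @param step1 result of [fit_lca()]: list with `fit` and `posteriors`.
#' @param se_method `"sandwich"` (default), `"naive_hessian"`, or `"none"`.
#' @param min_effective_n classes with a smaller posterior mass are fitted
#'   but flagged, and the overall fit is flagged.
#' @param tol,max_iter controls passed to [fit_weighted_lgm()].
#' @return A [two_phase_fit()].
#' @export
fit_case_weight <- function(dataset, step1,
                            se_method = c("sandwich", "naive_hessian", "none"),
                            min_effective_n = 30, tol = 1e-8,
                            max_iter = 2000L) {
  stopifnot(inherits(dataset, "two_phase_dataset"))
  se_method <- match.arg(se_method)
  Y <- dataset$outcomes
  n <- nrow(Y)
  post1 <- posterior_table(step1$posteriors)
  K <- ncol(post1)
  fits <- lapply(seq_len(K), function(c)
    fit_weighted_lgm(weighted_sample(Y, post1[, c]), tol = tol,
                     max_iter = max_iter, min_effective_n = min_effective_n,
                     se_method = se_method))
  growth <- lapply(fits, `[[`, "params")
  growth_ses <- if (se_method != "none") lapply(fits, `[[`, "estimated_ses")
  ll <- sum(vapply(fits, `[[`, numeric(1), "loglik"))
  class_ok <- vapply(fits, `[[`, logical(1), "converged")
  step_ok <- step1$fit$converged
  reason <- if (!step_ok) paste0("step1_", step1$fit$reason)
            else if (!all(class_ok)) fits[[which(!class_ok)[1]]]$reason
            else "ok"
  two_phase_fit("case_weight", step1$fit$params, growth,
                growth_ses = growth_ses,
                mixing_props_final = colMeans(post1),
                loglik = ll, n_params = (K - 1L) + 6L * K, n = n,
                converged = step_ok && all(class_ok), reason = reason,
                artifacts = list(posteriors = post1,
                                 effective_n = colSums(post1),
                                 class_converged = class_ok,
                                 entropy = if (K >= 2L) relative_entropy(post1) else NA_real_),
                loglik_comparable = FALSE)
}
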