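# First-step estimation: EM for K-class LCA on dichotomous indicators,
# posterior class probabilities, modal assignment, the classification-error
# table, relative entropy, and BIC.
#
# The EM runs on the collapsed table of distinct response patterns (at most
# 2^P of them), so its cost is independent of n.

ITEM_PROB_EPS <- 1e-6  # item probabilities outside [eps, 1-eps] flag a boundary

#' Fit-result container
#'
#' Common return type of the estimators: parameter estimates, log-likelihood,
#' parameter count, BIC (-2 loglik + n_params log n), convergence flag with a
#' reason code, and optional standard-error table.
#'
#' @param params estimated parameters (e.g. an [lca_params()]).
#' @param loglik maximised log-likelihood.
#' @param n_params number of free parameters.
#' @param n sample size used for the BIC penalty.
#' @param converged logical.
#' @param reason one of "ok", "max_iter", "boundary_proportion",
#'   "boundary_item_probability", "degenerate_posterior", "class_collapse",
#'   "small_effective_n", "not_positive_definite".
#' @param n_iterations EM iterations of the winning start.
#' @param estimated_ses optional named numeric vector of standard errors.
#' @param start_logliks final log-likelihoods of all starts.
#' @param extra optional list of method-specific artifacts.
#' @return An object of class `"fit_result"`.
#' @export
fit_result <- function(params, loglik, n_params, n, converged, reason = "ok",
                       n_iterations = NA_integer_, estimated_ses = NULL,
                       start_logliks = numeric(0), extra = list()) {
  if (isTRUE(converged) && !is.finite(loglik))
    stop("a converged fit must have a finite log-likelihood")
  structure(list(params = params, loglik = loglik,
                 n_params = as.integer(n_params),
                 bic = -2 * loglik + n_params * log(n),
                 n = as.integer(n),
                 converged = isTRUE(converged), reason = reason,
                 n_iterations = as.integer(n_iterations),
                 estimated_ses = estimated_ses,
                 start_logliks = start_logliks, extra = extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit: loglik %.4f, %d params, BIC %.2f, %s (%s)\n",
              x$loglik, x$n_params, x$bic,
              if (x$converged) "converged" else "NOT converged", x$reason))
  invisible(x)
}

# Validated posterior table: n x K matrix, rows on the simplex.
posterior_table <- function(probs) {
  probs <- as.matrix(probs)
  if (any(probs < -1e-12 | probs > 1 + 1e-12))
    stop("posterior probabilities must lie in [0, 1]")
  if (any(abs(rowSums(probs) - 1) > 1e-10))
    stop("posterior rows must sum to 1 (tolerance 1e-10)")
  probs
}

# logsumexp over rows of a matrix (pmax over columns: much faster than
# apply for the tall-thin matrices the E-steps produce).
row_logsumexp <- function(m) {
  K <- ncol(m)
  if (K == 1L) return(m[, 1L])
  mx <- m[, 1L]
  for (c in 2L:K) mx <- pmax(mx, m[, c])
  mx + log(rowSums(exp(m - mx)))
}

# Collapse an indicator matrix to distinct patterns with counts.
collapse_patterns <- function(indicators) {
  key <- apply(indicators, 1L, paste, collapse = "")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = indicators[first, , drop = FALSE],
       counts = as.numeric(tab),
       row_index = match(key, names(tab)))
}

# Per-pattern log Bernoulli likelihood under each class: M x K.
pattern_class_loglik <- function(patterns, item_probs) {
  lp <- log(item_probs); lq <- log1p(-item_probs)      # K x P
  patterns %*% t(lp) + (1 - patterns) %*% t(lq)
}

# One LCA EM run from given starting values, on collapsed patterns.  The
# E-step works on the likelihood scale: with item probabilities clipped to
# the TAU_CLIP range, per-pattern class likelihoods cannot underflow for
# the small P this model family uses.
lca_em_run <- function(patterns, counts, pi0, probs0, tol, max_iter,
                       keep_trace = FALSE) {
  n <- sum(counts)
  M <- nrow(patterns)
  patterns1m <- 1 - patterns
  pi_c <- pi0; probs <- probs0
  ll_old <- -Inf; trace <- if (keep_trace) numeric(0)
  iter <- 0L; degenerate <- FALSE; ll <- -Inf
  repeat {
    iter <- iter + 1L
    A <- patterns %*% t(log(probs)) + patterns1m %*% t(log1p(-probs))
    Fw <- exp(A) * rep(pi_c, each = M)                  # M x K joint likelihood
    s <- rowSums(Fw)
    if (any(s <= 0)) { degenerate <- TRUE; break }
    ll <- sum(counts * log(s))
    w <- Fw / s                                         # M x K posteriors
    if (keep_trace) trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    if (iter >= max_iter) break
    ll_old <- ll
    cw <- counts * w
    mass <- colSums(cw)
    if (any(mass < 1e-12)) { degenerate <- TRUE; break }
    pi_c <- mass / n
    probs <- crossprod(cw, patterns) / mass
    probs <- pmin(pmax(probs, item_response_prob(TAU_CLIP)),
                  item_response_prob(-TAU_CLIP))
  }
  list(pi = pi_c, probs = probs, loglik = ll, n_iterations = iter,
       hit_max_iter = iter >= max_iter, degenerate = degenerate,
       trace = trace)
}

# Random starting values for a K-class LCA.
lca_random_start <- function(K, P) {
  e <- stats::rexp(K)
  list(pi = e / sum(e),
       probs = matrix(stats::runif(K * P, 0.1, 0.9), K, P))
}

#' Fit a K-class latent class analysis by EM
#'
#' Maximises the LCA log-likelihood
#' \eqn{\sum_i \log \sum_c \pi_c \prod_p P(U_{ip}|c)} over the mixing
#' proportions and item endorsement probabilities, from `n_starts` random
#' starts (item probabilities uniform on (0.1, 0.9), mixing proportions flat
#' Dirichlet), returning the best run.  K = 1 is fitted in closed form (item
#' probabilities = sample means).  Classes are relabelled in order of
#' decreasing mixing proportion, so class K is always the smallest class.
#'
#' The fit is flagged non-converged (reason code, not an error) when the best
#' run hits `max_iter` or lands on a boundary: any mixing proportion below
#' 1/n, or any item probability outside [1e-6, 1 - 1e-6].
#'
#' @param dataset a [two_phase_dataset()] (only `indicators` is read).
#' @param K number of latent classes (>= 1; must not exceed the number of
#'   distinct response patterns).
#' @param n_starts random starts (default 16).
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter EM iteration cap per start.
#' @param seed integer seed for the random starts.
#' @param burn_iter,n_finish multi-start schedule: every start runs for
#'   `burn_iter` iterations and the best `n_finish` are polished to
#'   convergence (set `n_finish = n_starts` to run all starts fully).
#' @param keep_trace if TRUE, all starts run fully and their
#'   log-likelihood traces are stored in `fit$extra$traces`
#'   (testing/diagnostics).
#' @return list with elements `fit` (a [fit_result()] whose `params` is an
#'   [lca_params()]) and `posteriors` (n x K posterior matrix).
#' @export
fit_lca <- function(dataset, K, n_starts = 16L, tol = 1e-7, max_iter = 500L,
                    seed = 1L, burn_iter = 50L, n_finish = 4L,
                    keep_trace = FALSE) {
  stopifnot(inherits(dataset, "two_phase_dataset"))
  U <- dataset$indicators
  n <- nrow(U); P <- ncol(U)
  if (n < 1L) stop("empty dataset")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  cp <- collapse_patterns(U)
  if (K > nrow(cp$patterns))
    stop("K exceeds the number of distinct response patterns (",
         nrow(cp$patterns), ")")

  if (K == 1L) {
    pbar <- colMeans(U)
    pclip <- pmin(pmax(pbar, item_response_prob(TAU_CLIP)),
                  item_response_prob(-TAU_CLIP))
    ll <- sum(U %*% log(pclip) + (1 - U) %*% log1p(-pclip))
    params <- lca_params(matrix(prob_to_threshold(pbar), 1L, P), 1)
    fit <- fit_result(params, ll, n_params = P, n = n, converged = TRUE,
                      n_iterations = 0L, start_logliks = ll)
    return(list(fit = fit, posteriors = posterior_table(matrix(1, n, 1L))))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  starts <- lapply(seq_len(n_starts), function(s) lca_random_start(K, P))
  traces <- NULL
  if (keep_trace || n_finish >= n_starts) {
    runs <- lapply(starts, function(st)
      lca_em_run(cp$patterns, cp$counts, st$pi, st$probs, tol, max_iter,
                 keep_trace = keep_trace))
    if (keep_trace) traces <- lapply(runs, `[[`, "trace")
  } else {
    burns <- lapply(starts, function(st)
      lca_em_run(cp$patterns, cp$counts, st$pi, st$probs, tol, burn_iter))
    top <- order(vapply(burns, `[[`, numeric(1), "loglik"),
                 decreasing = TRUE)[seq_len(min(n_finish, n_starts))]
    runs <- lapply(burns[top], function(b) {
      if (b$degenerate) return(b)
      lca_em_run(cp$patterns, cp$counts, b$pi, b$probs, tol, max_iter)
    })
  }
  start_lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- runs[[which.max(start_lls)]]

  ord <- order(best$pi, decreasing = TRUE)
  pi_c <- best$pi[ord]
  probs <- best$probs[ord, , drop = FALSE]
  reason <- if (best$degenerate) "degenerate_posterior"
            else if (best$hit_max_iter) "max_iter"
            else if (any(pi_c < 1 / n)) "boundary_proportion"
            else if (any(probs < ITEM_PROB_EPS | probs > 1 - ITEM_PROB_EPS))
              "boundary_item_probability"
            else "ok"
  params <- lca_params(prob_to_threshold(probs), pi_c / sum(pi_c))
  fit <- fit_result(params, best$loglik, n_params = K * P + (K - 1L), n = n,
                    converged = reason == "ok", reason = reason,
                    n_iterations = best$n_iterations,
                    start_logliks = start_lls,
                    extra = if (keep_trace) list(traces = traces) else list())
  list(fit = fit, posteriors = posterior_probs(params, dataset))
}

#' Posterior class-membership probabilities
#'
#' Bayes rule per subject: \eqn{p_{ic} \propto \pi_c \prod_p P(U_{ip}|c)},
#' rows normalised to 1.
#'
#' @param params an [lca_params()].
#' @param dataset a [two_phase_dataset()] with matching indicator count.
#' @return n x K posterior matrix, rows summing to 1.
#' @export
posterior_probs <- function(params, dataset) {
  stopifnot(inherits(params, "lca_params"),
            inherits(dataset, "two_phase_dataset"))
  U <- dataset$indicators
  if (ncol(U) != ncol(params$thresholds))
    stop("indicator count does not match the parameter matrix")
  probs <- item_response_prob(params$thresholds)
  lw <- sweep(pattern_class_loglik(U, probs), 2L, log(params$mixing_props), "+")
  posterior_table(exp(lw - row_logsumexp(lw)))
}

#' Modal class assignment
#'
#' Assigns each subject to the class with the largest posterior probability;
#' exact ties (probability zero in continuous data, but possible in
#' principle) are broken toward the smaller class index.
#'
#' @param posteriors n x K posterior matrix.
#' @return integer vector of assigned classes.
#' @export
modal_assignment <- function(posteriors) {
  posteriors <- posterior_table(posteriors)
  max.col(posteriors, ties.method = "first")
}

#' Classification-error table of a modal assignment
#'
#' Average-posterior estimate of the K x K classification uncertainty rates
#' q[s, t] = P(assigned class W = t | true class C = s):
#' \eqn{q_{st} = \sum_{i: W_i = t} p_{is} / \sum_i p_{is}}.  Rows sum to 1.
#'
#' @param posteriors n x K posterior matrix.
#' @param W integer vector of modal assignments (defaults to
#'   [modal_assignment()] of `posteriors`).
#' @return list with `q` (K x K matrix) and `assigned_counts` (length-K
#'   class sizes under W).
#' @export
classification_table <- function(posteriors, W = modal_assignment(posteriors)) {
  posteriors <- posterior_table(posteriors)
  K <- ncol(posteriors)
  if (length(W) != nrow(posteriors))
    stop("W must have one entry per posterior row")
  mass <- colSums(posteriors)
  if (any(mass < 1e-12))
    stop("a class has zero total posterior mass (degenerate solution)")
  q <- matrix(0, K, K)
  for (t in seq_len(K)) {
    idx <- which(W == t)
    if (length(idx))
      q[, t] <- colSums(posteriors[idx, , drop = FALSE]) / mass
  }
  list(q = q, assigned_counts = tabulate(W, nbins = K))
}

#' Relative entropy of a posterior table
#'
#' Normalised certainty measure
#' \eqn{1 - \sum_i \sum_c -p_{ic} \log p_{ic} / (n \log K)}: 1 means every
#' subject is classified with certainty, 0 means posteriors are uniform.
#'
#' @param posteriors n x K posterior matrix.
#' @param K number of classes (>= 2); defaults to ncol(posteriors).
#' @return value in [0, 1].
#' @export
relative_entropy <- function(posteriors, K = ncol(posteriors)) {
  posteriors <- posterior_table(posteriors)
  if (K < 2L) stop("relative entropy requires K >= 2")
  plp <- posteriors * log(posteriors)
  plp[posteriors == 0] <- 0                 # 0 log 0 := 0
  1 - sum(-plp) / (nrow(posteriors) * log(K))
}
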