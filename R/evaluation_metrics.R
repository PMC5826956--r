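# Monte-Carlo recovery metrics (absolute relative bias, empirical SE,
# estimated/empirical SE ratio, RMSE, all with divisor r), BIC-based
# model-selection indicator, and truth alignment of fitted classes.

#' Metric input: one parameter's estimates across replications
#'
#' @param estimates length-r vector of estimates of one parameter.
#' @param true_value generating value of the parameter.
#' @param estimated_ses optional length-r vector of estimated SEs.
#' @return An object of class `"metric_input"`.
#' @export
metric_input <- function(estimates, true_value, estimated_ses = NULL) {
  estimates <- as.numeric(estimates)
  if (!length(estimates)) stop("at least one replication required")
  if (any(!is.finite(estimates))) stop("estimates must be finite")
  if (!is.null(estimated_ses) && length(estimated_ses) != length(estimates))
    stop("estimated_ses must match estimates in length")
  structure(list(estimates = estimates, true_value = as.numeric(true_value),
                 estimated_ses = estimated_ses, r = length(estimates)),
            class = "metric_input")
}

#' Absolute relative bias
#'
#' \eqn{| \bar{\hat\theta} - \theta | / |\theta|}: the absolute value of
#' the mean estimation error relative to the generating value.
#'
#' @param m a [metric_input()]; `true_value` must be nonzero.
#' @return non-negative scalar.
#' @export
absolute_relative_bias <- function(m) {
  stopifnot(inherits(m, "metric_input"))
  if (m$true_value == 0) stop("relative bias is undefined for a zero true value")
  abs((mean(m$estimates) - m$true_value) / m$true_value)
}

#' Empirical standard error
#'
#' Standard deviation of the estimates across replications with divisor r
#' (not r - 1), i.e. \eqn{\sqrt{\sum_i (\hat\theta_i - \bar{\hat\theta})^2 / r}}.
#'
#' @param m a [metric_input()].
#' @return non-negative scalar.
#' @export
empirical_se <- function(m) {
  stopifnot(inherits(m, "metric_input"))
  sqrt(mean((m$estimates - mean(m$estimates))^2))
}

#' Mean estimated SE relative to the empirical SE
#'
#' mean(estimated SEs) / empirical SE; values below 1 indicate that the
#' model-based SEs underestimate the realised sampling variability.
#'
#' @param m a [metric_input()] with `estimated_ses` present and a strictly
#'   positive empirical SE.
#' @return positive scalar.
#' @export
se_ratio <- function(m) {
  stopifnot(inherits(m, "metric_input"))
  if (is.null(m$estimated_ses)) stop("estimated_ses required for the SE ratio")
  es <- empirical_se(m)
  if (es <= 0) stop("empirical SE is zero; the ratio is undefined")
  mean(m$estimated_ses) / es
}

#' Root mean square error
#'
#' \eqn{\sqrt{\sum_i (\hat\theta_i - \theta)^2 / r}} (divisor r), so that
#' rmse^2 = bias^2 + empirical_se^2 holds exactly.
#'
#' @param m a [metric_input()].
#' @return non-negative scalar.
#' @export
rmse <- function(m) {
  stopifnot(inherits(m, "metric_input"))
  sqrt(mean((m$estimates - m$true_value)^2))
}

#' BIC-based correct-selection indicator
#'
#' TRUE iff the 2-class BIC is strictly smaller than both the 1-class and
#' 3-class BICs; ties count as incorrect.  A missing (NA) 3-class BIC —
#' e.g. a comparison fit that failed entirely — counts as "2-class
#' selected" when bic(2) < bic(1); a missing 1- or 2-class BIC gives FALSE.
#'
#' @param bics numeric vector of BICs named "1", "2", "3" (or positionally
#'   ordered K = 1, 2, 3).
#' @return logical.
#' @export
correct_selection <- function(bics) {
  if (is.null(names(bics))) names(bics) <- as.character(seq_along(bics))
  for (k in c("1", "2", "3"))
    if (!k %in% names(bics)) stop("BIC for K = ", k, " is missing")
  b <- bics[c("1", "2", "3")]
  if (is.na(b[1]) || is.na(b[2])) return(FALSE)
  if (is.na(b[3])) return(unname(b[2] < b[1]))
  unname(b[2] < b[1] && b[2] < b[3])
}

# Squared standardised distance between an estimated and a true growth
# parameter set; scale floors at 0.1 so near-zero truths do not dominate.
growth_sq_dist <- function(est, true) {
  e <- growth_par_vector(est); t_ <- growth_par_vector(true)
  sum(((e - t_) / pmax(abs(t_), 0.1))^2)
}

#' Align the classes of a fit to a generating model
#'
#' Chooses the class permutation minimising the summed squared standardised
#' distance between fitted and generating growth parameters, and applies it
#' to all class-indexed components of the fit (growth parameters, SEs,
#' mixing proportions, thresholds, posteriors, classification table,
#' assignments).  The chosen permutation and whether it disagrees with
#' size ordering (descending mixing proportion) are recorded in
#' `$alignment` and `$alignment_differs_from_size_order`.
#'
#' @param fit a [two_phase_fit()].
#' @param true_model a [two_phase_model()] with the same number of classes.
#' @return the permuted [two_phase_fit()].
#' @export
align_to_truth <- function(fit, true_model) {
  stopifnot(inherits(fit, "two_phase_fit"), inherits(true_model, "two_phase_model"))
  K <- length(fit$growth)
  if (K != true_model$lca$n_classes)
    stop("fit and generating model must have the same number of classes")
  perms <- all_permutations(K)
  cost <- vapply(perms, function(pm)
    sum(vapply(seq_len(K), function(c)
      growth_sq_dist(fit$growth[[pm[c]]], true_model$growth[[c]]),
      numeric(1))), numeric(1))
  pm <- perms[[which.min(cost)]]
  out <- fit
  out$growth <- fit$growth[pm]
  if (!is.null(fit$growth_ses)) out$growth_ses <- fit$growth_ses[pm]
  out$mixing_props_final <- fit$mixing_props_final[pm]
  out$lca <- lca_params(fit$lca$thresholds[pm, , drop = FALSE],
                        fit$lca$mixing_props[pm] / sum(fit$lca$mixing_props[pm]))
  if (!is.null(out$artifacts$posteriors))
    out$artifacts$posteriors <- fit$artifacts$posteriors[, pm, drop = FALSE]
  if (!is.null(out$artifacts$q))
    out$artifacts$q <- fit$artifacts$q[pm, pm, drop = FALSE]
  if (!is.null(out$artifacts$assignments))
    out$artifacts$assignments <- match(fit$artifacts$assignments, pm)
  if (!is.null(out$artifacts$effective_n))
    out$artifacts$effective_n <- fit$artifacts$effective_n[pm]
  out$alignment <- pm
  out$alignment_differs_from_size_order <-
    !identical(pm, order(fit$mixing_props_final, decreasing = TRUE))
  out
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (s in sub) for (pos in seq_len(K)) {
    out[[length(out) + 1L]] <- append(s, K, after = pos - 1L)
  }
  out
}

#' Per-parameter and class-averaged recovery metrics
#'
#' Computes the four recovery metrics for each growth parameter of each
#' class from a matrix of aligned replication estimates, plus the average
#' over the six parameters per class.
#'
#' @param estimates r x p matrix of aligned estimates, columns named
#'   `c<class>_<parameter>`.
#' @param ses optional matching matrix of estimated SEs.
#' @param true_model the generating [two_phase_model()].
#' @return data.frame with columns class, parameter (or "average"),
#'   abs_rel_bias, empirical_se, se_ratio, rmse, r.
#' @export
recovery_metrics <- function(estimates, true_model, ses = NULL) {
  estimates <- as.matrix(estimates)
  K <- true_model$lca$n_classes
  gnames <- c("mean_intercept", "mean_slope", "var_intercept", "var_slope",
              "cov_int_slope", "resid_var")
  rows <- list()
  for (c in seq_len(K)) {
    truth <- growth_par_vector(true_model$growth[[c]])
    per <- lapply(gnames, function(p) {
      col <- paste0("c", c, "_", p)
      m <- metric_input(estimates[, col], truth[[p]],
                        estimated_ses = if (!is.null(ses)) ses[, col])
      data.frame(class = c, parameter = p,
                 abs_rel_bias = absolute_relative_bias(m),
                 empirical_se = empirical_se(m),
                 se_ratio = if (!is.null(ses) && empirical_se(m) > 0)
                   se_ratio(m) else NA_real_,
                 rmse = rmse(m), r = m$r)
    })
    per <- do.call(rbind, per)
    avg <- data.frame(class = c, parameter = "average",
                      abs_rel_bias = mean(per$abs_rel_bias),
                      empirical_se = mean(per$empirical_se),
                      se_ratio = mean(per$se_ratio),
                      rmse = mean(per$rmse), r = per$r[1])
    rows[[c]] <- rbind(per, avg)
  }
  do.call(rbind, rows)
}
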