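# Parameter containers and design constants for the two-phase mixture model:
# a K-class LCA measurement phase on P dichotomous indicators, plus one
# linear growth model (LGM) per class for T repeated continuous outcomes.

# Thresholds beyond this magnitude give response probabilities that are
# numerically 0/1; clipping keeps exp() finite everywhere.
TAU_CLIP <- 35

#' LCA measurement-model parameters
#'
#' Container for the parameters of a K-class latent class analysis on P
#' dichotomous indicators: a K x P matrix of logit-scale thresholds and a
#' length-K vector of mixing proportions.
#'
#' The threshold parameterisation follows the convention
#' \eqn{P(U_p = 1 | c) = 1 / (1 + \exp(\tau_{cp}))}, so a *negative*
#' threshold means endorsement is *likely* (probability above 0.5).
#'
#' @param thresholds numeric K x P matrix of thresholds \eqn{\tau_{cp}}.
#'   A vector is treated as a single-class (1 x P) model.
#' @param mixing_props length-K vector of class proportions, strictly
#'   positive, summing to 1 (tolerance 1e-10).
#' @return An object of class `"lca_params"` with elements `n_classes`,
#'   `thresholds`, `mixing_props`.
#' @examples
#' lca_params(rbind(c(-1.75, -1.75, -1.75, -1.75),
#'                  c( 1.75,  1.75,  1.75,  1.75)), c(0.7, 0.3))
#' @export
lca_params <- function(thresholds, mixing_props) {
  if (is.vector(thresholds)) thresholds <- matrix(thresholds, nrow = 1L)
  thresholds <- as.matrix(thresholds)
  storage.mode(thresholds) <- "double"
  K <- nrow(thresholds)
  mixing_props <- as.numeric(mixing_props)
  if (length(mixing_props) != K)
    stop("mixing_props must have one entry per threshold row (K = ", K, ")")
  if (any(!is.finite(thresholds)))
    stop("thresholds must be finite")
  if (any(mixing_props <= 0))
    stop("mixing proportions must be strictly positive")
  if (abs(sum(mixing_props) - 1) > 1e-10)
    stop("mixing proportions must sum to 1 (tolerance 1e-10)")
  structure(list(n_classes = K,
                 thresholds = thresholds,
                 mixing_props = mixing_props),
            class = "lca_params")
}

#' Linear growth model parameters for one latent class
#'
#' Growth-factor means, covariance, and residual variance of a linear growth
#' model with latent intercept I and slope S.  The residual variance is a
#' single value, constrained equal over the T time points, with zero residual
#' covariances.
#'
#' @param mean_intercept,mean_slope growth-factor means.
#' @param var_intercept,var_slope growth-factor variances (> 0).
#' @param cov_int_slope intercept-slope covariance; the implied 2 x 2
#'   growth-factor covariance matrix must be positive definite.
#' @param resid_var residual variance (> 0), shared by all time points.
#' @return An object of class `"growth_params"`.
#' @examples
#' growth_params(0.6, 1.0, 1.9, 0.4, 0.5, 0.5)  # the packaged class-1 preset
#' @export
growth_params <- function(mean_intercept, mean_slope, var_intercept,
                          var_slope, cov_int_slope, resid_var) {
  p <- list(mean_intercept = as.numeric(mean_intercept),
            mean_slope = as.numeric(mean_slope),
            var_intercept = as.numeric(var_intercept),
            var_slope = as.numeric(var_slope),
            cov_int_slope = as.numeric(cov_int_slope),
            resid_var = as.numeric(resid_var))
  if (any(!vapply(p, is.finite, logical(1))))
    stop("growth parameters must be finite")
  psi <- growth_psi(p)
  if (p$var_intercept <= 0 || p$var_slope <= 0 ||
      det(psi) <= 0)
    stop("growth-factor covariance matrix must be positive definite")
  if (p$resid_var <= 0) stop("resid_var must be > 0")
  structure(p, class = "growth_params")
}

# 2x2 growth-factor covariance matrix Psi.
growth_psi <- function(p) {
  matrix(c(p$var_intercept, p$cov_int_slope,
           p$cov_int_slope, p$var_slope), 2L, 2L)
}

growth_mu <- function(p) c(p$mean_intercept, p$mean_slope)

# Growth parameters as a named numeric vector (the natural-scale ordering
# used for SE tables and truth alignment).
growth_par_vector <- function(p) {
  c(mean_intercept = p$mean_intercept, mean_slope = p$mean_slope,
    var_intercept = p$var_intercept, var_slope = p$var_slope,
    cov_int_slope = p$cov_int_slope, resid_var = p$resid_var)
}

growth_from_vector <- function(v) {
  growth_params(v[["mean_intercept"]], v[["mean_slope"]],
                v[["var_intercept"]], v[["var_slope"]],
                v[["cov_int_slope"]], v[["resid_var"]])
}

#' Fixed loading matrix of the linear growth model
#'
#' T x 2 matrix with an all-ones intercept column and a slope column coding
#' time as 0, 1, ..., T-1; the study configuration uses T = 4.
#'
#' @param n_times number of time points T.
#' @return numeric T x 2 matrix.
#' @export
growth_loadings <- function(n_times = 4L) {
  cbind(intercept = rep(1, n_times), slope = seq_len(n_times) - 1)
}

#' Two-phase mixture model
#'
#' Bundles the LCA measurement phase with one set of growth parameters per
#' latent class and the fixed loading matrix.
#'
#' @param lca an [lca_params()] object.
#' @param growth list of [growth_params()] objects, one per class, in class
#'   order.
#' @param loadings fixed T x 2 loading matrix; defaults to
#'   [growth_loadings()] with T = 4.
#' @return An object of class `"two_phase_model"`.
#' @export
two_phase_model <- function(lca, growth, loadings = growth_loadings()) {
  stopifnot(inherits(lca, "lca_params"))
  if (!is.list(growth) || !all(vapply(growth, inherits, logical(1), "growth_params")))
    stop("growth must be a list of growth_params objects")
  if (length(growth) != lca$n_classes)
    stop("need exactly one growth_params per latent class")
  loadings <- as.matrix(loadings)
  if (ncol(loadings) != 2L) stop("loadings must have two columns")
  structure(list(lca = lca, growth = growth, loadings = loadings),
            class = "two_phase_model")
}

#' @export
print.two_phase_model <- function(x, ...) {
  K <- x$lca$n_classes
  cat("Two-phase mixture model:", K, "latent classes,",
      ncol(x$lca$thresholds), "indicators,", nrow(x$loadings), "time points\n")
  cat("  mixing proportions:",
      paste(format(x$lca$mixing_props, digits = 4), collapse = ", "), "\n")
  for (c in seq_len(K)) {
    g <- growth_par_vector(x$growth[[c]])
    cat(sprintf("  class %d growth: ", c),
        paste(sprintf("%s=%.3g", names(g), g), collapse = ", "), "\n")
  }
  invisible(x)
}

# --- the packaged study design ---------------------------------------------

# Generating LGM parameter values for the two classes
# (class 1 = larger class, class 2 = smaller class).
TRUE_GROWTH <- list(
  class1 = list(mean_intercept = 0.6, mean_slope = 1.0, var_intercept = 1.9,
                var_slope = 0.4, cov_int_slope = 0.5, resid_var = 0.5),
  class2 = list(mean_intercept = 0.4, mean_slope = 1.8, var_intercept = 1.4,
                var_slope = 0.3, cov_int_slope = 0.3, resid_var = 0.7)
)

SEPARATION_THRESHOLDS <- c(low = 0.754, medium = 1.254, high = 1.750)

#' One cell of the simulation design
#'
#' @param sample_size number of subjects (500, 1000, or 2000 in the packaged
#'   design; any positive integer is accepted).
#' @param class2_prop proportion of the smaller class, in (0, 0.5).
#' @param separation_level one of `"low"`, `"medium"`, `"high"`; fixes the
#'   LCA threshold magnitude at 0.754 / 1.254 / 1.750 respectively.
#' @return An object of class `"sim_condition"` with fields `sample_size`,
#'   `class2_prop`, `separation_level`, `threshold_value`.
#' @export
sim_condition <- function(sample_size, class2_prop, separation_level) {
  separation_level <- match.arg(separation_level,
                                names(SEPARATION_THRESHOLDS))
  sample_size <- as.integer(sample_size)
  if (sample_size < 1L) stop("sample_size must be positive")
  class2_prop <- as.numeric(class2_prop)
  if (class2_prop <= 0 || class2_prop >= 0.5)
    stop("class2_prop must lie strictly in (0, 0.5): class 2 is the smaller class")
  structure(list(sample_size = sample_size,
                 class2_prop = class2_prop,
                 separation_level = separation_level,
                 threshold_value = unname(SEPARATION_THRESHOLDS[separation_level])),
            class = "sim_condition")
}

#' The 27-condition simulation grid
#'
#' Full crossing of three sample sizes (500, 1000, 2000), three smaller-class
#' proportions (0.05, 0.15, 0.30), and three class-separation levels
#' (low/medium/high, i.e. thresholds 0.754/1.254/1.750).  Order: sample size
#' outermost, proportion in the middle, separation innermost, so the first
#' cell is (500, 0.05, low).
#'
#' @return A list of 27 [sim_condition()] objects.
#' @export
study_condition_grid <- function() {
  out <- vector("list", 27L)
  i <- 0L
  for (n in c(500L, 1000L, 2000L))
    for (p2 in c(0.05, 0.15, 0.30))
      for (sep in c("low", "medium", "high")) {
        i <- i + 1L
        out[[i]] <- sim_condition(n, p2, sep)
      }
  out
}

#' Generating model for a design cell
#'
#' Builds the 2-class two-phase generating model for a simulation condition:
#' mixing proportions (1 - class2_prop, class2_prop); thresholds -tau for
#' every indicator in class 1 and +tau in class 2 (so the between-class
#' log-odds gap is 2 tau and class 1 endorses items with probability above
#' 0.5); growth parameters fixed at the packaged class-1/class-2 presets.
#'
#' @param condition a [sim_condition()] object.
#' @return A [two_phase_model()] with K = 2, P = 4 indicators, T = 4.
#' @export
build_true_model <- function(condition) {
  stopifnot(inherits(condition, "sim_condition"))
  tau <- condition$threshold_value
  p2 <- condition$class2_prop
  lca <- lca_params(rbind(rep(-tau, 4L), rep(tau, 4L)), c(1 - p2, p2))
  growth <- list(do.call(growth_params, TRUE_GROWTH$class1),
                 do.call(growth_params, TRUE_GROWTH$class2))
  two_phase_model(lca, growth)
}

#' Item endorsement probability of the threshold model
#'
#' Evaluates \eqn{P(U = 1 | c) = 1 / (1 + \exp(\tau))}; strictly decreasing
#' in the threshold, 0.5 at zero.  Thresholds are clipped to |tau| <= 35,
#' beyond which the probability is numerically 0 or 1 anyway.
#'
#' @param threshold numeric vector of logit-scale thresholds.
#' @return probabilities in (0, 1), same shape as `threshold`.
#' @examples
#' item_response_prob(0)      # 0.5
#' item_response_prob(1.750)  # ~0.148
#' @export
item_response_prob <- function(threshold) {
  threshold <- pmin(pmax(threshold, -TAU_CLIP), TAU_CLIP)
  1 / (1 + exp(threshold))
}

# Inverse of item_response_prob: probability -> threshold, clipped.
prob_to_threshold <- function(p) {
  p <- pmin(pmax(p, 1 / (1 + exp(TAU_CLIP))), 1 / (1 + exp(-TAU_CLIP)))
  log((1 - p) / p)
}
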