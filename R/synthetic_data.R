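# Data generation from a two-phase mixture model, implied outcome moments,
# and delimited-text dataset I/O.

#' Two-phase dataset container
#'
#' @param indicators n x P matrix of 0/1 indicator responses.
#' @param outcomes n x T matrix of repeated continuous outcomes.
#' @param true_class optional length-n integer vector of generating class
#'   labels in 1..K.  Kept for evaluation only; estimators never read it.
#' @param seed integer seed used to generate the data, if any (bookkeeping).
#' @return An object of class `"two_phase_dataset"`.
#' @export
two_phase_dataset <- function(indicators, outcomes, true_class = NULL,
                              seed = NA_integer_) {
  indicators <- as.matrix(indicators)
  outcomes <- as.matrix(outcomes)
  if (!all(indicators %in% c(0, 1)))
    stop("indicators must contain only 0 and 1")
  storage.mode(indicators) <- "integer"
  storage.mode(outcomes) <- "double"
  if (nrow(indicators) != nrow(outcomes))
    stop("indicators and outcomes must have the same number of rows")
  if (!is.null(true_class)) {
    true_class <- as.integer(true_class)
    if (length(true_class) != nrow(indicators))
      stop("true_class must have one entry per row")
    if (any(true_class < 1L))
      stop("true_class entries must be positive class indices")
  }
  structure(list(indicators = indicators, outcomes = outcomes,
                 true_class = true_class, seed = as.integer(seed)),
            class = "two_phase_dataset")
}

#' @export
print.two_phase_dataset <- function(x, ...) {
  cat("Two-phase dataset:", nrow(x$indicators), "subjects,",
      ncol(x$indicators), "indicators,", ncol(x$outcomes), "time points",
      if (!is.null(x$true_class)) "(true classes recorded)" else "", "\n")
  invisible(x)
}

#' Number of subjects in a dataset
#' @param dataset a [two_phase_dataset()].
#' @return integer row count.
#' @export
n_subjects <- function(dataset) nrow(dataset$indicators)

#' Generate a dataset from a two-phase mixture model
#'
#' Both phases are drawn simultaneously from the generating model: each
#' subject's latent class is drawn from the mixing proportions; indicators
#' are independent Bernoulli draws with class-specific endorsement
#' probabilities [item_response_prob()]; growth factors are bivariate normal
#' with the class's means and covariance; residuals are independent normals
#' with the class's residual variance; outcomes are loadings %*% eta +
#' residuals.  Deterministic given (model, n, seed): draws use R's default
#' Mersenne-Twister generator in a fixed order (classes, indicator uniforms,
#' growth-factor normals, residual normals).
#'
#' @param model a [two_phase_model()].
#' @param n number of subjects (>= 1).
#' @param seed integer seed.
#' @return A [two_phase_dataset()] with `true_class` filled in.
#' @export
generate_dataset <- function(model, n, seed) {
  stopifnot(inherits(model, "two_phase_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  K <- model$lca$n_classes
  P <- ncol(model$lca$thresholds)
  Tt <- nrow(model$loadings)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  cls <- sample.int(K, n, replace = TRUE, prob = model$lca$mixing_props)
  probs <- item_response_prob(model$lca$thresholds)      # K x P
  u <- matrix(stats::runif(n * P), n, P)
  indicators <- (u < probs[cls, , drop = FALSE]) * 1L

  eta_z <- matrix(stats::rnorm(n * 2L), n, 2L)
  eps <- matrix(stats::rnorm(n * Tt), n, Tt)
  outcomes <- matrix(NA_real_, n, Tt)
  for (c in seq_len(K)) {
    idx <- which(cls == c)
    if (!length(idx)) next
    g <- model$growth[[c]]
    R <- chol(growth_psi(g))                             # upper triangular
    eta <- eta_z[idx, , drop = FALSE] %*% R
    eta <- sweep(eta, 2L, growth_mu(g), "+")
    outcomes[idx, ] <- eta %*% t(model$loadings) +
      eps[idx, , drop = FALSE] * sqrt(g$resid_var)
  }
  two_phase_dataset(indicators, outcomes, cls, seed)
}

#' Model-implied outcome moments of a linear growth model
#'
#' Mean vector loadings %*% mu and covariance loadings %*% Psi %*% t(loadings)
#' + resid_var * I implied by one class's growth parameters.
#'
#' @param params a [growth_params()] object.
#' @param loadings T x 2 loading matrix; defaults to [growth_loadings()].
#' @return list with components `mean` (length T) and `cov` (T x T, symmetric
#'   positive definite).
#' @export
implied_outcome_moments <- function(params, loadings = growth_loadings()) {
  stopifnot(inherits(params, "growth_params"))
  loadings <- as.matrix(loadings)
  m <- drop(loadings %*% growth_mu(params))
  v <- loadings %*% growth_psi(params) %*% t(loadings) +
    diag(params$resid_var, nrow(loadings))
  list(mean = m, cov = (v + t(v)) / 2)
}

#' Write a dataset to a delimited text file
#'
#' Comma-separated table with header columns u1..uP, y1..yT, and optionally
#' true_class; indicators are written as integers and outcomes with 17
#' significant digits so a write/read round-trip is lossless to 1e-12.
#'
#' @param dataset a [two_phase_dataset()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "two_phase_dataset"))
  P <- ncol(dataset$indicators); Tt <- ncol(dataset$outcomes)
  df <- data.frame(dataset$indicators, dataset$outcomes)
  names(df) <- c(paste0("u", seq_len(P)), paste0("y", seq_len(Tt)))
  for (j in paste0("y", seq_len(Tt)))
    df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  if (!is.null(dataset$true_class)) df$true_class <- dataset$true_class
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset from a delimited text file
#'
#' Inverse of [write_dataset()]: expects columns u1..u4 and y1..y4 by
#' default (`n_items` / `n_times` generalise this) and an optional
#' true_class column.  Indicator columns must be strictly 0/1.
#'
#' @param path file path.
#' @param n_items,n_times expected number of indicator and outcome columns.
#' @return A [two_phase_dataset()].
#' @export
read_dataset <- function(path, n_items = 4L, n_times = 4L) {
  df <- utils::read.csv(path)
  u_cols <- paste0("u", seq_len(n_items))
  y_cols <- paste0("y", seq_len(n_times))
  for (nm in c(u_cols, y_cols))
    if (!nm %in% names(df))
      stop("missing expected column: ", nm)
  ind <- unname(as.matrix(df[u_cols]))
  if (!all(ind %in% c(0, 1)))
    stop("indicator columns must contain only 0 and 1")
  out <- unname(as.matrix(df[y_cols]))
  if (!all(is.finite(out)))
    stop("outcome columns must be finite numerics")
  two_phase_dataset(ind, out,
                    true_class = if ("true_class" %in% names(df)) df$true_class)
}
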