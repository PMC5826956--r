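# Orchestration of the simulation study: per-replication fitting of all
# methods and class counts, replication management (top up until enough
# converged + correctly-selected replications), aggregation into
# selection-rate and recovery summaries, and entropy summaries.

GROWTH_PAR_NAMES <- c("mean_intercept", "mean_slope", "var_intercept",
                      "var_slope", "cov_int_slope", "resid_var")

#' Simulation-study configuration
#'
#' @param conditions list of [sim_condition()]s (default: the full
#'   27-condition grid).
#' @param reps_target minimum number of converged and correctly-selected
#'   2-class replications per method per condition (the full study uses
#'   1000; the scaled-down default is 100).
#' @param max_reps_factor hard cap on generated replications, as a multiple
#'   of `reps_target`.
#' @param base_seed integer base seed; the seed of replication j in
#'   condition i is (base_seed + 100000 i + j) mod (2^31 - 1), so any
#'   single replication is reproducible in isolation.
#' @param methods subset of `c("one_step", "three_step", "case_weight")`.
#' @param n_starts random starts for 1-/2-class fits; `n_starts_k3` for the
#'   harder 3-class comparison fits.
#' @param tol,max_iter EM controls.
#' @param compute_ses TRUE/FALSE, or a character vector of method names:
#'   estimated SEs are computed for the named methods' 2-class fits (naive
#'   observed information for one-step and three-step, sandwich for
#'   case-weight).  SE computation is the runner's main fixed cost, so
#'   studies that only need point estimates can switch it off.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(conditions = study_condition_grid(),
                         reps_target = 100L, max_reps_factor = 5,
                         base_seed = 1234L,
                         methods = c("one_step", "three_step", "case_weight"),
                         n_starts = 16L, n_starts_k3 = 8L,
                         tol = 1e-7, max_iter = 500L, compute_ses = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (reps_target < 1L) stop("reps_target must be >= 1")
  structure(list(conditions = conditions, reps_target = as.integer(reps_target),
                 max_reps_factor = max_reps_factor,
                 base_seed = as.integer(base_seed), methods = methods,
                 n_starts = as.integer(n_starts),
                 n_starts_k3 = as.integer(n_starts_k3),
                 tol = tol, max_iter = as.integer(max_iter),
                 compute_ses = compute_ses),
            class = "study_config")
}

# Index of a condition in the packaged 27-cell grid (0 if not a grid cell).
condition_index <- function(condition) {
  grid <- study_condition_grid()
  for (i in seq_along(grid)) {
    g <- grid[[i]]
    if (g$sample_size == condition$sample_size &&
        abs(g$class2_prop - condition$class2_prop) < 1e-12 &&
        g$separation_level == condition$separation_level)
      return(i)
  }
  0L
}

#' Seed of one replication
#'
#' Deterministic derivation (base + 100000 * condition index + replication
#' index, modulo 2^31 - 1) so replications are independent of scheduling
#' order and individually re-runnable.
#'
#' @param base_seed integer base seed.
#' @param cond_id condition index (1..27 for grid cells).
#' @param rep_index replication index (1, 2, ...).
#' @return integer seed in [1, 2^31 - 2].
#' @export
replication_seed <- function(base_seed, cond_id, rep_index) {
  # modulus leaves headroom for small per-fit offsets added downstream
  s <- (as.double(base_seed) + 1e5 * cond_id + rep_index) %% 2147480000
  as.integer(max(s, 1))
}

# Flatten one aligned 2-class fit into named estimate / SE vectors.
flatten_growth <- function(fit) {
  est <- unlist(lapply(seq_along(fit$growth), function(c)
    stats::setNames(growth_par_vector(fit$growth[[c]]),
                    paste0("c", c, "_", GROWTH_PAR_NAMES))))
  ses <- if (!is.null(fit$growth_ses)) {
    unlist(lapply(seq_along(fit$growth_ses), function(c)
      stats::setNames(as.numeric(fit$growth_ses[[c]]),
                      paste0("se_c", c, "_", GROWTH_PAR_NAMES))))
  } else {
    stats::setNames(rep(NA_real_, 12L),
                    paste0("se_c", rep(1:2, each = 6L), "_", GROWTH_PAR_NAMES))
  }
  c(est, ses)
}

#' Run one simulation replication
#'
#' Generates one dataset from the condition's generating model and fits
#' everything the study needs: first-step LCA for K = 1, 2, 3 (shared by
#' the case-weight and three-step approaches), one-step joint fits for
#' K = 1, 2, 3, and the three-step and case-weight third steps on the
#' 2-class step-1 result.  Two-class fits are aligned to the generating
#' model before their estimates are recorded.  Failures are captured as
#' flags, never exceptions.
#'
#' @param condition a [sim_condition()].
#' @param rep_index replication index.
#' @param config a [study_config()].
#' @return One-row data.frame (a replication record).
#' @export
run_replication <- function(condition, rep_index, config = study_config()) {
  cond_id <- condition_index(condition)
  seed <- replication_seed(config$base_seed, cond_id, rep_index)
  true_model <- build_true_model(condition)
  dataset <- generate_dataset(true_model, condition$sample_size, seed)

  rec <- data.frame(sample_size = condition$sample_size,
                    class2_prop = condition$class2_prop,
                    separation_level = condition$separation_level,
                    rep_index = rep_index, seed = seed)

  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  want_se <- function(m) isTRUE(config$compute_ses) ||
    (is.character(config$compute_ses) && m %in% config$compute_ses)

  # ---- shared first-step LCA (case-weight / three-step) ----
  lca <- lapply(1:3, function(K)
    safe(fit_lca(dataset, K, n_starts = if (K == 3L) config$n_starts_k3 else config$n_starts,
                 tol = config$tol, max_iter = config$max_iter,
                 seed = seed + K)))
  for (K in 1:3) {
    rec[[paste0("lca_conv", K)]] <- !is.null(lca[[K]]) && lca[[K]]$fit$converged
    rec[[paste0("lca_bic", K)]] <-
      if (!is.null(lca[[K]]) && is.finite(lca[[K]]$fit$loglik)) lca[[K]]$fit$bic else NA_real_
  }
  rec$lca_entropy2 <- if (!is.null(lca[[2]]))
    relative_entropy(lca[[2]]$posteriors) else NA_real_
  rec$lca_selected <- if (rec$lca_conv2)
    correct_selection(c("1" = rec$lca_bic1, "2" = rec$lca_bic2,
                        "3" = rec$lca_bic3)) else FALSE

  record_method <- function(rec, prefix, fit2, conv2, bics) {
    rec[[paste0(prefix, "_conv2")]] <- conv2
    rec[[paste0(prefix, "_selected")]] <- if (conv2)
      correct_selection(bics) else FALSE
    vals <- if (!is.null(fit2)) flatten_growth(align_to_truth(fit2, true_model))
            else stats::setNames(rep(NA_real_, 24L),
                                 c(paste0("c", rep(1:2, each = 6L), "_", GROWTH_PAR_NAMES),
                                   paste0("se_c", rep(1:2, each = 6L), "_", GROWTH_PAR_NAMES)))
    for (nm in names(vals)) rec[[paste0(prefix, "_", nm)]] <- vals[[nm]]
    rec[[paste0(prefix, "_pi2")]] <- if (!is.null(fit2))
      min(align_to_truth(fit2, true_model)$mixing_props_final) else NA_real_
    rec
  }

  # ---- one-step ----
  if ("one_step" %in% config$methods) {
    os <- lapply(1:3, function(K)
      safe(fit_one_step(dataset, K,
                        n_starts = if (K == 3L) config$n_starts_k3 else config$n_starts,
                        tol = config$tol, max_iter = config$max_iter,
                        seed = seed + 10L + K,
                        se_method = if (K == 2L && want_se("one_step"))
                          "naive_hessian" else "none")))
    for (K in 1:3) {
      rec[[paste0("os_conv", K)]] <- !is.null(os[[K]]) && os[[K]]$converged
      rec[[paste0("os_bic", K)]] <-
        if (!is.null(os[[K]]) && is.finite(os[[K]]$loglik)) os[[K]]$bic else NA_real_
    }
    rec$os_entropy <- if (!is.null(os[[2]])) os[[2]]$artifacts$entropy else NA_real_
    rec <- record_method(rec, "os", os[[2]], rec$os_conv2,
                         c("1" = rec$os_bic1, "2" = rec$os_bic2,
                           "3" = rec$os_bic3))
  }

  lca_bics <- c("1" = rec$lca_bic1, "2" = rec$lca_bic2, "3" = rec$lca_bic3)

  # ---- three-step (third step on the 2-class step-1 result) ----
  if ("three_step" %in% config$methods) {
    ts <- if (!is.null(lca[[2]]))
      safe(fit_three_step(dataset, lca[[2]], tol = config$tol,
                          max_iter = config$max_iter,
                          se_method = if (want_se("three_step")) "naive_hessian" else "none"))
    rec <- record_method(rec, "ts", ts, !is.null(ts) && ts$converged, lca_bics)
  }

  # ---- case-weight ----
  if ("case_weight" %in% config$methods) {
    cw <- if (!is.null(lca[[2]]))
      safe(fit_case_weight(dataset, lca[[2]],
                           se_method = if (want_se("case_weight")) "sandwich" else "none"))
    rec <- record_method(rec, "cw", cw, !is.null(cw) && cw$converged, lca_bics)
    rec$cw_eff_n2 <- if (!is.null(cw)) min(cw$artifacts$effective_n) else NA_real_
  }
  rec
}

method_prefix <- c(one_step = "os", three_step = "ts", case_weight = "cw")

#' Run the simulation study
#'
#' For every condition, generates replications until every requested method
#' has `reps_target` replications that converged (for three-step and
#' case-weight: step 1 and step 3 both) *and* correctly selected the
#' 2-class model by BIC — first-step LCA BICs for three-step/case-weight,
#' joint BICs for one-step — or until the hard cap
#' `reps_target * max_reps_factor` is reached.  Aggregates the records into
#' a selection/convergence summary (one row per condition x method), a
#' recovery summary (the four metrics per condition x method x class x
#' parameter, computed over the first `reps_target` usable replications),
#' and an entropy summary.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, records and summaries are
#'   written there as CSV files.
#' @return list with `records`, `selection_summary`, `recovery_summary`,
#'   `entropy_summary`, `warnings`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  prefixes <- method_prefix[config$methods]
  all_records <- list()
  selection_rows <- list()
  recovery_rows <- list()
  warns <- character(0)

  for (ci in seq_along(config$conditions)) {
    condition <- config$conditions[[ci]]
    true_model <- build_true_model(condition)
    cap <- ceiling(config$reps_target * config$max_reps_factor)
    records <- list()
    usable <- stats::setNames(integer(length(prefixes)), prefixes)
    rep_index <- 0L
    while (any(usable < config$reps_target) && rep_index < cap) {
      rep_index <- rep_index + 1L
      rec <- run_replication(condition, rep_index, config)
      records[[rep_index]] <- rec
      for (p in prefixes)
        if (isTRUE(rec[[paste0(p, "_conv2")]]) &&
            isTRUE(rec[[paste0(p, "_selected")]]))
          usable[p] <- usable[p] + 1L
    }
    if (any(usable < config$reps_target))
      warns <- c(warns, sprintf(
        "condition %d (n=%d, p2=%.2f, %s): replication cap %d reached with usable counts %s",
        ci, condition$sample_size, condition$class2_prop,
        condition$separation_level, cap,
        paste(sprintf("%s=%d", names(usable), usable), collapse = ", ")))
    records <- do.call(rbind, records)
    all_records[[ci]] <- records

    for (m in config$methods) {
      p <- method_prefix[[m]]
      conv2 <- mean(records[[paste0(p, "_conv2")]])
      conv3 <- if (m == "one_step") mean(records$os_conv3)
               else mean(records$lca_conv3)
      sel <- records[[paste0(p, "_selected")]]
      sel_rate <- if (any(records[[paste0(p, "_conv2")]]))
        mean(sel[records[[paste0(p, "_conv2")]]]) else NA_real_
      selection_rows[[length(selection_rows) + 1L]] <- data.frame(
        sample_size = condition$sample_size, class2_prop = condition$class2_prop,
        separation_level = condition$separation_level, method = m,
        conv2_rate = conv2, conv3_rate = conv3,
        correct_selection_rate = sel_rate, n_reps = nrow(records),
        n_usable = usable[[p]])

      ok <- which(records[[paste0(p, "_conv2")]] & sel)
      ok <- utils::head(ok, config$reps_target)
      if (length(ok) >= 2L) {
        est_cols <- paste0(p, "_c", rep(1:2, each = 6L), "_", GROWTH_PAR_NAMES)
        se_cols <- paste0(p, "_se_c", rep(1:2, each = 6L), "_", GROWTH_PAR_NAMES)
        est <- as.matrix(records[ok, est_cols])
        colnames(est) <- sub(paste0("^", p, "_"), "", est_cols)
        ses <- as.matrix(records[ok, se_cols])
        colnames(ses) <- sub(paste0("^", p, "_se_"), "", se_cols)
        have_ses <- all(is.finite(ses))
        met <- recovery_metrics(est, true_model,
                                ses = if (have_ses) ses)
        met$sample_size <- condition$sample_size
        met$class2_prop <- condition$class2_prop
        met$separation_level <- condition$separation_level
        met$method <- m
        recovery_rows[[length(recovery_rows) + 1L]] <- met
      }
    }
  }

  records <- do.call(rbind, all_records)
  out <- list(records = records,
              selection_summary = do.call(rbind, selection_rows),
              recovery_summary = if (length(recovery_rows))
                do.call(rbind, recovery_rows) else NULL,
              entropy_summary = entropy_from_records(records),
              warnings = warns)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
    utils::write.csv(out$selection_summary,
                     file.path(out_dir, "selection_summary.csv"), row.names = FALSE)
    if (!is.null(out$recovery_summary))
      utils::write.csv(out$recovery_summary,
                       file.path(out_dir, "recovery_summary.csv"), row.names = FALSE)
    utils::write.csv(out$entropy_summary,
                     file.path(out_dir, "entropy_summary.csv"), row.names = FALSE)
  }
  out
}

entropy_from_records <- function(records) {
  agg <- stats::aggregate(lca_entropy2 ~ separation_level, records, mean)
  names(agg)[2] <- "mean_entropy"
  agg[order(match(agg$separation_level, c("low", "medium", "high"))), ,
      drop = FALSE]
}

#' Mean first-step entropy per class-separation level
#'
#' Generates `reps` datasets for every condition in the configuration, fits
#' the 2-class first-step LCA, and averages the relative entropy of its
#' posteriors over replications and over the conditions sharing each
#' separation level.  This is the light-weight entropy calibration of the
#' design (no auxiliary-model fitting).
#'
#' @param config a [study_config()]; only its conditions, seeds and LCA
#'   controls are used.
#' @param reps replications per condition (default `config$reps_target`).
#' @return list with `by_level` (separation level, mean entropy) and
#'   `by_condition` (per-cell breakdown).
#' @export
summarize_entropy <- function(config = study_config(),
                              reps = config$reps_target) {
  rows <- list()
  for (ci in seq_along(config$conditions)) {
    condition <- config$conditions[[ci]]
    cond_id <- condition_index(condition)
    model <- build_true_model(condition)
    ent <- numeric(reps)
    for (j in seq_len(reps)) {
      seed <- replication_seed(config$base_seed, cond_id, j)
      ds <- generate_dataset(model, condition$sample_size, seed)
      res <- fit_lca(ds, 2L, n_starts = config$n_starts, tol = config$tol,
                     max_iter = config$max_iter, seed = seed + 2L)
      ent[j] <- relative_entropy(res$posteriors)
    }
    rows[[ci]] <- data.frame(sample_size = condition$sample_size,
                             class2_prop = condition$class2_prop,
                             separation_level = condition$separation_level,
                             mean_entropy = mean(ent), reps = reps)
  }
  by_condition <- do.call(rbind, rows)
  agg <- stats::aggregate(mean_entropy ~ separation_level, by_condition, mean)
  agg <- agg[order(match(agg$separation_level, c("low", "medium", "high"))), ,
             drop = FALSE]
  list(by_level = agg, by_condition = by_condition)
}
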