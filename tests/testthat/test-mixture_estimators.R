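test_that("K = 1 one-step factorises into closed-form LCA plus unweighted LGM", {
  ds <- generate_dataset(design_model(), 300, seed = 12)
  os <- fit_one_step(ds, 1)
  lca1 <- fit_lca(ds, 1)
  lgm1 <- fit_weighted_lgm(weighted_sample(ds$outcomes))
  expect_equal(os$loglik, lca1$fit$loglik + lgm1$loglik, tolerance = 1e-8)
  expect_equal(os$lca$thresholds, lca1$fit$params$thresholds, tolerance = 1e-10)
  expect_equal(twophasemix:::growth_par_vector(os$growth[[1]]),
               twophasemix:::growth_par_vector(lgm1$params), tolerance = 1e-8)
  expect_equal(os$n_params, 10L)
})

test_that("one-step EM reaches the brute-force joint maximum on a tiny dataset", {
  ds <- toy_joint_dataset()
  os <- fit_one_step(ds, 2, n_starts = 24, seed = 5, n_finish = 8,
                     tol = 1e-13, max_iter = 20000)
  oracle <- oracle_one_step_max(ds$indicators, ds$outcomes, growth_loadings())
  expect_gte(os$loglik, oracle - 1e-3)
  expect_lte(os$loglik, oracle + 1e-2)
})

test_that("one-step EM is monotone and permutation-stable", {
  ds <- generate_dataset(design_model(0.3, "medium"), 300, seed = 14)
  os <- fit_one_step(ds, 2, n_starts = 4, seed = 2, keep_trace = TRUE)
  for (tr in os$artifacts$traces)
    expect_true(all(diff(tr) > -1e-8 * (abs(tr[-length(tr)]) + 1)))
  # construction orders classes by size
  expect_true(os$mixing_props_final[1] >= os$mixing_props_final[2])
  expect_equal(os$bic, -2 * os$loglik + os$n_params * log(300), tolerance = 1e-8)
})

test_that("perfect step-1 classification reduces three-step to subgroup fits", {
  ds <- generate_dataset(design_model(), 400, seed = 21)
  step1 <- hard_step1(ds)
  ts <- fit_three_step(ds, step1, tol = 1e-10)
  expect_equal(ts$artifacts$q, diag(2), tolerance = 1e-12)
  for (cls in 1:2) {
    sub <- fit_weighted_lgm(weighted_sample(ds$outcomes[ds$true_class == cls, ]),
                            tol = 1e-12)
    expect_equal(twophasemix:::growth_par_vector(ts$growth[[cls]]),
                 twophasemix:::growth_par_vector(sub$params), tolerance = 1e-6)
  }
  expect_equal(ts$mixing_props_final, unname(table(ds$true_class)) / 400,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a fully uniform q makes three-step a label-free outcome mixture", {
  ds <- generate_dataset(design_model(), 300, seed = 33)
  lca2 <- fit_lca(ds, 2, seed = 3)
  qu <- matrix(0.5, 2, 2)
  ts <- fit_three_step(ds, lca2, tol = 1e-9, max_iter = 600, q_override = qu)

  # oracle: outcome-only mixture EM from the same starting values
  Y <- ds$outcomes
  L <- growth_loadings()
  post1 <- lca2$posteriors
  pi_c <- lca2$fit$params$mixing_props
  growth <- lapply(1:2, function(c)
    twophasemix:::lgm_moment_start(Y, pmax(post1[, c], 1e-8), L))
  ll_old <- -Inf
  for (it in 1:600) {
    lw <- sapply(1:2, function(c)
      log(pi_c[c]) + twophasemix:::lgm_logdens_rows(growth[[c]], Y, L))
    lse <- twophasemix:::row_logsumexp(lw)
    ll <- sum(lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-9 * (abs(ll_old) + 1)) break
    ll_old <- ll
    w <- exp(lw - lse)
    pi_c <- colMeans(w)
    for (c in 1:2) {
      fm <- twophasemix:::lgm_factor_moments(growth[[c]], Y, L)
      growth[[c]] <- twophasemix:::lgm_m_step(fm, Y, w[, c], L)
    }
  }
  # the q term only contributes the constant n log(1/2); both EMs run the
  # same iteration sequence, so parameters coincide too
  expect_equal(ts$loglik, ll + 300 * log(0.5), tolerance = 1e-5)
  ord <- order(pi_c, decreasing = TRUE)
  expect_equal(ts$mixing_props_final, pi_c[ord], tolerance = 1e-4)
  for (k in 1:2)
    expect_equal(twophasemix:::growth_par_vector(ts$growth[[k]]),
                 unlist(growth[[ord[k]]])[names(twophasemix:::growth_par_vector(ts$growth[[k]]))],
                 tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("0/1 posteriors make case-weight identical to classify-and-analyze", {
  ds <- generate_dataset(design_model(), 400, seed = 55)
  step1 <- hard_step1(ds)
  cw <- fit_case_weight(ds, step1, se_method = "none")
  for (cls in 1:2) {
    sub <- fit_weighted_lgm(weighted_sample(ds$outcomes[ds$true_class == cls, ]))
    expect_equal(twophasemix:::growth_par_vector(cw$growth[[cls]]),
                 twophasemix:::growth_par_vector(sub$params), tolerance = 1e-8)
  }
  expect_false(cw$loglik_comparable)
})

test_that("case-weight effective sample sizes are the posterior column sums", {
  ds <- generate_dataset(design_model(0.30), 800, seed = 60)
  lca2 <- fit_lca(ds, 2, seed = 4)
  cw <- fit_case_weight(ds, lca2, se_method = "none")
  expect_equal(cw$artifacts$effective_n, colSums(cw$artifacts$posteriors),
               tolerance = 1e-12, ignore_attr = TRUE)
  # at high separation the class-2 mass concentrates near n * pi_2
  expect_equal(min(cw$artifacts$effective_n) / 800, 0.30, tolerance = 0.12)
})

test_that("three-step recovers class-2 growth parameters at high separation", {
  m <- design_model(0.30)
  ds <- generate_dataset(m, 5000, seed = 71)
  lca2 <- fit_lca(ds, 2, seed = 6)
  ts <- align_to_truth(fit_three_step(ds, lca2), m)
  est <- twophasemix:::growth_par_vector(ts$growth[[2]])
  truth <- twophasemix:::growth_par_vector(m$growth[[2]])
  expect_true(all(abs(est - truth) < c(0.12, 0.08, 0.25, 0.08, 0.10, 0.08)))
})

test_that("three-step and case-weight coincide as entropy approaches 1", {
  # |tau| = 6: indicators are nearly deterministic given the class
  lca_true <- lca_params(rbind(rep(-6, 4), rep(6, 4)), c(0.7, 0.3))
  m <- two_phase_model(lca_true, design_model()$growth)
  ds <- generate_dataset(m, 1500, seed = 81)
  lca2 <- fit_lca(ds, 2, seed = 3)
  expect_gt(relative_entropy(lca2$posteriors), 0.999)
  ts <- fit_three_step(ds, lca2, tol = 1e-10)
  cw <- fit_case_weight(ds, lca2, se_method = "none", tol = 1e-12)
  for (cls in 1:2)
    expect_true(all(abs(twophasemix:::growth_par_vector(ts$growth[[cls]]) -
                        twophasemix:::growth_par_vector(cw$growth[[cls]])) < 0.01))
})

test_that("the three approaches agree on class-1 parameters at high separation", {
  m <- design_model(0.30)
  diffs_ts <- diffs_cw <- matrix(NA_real_, 12, 6)
  for (r in 1:12) {
    ds <- generate_dataset(m, 1000, seed = 900 + r)
    os <- align_to_truth(fit_one_step(ds, 2, seed = r), m)
    lca2 <- fit_lca(ds, 2, seed = r)
    ts <- align_to_truth(fit_three_step(ds, lca2), m)
    cw <- align_to_truth(fit_case_weight(ds, lca2, se_method = "none"), m)
    g <- function(f) twophasemix:::growth_par_vector(f$growth[[1]])
    diffs_ts[r, ] <- g(os) - g(ts)
    diffs_cw[r, ] <- g(os) - g(cw)
  }
  # one-step and three-step are statistically indistinguishable for
  # class 1; case-weight keeps a small residual bias, an order of
  # magnitude below its class-2 bias, so "nearly indistinguishable"
  for (j in 1:6) {
    se <- sd(diffs_ts[, j]) / sqrt(nrow(diffs_ts))
    expect_lt(abs(mean(diffs_ts[, j])), max(2 * se, 0.02))
    expect_lt(abs(mean(diffs_cw[, j])), 0.05)
  }
})

test_that("estimators never see the true class labels", {
  ds <- generate_dataset(design_model(), 200, seed = 91)
  blinded <- two_phase_dataset(ds$indicators, ds$outcomes)   # labels dropped
  expect_equal(fit_lca(blinded, 2, seed = 1)$fit$loglik,
               fit_lca(ds, 2, seed = 1)$fit$loglik)
  expect_equal(fit_one_step(blinded, 2, seed = 1)$loglik,
               fit_one_step(ds, 2, seed = 1)$loglik)
})
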