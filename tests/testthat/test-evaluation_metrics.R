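test_that("the four recovery metrics match their printed formulas", {
  expect_equal(absolute_relative_bias(metric_input(c(1, 1, 1), 1)), 0)
  expect_equal(absolute_relative_bias(metric_input(c(1.1, 0.9), 1)), 0)
  expect_equal(absolute_relative_bias(metric_input(c(1.2, 1.2), 1)), 0.2)
  expect_error(absolute_relative_bias(metric_input(c(1, 2), 0)), "zero true value")

  expect_equal(empirical_se(metric_input(c(3, 3, 3), 1)), 0)
  expect_equal(empirical_se(metric_input(c(0, 2), 1)), 1)

  expect_equal(se_ratio(metric_input(c(0, 2), 1, estimated_ses = c(1, 1))), 1)
  expect_equal(se_ratio(metric_input(c(0, 2), 1, estimated_ses = c(0.5, 0.5))), 0.5)
  expect_equal(se_ratio(metric_input(c(0, 0.4), 5, estimated_ses = c(0.1, 0.3))), 1)
  expect_error(se_ratio(metric_input(c(1, 1), 1, estimated_ses = c(1, 1))),
               "empirical SE is zero")

  expect_equal(rmse(metric_input(c(2, 2), 2)), 0)
  expect_equal(rmse(metric_input(c(0, 2), 0)), sqrt(2))
})

test_that("rmse^2 = bias^2 + empirical_se^2 and divisor-r identities hold", {
  set.seed(321)
  for (k in 1:1000) {
    r <- sample(2:30, 1)
    est <- rnorm(r, sd = runif(1, 0.1, 3))
    theta <- rnorm(1)
    m <- metric_input(est, theta)
    expect_equal(rmse(m)^2,
                 (mean(est) - theta)^2 + empirical_se(m)^2, tolerance = 1e-10)
    expect_equal(empirical_se(m)^2, mean(est^2) - mean(est)^2, tolerance = 1e-10)
    # replication order is irrelevant
    expect_equal(rmse(metric_input(rev(est), theta)), rmse(m))
  }
})

test_that("metrics are scale-equivariant", {
  set.seed(12)
  est <- rnorm(50, 2); ses <- runif(50, 0.1, 0.4); a <- 3.7
  m1 <- metric_input(est, 2, ses)
  m2 <- metric_input(a * est, a * 2, a * ses)
  expect_equal(absolute_relative_bias(m2), absolute_relative_bias(m1))
  expect_equal(se_ratio(m2), se_ratio(m1))
  expect_equal(empirical_se(m2), a * empirical_se(m1))
  expect_equal(rmse(m2), a * rmse(m1))
})

test_that("correct selection requires the 2-class BIC to be strictly smallest", {
  expect_true(correct_selection(c("1" = 10, "2" = 5, "3" = 8)))
  expect_false(correct_selection(c("1" = 5, "2" = 5, "3" = 8)))
  expect_false(correct_selection(c("1" = 4, "2" = 5, "3" = 8)))
  # a failed 3-class comparison fit: decided against the 1-class model only
  expect_true(correct_selection(c("1" = 10, "2" = 5, "3" = NA)))
  expect_false(correct_selection(c("1" = 4, "2" = 5, "3" = NA)))
  expect_false(correct_selection(c("1" = NA, "2" = 5, "3" = 8)))
  expect_error(correct_selection(c("1" = 4, "2" = 5)), "missing")
})

test_that("alignment to truth recovers the generating permutation", {
  m <- design_model()
  make_fit <- function(growth, pis) {
    two_phase_fit("one_step", lca_params(matrix(0, 2, 4), c(0.5, 0.5)),
                  growth, mixing_props_final = pis, loglik = -10,
                  n_params = 21, n = 100, converged = TRUE)
  }
  # already aligned: identity
  fit <- make_fit(m$growth, c(0.7, 0.3))
  expect_equal(align_to_truth(fit, m)$alignment, 1:2)

  # swapped classes: constructor reorders by size, so build a fit whose
  # size order conflicts with parameter proximity
  fit2 <- make_fit(m$growth[2:1], c(0.7, 0.3))
  al2 <- align_to_truth(fit2, m)
  expect_equal(al2$alignment, 2:1)
  expect_equal(al2$growth[[1]]$mean_slope, 1.0)
  expect_equal(al2$growth[[2]]$mean_slope, 1.8)
  expect_true(al2$alignment_differs_from_size_order)

  # noisy copies of the truth: permutation always recovered
  set.seed(2718)
  hits <- 0L
  for (k in 1:100) {
    jitter <- function(g) {
      v <- twophasemix:::growth_par_vector(g) + rnorm(6, 0, 0.05)
      v[3:4] <- pmax(v[3:4], 0.05)
      v[5] <- sign(v[5]) * min(abs(v[5]), 0.9 * sqrt(v[3] * v[4]))
      v[6] <- max(v[6], 0.05)
      twophasemix:::growth_from_vector(v)
    }
    swap <- sample(c(TRUE, FALSE), 1)
    growth <- lapply(m$growth[if (swap) 2:1 else 1:2], jitter)
    fit <- make_fit(growth, c(0.5 + 1e-6, 0.5 - 1e-6))
    al <- align_to_truth(fit, m)
    if (identical(al$alignment, if (swap) 2:1 else 1:2)) hits <- hits + 1L
  }
  expect_equal(hits, 100L)
})

test_that("recovery_metrics averages per-parameter metrics per class", {
  m <- design_model()
  set.seed(7)
  cols <- paste0("c", rep(1:2, each = 6), "_", twophasemix:::GROWTH_PAR_NAMES)
  est <- matrix(rnorm(20 * 12, mean = 1, sd = 0.2), 20, 12,
                dimnames = list(NULL, cols))
  ses <- matrix(runif(20 * 12, 0.05, 0.3), 20, 12,
                dimnames = list(NULL, cols))
  met <- recovery_metrics(est, m, ses = ses)
  for (cls in 1:2) {
    sub <- met[met$class == cls & met$parameter != "average", ]
    avg <- met[met$class == cls & met$parameter == "average", ]
    expect_equal(avg$abs_rel_bias, mean(sub$abs_rel_bias), tolerance = 1e-10)
    expect_equal(avg$rmse, mean(sub$rmse), tolerance = 1e-10)
    expect_equal(avg$se_ratio, mean(sub$se_ratio), tolerance = 1e-10)
  }
})
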