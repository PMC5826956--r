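test_that("K = 1 is fitted in closed form", {
  ds <- toy_dataset()
  res <- fit_lca(ds, 1)
  pbar <- colMeans(ds$indicators)
  expect_equal(item_response_prob(res$fit$params$thresholds[1, ]), pbar,
               tolerance = 1e-12, ignore_attr = TRUE)
  ll <- sum(ds$indicators %*% log(pbar) + (1 - ds$indicators) %*% log(1 - pbar))
  expect_equal(res$fit$loglik, ll)
  expect_equal(res$fit$n_params, 4L)
  expect_true(all(res$posteriors == 1))
})

test_that("2-class EM reaches the brute-force maximum on a tiny dataset", {
  ds <- toy_dataset()
  res <- fit_lca(ds, 2, n_starts = 16, seed = 3)
  oracle <- oracle_lca_max(ds$indicators)
  expect_gte(res$fit$loglik, oracle - 1e-4)
  expect_lte(res$fit$loglik, oracle + 1e-3)
})

test_that("thresholds are recovered on well separated simulated data", {
  m <- design_model(class2_prop = 0.30)
  ds <- generate_dataset(m, 2000, seed = 31)
  res <- fit_lca(ds, 2, seed = 8)
  expect_true(res$fit$converged)
  # classes come out ordered by size: class 1 is the tau = -1.75 class.
  # 3 Monte-Carlo SEs of a threshold estimate at these class sizes are
  # about 0.23 (class 1) and 0.35 (class 2).
  expect_true(all(abs(res$fit$params$thresholds[1, ] - (-1.750)) < 0.25))
  expect_true(all(abs(res$fit$params$thresholds[2, ] - 1.750) < 0.35))
  expect_equal(res$fit$params$mixing_props[2], 0.30, tolerance = 0.12)
  expect_equal(res$fit$bic,
               -2 * res$fit$loglik + 9 * log(2000), tolerance = 1e-8)
})

test_that("posterior probabilities follow Bayes rule", {
  params <- lca_params(rbind(rep(-0.754, 4), rep(0.754, 4)), c(0.7, 0.3))
  ds <- two_phase_dataset(matrix(1, 1, 4), matrix(0, 1, 4))
  post <- posterior_probs(params, ds)
  # hand Bayes arithmetic with p1 = 0.68009, p2 = 0.31991
  p1 <- 1 / (1 + exp(-0.754)); p2 <- 1 / (1 + exp(0.754))
  expected <- 0.7 * p1^4 / (0.7 * p1^4 + 0.3 * p2^4)
  expect_equal(post[1, 1], expected, tolerance = 1e-12)
  expect_equal(expected, 0.979, tolerance = 1e-3)

  # indistinguishable classes: posteriors equal the prior
  params0 <- lca_params(matrix(0, 2, 4), c(0.5, 0.5))
  ds2 <- generate_dataset(design_model(), 40, seed = 2)
  post2 <- posterior_probs(params0, ds2)
  expect_true(all(abs(post2 - 0.5) < 1e-12))

  post3 <- posterior_probs(lca_params(rbind(rep(-2, 4), rep(1, 4)), c(0.6, 0.4)), ds2)
  expect_true(all(abs(rowSums(post3) - 1) < 1e-10))
})

test_that("modal assignment picks the largest posterior with a deterministic tie-break", {
  expect_equal(modal_assignment(rbind(c(0.2, 0.8))), 2L)
  expect_equal(modal_assignment(rbind(c(0.5, 0.5))), 1L)
  post <- rbind(c(1, 0), c(0, 1), c(0.3, 0.7))
  expect_equal(modal_assignment(post), c(1L, 2L, 2L))
})

test_that("classification tables average posteriors per assigned class", {
  # perfect classification: identity matrix
  post <- rbind(c(1, 0), c(0, 1), c(1, 0))
  ct <- classification_table(post)
  expect_equal(ct$q, diag(2))
  expect_equal(ct$assigned_counts, c(2L, 1L))

  # hand arithmetic: all mass assigned to class 1
  post2 <- rbind(c(0.8, 0.2), c(0.6, 0.4))
  ct2 <- classification_table(post2)
  expect_equal(modal_assignment(post2), c(1L, 1L))
  expect_equal(ct2$q, rbind(c(1, 0), c(1, 0)))
  expect_true(all(abs(rowSums(ct2$q) - 1) < 1e-10))

  # high separation: diagonal dominance
  ds <- generate_dataset(design_model(), 1500, seed = 21)
  res <- fit_lca(ds, 2, seed = 5)
  q <- classification_table(res$posteriors)$q
  expect_true(all(diag(q) >= q[row(q) != col(q)]))
  expect_true(all(abs(rowSums(q) - 1) < 1e-10))
})

test_that("relative entropy is 1 under certainty, 0 under uniformity", {
  expect_equal(relative_entropy(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(relative_entropy(matrix(1 / 3, 5, 3)), 0)
  expect_equal(relative_entropy(rbind(c(1, 0), c(0.5, 0.5))), 0.5)
  expect_error(relative_entropy(matrix(1, 3, 1)), "K >= 2")
})

test_that("every EM start increases the log-likelihood monotonically", {
  ds <- generate_dataset(design_model(0.15, "medium"), 400, seed = 9)
  res <- fit_lca(ds, 2, n_starts = 6, seed = 13, keep_trace = TRUE)
  for (tr in res$fit$extra$traces)
    expect_true(all(diff(tr) > -1e-9))
})

test_that("label permutation leaves likelihood, BIC and entropy unchanged", {
  ds <- generate_dataset(design_model(0.3, "medium"), 400, seed = 10)
  params <- lca_params(rbind(rep(-1, 4), rep(1.2, 4)), c(0.65, 0.35))
  swapped <- lca_params(params$thresholds[2:1, ], params$mixing_props[2:1])
  # mixture likelihood computed directly in the test
  mix_ll <- function(p) {
    probs <- item_response_prob(p$thresholds)
    lik <- sapply(1:2, function(c)
      p$mixing_props[c] *
        apply(ds$indicators, 1, function(u) prod(probs[c, ]^u * (1 - probs[c, ])^(1 - u))))
    sum(log(rowSums(lik)))
  }
  expect_equal(mix_ll(params), mix_ll(swapped), tolerance = 1e-12)
  expect_equal(relative_entropy(posterior_probs(params, ds)),
               relative_entropy(posterior_probs(swapped, ds)), tolerance = 1e-12)
})

test_that("fit_lca rejects impossible inputs", {
  ds <- toy_dataset()
  expect_error(fit_lca(ds, 0), "K must be")
  expect_error(fit_lca(ds, 6), "distinct response patterns")
})
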