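test_that("the weighted log-likelihood honours its weighting contract", {
  set.seed(100)
  Y <- matrix(rnorm(40, sd = 1.5), 10, 4) + outer(rep(1, 10), c(0, 1, 2, 3))
  g <- growth_params(0.2, 0.9, 1.2, 0.4, 0.1, 0.6)

  ll_unw <- lgm_loglik(g, weighted_sample(Y))
  expect_equal(lgm_loglik(g, weighted_sample(Y, rep(1, 10))), ll_unw)

  # duplicating a row equals giving it weight 2
  Y2 <- rbind(Y, Y[3, ])
  w <- rep(1, 10); w[3] <- 2
  expect_equal(lgm_loglik(g, weighted_sample(Y2)),
               lgm_loglik(g, weighted_sample(Y, w)), tolerance = 1e-10)

  # single subject, Psi ~ 0, theta = 1, mean matched: T * log phi(0; 0, 1)
  y <- matrix(c(0.5, 1.5, 2.5, 3.5), 1, 4)
  g0 <- growth_params(0.5, 1.0, 1e-10, 1e-10, 0, 1)
  expect_equal(lgm_loglik(g0, weighted_sample(y)),
               4 * dnorm(0, log = TRUE), tolerance = 1e-6)
})

test_that("unweighted ML recovers the generating growth parameters at large n", {
  m <- design_model()
  lca1 <- lca_params(matrix(0, 1, 4), 1)
  m1 <- two_phase_model(lca1, m$growth[1])
  ds <- generate_dataset(m1, 100000, seed = 404)
  fit <- fit_weighted_lgm(weighted_sample(ds$outcomes),
                          se_method = "naive_hessian")
  expect_true(fit$converged)
  est <- twophasemix:::growth_par_vector(fit$params)
  truth <- c(mean_intercept = 0.6, mean_slope = 1.0, var_intercept = 1.9,
             var_slope = 0.4, cov_int_slope = 0.5, resid_var = 0.5)
  # at this n the estimated SEs are accurate Monte-Carlo SEs
  expect_true(all(abs(est - truth) < 3 * fit$estimated_ses))

  # the fitted likelihood is at least the truth's likelihood
  expect_gte(fit$loglik, lgm_loglik(m$growth[[1]], weighted_sample(ds$outcomes)))
})

test_that("rescaling all weights leaves the maximiser unchanged", {
  ds <- generate_dataset(design_model(), 200, seed = 6)
  f1 <- fit_weighted_lgm(weighted_sample(ds$outcomes))
  f2 <- fit_weighted_lgm(weighted_sample(ds$outcomes, rep(3.7, 200)))
  expect_equal(twophasemix:::growth_par_vector(f1$params),
               twophasemix:::growth_par_vector(f2$params), tolerance = 1e-7)
  expect_equal(f2$loglik, 3.7 * f1$loglik, tolerance = 1e-8)
})

test_that("EM and quasi-Newton fitters agree across random fixtures", {
  set.seed(909)
  for (k in 1:20) {
    g <- random_growth_params()
    m <- two_phase_model(lca_params(matrix(0, 1, 4), 1), list(g))
    ds <- generate_dataset(m, 60, seed = 1000 + k)
    w <- runif(60, 0.05, 1)
    s <- weighted_sample(ds$outcomes, w)
    fe <- fit_weighted_lgm(s, method = "em")
    fo <- fit_weighted_lgm(s, method = "optim")
    expect_lt(abs(fe$loglik - fo$loglik), 1e-5)
    # reparameterisation invariance of the implied moments
    me <- implied_outcome_moments(fe$params)
    mo <- implied_outcome_moments(fo$params)
    expect_equal(me$mean, mo$mean, tolerance = 1e-3)
    expect_equal(me$cov, mo$cov, tolerance = 2e-3)
  }
})

test_that("the weighted EM log-likelihood is monotone", {
  set.seed(77)
  ds <- generate_dataset(design_model(), 120, seed = 3)
  s <- weighted_sample(ds$outcomes, runif(120, 0.1, 1))
  fit <- fit_weighted_lgm(s, keep_trace = TRUE)
  expect_true(all(diff(fit$extra$trace) > -1e-9))
})

test_that("degenerate and small samples are flagged, not thrown", {
  ds <- generate_dataset(design_model(), 40, seed = 3)
  w <- rep(0, 40); w[1:2] <- 1
  fit <- fit_weighted_lgm(weighted_sample(ds$outcomes, w))
  expect_false(fit$converged)
  expect_equal(fit$reason, "degenerate_sample")

  fit2 <- fit_weighted_lgm(weighted_sample(ds$outcomes[1:10, ]))
  expect_false(fit2$converged)
  expect_equal(fit2$reason, "small_effective_n")
})

test_that("estimate_ses matches closed forms", {
  # quadratic objective -sum w (x - mu)^2 / 2: SE(mu) = 1/sqrt(sum w)
  w <- c(2, 3, 5)
  x <- c(0.4, -1, 2)
  fn <- function(par) -sum(w * (x - par)^2) / 2
  se <- estimate_ses(fn, c(mu = sum(w * x) / sum(w)))$se
  expect_equal(unname(se), 1 / sqrt(sum(w)), tolerance = 1e-6)

  # iid normal mean with known variance: SE = sigma / sqrt(n)
  set.seed(5)
  sigma <- 1.7; z <- rnorm(400, 2, sigma)
  fn2 <- function(par) sum(dnorm(z, par, sigma, log = TRUE))
  se2 <- estimate_ses(fn2, c(mu = mean(z)))$se
  expect_equal(unname(se2), sigma / sqrt(400), tolerance = 1e-6)
})

test_that("naive and sandwich SEs agree under correct specification", {
  m <- design_model()
  m1 <- two_phase_model(lca_params(matrix(0, 1, 4), 1), m$growth[1])
  ds <- generate_dataset(m1, 10000, seed = 88)
  s <- weighted_sample(ds$outcomes)
  fit <- fit_weighted_lgm(s)
  obj <- twophasemix:::lgm_objective(s)
  par <- twophasemix:::growth_par_vector(fit$params)
  naive <- estimate_ses(obj$fn, par, "naive_hessian")$se
  sand <- estimate_ses(obj$fn, par, "sandwich", fn_i = obj$fn_i,
                       weights = s$weights)$se
  expect_true(all(abs(sand / naive - 1) < 0.10))
})
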