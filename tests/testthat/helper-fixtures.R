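# Shared fixtures built in code at test time.

design_model <- function(class2_prop = 0.30, separation = "high") {
  build_true_model(sim_condition(2000, class2_prop, separation))
}

# Tiny fixed indicator matrix with repeated patterns (6 subjects, 4 items).
toy_indicators <- function() {
  rbind(c(1, 1, 1, 1),
        c(1, 1, 0, 1),
        c(1, 1, 1, 1),
        c(0, 0, 0, 0),
        c(0, 1, 0, 0),
        c(0, 0, 0, 1))
}

toy_dataset <- function() {
  set.seed(4242)
  y <- matrix(rnorm(24), 6, 4)
  two_phase_dataset(toy_indicators(), y)
}

# 8-subject joint toy for the one-step oracle: generated from a well
# separated 2-class model so the small-sample likelihood is well behaved.
toy_joint_dataset <- function() {
  m <- build_true_model(sim_condition(500, 0.4999, "high"))
  generate_dataset(m, 8, seed = 515)
}

# Random valid growth parameters for property-style fixtures.
random_growth_params <- function() {
  repeat {
    vi <- runif(1, 0.4, 2.5); vs <- runif(1, 0.1, 0.8)
    cv <- runif(1, -0.5, 0.9) * sqrt(vi * vs)
    p <- try(growth_params(runif(1, -1, 1), runif(1, 0.5, 2), vi, vs, cv,
                           runif(1, 0.2, 1.2)), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# A step-1 object with hard (0/1) posteriors built from true classes.
hard_step1 <- function(dataset, K = 2) {
  post <- matrix(0, n_subjects(dataset), K)
  post[cbind(seq_len(nrow(post)), dataset$true_class)] <- 1
  pi_c <- colMeans(post)
  params <- lca_params(matrix(rep(c(-2, 2), each = 4), K, 4, byrow = TRUE),
                       pi_c)
  fit <- fit_result(params, loglik = 0, n_params = 9, n = nrow(post),
                    converged = TRUE)
  list(fit = fit, posteriors = post)
}
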