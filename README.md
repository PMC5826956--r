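# twophasemix

Estimation and Monte-Carlo evaluation of **two-phase mixture models**: a
latent class analysis (LCA) measurement phase on dichotomous indicators,
combined with a class-specific auxiliary **linear growth model** (LGM) for
repeated continuous outcomes.  The package is aimed at methodologists and
applied researchers in the behavioural and health sciences who need to link
latent classes to an auxiliary growth model and want to understand — or
simulate — how the choice of linking approach affects bias, standard
errors, convergence and model selection.

## The model

The measurement phase is a K-class LCA with threshold parameterisation

    P(U_p = 1 | c) = 1 / (1 + exp(tau_cp)),

and the auxiliary phase is a linear growth model

    y = Lambda eta + eps,   Lambda = [1 1 1 1; 0 1 2 3]',

with class-specific growth-factor means mu_c and covariance Psi_c,
eta | c ~ N(mu_c, Psi_c), and equal uncorrelated residual variances
theta_c.  Three linking approaches are implemented:

* **one-step** — joint maximum likelihood of both phases by EM
  (`fit_one_step()`);
* **three-step** — LCA first (`fit_lca()`), modal assignment plus the
  classification-error matrix q, then ML re-estimation of the growth
  parameters with q fixed (`fit_three_step()`);
* **case-weight** — one weighted growth-model fit per class with the
  posterior probabilities as case weights (`fit_case_weight()`), sandwich
  standard errors by default.

Supporting machinery: a seedable generator for the two-phase model
(`generate_dataset()`), the weighted growth kernel (`fit_weighted_lgm()`,
EM and quasi-Newton), numerical observed-information and sandwich SEs
(`estimate_ses()`), recovery metrics with divisor-r formulas
(`absolute_relative_bias()`, `empirical_se()`, `se_ratio()`, `rmse()`),
BIC selection (`correct_selection()`), truth alignment
(`align_to_truth()`), and a simulation-study runner over the packaged
3 × 3 × 3 design (`run_study()`, `summarize_entropy()`).

## Worked example

```r
library(twophasemix)

cond  <- sim_condition(2000, 0.30, "high")   # n, smaller-class prop, separation
model <- build_true_model(cond)
ds    <- generate_dataset(model, n = 2000, seed = 42)

step1 <- fit_lca(ds, K = 2, seed = 7)
relative_entropy(step1$posteriors)
#> [1] 0.838

step1$fit
#> Fit: loglik -4349.4581, 9 params, BIC 8767.32, converged (ok)

os <- fit_one_step(ds, K = 2, seed = 7)
align_to_truth(os, model)
#> Two-phase fit (one_step): 2 classes, loglik -17562.032, BIC 35283.68, converged (ok)
#>   mixing proportions: 0.6926, 0.3074
#>   class 1:  mean_intercept=0.631, mean_slope=1.007, var_intercept=1.928, var_slope=0.417, cov_int_slope=0.494, resid_var=0.498
#>   class 2:  mean_intercept=0.317, mean_slope=1.786, var_intercept=1.392, var_slope=0.320, cov_int_slope=0.343, resid_var=0.713

cw <- fit_case_weight(ds, step1)
cw$artifacts$effective_n
#> [1] 1384.4  615.6
```

The one-step fit recovers the generating values (class-2 slope mean 1.8,
class-1 intercept variance 1.9, mixing proportion 0.30) to within sampling
error at this sample size; the case-weight effective class sizes are the
posterior column sums, close to n times the class proportions.  The relative
entropy of 0.84 says the four indicators classify subjects well but not
perfectly at this separation level.

A scaled-down simulation study over selected design cells:

```r
cfg <- study_config(conditions = study_condition_grid()[25:27],
                    reps_target = 20, compute_ses = FALSE)
out <- run_study(cfg)
out$selection_summary   # convergence and BIC-selection rates per method
out$recovery_summary    # bias / empirical SE / SE ratio / RMSE per class
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantities from
scratch by running the estimators on freshly generated data: the mean
fitted 2-class LCA entropy per class-separation level (100 replications for
each of the nine design cells per level), the Monte-Carlo means of one-step
estimates at n = 2000 / smaller-class proportion 0.30 / high separation
(100 replications, classes aligned to truth), and the percentage of
replications in which BIC picks the 2-class LCA at n = 2000 / proportion
0.05 / high separation.  Run it from the repository root against the
installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
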