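test_that("predictions at observation times match the trajectory and guard the ratio", {
  p <- coculture_params()
  init <- coculture_state(B = 3, D = 7)
  pr <- predict_at_times(p, init, times = 0)
  expect_equal(pr$B, 3)
  expect_equal(pr$D, 7)
  # logistic special case agrees with the closed form at the sampling days
  p2 <- update_params(p, lam = 0, nu_delta_D = 0)
  pr2 <- predict_at_times(p2, coculture_state(B = 0, D = 2e5),
                          times = c(7, 14, 21, 28))
  expect_equal(pr2$D,
               logistic_closed_form(2e5, p2$nu_mu_D, p2$CC_D, pr2$time),
               tolerance = 1e-6)
  # ratio against an extinct bacterial series is missing, with a warning
  expect_warning(
    pr3 <- predict_at_times(p2, coculture_state(B = 0, D = 2e5),
                            times = c(0, 7), include_ratio = TRUE),
    "denominator")
  expect_true(all(is.na(pr3$ratio)))
})

test_that("squared deviation: exact predictions give zero, hand cases check out", {
  truth <- ref_truth()
  syn <- generate_observations(truth, synthetic_design(noise_cv = 0, seed = 1))
  cfg <- fit_config()
  expect_lt(squared_deviation(syn$observations, truth$params, truth$init,
                              cfg, truth$options), 1e-10)
  # single observation, linear scale: (5 - 3)^2 = 4
  obs1 <- data.frame(time_days = 0, species = "B", replicate = 1L, value = 5)
  expect_equal(
    squared_deviation(obs1, truth$params, coculture_state(B = 3, D = 1),
                      fit_config(objective_scale = "linear")),
    4)
  # two replicates {10, 1000} vs prediction 100 on the log10 scale; the
  # 1-count offset makes it (log10(11)-log10(101))^2 + (log10(1001)-log10(101))^2
  obs2 <- data.frame(time_days = 0, species = "B", replicate = 1:2,
                     value = c(10, 1000))
  got <- squared_deviation(obs2, truth$params, coculture_state(B = 100, D = 1),
                           fit_config())
  want <- (log10(11) - log10(101))^2 + (log10(1001) - log10(101))^2
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, 2, tolerance = 0.05) # offset-free hand value, loosely
})

test_that("objective is invariant to record order and replicate relabeling", {
  truth <- ref_truth()
  syn <- generate_observations(truth, synthetic_design(noise_cv = 0.1, seed = 5))
  obs <- syn$observations
  cfg <- fit_config()
  v0 <- squared_deviation(obs, truth$params, truth$init, cfg)
  set.seed(1)
  shuf <- obs[sample(nrow(obs)), ]
  expect_equal(squared_deviation(shuf, truth$params, truth$init, cfg), v0)
  relab <- obs
  relab$replicate <- ((relab$replicate) %% 3L) + 1L
  expect_equal(squared_deviation(relab, truth$params, truth$init, cfg), v0)
})

test_that("goodness of fit: perfect and affine predictions, hand Pearson value", {
  obs <- c(1, 2, 3, 4, 5)
  expect_equal(goodness_of_fit(obs, obs)$R2, 1)
  expect_equal(goodness_of_fit(obs, c(2, 4, 6, 8, 10))$R2, 1)
  # brute-force Pearson for observed = (1,2,3), predicted = (1,2,4)
  o <- c(1, 2, 3); pr <- c(1, 2, 4)
  r_hand <- sum((o - mean(o)) * (pr - mean(pr))) /
    sqrt(sum((o - mean(o))^2) * sum((pr - mean(pr))^2))
  g <- goodness_of_fit(o, pr)
  expect_equal(g$R2, r_hand^2, tolerance = 1e-12)
  expect_equal(g$R2, 0.9643, tolerance = 1e-4)
  # p-value equals the explicit correlation t-test
  t_hand <- r_hand * sqrt(1) / sqrt(1 - r_hand^2)
  expect_equal(g$p_value, 2 * stats::pt(abs(t_hand), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # SS-based alternative differs and may legitimately be negative
  expect_equal(goodness_of_fit(o, pr, method = "ss")$R2,
               1 - sum((o - pr)^2) / sum((o - mean(o))^2))
  expect_lt(goodness_of_fit(o, c(10, -10, 10), method = "ss")$R2, 0)
  expect_error(goodness_of_fit(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(goodness_of_fit(c(1, 2), c(1, 2)), "3")
})

test_that("annealed simplex degenerates to plain Nelder-Mead on a quadratic", {
  fq <- function(x) sum((x - c(1.3, -0.7))^2) + 2
  res <- neldermead_sa(fq, c(0, 0), lower = -5, upper = 5,
                       control = list(T0 = 1e-14, restarts = 1L),
                       seed = 11)
  ref <- stats::optim(c(0, 0), fq, method = "Nelder-Mead",
                      control = list(reltol = 1e-12))
  expect_equal(res$par, c(1.3, -0.7), tolerance = 1e-4)
  expect_equal(res$par, ref$par, tolerance = 1e-3)
  expect_equal(res$value, 2, tolerance = 1e-8)
  expect_true(res$converged)
})

test_that("annealing escapes a local minimum that plain descent falls into", {
  # double well: local minimum near x = 1, global near x = -1
  fw <- function(x) (x[1]^2 - 1)^2 + 0.3 * x[1]
  res <- neldermead_sa(fw, c(0.95), lower = -2, upper = 2,
                       control = list(T0 = 1, steps_per_temp = 25L,
                                      restarts = 2L), seed = 4)
  expect_lt(res$par[1], 0)
})

test_that("fits are deterministic given the seed and respect bounds", {
  truth <- ref_truth()
  syn <- generate_observations(truth, synthetic_design(noise_cv = 0.05,
                                                       seed = 21))
  cfg <- light_cfg(c("nu_mu_B", "lam"))
  f1 <- fit_coculture(syn$observations, cfg, params = truth$params,
                      init = truth$init)
  f2 <- fit_coculture(syn$observations, cfg, params = truth$params,
                      init = truth$init)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective_value, f2$objective_value)
  expect_identical(f1$n_evaluations, f2$n_evaluations)
  # truth nu_mu_B = 2.5 outside the box [1, 2]: estimate pinned at a bound
  cfgb <- light_cfg("nu_mu_B", bounds = list(nu_mu_B = c(1, 2)))
  fb <- fit_coculture(syn$observations, cfgb, params = truth$params,
                      init = truth$init)
  est <- coef(fb)[["nu_mu_B"]]
  expect_gte(est, 1); expect_lte(est, 2)
  expect_true(fb$at_bound[["nu_mu_B"]])
  expect_false(fb$converged)
})

test_that("noise-free synthetic data are recovered to within 5 percent", {
  truth <- ref_truth()
  syn <- generate_observations(truth, synthetic_design(noise_cv = 0, seed = 2))
  cfg <- light_cfg(c("nu_mu_B", "lam", "K_DOME"))
  fit <- fit_coculture(syn$observations, cfg, params = truth$params,
                       init = truth$init)
  expect_lt(fit$objective_value, 1e-6)
  tv <- c(nu_mu_B = truth$params$nu_mu_B, lam = truth$params$lam,
          K_DOME = truth$params$K_DOME)
  expect_lt(max(abs(coef(fit) / tv - 1)), 0.05)
  g <- fit$gof
  expect_gt(g$R2[g$series == "B"], 0.999)
  expect_gt(g$R2[g$series == "D"], 0.999)
})

test_that("fit_coculture validates its inputs", {
  truth <- ref_truth()
  obs <- generate_observations(truth, synthetic_design(seed = 3))$observations
  expect_error(fit_config(free = "not_a_parameter"), "unknown")
  expect_error(fit_config(free = "lam", bounds = list(lam = c(2, 1))),
               "bounds")
  # more free parameters than data points
  tiny <- obs[1:2, ]
  expect_error(fit_coculture(tiny, fit_config(free = c("nu_mu_B", "lam",
                                                       "K_DOME"))),
               "free parameters")
})
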