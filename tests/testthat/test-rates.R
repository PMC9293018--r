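test_that("diatom logistic growth rate: zero density, capacity, half-capacity", {
  p <- coculture_params(nu_mu_D = 0.5)
  expect_equal(growth_rate_diatom(0, p), 0.5)
  expect_equal(growth_rate_diatom(p$CC_D, p), 0)
  expect_equal(growth_rate_diatom(p$CC_D / 2, p), 0.25)
  # overcapacity decline is permitted
  expect_lt(growth_rate_diatom(2 * p$CC_D, p), 0)
  expect_error(growth_rate_diatom(1e5, coculture_params(CC_D = 0)), "CC_D")
})

test_that("diatom death rate decreases with growth and rejects mu_D <= -1", {
  p <- coculture_params(nu_delta_D = 0.2)
  expect_equal(death_rate_diatom(0, p), 0.2)
  expect_equal(death_rate_diatom(1, p), 0.1)
  expect_equal(death_rate_diatom(3, coculture_params(nu_delta_D = 0.4)), 0.1)
  expect_error(death_rate_diatom(-1, p), "mu_D")
  mu <- seq(-0.9, 5, by = 0.1)
  expect_true(all(diff(death_rate_diatom(mu, p)) < 0))
})

test_that("bacterial growth fixed point solves mu(1+mu) = nu_mu_B * S", {
  p2 <- coculture_params(nu_mu_B = 2)
  expect_equal(growth_rate_bacterium(0, 0, p2),
               list(mu_B = 0, mu_B_E = 0, mu_B_B = 0))
  # saturated single pool: S -> 1, root of mu^2 + mu - 2 = 0 is 1
  g1 <- growth_rate_bacterium(1e14, 0, p2)
  expect_equal(g1$mu_B, 1, tolerance = 1e-6)
  expect_equal(g1$mu_B_B, 0)
  # both pools saturated: S -> 2, root (-1 + sqrt(17)) / 2, split evenly
  g2 <- growth_rate_bacterium(1e14, 1e14, p2)
  expect_equal(g2$mu_B, (-1 + sqrt(17)) / 2, tolerance = 1e-6)
  expect_equal(g2$mu_B_E, g2$mu_B / 2, tolerance = 1e-6)
  expect_equal(g2$mu_B_B, g2$mu_B / 2, tolerance = 1e-6)
  # against the independent bisection oracle on exact Monod fractions
  S <- 1e14 / (1e14 + p2$K_DOME) + 1e14 / (1e14 + p2$K_DOMB)
  expect_equal(g2$mu_B, mu_B_bisect(2, S), tolerance = 1e-12)
})

test_that("fixed-point residual vanishes over random draws and mu_B is monotone", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_params()
    E <- 10^stats::runif(1, 0, 9); M <- 10^stats::runif(1, 0, 9)
    g <- growth_rate_bacterium(E, M, p)
    S <- E / (E + p$K_DOME) + M / (M + p$K_DOMB)
    expect_lt(abs(g$mu_B * (1 + g$mu_B) - p$nu_mu_B * S), 1e-10)
    expect_equal(g$mu_B, g$mu_B_E + g$mu_B_B, tolerance = 1e-12)
  }
  p <- coculture_params()
  E <- 10^seq(2, 9, by = 0.5)
  muE <- vapply(E, function(e) growth_rate_bacterium(e, 1e5, p)$mu_B, 0)
  muM <- vapply(E, function(m) growth_rate_bacterium(1e5, m, p)$mu_B, 0)
  expect_true(all(diff(muE) > 0))
  expect_true(all(diff(muM) > 0))
})

test_that("explicit (no self-term) resolution returns nu_mu_B * S", {
  p <- coculture_params(nu_mu_B = 2)
  o <- coculture_options(mu_B_resolution = "explicit_no_self_term")
  g <- growth_rate_bacterium(1e14, 1e14, p, o)
  expect_equal(g$mu_B, 2 * (1e14 / (1e14 + p$K_DOME) +
                            1e14 / (1e14 + p$K_DOMB)), tolerance = 1e-12)
  # explicit rate exceeds the self-saturated one whenever S > 0
  gq <- growth_rate_bacterium(1e6, 1e6, p)
  ge <- growth_rate_bacterium(1e6, 1e6, p, o)
  expect_gt(ge$mu_B, gq$mu_B)
})

test_that("bacterial death rate halves per unit growth and is nonincreasing", {
  p <- coculture_params(nu_delta_B = 0.3)
  expect_equal(death_rate_bacterium(0, p), 0.3)
  expect_equal(death_rate_bacterium(1, p), 0.15)
  expect_equal(death_rate_bacterium(0.5, coculture_params(nu_delta_B = 0.12)),
               0.08)
  mu <- seq(0, 5, by = 0.25)
  expect_true(all(diff(death_rate_bacterium(mu, p)) < 0))
})

test_that("parameter validation rejects negatives and CC_B warns", {
  expect_error(coculture_params(lam = -0.1), "lam")
  expect_error(coculture_params(K_DOME = 0), "K_DOME")
  expect_warning(coculture_params(CC_B = 5e8), "CC_B")
  p <- coculture_params()
  expect_error(update_params(p, nonsense = 1), "unknown")
  expect_equal(update_params(p, lam = 0)$lam, 0)
})
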