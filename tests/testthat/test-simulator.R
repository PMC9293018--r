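test_that("a single-point grid returns the initial state unchanged", {
  init <- coculture_state(B = 1e5, D = 2e5, DOM_E = 7, DOM_B = 3)
  tr <- integrate_coculture(coculture_params(), init, times = 0)
  expect_equal(nrow(tr), 1L)
  expect_equal(unlist(tr[1, c("B", "D", "DOM_E", "DOM_B")]),
               unclass(init), ignore_attr = TRUE)
})

test_that("bacterium-only decay matches the exponential closed form", {
  p <- coculture_params()
  tr <- integrate_coculture(p, coculture_state(B = 1e5, D = 0),
                            times = c(0, 7, 14, 21, 28))
  expect_equal(tr$B, exp_decay_closed_form(1e5, p$nu_delta_B, tr$time),
               tolerance = 1e-6)
  expect_equal(tr$D, rep(0, 5))
})

test_that("diatom-only growth matches the Verhulst closed form", {
  p <- update_params(coculture_params(), lam = 0, nu_delta_D = 0)
  tr <- integrate_coculture(p, coculture_state(B = 0, D = 2e5),
                            times = c(0, 7, 14, 21, 28))
  expect_equal(tr$D,
               logistic_closed_form(2e5, p$nu_mu_D, p$CC_D, tr$time),
               tolerance = 1e-6)
})

test_that("adaptive integrator agrees with an independent fixed-step RK4", {
  p <- coculture_params()
  init <- coculture_state(DOM_E = 1e5)
  times <- c(0, 3, 7, 14)
  tr <- integrate_coculture(p, init, times)
  ref <- rk4_reference(p, init, times, dt = 0.01)
  for (v in c("B", "D", "DOM_E", "DOM_B"))
    expect_equal(tr[[v]], unname(ref[, v]), tolerance = 1e-6)
})

test_that("tightening tolerances changes the day-28 state by < 1e-5 relative", {
  p <- coculture_params()
  a <- integrate_coculture(p, coculture_state(), rtol = 1e-8, atol = 1e-10)
  b <- integrate_coculture(p, coculture_state(), rtol = 1e-10, atol = 1e-12)
  ya <- unlist(a[nrow(a), -1]); yb <- unlist(b[nrow(b), -1])
  expect_lt(max(abs(ya - yb) / pmax(abs(yb), 1)), 1e-5)
})

test_that("cumulative DOM production minus consumption balances the pools", {
  # split mode, no washout: integral of (lam + delta_D) * D minus integral
  # of mu_B * B must equal the net change of DOM_E + DOM_B (trapezoid
  # quadrature on a fine grid).
  p <- coculture_params(delta_DOME = 0, delta_DOMB = 0)
  times <- seq(0, 28, by = 0.1)
  tr <- integrate_coculture(p, coculture_state(), times)
  rates <- lapply(seq_len(nrow(tr)), function(i)
    coculture_rates(c(B = tr$B[i], D = tr$D[i],
                      DOM_E = tr$DOM_E[i], DOM_B = tr$DOM_B[i]), p))
  prod <- (p$lam + vapply(rates, `[[`, 0, "delta_D")) * tr$D
  cons <- vapply(rates, `[[`, 0, "mu_B") * tr$B
  trapz <- function(y) sum(diff(times) * (head(y, -1) + tail(y, -1)) / 2)
  lhs <- trapz(prod) - trapz(cons)
  rhs <- (tr$DOM_E + tr$DOM_B)[nrow(tr)] - (tr$DOM_E + tr$DOM_B)[1]
  expect_equal(lhs, rhs, tolerance = 1e-4)
})

test_that("exudation sweep: identity level reproduces baseline, zero lambda starves B", {
  p <- coculture_params()
  sw <- sweep_exudation(p, fractions = 1, horizon = 28)
  base <- integrate_coculture(p, coculture_state(), 0:28)
  expect_equal(attr(sw, "trajectories")[[1]]$B, base$B, tolerance = 1e-10)
  # lam = 0 and no diatom death: no DOM source, B declines monotonically
  p0 <- update_params(p, nu_delta_D = 0)
  sw0 <- sweep_exudation(p0, fractions = 0, horizon = 28)
  B0 <- attr(sw0, "trajectories")[[1]]$B
  expect_true(all(diff(B0) < 0))
  expect_warning(sweep_exudation(p, fractions = c(1, 1.5), horizon = 7),
                 "extrapolate")
})

test_that("final bacterial density is nondecreasing in the exudation fraction", {
  sw <- sweep_exudation(coculture_params(),
                        fractions = c(0, 0.25, 0.5, 0.75, 1), horizon = 100)
  expect_true(all(diff(sw$final_B) >= 0))
  expect_lte(sw$final_B[1], sw$final_B[5])
})

test_that("initial-DOM sweep shortens the bacterial lag and handles no-growth", {
  p <- coculture_params()
  init <- coculture_state(DOM_E = 1e5, DOM_B = 1e5)
  sw <- sweep_initial_dom(p, init, multipliers = c(1, 5), horizon = 28)
  expect_equal(attr(sw, "trajectories")[[1]]$B[1], 1e5)
  expect_lte(sw$lag_days[2], sw$lag_days[1])
  # no carbon at all: B never doubles, lag reported as missing
  p0 <- update_params(p, lam = 0, nu_delta_D = 0)
  sw0 <- sweep_initial_dom(p0, coculture_state(), multipliers = 0,
                           horizon = 28)
  expect_true(is.na(sw0$lag_days[1]))
})

test_that("generic parameter sweep covers the diatom death rate", {
  sw <- sweep_parameter(coculture_params(), "nu_delta_D",
                        fractions = c(0, 1), horizon = 28)
  expect_equal(nrow(sw), 2L)
  expect_true(all(is.finite(sw$final_B)))
})
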