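#' Realized diatom growth rate (Verhulst)
#'
#' Generalized logistic growth: `mu_D = nu_mu_D * (1 - D / CC_D)`. The rate
#' is maximal at vanishing density, zero at carrying capacity, and negative
#' above it (overcapacity decline).
#'
#' @param D Diatom concentration, cells ml^-1 (vectorized).
#' @param params A [coculture_params()] object.
#' @return Growth rate(s), day^-1.
#' @examples
#' p <- coculture_params(nu_mu_D = 0.5)
#' growth_rate_diatom(c(0, p$CC_D / 2, p$CC_D), p)
#' @export
growth_rate_diatom <- function(D, params) {
  stopifnot(all(D >= 0))
  if (params$CC_D <= 0) stop("CC_D must be > 0", call. = FALSE)
  params$nu_mu_D * (1 - D / params$CC_D)
}

#' Realized diatom death rate
#'
#' Death slows when the population grows: `delta_D = nu_delta_D / (1 + mu_D)`,
#' strictly decreasing in the realized growth rate.
#'
#' @param mu_D Realized diatom growth rate, day^-1 (vectorized); must exceed
#'   -1 so the denominator stays positive.
#' @param params A [coculture_params()] object.
#' @return Death rate(s), day^-1.
#' @examples
#' death_rate_diatom(c(0, 1), coculture_params(nu_delta_D = 0.2))
#' @export
death_rate_diatom <- function(mu_D, params) {
  if (any(mu_D <= -1))
    stop("death_rate_diatom: mu_D must be > -1", call. = FALSE)
  params$nu_delta_D / (1 + mu_D)
}

#' Realized bacterial growth rate on the two DOM pools
#'
#' Monod-limited growth on the exudate and dead-biomass pools with a
#' self-saturating factor: writing
#' `S = DOM_E/(DOM_E + K_DOME) + DOM_B/(DOM_B + K_DOMB)`, the growth law is
#' `mu_B = nu_mu_B * S / (1 + mu_B)`, in which the realized rate appears on
#' both sides. Under the default `quadratic_fixed_point` resolution the
#' unique nonnegative fixed point is returned,
#' `mu_B = (-1 + sqrt(1 + 4 * nu_mu_B * S)) / 2`; under
#' `explicit_no_self_term` the self-saturation factor is dropped and
#' `mu_B = nu_mu_B * S`. The total is split into per-pool components
#' proportionally to each pool's Monod fraction.
#'
#' @param DOM_E,DOM_B Nonnegative pool concentrations (scalars).
#' @param params A [coculture_params()] object.
#' @param options A [coculture_options()] object.
#' @return A list with components `mu_B`, `mu_B_E`, `mu_B_B` (day^-1),
#'   satisfying `mu_B = mu_B_E + mu_B_B`.
#' @examples
#' p <- coculture_params(nu_mu_B = 2)
#' growth_rate_bacterium(1e12, 0, p)$mu_B # saturated single pool: S = 1
#' @export
growth_rate_bacterium <- function(DOM_E, DOM_B, params,
                                  options = coculture_options()) {
  stopifnot(DOM_E >= 0, DOM_B >= 0)
  S_E <- if (DOM_E > 0) DOM_E / (DOM_E + params$K_DOME) else 0
  S_B <- if (DOM_B > 0) DOM_B / (DOM_B + params$K_DOMB) else 0
  S <- S_E + S_B
  if (S == 0) return(list(mu_B = 0, mu_B_E = 0, mu_B_B = 0))
  mu_B <- if (options$mu_B_resolution == "quadratic_fixed_point") {
    (-1 + sqrt(1 + 4 * params$nu_mu_B * S)) / 2
  } else {
    params$nu_mu_B * S
  }
  list(mu_B = mu_B, mu_B_E = mu_B * S_E / S, mu_B_B = mu_B * S_B / S)
}

#' Realized bacterial death rate
#'
#' `delta_B = nu_delta_B / (1 + mu_B)`: starvation-level death at zero
#' growth, reduced when substrate supports growth.
#'
#' @param mu_B Realized bacterial growth rate, day^-1 (vectorized, >= 0).
#' @param params A [coculture_params()] object.
#' @return Death rate(s), day^-1.
#' @examples
#' death_rate_bacterium(c(0, 1), coculture_params(nu_delta_B = 0.3))
#' @export
death_rate_bacterium <- function(mu_B, params) {
  stopifnot(all(mu_B >= 0))
  params$nu_delta_B / (1 + mu_B)
}

#' All state-dependent rates at one system state
#'
#' Evaluates the four rate laws at a given state and returns the complete
#' rate set, including the per-pool components of bacterial growth.
#'
#' @param state A [coculture_state()] object (or named numeric vector with
#'   elements B, D, DOM_E, DOM_B).
#' @param params A [coculture_params()] object.
#' @param options A [coculture_options()] object.
#' @return A list with elements `mu_D`, `delta_D`, `mu_B`, `mu_B_E`,
#'   `mu_B_B`, `delta_B` (all day^-1).
#' @export
coculture_rates <- function(state, params, options = coculture_options()) {
  s <- pmax(as.numeric(state), 0)
  names(s) <- names(state)
  mu_D <- growth_rate_diatom(s[["D"]], params)
  gb <- growth_rate_bacterium(s[["DOM_E"]], s[["DOM_B"]], params, options)
  # guarded denominator, matching the compiled RHS: far above carrying
  # capacity mu_D drops below -1 and the strict death law leaves its domain
  list(mu_D = mu_D,
       delta_D = params$nu_delta_D / max(1 + mu_D, 1e-12),
       mu_B = gb$mu_B, mu_B_E = gb$mu_B_E, mu_B_B = gb$mu_B_B,
       delta_B = death_rate_bacterium(gb$mu_B, params))
}

#' Right-hand side of the co-culture ODE system
#'
#' Time derivatives of the four state variables:
#' \describe{
#'   \item{dB/dt}{`(mu_B - delta_B) * B` -- Monod-limited growth minus
#'     growth-dependent death. The DOM dependence of `mu_B` lives inside the
#'     Monod fractions of [growth_rate_bacterium()].}
#'   \item{dD/dt}{`(mu_D - delta_D - lam) * D` -- logistic growth minus death
#'     minus the exudation cost (the `-lam * D` term is dropped when
#'     `options$exudation_costs_biomass` is `FALSE`).}
#'   \item{dDOM_E/dt}{`lam * D - c_E * B / yield - delta_DOME * DOM_E`}
#'   \item{dDOM_B/dt}{`delta_D * D - c_B * B / yield - delta_DOMB * DOM_B`}
#' }
#' where in `split` consumption mode `c_E = mu_B_E`, `c_B = mu_B_B` (uptake
#' apportioned by Monod fraction, mass-conserving) and in `literal` mode
#' `c_E = c_B = mu_B`. Negative state components are clamped to zero before
#' rate evaluation (adaptive-stepper overshoot guard).
#'
#' @param t Time, days (unused: the system is autonomous; kept for the
#'   standard `f(t, y)` signature).
#' @param state Named numeric vector (B, D, DOM_E, DOM_B).
#' @param params A [coculture_params()] object.
#' @param options A [coculture_options()] object.
#' @return Named numeric vector of derivatives `(B, D, DOM_E, DOM_B)`.
#' @examples
#' ode_rhs(0, coculture_state(), coculture_params())
#' @export
ode_rhs <- function(t, state, params, options = coculture_options()) {
  if (any(!is.finite(state)))
    stop("non-finite state at t = ", t, call. = FALSE)
  s <- pmax(as.numeric(state), 0)
  names(s) <- c("B", "D", "DOM_E", "DOM_B")
  r <- coculture_rates(s, params, options)
  cons <- if (options$consumption_mode == "split") {
    c(E = r$mu_B_E, B = r$mu_B_B)
  } else {
    c(E = r$mu_B, B = r$mu_B)
  }
  exu <- if (options$exudation_costs_biomass) params$lam else 0
  c(B = (r$mu_B - r$delta_B) * s[["B"]],
    D = (r$mu_D - r$delta_D - exu) * s[["D"]],
    DOM_E = params$lam * s[["D"]] - cons[["E"]] * s[["B"]] / params$yield -
      params$delta_DOME * s[["DOM_E"]],
    DOM_B = r$delta_D * s[["D"]] - cons[["B"]] * s[["B"]] / params$yield -
      params$delta_DOMB * s[["DOM_B"]])
}
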