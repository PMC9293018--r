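#' Model parameters for the diatom-bacterium co-culture model
#'
#' Rate constants, carrying capacities and Monod half-saturation constants of
#' the four-variable co-culture model. All rates are first-order in units of
#' day^-1; cell densities in cells ml^-1; the two dissolved-organic-matter
#' (DOM) pools are denominated in bacterial cell equivalents ml^-1, i.e. one
#' DOM unit converts to one bacterial cell at the default yield.
#'
#' The defaults are the package's reference parameterization used by the
#' synthetic-data generator. They were chosen once to reproduce the
#' qualitative shape of the experimental co-culture (a diatom rising
#' near-linearly to ~1e7 cells ml^-1 over 28 days, a bacterial lag of about
#' two weeks followed by growth of 2-3 orders of magnitude). They are a
#' synthetic stand-in, NOT fitted values from any experiment.
#'
#' @param nu_mu_D Maximal diatom growth rate (day^-1).
#' @param nu_delta_D Maximal diatom death rate (day^-1).
#' @param nu_mu_B Maximal bacterial growth rate (day^-1).
#' @param nu_delta_B Maximal bacterial death rate (day^-1).
#' @param lam Exudation rate lambda: first-order rate at which living diatom
#'   cells release photosynthates into the exudate DOM pool (day^-1).
#' @param CC_D Diatom carrying capacity (cells ml^-1).
#' @param CC_B Bacterial carrying capacity (cells ml^-1). Accepted for
#'   completeness but unused by the rate laws; a warning is emitted when a
#'   non-default value is supplied.
#' @param K_DOME Monod half-saturation constant of the exudate pool.
#' @param K_DOMB Monod half-saturation constant of the dead-biomass pool.
#' @param delta_DOME Washout/loss rate of unused exudate DOM (day^-1).
#' @param delta_DOMB Washout/loss rate of unused dead-biomass DOM (day^-1).
#' @param yield DOM-to-cell conversion: bacterial cells produced per DOM unit
#'   consumed. Default 1 (DOM measured in cell equivalents).
#'
#' @return An object of class `coculture_params`: a named list of validated
#'   numeric scalars.
#' @seealso [coculture_state()], [coculture_options()], [integrate_coculture()]
#' @examples
#' p <- coculture_params(lam = 0.02)
#' p$lam
#' @export
coculture_params <- function(nu_mu_D = 0.25, nu_delta_D = 0.05,
                             nu_mu_B = 2.5, nu_delta_B = 0.2,
                             lam = 0.05, CC_D = 2e7, CC_B = 1e9,
                             K_DOME = 1.5e6, K_DOMB = 1.5e6,
                             delta_DOME = 0.01, delta_DOMB = 0.01,
                             yield = 1) {
  p <- list(nu_mu_D = nu_mu_D, nu_delta_D = nu_delta_D,
            nu_mu_B = nu_mu_B, nu_delta_B = nu_delta_B,
            lam = lam, CC_D = CC_D, CC_B = CC_B,
            K_DOME = K_DOME, K_DOMB = K_DOMB,
            delta_DOME = delta_DOME, delta_DOMB = delta_DOMB,
            yield = yield)
  validate_coculture_params(p)
  if (!missing(CC_B) && CC_B != 1e9) {
    warning("CC_B is accepted but does not affect the dynamics: ",
            "no bacterial logistic term appears in the rate laws",
            call. = FALSE)
  }
  structure(p, class = "coculture_params")
}

validate_coculture_params <- function(p) {
  fields <- c("nu_mu_D", "nu_delta_D", "nu_mu_B", "nu_delta_B", "lam",
              "CC_D", "CC_B", "K_DOME", "K_DOMB", "delta_DOME",
              "delta_DOMB", "yield")
  missing_f <- setdiff(fields, names(p))
  if (length(missing_f))
    stop("missing parameter field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a finite numeric scalar",
           call. = FALSE)
    if (v < 0)
      stop("parameter '", f, "' must be >= 0 (got ", v, ")", call. = FALSE)
  }
  if (p$CC_D <= 0) stop("CC_D must be > 0", call. = FALSE)
  if (p$K_DOME <= 0) stop("K_DOME must be > 0", call. = FALSE)
  if (p$K_DOMB <= 0) stop("K_DOMB must be > 0", call. = FALSE)
  if (p$yield <= 0) stop("yield must be > 0", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced; validation is
#' re-run on the result.
#'
#' @param params A [coculture_params()] object.
#' @param ... Named replacement values, e.g. `lam = 0`.
#' @return A `coculture_params` object.
#' @examples
#' p0 <- coculture_params()
#' p1 <- update_params(p0, lam = 0, nu_delta_D = 0)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "coculture_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params[names(repl)] <- repl
  p <- unclass(params)
  validate_coculture_params(p)
  structure(p, class = "coculture_params")
}

#' @export
print.coculture_params <- function(x, ...) {
  cat("Co-culture model parameters (rates day^-1, densities ml^-1):\n")
  v <- unlist(x)
  print(signif(v, 4))
  invisible(x)
}

#' System state of the co-culture model
#'
#' One point of the four-variable state: bacterial concentration `B`
#' (CFU ml^-1), diatom concentration `D` (cells ml^-1), and the exudate
#' (`DOM_E`) and dead-biomass (`DOM_B`) dissolved-organic-matter pools
#' (cell equivalents ml^-1). Defaults are the co-culture inoculation
#' densities (1e5 CFU ml^-1 bacterium, 2e5 cells ml^-1 diatom) with no
#' initial DOM.
#'
#' @param B,D,DOM_E,DOM_B Nonnegative numeric scalars.
#' @return An object of class `coculture_state` (a named numeric vector).
#' @examples
#' coculture_state(DOM_E = 1e6)
#' @export
coculture_state <- function(B = 1e5, D = 2e5, DOM_E = 0, DOM_B = 0) {
  s <- c(B = B, D = D, DOM_E = DOM_E, DOM_B = DOM_B)
  validate_coculture_state(s)
  structure(s, class = "coculture_state")
}

validate_coculture_state <- function(s) {
  nm <- c("B", "D", "DOM_E", "DOM_B")
  if (!is.numeric(s) || length(s) != 4L || !identical(names(s), nm))
    stop("state must be a numeric vector with names B, D, DOM_E, DOM_B",
         call. = FALSE)
  if (any(!is.finite(s))) stop("state must be finite", call. = FALSE)
  if (any(s < 0)) stop("state components must be >= 0", call. = FALSE)
  invisible(s)
}

#' @export
print.coculture_state <- function(x, ...) {
  cat("Co-culture state (cells ml^-1 / DOM cell-equivalents ml^-1):\n")
  print(signif(unclass(x), 4))
  invisible(x)
}

#' Structural options of the co-culture model
#'
#' Resolves the structural ambiguities of the model and toggles
#' the exudation cost term:
#'
#' * `consumption_mode`: how bacterial DOM consumption is apportioned between
#'   the two pools. `"split"` (default) divides the total uptake flux
#'   `mu_B * B` between exudate and dead-biomass pools proportionally to
#'   their Monod fractions, conserving mass. `"literal"` subtracts the full
#'   `mu_B * B` from each pool as the equations print it, which double-counts
#'   uptake and can drive an empty pool negative; it is retained for fidelity
#'   checks only.
#' * `mu_B_resolution`: the bacterial growth law is self-referential (the
#'   realized rate appears inside its own saturation factor).
#'   `"quadratic_fixed_point"` (default) solves the fixed point exactly as
#'   the nonnegative root of `mu_B * (1 + mu_B) = nu_mu_B * S`;
#'   `"explicit_no_self_term"` drops the `1/(1 + mu_B)` factor and returns
#'   `nu_mu_B * S`.
#' * `exudation_costs_biomass`: whether exudation depletes the diatom cell
#'   count (the `-lam * D` term in the diatom equation). Default `TRUE`.
#'
#' @param consumption_mode `"split"` or `"literal"`.
#' @param exudation_costs_biomass Logical.
#' @param mu_B_resolution `"quadratic_fixed_point"` or
#'   `"explicit_no_self_term"`.
#' @return An object of class `coculture_options`.
#' @examples
#' coculture_options(consumption_mode = "literal")
#' @export
coculture_options <- function(consumption_mode = c("split", "literal"),
                              exudation_costs_biomass = TRUE,
                              mu_B_resolution = c("quadratic_fixed_point",
                                                  "explicit_no_self_term")) {
  consumption_mode <- match.arg(consumption_mode)
  mu_B_resolution <- match.arg(mu_B_resolution)
  stopifnot(is.logical(exudation_costs_biomass),
            length(exudation_costs_biomass) == 1L,
            !is.na(exudation_costs_biomass))
  structure(list(consumption_mode = consumption_mode,
                 exudation_costs_biomass = exudation_costs_biomass,
                 mu_B_resolution = mu_B_resolution),
            class = "coculture_options")
}

#' @export
print.coculture_options <- function(x, ...) {
  cat("Co-culture model options:\n")
  cat("  consumption_mode:        ", x$consumption_mode, "\n")
  cat("  exudation_costs_biomass: ", x$exudation_costs_biomass, "\n")
  cat("  mu_B_resolution:         ", x$mu_B_resolution, "\n")
  invisible(x)
}

# Flatten params/options into the fixed vectors the compiled RHS expects.
.cc_par_vec <- function(params) {
  c(params$nu_mu_D, params$nu_delta_D, params$nu_mu_B, params$nu_delta_B,
    params$lam, params$CC_D, params$K_DOME, params$K_DOMB,
    params$delta_DOME, params$delta_DOMB, params$yield)
}

.cc_opt_vec <- function(options) {
  as.integer(c(options$consumption_mode == "split",
               options$exudation_costs_biomass,
               options$mu_B_resolution == "quadratic_fixed_point"))
}
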