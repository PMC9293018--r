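#' Integrate the co-culture ODE system
#'
#' Solves the four-variable system with an adaptive Dormand-Prince
#' Runge-Kutta 4(5) scheme (compiled), reporting the state on the requested
#' time grid. Steps land exactly on each grid point, so no interpolation
#' error enters the reported states.
#'
#' @param params A [coculture_params()] object.
#' @param init A [coculture_state()] object: the day-0 state.
#' @param times Numeric grid of output times in days, starting at 0 and
#'   strictly increasing. Default: daily grid over the 28-day experiment.
#' @param options A [coculture_options()] object.
#' @param rtol,atol Relative and absolute local-error tolerances of the
#'   embedded 4(5) error estimate.
#' @return An object of class `coculture_trajectory`: a data frame with
#'   columns `time`, `B`, `D`, `DOM_E`, `DOM_B` and attributes `params` and
#'   `options` recording the inputs.
#' @examples
#' tr <- integrate_coculture(coculture_params(), coculture_state())
#' tail(tr, 2)
#' @export
integrate_coculture <- function(params, init = coculture_state(),
                                times = 0:28,
                                options = coculture_options(),
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "coculture_params"))
  validate_coculture_state(structure(as.numeric(init),
                                     names = c("B", "D", "DOM_E", "DOM_B")))
  if (length(times) < 1L || times[1] != 0 ||
      (length(times) > 1L && any(diff(times) <= 0)))
    stop("times must start at 0 and be strictly increasing", call. = FALSE)
  y <- .cc_integrate_cpp(as.numeric(times), as.numeric(init),
                         .cc_par_vec(params), .cc_opt_vec(options),
                         rtol, atol)
  out <- data.frame(time = as.numeric(times),
                    B = y[, 1], D = y[, 2], DOM_E = y[, 3], DOM_B = y[, 4])
  structure(out, class = c("coculture_trajectory", "data.frame"),
            params = params, options = options, init = init)
}

#' @export
print.coculture_trajectory <- function(x, ...) {
  cat("Co-culture trajectory:", nrow(x), "time points over",
      max(x$time), "days\n")
  n <- nrow(x)
  show <- unique(c(1L, seq(1L, n, length.out = min(n, 6L))))
  print.data.frame(signif(x[round(show), , drop = FALSE], 4),
                   row.names = FALSE)
  invisible(x)
}

#' @param x A `coculture_trajectory`.
#' @param log Axis log specification passed to [graphics::matplot()];
#'   default `"y"` since counts span several decades.
#' @param ... Further graphical parameters.
#' @rdname integrate_coculture
#' @export
plot.coculture_trajectory <- function(x, log = "y", ...) {
  cols <- c(B = "firebrick", D = "forestgreen",
            DOM_E = "steelblue", DOM_B = "tan4")
  y <- as.matrix(x[, c("B", "D", "DOM_E", "DOM_B")])
  if (grepl("y", log)) y[y <= 0] <- NA
  graphics::matplot(x$time, y, type = "l", lty = 1, col = cols, log = log,
                    xlab = "time (days)",
                    ylab = "cells or DOM cell-equivalents ml^-1", ...)
  graphics::legend("bottomright", legend = names(cols), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Sweep the exudation rate
#'
#' Re-runs the simulation with the exudation rate `lam` set to each given
#' fraction of its baseline value, all other parameters fixed, over a long
#' horizon (default 100 days, long enough to approach steady state). Used to
#' probe how strongly the bacterium depends on actively released
#' photosynthates versus dead-biomass DOM.
#'
#' @param base_params Baseline [coculture_params()].
#' @param init A [coculture_state()].
#' @param fractions Multipliers of the baseline `lam`, each in `[0, 1]`
#'   (values above 1 are permitted with a warning).
#' @param horizon Simulation horizon, days.
#' @param options,rtol,atol Passed to [integrate_coculture()].
#' @return An object of class `coculture_sweep`: a data frame with one row
#'   per level (columns `level`, `lam`, `final_B`, `final_D`) and the full
#'   trajectories in `attr(, "trajectories")`.
#' @examples
#' sw <- sweep_exudation(coculture_params(), fractions = c(0, 1),
#'                       horizon = 30)
#' sw$final_B
#' @export
sweep_exudation <- function(base_params, init = coculture_state(),
                            fractions = c(0, 0.25, 0.5, 0.75, 1),
                            horizon = 100,
                            options = coculture_options(),
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(fractions) >= 1L, all(fractions >= 0), horizon > 0)
  if (any(fractions > 1))
    warning("fractions > 1 extrapolate beyond the baseline exudation rate",
            call. = FALSE)
  times <- seq(0, horizon, by = min(1, horizon))
  trajs <- lapply(fractions, function(f) {
    integrate_coculture(update_params(base_params, lam = f * base_params$lam),
                        init, times, options, rtol, atol)
  })
  out <- data.frame(level = fractions,
                    lam = fractions * base_params$lam,
                    final_B = vapply(trajs, function(tr) tr$B[nrow(tr)], 0),
                    final_D = vapply(trajs, function(tr) tr$D[nrow(tr)], 0))
  structure(out, class = c("coculture_sweep", "data.frame"),
            swept = "lam", trajectories = trajs)
}

#' Sweep the initial DOM concentration
#'
#' Scales the initial exudate and dead-biomass pools by each multiplier and
#' reports the bacterial lag time, operationalized as the first grid time at
#' which the bacterial count exceeds `lag_threshold` times its inoculum.
#' Probes whether a head start of dissolved carbon shortens the long
#' bacterial lag observed in co-culture.
#'
#' @param base_params Baseline [coculture_params()].
#' @param init A [coculture_state()]; its `DOM_E` and `DOM_B` components are
#'   multiplied by each level.
#' @param multipliers Nonnegative multipliers of the initial DOM pools.
#' @param horizon Simulation horizon, days.
#' @param lag_threshold Fold increase of B over its inoculum defining the
#'   end of the lag phase (default 2).
#' @param options,rtol,atol Passed to [integrate_coculture()].
#' @return A `coculture_sweep` data frame with columns `level`, `lag_days`
#'   (`NA` when B never crosses the threshold), `final_B`, `final_D`, and
#'   trajectories in `attr(, "trajectories")`.
#' @examples
#' p <- coculture_params()
#' s0 <- coculture_state(DOM_E = 1e6)
#' sw <- sweep_initial_dom(p, s0, multipliers = c(1, 5), horizon = 28)
#' sw$lag_days
#' @export
sweep_initial_dom <- function(base_params, init = coculture_state(),
                              multipliers = 1:5, horizon = 28,
                              lag_threshold = 2,
                              options = coculture_options(),
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(multipliers) >= 1L, all(multipliers >= 0), horizon > 0,
            lag_threshold > 1)
  times <- seq(0, horizon, by = min(1, horizon))
  trajs <- lapply(multipliers, function(m) {
    s <- coculture_state(B = init[["B"]], D = init[["D"]],
                         DOM_E = m * init[["DOM_E"]],
                         DOM_B = m * init[["DOM_B"]])
    integrate_coculture(base_params, s, times, options, rtol, atol)
  })
  lag <- vapply(trajs, function(tr) {
    i <- which(tr$B >= lag_threshold * tr$B[1])
    if (length(i)) tr$time[min(i)] else NA_real_
  }, 0)
  out <- data.frame(level = multipliers, lag_days = lag,
                    final_B = vapply(trajs, function(tr) tr$B[nrow(tr)], 0),
                    final_D = vapply(trajs, function(tr) tr$D[nrow(tr)], 0))
  structure(out, class = c("coculture_sweep", "data.frame"),
            swept = "initial_DOM_scale", trajectories = trajs)
}

#' Sweep an arbitrary rate parameter
#'
#' Generalization of [sweep_exudation()] to any single rate constant
#' (e.g. `nu_delta_D`, whose sweep probes the role of dead-biomass DOM).
#'
#' @param base_params Baseline [coculture_params()].
#' @param symbol Name of the parameter field to sweep.
#' @param init,fractions,horizon,options,rtol,atol As in [sweep_exudation()].
#' @return A `coculture_sweep` data frame.
#' @export
sweep_parameter <- function(base_params, symbol,
                            init = coculture_state(),
                            fractions = c(0, 0.25, 0.5, 0.75, 1),
                            horizon = 100,
                            options = coculture_options(),
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(symbol %in% names(base_params), all(fractions >= 0), horizon > 0)
  times <- seq(0, horizon, by = min(1, horizon))
  base_val <- base_params[[symbol]]
  trajs <- lapply(fractions, function(f) {
    p <- base_params
    p[[symbol]] <- f * base_val
    p <- structure(unclass(p), class = "coculture_params")
    validate_coculture_params(p)
    integrate_coculture(p, init, times, options, rtol, atol)
  })
  out <- data.frame(level = fractions,
                    value = fractions * base_val,
                    final_B = vapply(trajs, function(tr) tr$B[nrow(tr)], 0),
                    final_D = vapply(trajs, function(tr) tr$D[nrow(tr)], 0))
  structure(out, class = c("coculture_sweep", "data.frame"),
            swept = symbol, trajectories = trajs)
}

#' @export
print.coculture_sweep <- function(x, ...) {
  cat("Parameter sweep over", attr(x, "swept"), "(",
      nrow(x), "levels )\n")
  print.data.frame(signif(as.data.frame(x), 4), row.names = FALSE)
  invisible(x)
}
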