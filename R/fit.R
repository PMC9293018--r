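# Parameter names the fitting engine may free. Initial DOM pools are
# addressed as DOM_E0 / DOM_B0 (the day-0 state, not a rate constant).
.fittable_rates <- c("nu_mu_D", "nu_delta_D", "nu_mu_B", "nu_delta_B",
                     "lam", "delta_DOME", "delta_DOMB")
.fittable_pools <- c("CC_D", "K_DOME", "K_DOMB", "DOM_E0", "DOM_B0")

#' Fit configuration
#'
#' Collects the choices of the parameter-estimation engine: which parameters
#' are free, their box bounds, the deviation scale, and the annealing
#' schedule of the simplex + simulated-annealing hybrid.
#'
#' @param free Character vector of free parameter names: any of
#'   `nu_mu_D`, `nu_delta_D`, `nu_mu_B`, `nu_delta_B`, `lam`, `delta_DOME`,
#'   `delta_DOMB`, `CC_D`, `K_DOME`, `K_DOMB`, `DOM_E0`, `DOM_B0`.
#'   Everything not listed is frozen at its value in the `params`/`init`
#'   passed to [fit_coculture()]. Default: all rate constants, capacities
#'   and both initial DOM pools.
#' @param bounds Named list of `c(lower, upper)` per free parameter.
#'   Defaults: `[1e-6, 1e3]` for rates, `[1e3, 1e10]` for capacities,
#'   half-saturation constants and initial pools. Partial lists override
#'   only the named entries.
#' @param objective_scale `"log10"` (default) or `"linear"`. Counts span
#'   roughly 1e4-1e8 per ml, so a linear deviation would be dominated by the
#'   late diatom points; the log10 transform `g(x) = log10(x + 1)` weighs
#'   decades evenly.
#' @param fit_replicates If `TRUE` (default) the deviation sums over every
#'   replicate record; if `FALSE`, over per-time replicate means.
#' @param include_ratio_series If `TRUE`, replicate-matched diatom:bacterium
#'   count ratios enter the objective as a third series.
#' @param ratio_orientation `"D_over_B"` (default) or `"B_over_D"`.
#' @param weight_series If `TRUE`, each series' squared deviations are
#'   divided by the variance of its transformed observations, equalizing
#'   series influence.
#' @param T0 Initial annealing temperature; `NULL` uses the objective value
#'   at the start point.
#' @param cooling Geometric cooling factor in (0,1); default 0.9.
#' @param steps_per_temp Simplex iterations per temperature; default 50.
#' @param restarts Annealing schedule restarts; default 3.
#' @param t_min_ratio Stop cooling below `T0 * t_min_ratio`; default 1e-3.
#' @param seed Integer RNG seed; fits are bit-reproducible given the seed.
#' @return An object of class `fit_config`.
#' @examples
#' fit_config(free = c("nu_mu_B", "lam", "K_DOME"))
#' @export
fit_config <- function(free = c(.fittable_rates,
                                c("CC_D", "K_DOME", "K_DOMB",
                                  "DOM_E0", "DOM_B0")),
                       bounds = NULL,
                       objective_scale = c("log10", "linear"),
                       fit_replicates = TRUE,
                       include_ratio_series = FALSE,
                       ratio_orientation = c("D_over_B", "B_over_D"),
                       weight_series = FALSE,
                       T0 = NULL, cooling = 0.9, steps_per_temp = 50L,
                       restarts = 3L, t_min_ratio = 1e-3, seed = 1L) {
  objective_scale <- match.arg(objective_scale)
  ratio_orientation <- match.arg(ratio_orientation)
  allowed <- c(.fittable_rates, .fittable_pools)
  unknown <- setdiff(free, allowed)
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  if (!length(free)) stop("at least one free parameter required",
                          call. = FALSE)
  b <- .default_bounds(free)
  if (!is.null(bounds)) {
    stopifnot(is.list(bounds))
    for (nm in names(bounds)) {
      if (!nm %in% free)
        stop("bounds given for non-free parameter '", nm, "'", call. = FALSE)
      bb <- bounds[[nm]]
      if (length(bb) != 2L || !all(is.finite(bb)) || bb[1] > bb[2])
        stop("bounds for '", nm, "' must be finite c(lower, upper)",
             call. = FALSE)
      b[[nm]] <- as.numeric(bb)
    }
  }
  if (!is.null(T0)) stopifnot(T0 > 0)
  stopifnot(cooling > 0, cooling < 1, steps_per_temp >= 1, restarts >= 1,
            t_min_ratio > 0, t_min_ratio < 1)
  structure(list(free = free, bounds = b,
                 objective_scale = objective_scale,
                 fit_replicates = fit_replicates,
                 include_ratio_series = include_ratio_series,
                 ratio_orientation = ratio_orientation,
                 weight_series = weight_series,
                 T0 = T0, cooling = cooling,
                 steps_per_temp = as.integer(steps_per_temp),
                 restarts = as.integer(restarts),
                 t_min_ratio = t_min_ratio,
                 seed = as.integer(seed)),
            class = "fit_config")
}

.default_bounds <- function(free) {
  b <- lapply(free, function(nm) {
    if (nm %in% .fittable_rates) c(1e-6, 1e3) else c(1e3, 1e10)
  })
  names(b) <- free
  b
}

# Split a full parameter vector (rates + optional initial pools) into the
# coculture_params / coculture_state pieces.
.apply_theta <- function(theta, params, init) {
  rates <- intersect(names(theta), names(params))
  if (length(rates)) {
    params[rates] <- as.list(theta[rates])
    params <- structure(unclass(params), class = "coculture_params")
    validate_coculture_params(params)
  }
  s <- as.numeric(init)
  names(s) <- c("B", "D", "DOM_E", "DOM_B")
  if ("DOM_E0" %in% names(theta)) s[["DOM_E"]] <- theta[["DOM_E0"]]
  if ("DOM_B0" %in% names(theta)) s[["DOM_B"]] <- theta[["DOM_B0"]]
  list(params = params,
       init = structure(s, class = "coculture_state"))
}

#' Model predictions at observation times
#'
#' Thin adapter over [integrate_coculture()] returning predicted bacterial
#' and diatom concentrations (and optionally their ratio) at exactly the
#' requested times.
#'
#' @param params A [coculture_params()] object.
#' @param init A [coculture_state()] object.
#' @param times Observation times, days (nonnegative; need not include 0).
#' @param options A [coculture_options()] object.
#' @param include_ratio Add a `ratio` column (diatom:bacterium by default).
#' @param ratio_orientation `"D_over_B"` or `"B_over_D"`.
#' @param rtol,atol Integrator tolerances.
#' @return Data frame with columns `time`, `B`, `D` and optionally `ratio`
#'   (`NA` with a warning where the denominator is 0).
#' @examples
#' predict_at_times(coculture_params(), coculture_state(), c(0, 7, 14))
#' @export
predict_at_times <- function(params, init, times,
                             options = coculture_options(),
                             include_ratio = FALSE,
                             ratio_orientation = "D_over_B",
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(times >= 0), !anyDuplicated(times))
  grid <- sort(unique(c(0, times)))
  tr <- integrate_coculture(params, init, grid, options, rtol, atol)
  i <- match(times, tr$time)
  out <- data.frame(time = times, B = tr$B[i], D = tr$D[i])
  if (include_ratio) {
    num <- if (ratio_orientation == "D_over_B") out$D else out$B
    den <- if (ratio_orientation == "D_over_B") out$B else out$D
    if (any(den == 0))
      warning("ratio undefined where the denominator species is 0",
              call. = FALSE)
    out$ratio <- ifelse(den == 0, NA_real_, num / den)
  }
  out
}

.g_transform <- function(x, scale) {
  if (scale == "log10") log10(x + 1) else x
}

#' Squared-deviation objective
#'
#' The misfit minimized by the fitting engine: the sum over series, times
#' and replicates of `(g(obs) - g(pred))^2`, with `g(x) = log10(x + 1)`
#' under the default log10 scale (the +1 count ml^-1 offset keeps all-zero
#' series finite) or the identity under the linear scale.
#'
#' @param obs Observation data frame with columns `time_days`, `species`
#'   (`"B"`/`"D"`), `replicate`, `value` (see [read_observations()]).
#' @param params,init,options Model configuration to predict from.
#' @param config A [fit_config()] (controls scale, replicate handling,
#'   ratio series, series weighting).
#' @param rtol,atol Integrator tolerances.
#' @return Nonnegative scalar.
#' @examples
#' obs <- data.frame(time_days = 0, species = "B", replicate = 1, value = 5)
#' p <- coculture_params(); s <- coculture_state(B = 3, D = 1)
#' squared_deviation(obs, p, s,
#'                   config = fit_config(objective_scale = "linear"))
#' @export
squared_deviation <- function(obs, params, init, config = fit_config(),
                              options = coculture_options(),
                              rtol = 1e-8, atol = 1e-10) {
  obs <- validate_observations(obs)
  if (!nrow(obs)) stop("empty observation set", call. = FALSE)
  if (config$objective_scale == "log10") {
    for (sp in unique(obs$species))
      if (all(obs$value[obs$species == sp] == 0))
        warning("all-zero '", sp, "' series under log10 scale; ",
                "offset of 1 count ml^-1 applied", call. = FALSE)
  }
  pred <- predict_at_times(params, init, sort(unique(obs$time_days)),
                           options,
                           include_ratio = config$include_ratio_series,
                           ratio_orientation = config$ratio_orientation,
                           rtol = rtol, atol = atol)
  long <- obs[, c("time_days", "species", "replicate", "value")]
  if (config$include_ratio_series) {
    long <- rbind(long, .ratio_records(obs, config$ratio_orientation))
  }
  if (!config$fit_replicates) {
    agg <- stats::aggregate(value ~ time_days + species, data = long, mean)
    agg$replicate <- 1L
    long <- agg[, c("time_days", "species", "replicate", "value")]
  }
  pcol <- c(B = "B", D = "D", ratio = "ratio")
  pred_val <- mapply(function(tt, sp) {
    pred[[pcol[[sp]]]][match(tt, pred$time)]
  }, long$time_days, long$species)
  keep <- !is.na(pred_val) & !is.na(long$value)
  gobs <- .g_transform(long$value[keep], config$objective_scale)
  gprd <- .g_transform(pred_val[keep], config$objective_scale)
  sq <- (gobs - gprd)^2
  if (config$weight_series) {
    sp <- long$species[keep]
    w <- vapply(split(gobs, sp), stats::var, 0)[sp]
    w[!is.finite(w) | w <= 0] <- 1
    sq <- sq / w
  }
  sum(sq)
}

# Replicate-matched ratio pseudo-records from paired B/D observations.
.ratio_records <- function(obs, orientation) {
  bs <- obs[obs$species == "B", ]
  ds <- obs[obs$species == "D", ]
  key_b <- paste(bs$time_days, bs$replicate)
  key_d <- paste(ds$time_days, ds$replicate)
  common <- intersect(key_b, key_d)
  if (!length(common))
    return(data.frame(time_days = numeric(0), species = character(0),
                      replicate = integer(0), value = numeric(0)))
  b <- bs[match(common, key_b), ]
  d <- ds[match(common, key_d), ]
  num <- if (orientation == "D_over_B") d$value else b$value
  den <- if (orientation == "D_over_B") b$value else d$value
  ok <- den > 0
  data.frame(time_days = b$time_days[ok], species = "ratio",
             replicate = b$replicate[ok], value = num[ok] / den[ok])
}

#' Coefficient of determination between observed and predicted series
#'
#' Default definition: the squared Pearson correlation between observed and
#' predicted values across time points, with a two-sided p-value from the
#' correlation t-statistic \eqn{r \sqrt{n-2} / \sqrt{1-r^2}} on `n - 2`
#' degrees of freedom. The alternative `"ss"` definition
#' `1 - SS_res / SS_tot` (which may be negative and is reported as-is) is
#' available by flag; its p-value is still the correlation test.
#'
#' @param observed,predicted Paired numeric vectors (>= 3 points, no NAs).
#' @param method `"pearson"` (default) or `"ss"`.
#' @param n Sample size used in the p-value's degrees of freedom; defaults
#'   to `length(observed)`. Exposed because replicate-level conventions
#'   differ; see Details.
#' @details With 5 time points the correlation test has 3 degrees of
#'   freedom. When the observed means summarize replicated counts some
#'   analyses use the replicate-level record count instead; pass that via
#'   `n` if wanted. No convention is claimed to be canonical.
#' @return List with elements `R2`, `p_value`, `n`, `method`.
#' @examples
#' goodness_of_fit(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))$R2 # exactly 1
#' @export
goodness_of_fit <- function(observed, predicted,
                            method = c("pearson", "ss"), n = NULL) {
  method <- match.arg(method)
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3L)
    stop("goodness_of_fit needs >= 3 paired points", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("zero variance in observed or predicted values: R2 undefined",
         call. = FALSE)
  r <- stats::cor(observed, predicted)
  if (is.null(n)) n <- length(observed)
  tstat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  R2 <- if (method == "pearson") {
    r^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
  list(R2 = R2, p_value = p, n = n, method = method)
}

#' Fit the co-culture model to observed count time series
#'
#' Estimates the free parameters by minimizing the squared-deviation
#' objective with the simplex + simulated-annealing hybrid
#' ([neldermead_sa()]), searching in log10 parameter space within box
#' bounds. Frozen parameters keep their values from `params`/`init`, which
#' also provide the start point for the free ones (clamped into bounds).
#'
#' @param obs Observation data frame (`time_days`, `species`, `replicate`,
#'   `value`), e.g. from [read_observations()] or [generate_observations()].
#' @param config A [fit_config()].
#' @param params Start / frozen values, a [coculture_params()].
#' @param init Day-0 state, a [coculture_state()]; its DOM pools serve as
#'   start values when `DOM_E0` / `DOM_B0` are free.
#' @param options A [coculture_options()].
#' @param rtol,atol Integrator tolerances used inside the objective.
#' @param gof_n Optional sample-size override passed to
#'   [goodness_of_fit()].
#' @return An object of class `coculture_fit` with components `params_hat`,
#'   `init_hat`, `objective_value`, `gof` (per-series R2 and p for B, D and
#'   their ratio), `n_evaluations`, `converged`, `seed`, `trace`, plus the
#'   inputs. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' truth <- ground_truth()
#' obs <- generate_observations(truth,
#'          synthetic_design(noise_cv = 0, seed = 1))$observations
#' cfg <- fit_config(free = c("nu_mu_B", "lam"), restarts = 1,
#'                   steps_per_temp = 10, t_min_ratio = 0.1)
#' fit <- fit_coculture(obs, cfg, params = truth$params, init = truth$init)
#' coef(fit)
#' }
#' @export
fit_coculture <- function(obs, config = fit_config(),
                          params = coculture_params(),
                          init = coculture_state(),
                          options = coculture_options(),
                          rtol = 1e-6, atol = 1e-8, gof_n = NULL) {
  stopifnot(inherits(config, "fit_config"))
  obs <- validate_observations(obs)
  if (nrow(obs) < length(config$free))
    stop("fewer data points (", nrow(obs), ") than free parameters (",
         length(config$free), ")", call. = FALSE)

  start_full <- c(unlist(unclass(params)[intersect(names(params),
                                                   .fittable_rates)]),
                  unlist(unclass(params)[intersect(names(params),
                                                   .fittable_pools)]),
                  DOM_E0 = init[["DOM_E"]], DOM_B0 = init[["DOM_B"]])
  theta0 <- start_full[config$free]
  lo <- vapply(config$bounds[config$free], `[`, 0, 1L)
  hi <- vapply(config$bounds[config$free], `[`, 0, 2L)
  theta0 <- pmin(pmax(theta0, lo), hi)

  # search in log10 space: parameters are positive and span decades
  obj <- function(z) {
    theta <- 10^z
    names(theta) <- config$free
    pi_ <- tryCatch(.apply_theta(theta, params, init), error = function(e) NULL)
    if (is.null(pi_)) return(Inf)
    tryCatch(
      squared_deviation(obs, pi_$params, pi_$init, config, options,
                        rtol, atol),
      error = function(e) Inf)
  }
  z0 <- log10(theta0)
  f0 <- obj(z0)
  if (!is.finite(f0))
    stop("objective non-finite at the start point; check start values of ",
         paste(config$free, collapse = ", "), call. = FALSE)

  res <- neldermead_sa(obj, z0, lower = log10(lo), upper = log10(hi),
                       control = list(T0 = config$T0,
                                      cooling = config$cooling,
                                      steps_per_temp = config$steps_per_temp,
                                      restarts = config$restarts,
                                      t_min_ratio = config$t_min_ratio),
                       seed = config$seed)

  theta_hat <- 10^res$par
  names(theta_hat) <- config$free
  at_bound <- theta_hat <= lo * (1 + 1e-6) | theta_hat >= hi * (1 - 1e-6)
  pi_hat <- .apply_theta(theta_hat, params, init)

  gof <- .fit_gof(obs, pi_hat$params, pi_hat$init, options, config,
                  rtol, atol, gof_n)

  structure(list(params_hat = pi_hat$params, init_hat = pi_hat$init,
                 theta_hat = theta_hat, at_bound = at_bound,
                 objective_value = res$value, gof = gof,
                 n_evaluations = res$n_evaluations,
                 converged = res$converged && !any(at_bound),
                 seed = config$seed, trace = res$trace,
                 config = config, options = options, obs = obs,
                 start = theta0),
            class = "coculture_fit")
}

# Per-series goodness of fit on per-time replicate means (B, D, and their
# replicate-mean ratio), as the fit-quality report.
.fit_gof <- function(obs, params, init, options, config, rtol, atol,
                     gof_n = NULL) {
  times <- sort(unique(obs$time_days))
  pred <- predict_at_times(params, init, times, options,
                           include_ratio = TRUE,
                           ratio_orientation = config$ratio_orientation,
                           rtol = rtol, atol = atol)
  mean_of <- function(sp) {
    sub <- obs[obs$species == sp, ]
    out <- rep(NA_real_, length(times))
    if (nrow(sub)) {
      m <- tapply(sub$value, sub$time_days, mean)
      out[match(as.numeric(names(m)), times)] <- m
    }
    out
  }
  mB <- mean_of("B"); mD <- mean_of("D")
  ratio_obs <- ifelse(
    (if (config$ratio_orientation == "D_over_B") mB else mD) > 0,
    if (config$ratio_orientation == "D_over_B") mD / mB else mB / mD,
    NA_real_)
  series <- list(B = list(o = mB, p = pred$B),
                 D = list(o = mD, p = pred$D),
                 ratio = list(o = ratio_obs, p = pred$ratio))
  rows <- lapply(names(series), function(nm) {
    o <- series[[nm]]$o; p <- series[[nm]]$p
    ok <- is.finite(o) & is.finite(p)
    if (sum(ok) < 3L || stats::sd(o[ok]) == 0 || stats::sd(p[ok]) == 0)
      return(data.frame(series = nm, R2 = NA_real_, p_value = NA_real_,
                        n = sum(ok)))
    g <- goodness_of_fit(o[ok], p[ok], n = gof_n)
    data.frame(series = nm, R2 = g$R2, p_value = g$p_value, n = g$n)
  })
  do.call(rbind, rows)
}

#' @export
print.coculture_fit <- function(x, ...) {
  cat("Co-culture model fit (simplex + simulated annealing)\n")
  cat("  free parameters:", paste(x$config$free, collapse = ", "), "\n")
  cat("  squared deviation (", x$config$objective_scale, " scale): ",
      signif(x$objective_value, 6), "\n", sep = "")
  cat("  objective evaluations:", x$n_evaluations,
      "| converged:", x$converged, "\n")
  g <- x$gof
  cat("  R2 (per-time means): ",
      paste(sprintf("%s = %.3f", g$series, g$R2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.coculture_fit <- function(object, ...) {
  est <- data.frame(parameter = names(object$theta_hat),
                    estimate = unname(object$theta_hat),
                    start = unname(object$start),
                    at_bound = unname(object$at_bound))
  out <- list(estimates = est, gof = object$gof,
              objective_value = object$objective_value,
              n_evaluations = object$n_evaluations,
              converged = object$converged, seed = object$seed)
  class(out) <- "summary.coculture_fit"
  out
}

#' @export
print.summary.coculture_fit <- function(x, ...) {
  cat("Parameter estimates:\n")
  est <- x$estimates
  est$estimate <- signif(est$estimate, 5)
  est$start <- signif(est$start, 5)
  print(est, row.names = FALSE)
  cat("\nGoodness of fit (squared Pearson R2, per-time replicate means):\n")
  g <- x$gof
  g$R2 <- signif(g$R2, 4); g$p_value <- signif(g$p_value, 4)
  print(g, row.names = FALSE)
  cat("\nObjective:", signif(x$objective_value, 6),
      "| evaluations:", x$n_evaluations,
      "| converged:", x$converged, "| seed:", x$seed, "\n")
  invisible(x)
}

#' @export
coef.coculture_fit <- function(object, ...) object$theta_hat

#' @export
predict.coculture_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- sort(unique(object$obs$time_days))
  predict_at_times(object$params_hat, object$init_hat, times,
                   object$options, include_ratio = TRUE,
                   ratio_orientation = object$config$ratio_orientation)
}

#' @export
fitted.coculture_fit <- function(object, ...) {
  pred <- predict(object)
  i <- match(object$obs$time_days, pred$time)
  ifelse(object$obs$species == "B", pred$B[i], pred$D[i])
}

#' @export
residuals.coculture_fit <- function(object, ...) {
  sc <- object$config$objective_scale
  .g_transform(object$obs$value, sc) - .g_transform(fitted(object), sc)
}

#' @export
plot.coculture_fit <- function(x, ...) {
  obs <- x$obs
  horizon <- max(obs$time_days)
  pred <- predict(x, times = seq(0, horizon, length.out = 141))
  cols <- c(B = "firebrick", D = "forestgreen")
  ylim <- range(c(obs$value[obs$value > 0], pred$B[pred$B > 0],
                  pred$D[pred$D > 0]))
  graphics::plot(NA, xlim = c(0, horizon), ylim = ylim, log = "y",
                 xlab = "time (days)", ylab = "cells ml^-1", ...)
  graphics::lines(pred$time, pmax(pred$B, .Machine$double.xmin),
                  col = cols["B"])
  graphics::lines(pred$time, pmax(pred$D, .Machine$double.xmin),
                  col = cols["D"])
  for (sp in c("B", "D")) {
    sub <- obs[obs$species == sp & obs$value > 0, ]
    graphics::points(sub$time_days, sub$value, col = cols[sp], pch = 1)
  }
  graphics::legend("bottomright", legend = c("bacterium B", "diatom D"),
                   col = cols, lty = 1, pch = 1, bty = "n")
  invisible(x)
}

#' @export
simulate.coculture_fit <- function(object, nsim = 1, seed = NULL, ...) {
  obs <- object$obs
  design <- synthetic_design(
    sample_times = sort(unique(obs$time_days)),
    n_replicates = max(obs$replicate),
    seed = if (is.null(seed)) 1L else seed)
  truth <- ground_truth(object$params_hat, object$init_hat, object$options)
  out <- lapply(seq_len(nsim), function(i) {
    design$seed <- design$seed + i - 1L
    generate_observations(truth, design)$observations
  })
  if (nsim == 1) out[[1]] else out
}
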