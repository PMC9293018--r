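#' Sampling design for synthetic observation sets
#'
#' Describes how a noiseless model trajectory is turned into count
#' observations with the statistical structure of the co-culture experiment:
#' 5 sampling days spread over 28 days, triplicate cultures, multiplicative
#' counting noise, and a plate-count detection floor.
#'
#' @param sample_times Sampling days; default `c(0, 7, 14, 21, 28)` (weekly
#'   over the 28-day experiment).
#' @param n_replicates Replicate cultures per time point; default 3.
#' @param noise_model `"lognormal_cv"` (default): multiplicative lognormal
#'   noise with fixed coefficient of variation, the usual error structure of
#'   plate and haemocytometer counts; or `"poisson_counting"`: Poisson draws
#'   with the model value as mean.
#' @param noise_cv Coefficient of variation of the lognormal noise; default
#'   0.1 (plate-count CVs typically run 5-20%).
#' @param detection_floor Counts ml^-1 below which observations are censored
#'   up to the floor (default 10); censored records are flagged.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_design`.
#' @examples
#' synthetic_design(noise_cv = 0.05, seed = 42)
#' @export
synthetic_design <- function(sample_times = c(0, 7, 14, 21, 28),
                             n_replicates = 3L,
                             noise_model = c("lognormal_cv",
                                             "poisson_counting"),
                             noise_cv = 0.1, detection_floor = 10,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(sample_times) >= 1L, all(sample_times >= 0),
            !is.unsorted(sample_times, strictly = TRUE),
            n_replicates >= 1L, noise_cv >= 0, detection_floor >= 0)
  structure(list(sample_times = as.numeric(sample_times),
                 n_replicates = as.integer(n_replicates),
                 noise_model = noise_model, noise_cv = noise_cv,
                 detection_floor = detection_floor,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("Synthetic sampling design:\n")
  cat("  sample days:     ", paste(x$sample_times, collapse = ", "), "\n")
  cat("  replicates:      ", x$n_replicates, "\n")
  cat("  noise:           ", x$noise_model,
      if (x$noise_model == "lognormal_cv") sprintf("(cv = %g)", x$noise_cv),
      "\n")
  cat("  detection floor: ", x$detection_floor, "per ml\n")
  cat("  seed:            ", x$seed, "\n")
  invisible(x)
}

#' Ground truth for synthetic experiments
#'
#' Bundles the parameter set, initial state and structural options that
#' generate a synthetic dataset. The defaults are the package's reference
#' parameterization (see [coculture_params()]) with the experimental
#' inoculation densities; they are a synthetic stand-in chosen for the
#' qualitative co-culture shape, not fitted values.
#'
#' @param params A [coculture_params()].
#' @param init A [coculture_state()].
#' @param options A [coculture_options()].
#' @return An object of class `ground_truth`.
#' @examples
#' ground_truth(coculture_params(lam = 0.02))
#' @export
ground_truth <- function(params = coculture_params(),
                         init = coculture_state(),
                         options = coculture_options()) {
  stopifnot(inherits(params, "coculture_params"))
  structure(list(params = params, init = init, options = options),
            class = "ground_truth")
}

#' Generate a synthetic observation set
#'
#' Integrates the model under the ground truth, samples it at the design's
#' time points, and perturbs each replicate with observation noise. Under
#' the lognormal model a value is drawn as
#' `mean * exp(sigma * Z - sigma^2 / 2)` with
#' `sigma = sqrt(log(1 + cv^2))`, which is unbiased in expectation, so
#' noiseless fits are consistent. Values below the detection floor are
#' censored up to the floor and flagged.
#'
#' @param truth A [ground_truth()] object.
#' @param design A [synthetic_design()] object.
#' @param rtol,atol Integrator tolerances.
#' @return A list with `observations` (data frame `time_days`, `species`,
#'   `replicate`, `value`, `censored`) and `trajectory` (the noiseless model
#'   values at the sample times, for auditing).
#' @examples
#' syn <- generate_observations(ground_truth(),
#'                              synthetic_design(noise_cv = 0, seed = 7))
#' head(syn$observations)
#' @export
generate_observations <- function(truth, design = synthetic_design(),
                                  rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(design, "synthetic_design"))
  grid <- sort(unique(c(0, design$sample_times)))
  tr <- integrate_coculture(truth$params, truth$init, grid, truth$options,
                            rtol, atol)
  i <- match(design$sample_times, tr$time)
  mean_tab <- data.frame(time_days = design$sample_times,
                         B = tr$B[i], D = tr$D[i])

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)

  nt <- length(design$sample_times)
  nr <- design$n_replicates
  out <- expand.grid(replicate = seq_len(nr),
                     time_days = design$sample_times,
                     species = c("B", "D"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(out$species == "B",
               mean_tab$B[match(out$time_days, mean_tab$time_days)],
               mean_tab$D[match(out$time_days, mean_tab$time_days)])
  value <- if (design$noise_model == "lognormal_cv") {
    sigma <- sqrt(log(1 + design$noise_cv^2))
    mu * exp(sigma * stats::rnorm(nrow(out)) - sigma^2 / 2)
  } else {
    stats::rpois(nrow(out), lambda = mu)
  }
  censored <- value < design$detection_floor
  value[censored] <- design$detection_floor
  out$value <- value
  out$censored <- censored
  out <- out[, c("time_days", "species", "replicate", "value", "censored")]
  list(observations = out, trajectory = mean_tab)
}

#' Closed-loop parameter-recovery experiment
#'
#' Generates `n_datasets` synthetic observation sets from a known ground
#' truth and refits each one, reporting how well the free parameters are
#' recovered: per-parameter relative errors and bias, and the per-series
#' goodness of fit of each refit. This is the package's internal check that
#' the sparse 5-point triplicate design identifies the parameters it is
#' asked to identify.
#'
#' @param truth A [ground_truth()].
#' @param design A [synthetic_design()]; its seed is re-derived per dataset
#'   from `seed`.
#' @param config A [fit_config()] naming the free parameters (start values
#'   are taken from `truth` unless `start_params` is given).
#' @param n_datasets Number of generate-and-refit rounds.
#' @param seed Master seed; dataset `i` uses `seed * 1000 + i` for
#'   generation and seeds the fit with `seed + i`.
#' @param start_params,start_init Optional start point for the fits
#'   (defaults: the truth itself, the usual convention for identifiability
#'   checks; supply perturbed values to probe basin width).
#' @return An object of class `recovery_report`: list with `per_dataset`
#'   (data frame of fitted values, one row per dataset x parameter),
#'   `summary` (per-parameter median absolute relative error and median
#'   signed bias), `gof` (per dataset and series), `failures`.
#' @examples
#' \donttest{
#' cfg <- fit_config(free = c("nu_mu_B", "lam"), restarts = 1,
#'                   steps_per_temp = 5, t_min_ratio = 0.5)
#' rep <- parameter_recovery_experiment(ground_truth(),
#'          synthetic_design(noise_cv = 0.05), cfg, n_datasets = 2)
#' rep$summary
#' }
#' @export
parameter_recovery_experiment <- function(truth, design, config,
                                          n_datasets = 20L, seed = 1L,
                                          start_params = NULL,
                                          start_init = NULL) {
  stopifnot(n_datasets >= 1L)
  if (is.null(start_params)) start_params <- truth$params
  if (is.null(start_init)) start_init <- truth$init
  truth_full <- c(unlist(unclass(truth$params)[.fittable_rates]),
                  unlist(unclass(truth$params)[
                    intersect(.fittable_pools, names(truth$params))]),
                  DOM_E0 = truth$init[["DOM_E"]],
                  DOM_B0 = truth$init[["DOM_B"]])
  per <- list(); gofs <- list(); failures <- list()
  for (i in seq_len(n_datasets)) {
    d <- design
    d$seed <- as.integer(seed * 1000L + i)
    syn <- generate_observations(truth, d)
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    fit <- tryCatch(
      fit_coculture(syn$observations, cfg, params = start_params,
                    init = start_init, options = truth$options),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(dataset = i, message = conditionMessage(fit))
      next
    }
    th <- coef(fit)
    tv <- truth_full[names(th)]
    per[[length(per) + 1L]] <- data.frame(
      dataset = i, parameter = names(th), truth = unname(tv),
      estimate = unname(th),
      rel_error = unname(ifelse(tv > 0, (th - tv) / tv, NA_real_)),
      objective = fit$objective_value)
    g <- fit$gof
    g$dataset <- i
    gofs[[length(gofs) + 1L]] <- g
  }
  if (!length(per))
    stop("all ", n_datasets, " fits failed", call. = FALSE)
  per_dataset <- do.call(rbind, per)
  summ <- do.call(rbind, lapply(split(per_dataset, per_dataset$parameter),
    function(s) data.frame(
      parameter = s$parameter[1],
      truth = s$truth[1],
      median_estimate = stats::median(s$estimate),
      median_abs_rel_error = stats::median(abs(s$rel_error)),
      median_bias = stats::median(s$rel_error),
      n = nrow(s))))
  rownames(summ) <- NULL
  structure(list(per_dataset = per_dataset, summary = summ,
                 gof = do.call(rbind, gofs),
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 n_datasets = n_datasets, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  ok <- length(unique(x$per_dataset$dataset))
  cat("Parameter-recovery experiment:", ok, "of", x$n_datasets,
      "fits succeeded (seed", x$seed, ")\n")
  s <- x$summary
  s[-1] <- lapply(s[-1], function(v) signif(v, 4))
  print(s, row.names = FALSE)
  if (!is.null(x$gof)) {
    r2 <- x$gof$R2[x$gof$series %in% c("B", "D")]
    cat("per-series R2 (B, D): median", signif(stats::median(r2, na.rm = TRUE), 3),
        "| min", signif(min(r2, na.rm = TRUE), 3), "\n")
  }
  invisible(x)
}
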