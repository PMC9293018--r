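# Delimited-text and JSON round-tripping for observations, configs,
# trajectories and fit reports. Comma is the default field separator; tab
# is accepted on read (auto-detected from the header line).

#' Read an observation table
#'
#' Reads replicated count time series from delimited text with the header
#' `time_days, species, replicate, value` (comma or tab separated; an
#' optional `censored` column is preserved). Lines starting with `#` are
#' treated as metadata and echoed back as the `"metadata"` attribute
#' (conventionally unit declarations such as `# units B: CFU/ml`).
#'
#' @param path File path.
#' @return A validated observation data frame; species restricted to `"B"`
#'   (bacterium, CFU ml^-1) and `"D"` (diatom, cells ml^-1).
#' @seealso [write_observations()]
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) stop("no data in ", path, call. = FALSE)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  obs <- utils::read.table(text = body, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  obs <- validate_observations(obs, where = path)
  attr(obs, "metadata") <- sub("^#\\s*", "", meta)
  obs
}

#' Validate an observation data frame
#'
#' Schema check shared by the reader, the objective and the fitter: required
#' columns present, species labels known, values nonnegative and finite
#' (errors name the offending row).
#'
#' @param obs Data frame to validate.
#' @param where Label used in error messages.
#' @return The data frame, with `species` as character.
#' @export
validate_observations <- function(obs, where = "observations") {
  req <- c("time_days", "species", "replicate", "value")
  miss <- setdiff(req, names(obs))
  if (length(miss))
    stop("schema error in ", where, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  obs$species <- as.character(obs$species)
  bad_sp <- !obs$species %in% c("B", "D")
  if (any(bad_sp))
    stop("unknown species label(s) in ", where, ": ",
         paste(unique(obs$species[bad_sp]), collapse = ", "),
         " (allowed: B, D)", call. = FALSE)
  if (!is.numeric(obs$time_days) || any(!is.finite(obs$time_days)) ||
      any(obs$time_days < 0))
    stop("time_days must be finite and >= 0 in ", where, call. = FALSE)
  bad <- which(!is.finite(obs$value) | obs$value < 0)
  if (length(bad))
    stop("invalid value at row ", bad[1], " of ", where,
         ": values must be finite and >= 0 (got ", obs$value[bad[1]], ")",
         call. = FALSE)
  obs
}

#' Write an observation table
#'
#' @param obs Observation data frame.
#' @param path Output path.
#' @param sep Field separator (`","` default, `"\t"` accepted).
#' @param metadata Optional character vector written as leading `#` lines.
#' @export
write_observations <- function(obs, path, sep = ",", metadata = NULL) {
  obs <- validate_observations(obs)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(paste("#", metadata), con)
  utils::write.table(obs, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write model configuration
#'
#' Parameters, structural options and the initial state share one flat
#' key-value JSON file whose keys are exactly the field names of
#' [coculture_params()], [coculture_options()] and [coculture_state()]
#' (state keys: `B`, `D`, `DOM_E`, `DOM_B`). Unknown keys are an error.
#' Absent groups fall back to defaults, so a file containing only `lam`
#' overrides just the exudation rate.
#'
#' @param path JSON file path.
#' @return For `read_model_config()`: list with elements `params`,
#'   `options`, `init`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  kv <- jsonlite::read_json(path, simplifyVector = TRUE)
  kv <- kv[!startsWith(names(kv), "_")] # underscore keys are comments
  par_f <- c("nu_mu_D", "nu_delta_D", "nu_mu_B", "nu_delta_B", "lam",
             "CC_D", "CC_B", "K_DOME", "K_DOMB", "delta_DOME",
             "delta_DOMB", "yield")
  opt_f <- c("consumption_mode", "exudation_costs_biomass",
             "mu_B_resolution")
  st_f <- c("B", "D", "DOM_E", "DOM_B")
  unknown <- setdiff(names(kv), c(par_f, opt_f, st_f))
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  params <- do.call(coculture_params, kv[intersect(names(kv), par_f)])
  options <- do.call(coculture_options, kv[intersect(names(kv), opt_f)])
  init <- do.call(coculture_state, kv[intersect(names(kv), st_f)])
  list(params = params, options = options, init = init)
}

#' @param params A [coculture_params()] (or `NULL` to omit).
#' @param options A [coculture_options()] (or `NULL`).
#' @param init A [coculture_state()] (or `NULL`).
#' @rdname read_model_config
#' @export
write_model_config <- function(path, params = NULL, options = NULL,
                               init = NULL) {
  kv <- list()
  if (!is.null(params)) kv <- c(kv, unclass(params))
  if (!is.null(options)) kv <- c(kv, unclass(options))
  if (!is.null(init)) kv <- c(kv, as.list(unclass(init)))
  jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a trajectory as tidy long-format text
#'
#' One row per (time, variable): columns `time_days`, `variable` (one of
#' `B`, `D`, `DOM_E`, `DOM_B`), `value`. Sweep tables gain a leading
#' `level` column.
#'
#' @param traj A `coculture_trajectory`.
#' @param path Output path.
#' @param sep Field separator.
#' @param level Optional sweep level prepended as a column.
#' @export
write_trajectory <- function(traj, path, sep = ",", level = NULL) {
  long <- trajectory_long(traj, level)
  utils::write.table(long, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
trajectory_long <- function(traj, level = NULL) {
  vars <- c("B", "D", "DOM_E", "DOM_B")
  long <- data.frame(
    time_days = rep(traj$time, length(vars)),
    variable = rep(vars, each = nrow(traj)),
    value = unlist(lapply(vars, function(v) traj[[v]]), use.names = FALSE))
  if (!is.null(level)) long <- cbind(level = level, long)
  long
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_days", "variable", "value")
  if (!all(req %in% names(long)))
    stop("schema error in ", path, ": need columns ",
         paste(req, collapse = ", "), call. = FALSE)
  wide <- stats::reshape(long[, req], idvar = "time_days",
                         timevar = "variable", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  names(wide)[1] <- "time"
  wide[order(wide$time), c("time", "B", "D", "DOM_E", "DOM_B")]
}

#' Serialize a fit result
#'
#' Writes a plain-text key-value report (objective, per-series R2 and
#' p-values, optimizer diagnostics, estimates) and, optionally, a flat JSON
#' parameter file directly reusable by the simulator.
#'
#' @param fit A `coculture_fit`.
#' @param path Report path.
#' @param params_path Optional path for the fitted-parameter JSON config.
#' @export
write_fit_report <- function(fit, path, params_path = NULL) {
  stopifnot(inherits(fit, "coculture_fit"))
  g <- fit$gof
  lines <- c(
    "# co-culture model fit report",
    paste0("objective_scale: ", fit$config$objective_scale),
    paste0("objective_value: ", format(fit$objective_value, digits = 12)),
    paste0("n_evaluations: ", fit$n_evaluations),
    paste0("converged: ", fit$converged),
    paste0("seed: ", fit$seed),
    paste0("free_parameters: ", paste(fit$config$free, collapse = ",")),
    vapply(seq_along(fit$theta_hat), function(i) {
      paste0("estimate_", names(fit$theta_hat)[i], ": ",
             format(fit$theta_hat[[i]], digits = 12))
    }, ""),
    vapply(seq_len(nrow(g)), function(i) {
      sprintf("R2_%s: %s (p = %s, n = %d)", g$series[i],
              format(g$R2[i], digits = 6),
              format(g$p_value[i], digits = 6), g$n[i])
    }, ""))
  writeLines(lines, path)
  if (!is.null(params_path))
    write_model_config(params_path, params = fit$params_hat,
                       init = fit$init_hat)
  invisible(path)
}

#' Write a run manifest
#'
#' Every command-line run records what produced its outputs: command,
#' resolved configuration, input/output paths, seed, package version and
#' wall-clock start, as JSON next to the primary output.
#'
#' @param command Subcommand name.
#' @param config Named list of resolved option values.
#' @param inputs,outputs Character vectors of paths.
#' @param seed Integer seed in effect.
#' @param path Manifest path.
#' @export
write_manifest <- function(command, config, inputs, outputs, seed, path) {
  m <- list(command = command, config = config,
            inputs = as.character(inputs), outputs = as.character(outputs),
            rng_seed = seed,
            package_version =
              as.character(utils::packageVersion("microloop")),
            started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
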