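#' Downhill simplex with simulated annealing
#'
#' Bound-constrained minimizer combining the Nelder-Mead simplex with
#' simulated annealing: during vertex comparisons, each stored vertex value
#' is penalized by a positive Boltzmann deviate `-T * log(u)` and each trial
#' point is favored by subtracting an independent deviate, so at temperature
#' `T` the simplex performs a biased random walk that can climb out of local
#' minima. The temperature is cooled geometrically; at `T = 0` the method is
#' the plain downhill simplex. The simplex is re-seeded around the incumbent
#' best point at the start of every temperature stage (and across
#' `restarts` full schedules with a shrinking initial scale).
#'
#' @param fn Objective function of a numeric vector, to minimize. Non-finite
#'   values are treated as a large penalty.
#' @param x0 Numeric start vector (clamped into the bounds).
#' @param lower,upper Bounds, recycled to `length(x0)`. Proposed points are
#'   projected onto the box.
#' @param control List of tuning constants:
#'   \describe{
#'     \item{T0}{Initial temperature. `NULL` (default) sets it to the
#'       objective value at `x0`, so the initial thermal noise is on the
#'       scale of the misfit itself.}
#'     \item{cooling}{Geometric cooling factor in (0,1); default 0.9.}
#'     \item{steps_per_temp}{Simplex iterations per temperature; default 50.}
#'     \item{restarts}{Full annealing schedules; default 3.}
#'     \item{t_min_ratio}{Cooling stops when `T < T0 * t_min_ratio`
#'       (default 1e-3), after which a zero-temperature polish runs.}
#'     \item{scale}{Initial simplex edge length (in the units of `x0`);
#'       default 0.25.}
#'     \item{tol}{Relative spread of vertex values declaring convergence of
#'       the zero-temperature polish; default 1e-10.}
#'     \item{polish_iter}{Maximum iterations of the final polish;
#'       default 500.}
#'   }
#' @param seed Integer seed making the run reproducible; `NULL` uses the
#'   current RNG state.
#' @return A list: `par` (best point), `value`, `n_evaluations`,
#'   `converged` (polish converged within `tol`), `trace` (best value at
#'   the end of each temperature stage).
#' @examples
#' # seeded quartic with two wells; annealing finds the global one
#' f <- function(x) (x[1]^2 - 1)^2 + 0.5 * x[1] + x[2]^2
#' neldermead_sa(f, c(0.9, 0.5), -2, 2, seed = 1)$par
#' @export
neldermead_sa <- function(fn, x0, lower = -Inf, upper = Inf,
                          control = list(), seed = NULL) {
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  stopifnot(all(lower <= upper), n >= 1)
  ctl <- modifyList(list(T0 = NULL, cooling = 0.9, steps_per_temp = 50L,
                         restarts = 3L, t_min_ratio = 1e-3, scale = 0.25,
                         tol = 1e-10, polish_iter = 500L), control)
  stopifnot(ctl$cooling > 0, ctl$cooling < 1, ctl$steps_per_temp >= 1,
            ctl$restarts >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }

  clamp <- function(x) pmin(pmax(x, lower), upper)
  nev <- 0L
  evalf <- function(x) {
    nev <<- nev + 1L
    v <- fn(x)
    if (!is.finite(v)) v <- 1e300
    v
  }

  x0 <- clamp(x0)
  f0 <- evalf(x0)
  if (f0 >= 1e300)
    stop("objective is non-finite at the start point", call. = FALSE)
  T0 <- if (is.null(ctl$T0)) f0 else ctl$T0
  if (T0 < 0) stop("T0 must be >= 0", call. = FALSE)

  best_x <- x0
  best_f <- f0
  trace <- numeric(0)

  make_simplex <- function(center, scale) {
    P <- matrix(rep(center, n + 1L), nrow = n + 1L, byrow = TRUE)
    for (i in seq_len(n)) {
      step <- scale * max(abs(center[i]), 1)
      # flip direction if the step would leave the box
      if (center[i] + step > upper[i]) step <- -step
      P[i + 1L, i] <- center[i] + step
    }
    P <- t(apply(P, 1L, clamp))
    if (n == 1L) P <- matrix(P, ncol = 1L)
    P
  }

  # one Nelder-Mead update at temperature Temp (amebsa-style thermal noise)
  nm_step <- function(P, y, Temp) {
    yt <- y + if (Temp > 0) -Temp * log(stats::runif(n + 1L)) else 0
    ord <- order(yt)
    P <- P[ord, , drop = FALSE]; y <- y[ord]; yt <- yt[ord]
    hi <- n + 1L
    centroid <- colMeans(P[-hi, , drop = FALSE])
    try_point <- function(fac) {
      xt <- clamp(centroid + fac * (P[hi, ] - centroid))
      ft <- evalf(xt)
      list(x = xt, f = ft,
           ftherm = ft - if (Temp > 0) -Temp * log(stats::runif(1L)) else 0)
    }
    refl <- try_point(-1)
    if (refl$f < best_f) { best_x <<- refl$x; best_f <<- refl$f }
    if (refl$ftherm < yt[1L]) {
      exp_ <- try_point(-2)
      if (exp_$f < best_f) { best_x <<- exp_$x; best_f <<- exp_$f }
      if (exp_$ftherm < refl$ftherm) {
        P[hi, ] <- exp_$x; y[hi] <- exp_$f
      } else {
        P[hi, ] <- refl$x; y[hi] <- refl$f
      }
    } else if (refl$ftherm < yt[n]) {
      P[hi, ] <- refl$x; y[hi] <- refl$f
    } else {
      ctr <- try_point(0.5)
      if (ctr$f < best_f) { best_x <<- ctr$x; best_f <<- ctr$f }
      if (ctr$ftherm < yt[hi]) {
        P[hi, ] <- ctr$x; y[hi] <- ctr$f
      } else { # shrink toward the current best vertex
        for (i in 2L:(n + 1L)) {
          P[i, ] <- clamp(P[1L, ] + 0.5 * (P[i, ] - P[1L, ]))
          y[i] <- evalf(P[i, ])
          if (y[i] < best_f) { best_x <<- P[i, ]; best_f <<- y[i] }
        }
      }
    }
    list(P = P, y = y)
  }

  run_stage <- function(P, y, Temp, iters) {
    for (k in seq_len(iters)) {
      st <- nm_step(P, y, Temp)
      P <- st$P; y <- st$y
    }
    list(P = P, y = y)
  }

  for (r in seq_len(ctl$restarts)) {
    scale_r <- ctl$scale / r
    P <- make_simplex(best_x, scale_r)
    y <- apply(P, 1L, evalf)
    if (min(y) < best_f) {
      i <- which.min(y); best_x <- P[i, ]; best_f <- y[i]
    }
    Temp <- T0
    while (Temp > T0 * ctl$t_min_ratio && Temp > 0) {
      st <- run_stage(P, y, Temp, ctl$steps_per_temp)
      # re-seed the simplex around the incumbent best for the next stage
      P <- make_simplex(best_x, scale_r * max(Temp / T0, 0.01))
      y <- apply(P, 1L, evalf)
      if (min(y) < best_f) {
        i <- which.min(y); best_x <- P[i, ]; best_f <- y[i]
      }
      Temp <- Temp * ctl$cooling
      trace <- c(trace, best_f)
    }
  }

  # zero-temperature polish from the best point found
  P <- make_simplex(best_x, ctl$scale * 0.05)
  y <- apply(P, 1L, evalf)
  converged <- FALSE
  for (k in seq_len(ctl$polish_iter)) {
    st <- nm_step(P, y, 0)
    P <- st$P; y <- st$y
    spread <- (max(y) - min(y)) / (abs(min(y)) + 1e-12)
    if (spread < ctl$tol) { converged <- TRUE; break }
  }
  i <- which.min(y)
  if (y[i] < best_f) { best_x <- P[i, ]; best_f <- y[i] }

  list(par = best_x, value = best_f, n_evaluations = nev,
       converged = converged, trace = trace)
}
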