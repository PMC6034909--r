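#' Motion parameters for a velocity jump process
#'
#' Bundles the generative parameters of a planar velocity jump process
#' (VJP): straight runs at fixed speed `c` interrupted by instantaneous
#' reorientations arriving at rate `lambda`, with the turning angle at each
#' reorientation drawn from a reorientation kernel. Run durations are
#' i.i.d. exponential(`lambda`) and there is no waiting phase between runs.
#'
#' @param lambda reorientation rate, per second (`lambda >= 0`).
#' @param speed running speed `c`, micrometres per second (`> 0`).
#' @param kernel reorientation kernel: `"uniform"` (uniform on
#'   \eqn{[-\pi,\pi)}) or `"wrapped_normal"`.
#' @param gamma dispersion of the wrapped-normal kernel, radians (the
#'   pre-wrap standard deviation); required iff `kernel = "wrapped_normal"`.
#' @param initial_heading initial direction of travel, radians; the default 0
#'   points along the positive x-axis.
#' @return an object of class `vjp_params`.
#' @examples
#' vjp_params(lambda = 0.2, speed = 50)
#' @export
vjp_params <- function(lambda, speed, kernel = c("uniform", "wrapped_normal"),
                       gamma = NULL, initial_heading = 0) {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0,
            is.numeric(speed), length(speed) == 1, speed > 0)
  if (kernel == "wrapped_normal") {
    if (is.null(gamma) || !is.numeric(gamma) || gamma <= 0)
      stop("a positive dispersion `gamma` is required for the wrapped-normal kernel")
  } else {
    gamma <- NULL
  }
  structure(list(lambda = lambda, speed = speed, kernel = kernel,
                 gamma = gamma, initial_heading = wrap_angle(initial_heading)),
            class = "vjp_params")
}

#' @export
print.vjp_params <- function(x, ...) {
  cat("VJP motion parameters\n")
  cat(sprintf("  reorientation rate lambda: %g s^-1\n", x$lambda))
  cat(sprintf("  speed c:                   %g um s^-1\n", x$speed))
  cat(sprintf("  kernel:                    %s%s\n", x$kernel,
              if (x$kernel == "wrapped_normal")
                sprintf(" (gamma = %g rad)", x$gamma) else ""))
  invisible(x)
}

## Draw n turning angles from the reorientation kernel.
draw_turns <- function(params, n) {
  if (n == 0) return(numeric(0))
  switch(params$kernel,
         uniform = stats::runif(n, -pi, pi),
         wrapped_normal = wrap_angle(stats::rnorm(n, 0, params$gamma)))
}

#' Simulate a velocity jump process trajectory in continuous time
#'
#' Exact event-driven simulation: run durations are i.i.d.
#' exponential(`lambda`), reorientations are instantaneous, and each new
#' heading is the previous heading plus a kernel draw, wrapped to
#' \eqn{[-\pi,\pi)}. The final run is truncated at `t_final`. With
#' `lambda = 0` the trajectory is a single straight run.
#'
#' @param params a [vjp_params] object.
#' @param t_final total duration of the trajectory, seconds (`> 0`).
#' @param seed optional integer seed.
#' @return an object of class `vjp_trajectory` with components
#'   `event_times` (strictly increasing reorientation times in
#'   `(0, t_final)`), `headings` (one per run, length
#'   `length(event_times) + 1`), `event_positions` (positions at the
#'   reorientation times, a matrix with columns `x`, `y`), `start`,
#'   `end` (position at `t_final`), `t_final` and `params`.
#' @examples
#' traj <- simulate_trajectory(vjp_params(0.2, 50), t_final = 64, seed = 1)
#' length(traj$event_times)
#' @export
simulate_trajectory <- function(params, t_final, seed = NULL) {
  stopifnot(inherits(params, "vjp_params"), t_final > 0)
  set_seed_if(seed)
  lambda <- params$lambda
  ## draw exponential run times in batches until the path covers t_final
  times <- numeric(0)
  if (lambda > 0) {
    total <- 0
    batch <- max(16L, ceiling(lambda * t_final + 6 * sqrt(lambda * t_final)))
    repeat {
      gaps <- stats::rexp(batch, lambda)
      times <- c(times, total + cumsum(gaps))
      total <- times[length(times)]
      if (total > t_final) break
    }
    times <- times[times < t_final]
  }
  n_ev <- length(times)
  headings <- wrap_angle(params$initial_heading + c(0, cumsum(draw_turns(params, n_ev))))
  ## piecewise-linear path: segment i runs at headings[i] for durations[i]
  knots <- c(0, times, t_final)
  durations <- diff(knots)
  dx <- params$speed * durations * cos(headings)
  dy <- params$speed * durations * sin(headings)
  xs <- cumsum(c(0, dx))
  ys <- cumsum(c(0, dy))
  ev_pos <- cbind(x = xs[seq_len(n_ev) + 1], y = ys[seq_len(n_ev) + 1])
  structure(list(event_times = times, headings = headings,
                 event_positions = ev_pos,
                 start = c(x = 0, y = 0),
                 end = c(x = xs[length(xs)], y = ys[length(ys)]),
                 knot_times = knots, knot_x = xs, knot_y = ys,
                 t_final = t_final, params = params),
            class = "vjp_trajectory")
}

#' @export
print.vjp_trajectory <- function(x, ...) {
  cat(sprintf("VJP trajectory: %d reorientations over %g s (lambda = %g, c = %g)\n",
              length(x$event_times), x$t_final, x$params$lambda, x$params$speed))
  invisible(x)
}

#' Observation grid for discrete sampling of a trajectory
#'
#' @param dt sampling interval, seconds (`> 0`).
#' @param n_obs observation count `T`, so that positions are recorded at
#'   times `0, dt, ..., T * dt`; at least 3 (two direction estimates, one
#'   angle change).
#' @return an object of class `observation_grid`.
#' @export
observation_grid <- function(dt, n_obs) {
  stopifnot(dt > 0, n_obs >= 3, n_obs == round(n_obs))
  structure(list(dt = dt, n_obs = as.integer(n_obs)), class = "observation_grid")
}

#' Observe trajectory positions at fixed intervals
#'
#' Positions at times \eqn{k\Delta t}, \eqn{k = 0, \dots, T}, obtained by
#' linear interpolation along the piecewise-linear continuous path.
#'
#' @param traj a [simulate_trajectory] result.
#' @param grid an [observation_grid]; must not extend past `traj$t_final`.
#' @return a matrix with `grid$n_obs + 1` rows and columns `t`, `x`, `y`.
#' @export
observe_positions <- function(traj, grid) {
  stopifnot(inherits(traj, "vjp_trajectory"), inherits(grid, "observation_grid"))
  t_obs <- (0:grid$n_obs) * grid$dt
  if (t_obs[length(t_obs)] > traj$t_final + 1e-9)
    stop("observation grid extends past the end of the trajectory")
  x <- stats::approx(traj$knot_times, traj$knot_x, xout = t_obs, rule = 2)$y
  y <- stats::approx(traj$knot_times, traj$knot_y, xout = t_obs, rule = 2)$y
  cbind(t = t_obs, x = x, y = y)
}

#' Observed angle-change series
#'
#' Container for the observed angle changes \eqn{z_k \in [-\pi,\pi)} of a
#' discretely observed trajectory at fixed interval `dt`, with optional
#' ground truth carried along by the synthetic-data generator.
#'
#' @param values numeric vector of angle changes, radians in
#'   \eqn{[-\pi,\pi)}.
#' @param dt sampling interval, seconds.
#' @param sigma wrapped-normal noise s.d. used to generate the series
#'   (radians), if synthetic; `NA` if unknown.
#' @param theta_true optional noiseless angle changes (same length).
#' @param states_true optional true binary hidden states per interval
#'   (length `length(values) + 1`: one per observation interval).
#' @param event_counts optional true per-interval reorientation counts
#'   (same length as `states_true`).
#' @return an object of class `angle_series`.
#' @export
angle_series <- function(values, dt, sigma = NA_real_, theta_true = NULL,
                         states_true = NULL, event_counts = NULL) {
  stopifnot(is.numeric(values), dt > 0,
            all(values >= -pi & values < pi))
  if (!is.null(theta_true)) stopifnot(length(theta_true) == length(values))
  if (!is.null(states_true)) stopifnot(length(states_true) == length(values) + 1)
  if (!is.null(event_counts)) stopifnot(length(event_counts) == length(values) + 1)
  structure(list(values = as.numeric(values), dt = dt, sigma = sigma,
                 theta_true = theta_true, states_true = states_true,
                 event_counts = event_counts),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("Angle-change series: %d values at dt = %g s%s\n",
              length(x$values), x$dt,
              if (is.finite(x$sigma)) sprintf(" (noise sd %g rad)", x$sigma) else ""))
  invisible(x)
}

#' Extract observed angle changes from a position sequence
#'
#' Directions of travel are computed with the full-quadrant arctangent of
#' successive displacements; each angle change is the wrapped difference of
#' consecutive directions.
#'
#' @param positions a matrix of observed positions with columns `x`, `y`
#'   (and optionally `t`), at least 3 rows, no two consecutive positions
#'   identical.
#' @param dt sampling interval, seconds; inferred from the `t` column when
#'   present.
#' @return an [angle_series] (noiseless: `sigma = 0`).
#' @examples
#' pos <- cbind(x = c(0, 1, 1), y = c(0, 0, 1))
#' extract_angle_changes(pos, dt = 1)$values  # pi/2
#' @export
extract_angle_changes <- function(positions, dt = NULL) {
  positions <- as.matrix(positions)
  if (is.null(dt)) {
    if (!"t" %in% colnames(positions))
      stop("provide `dt` or a `t` column")
    dt <- stats::median(diff(positions[, "t"]))
  }
  x <- positions[, "x"]
  y <- positions[, "y"]
  if (length(x) < 3) stop("need at least 3 positions for one angle change")
  ddx <- diff(x)
  ddy <- diff(y)
  if (any(ddx == 0 & ddy == 0))
    stop("coincident consecutive positions: zero displacement has no direction")
  dirs <- atan2(ddy, ddx)
  z <- wrap_angle(diff(dirs))
  angle_series(z, dt = dt, sigma = 0, theta_true = z)
}

#' Add wrapped-normal measurement noise to an angle series
#'
#' Each observed value becomes \eqn{z_k = \mathrm{wrap}(\theta_k +
#' \epsilon_k)} with \eqn{\epsilon_k} i.i.d. normal\eqn{(0, \sigma^2)},
#' independent across `k`.
#'
#' @param series an [angle_series].
#' @param sigma noise standard deviation, radians (`>= 0`).
#' @param seed optional integer seed.
#' @return an [angle_series] with noisy `values`, `sigma` set, and the
#'   input's noiseless values retained in `theta_true`.
#' @export
add_measurement_noise <- function(series, sigma, seed = NULL) {
  stopifnot(inherits(series, "angle_series"), sigma >= 0)
  set_seed_if(seed)
  theta <- if (!is.null(series$theta_true)) series$theta_true else series$values
  z <- if (sigma == 0) theta else
    wrap_angle(theta + stats::rnorm(length(theta), 0, sigma))
  angle_series(z, dt = series$dt, sigma = sigma, theta_true = theta,
               states_true = series$states_true,
               event_counts = series$event_counts)
}

#' Count reorientation events per observation interval
#'
#' Counts the reorientation times falling in each interval
#' \eqn{[k\Delta t, (k+1)\Delta t)} and the implied binary hidden states
#' \eqn{X_k = 1} iff at least one event occurred.
#'
#' @param traj a [simulate_trajectory] result.
#' @param grid an [observation_grid].
#' @return a list with integer vector `counts` (length `grid$n_obs`) and
#'   binary vector `states`.
#' @export
interval_event_counts <- function(traj, grid) {
  stopifnot(inherits(traj, "vjp_trajectory"), inherits(grid, "observation_grid"))
  if (grid$n_obs * grid$dt > traj$t_final + 1e-9)
    stop("observation grid extends past the end of the trajectory")
  breaks <- (0:grid$n_obs) * grid$dt
  counts <- if (length(traj$event_times) == 0) integer(grid$n_obs) else
    tabulate(findInterval(traj$event_times, breaks, left.open = FALSE),
             nbins = grid$n_obs)
  list(counts = as.integer(counts), states = as.integer(counts >= 1))
}

#' Simulate a complete synthetic angle-change dataset
#'
#' Convenience generator chaining [simulate_trajectory],
#' [observe_positions], [extract_angle_changes] and
#' [add_measurement_noise], attaching the true hidden states.
#'
#' @param params a [vjp_params] object.
#' @param dt sampling interval, seconds.
#' @param t_final total duration, seconds (`t_final / dt` observations).
#' @param sigma measurement noise s.d., radians.
#' @param seed optional integer seed.
#' @return an [angle_series] with ground truth attached, plus the observed
#'   positions in attribute `"positions"`.
#' @examples
#' z <- simulate_angle_dataset(vjp_params(0.2, 50), dt = 1, t_final = 64,
#'                             sigma = 0.04, seed = 1)
#' @export
simulate_angle_dataset <- function(params, dt, t_final, sigma, seed = NULL) {
  set_seed_if(seed)
  n_obs <- floor(t_final / dt + 1e-9)
  stopifnot(n_obs >= 3)
  grid <- observation_grid(dt, n_obs)
  traj <- simulate_trajectory(params, t_final)
  pos <- observe_positions(traj, grid)
  ev <- interval_event_counts(traj, grid)
  s <- extract_angle_changes(pos, dt = dt)
  ## angle change k compares intervals k and k+1; states_true has one entry
  ## per interval (n_obs of them), trimmed to the n_values + 1 involved
  n_val <- length(s$values)
  s$states_true <- ev$states[seq_len(n_val + 1)]
  s$event_counts <- ev$counts[seq_len(n_val + 1)]
  out <- add_measurement_noise(s, sigma)
  attr(out, "positions") <- pos
  attr(out, "params") <- params
  out
}
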