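## Rejection ABC for (lambda, sigma) with three summary statistics: the full
## angle-change series, a threshold exceedance count, and a transition-matrix
## binning of consecutive angle-change pairs. Acceptance is quantile-based
## (keep the closest fraction), matching the reference procedure; the
## implied tolerance (largest accepted distance) is reported.

#' Summary statistic specification for ABC
#'
#' @param variant `"full_series"` (the angle-change vector itself),
#'   `"threshold_count"` (number of changes with magnitude above `h`), or
#'   `"transition_matrix"` (flattened `n_bins` x `n_bins` count matrix of
#'   consecutive change pairs, equal-width bins on \eqn{[-\pi,\pi)}).
#' @param h threshold, radians (`> 0`); default 0.1.
#' @param n_bins transition-matrix bin count (`>= 2`); default 5.
#' @return an object of class `summary_statistic`.
#' @export
summary_statistic <- function(variant = c("full_series", "threshold_count",
                                          "transition_matrix"),
                              h = 0.1, n_bins = 5) {
  variant <- match.arg(variant)
  stopifnot(h > 0, n_bins >= 2, n_bins == round(n_bins))
  structure(list(variant = variant, h = h, n_bins = as.integer(n_bins)),
            class = "summary_statistic")
}

#' Compute a summary statistic of an angle-change series
#'
#' @param z an [angle_series] or numeric vector of angle changes.
#' @param stat a [summary_statistic].
#' @return numeric vector: the series itself, a scalar exceedance count,
#'   or the flattened transition-count matrix (entries sum to
#'   `length(z) - 1`).
#' @examples
#' abc_summary(c(0.05, 0.2, -0.15, 0), summary_statistic("threshold_count"))
#' @export
abc_summary <- function(z, stat) {
  stopifnot(inherits(stat, "summary_statistic"))
  zv <- series_values(z)
  if (length(zv) == 0) stop("empty series")
  switch(stat$variant,
         full_series = zv,
         threshold_count = sum(abs(zv) > stat$h),
         transition_matrix = {
           if (length(zv) < 2)
             stop("transition matrix needs a series of length >= 2")
           b <- findInterval(zv, seq(-pi, pi, length.out = stat$n_bins + 1),
                             rightmost.closed = TRUE)
           n <- length(zv)
           counts <- table(factor(b[-n], levels = seq_len(stat$n_bins)),
                           factor(b[-1], levels = seq_len(stat$n_bins)))
           as.numeric(counts)
         })
}

## Lean internal simulator of one synthetic angle series (numeric vector),
## used inside the ABC loop: exponential event times, kernel turns,
## piecewise-linear discretisation, wrapped-normal noise.
sim_angle_values <- function(lambda, sigma, speed, dt, n_obs,
                             kernel = "uniform", gamma = NULL) {
  t_final <- n_obs * dt
  times <- numeric(0)
  if (lambda > 0) {
    total <- 0
    batch <- max(16L, ceiling(lambda * t_final + 6 * sqrt(lambda * t_final)))
    repeat {
      times <- c(times, total + cumsum(stats::rexp(batch, lambda)))
      total <- times[length(times)]
      if (total > t_final) break
    }
    times <- times[times < t_final]
  }
  n_ev <- length(times)
  turns <- if (kernel == "uniform") stats::runif(n_ev, -pi, pi) else
    wrap_angle(stats::rnorm(n_ev, 0, gamma))
  headings <- c(0, cumsum(turns))
  knots <- c(0, times, t_final)
  dur <- diff(knots)
  xs <- cumsum(c(0, speed * dur * cos(headings)))
  ys <- cumsum(c(0, speed * dur * sin(headings)))
  t_obs <- (0:n_obs) * dt
  x <- stats::approx(knots, xs, xout = t_obs, rule = 2)$y
  y <- stats::approx(knots, ys, xout = t_obs, rule = 2)$y
  dirs <- atan2(diff(y), diff(x))
  theta <- wrap_angle(diff(dirs))
  if (sigma > 0) wrap_angle(theta + stats::rnorm(length(theta), 0, sigma))
  else theta
}

#' Rejection ABC for the reorientation rate and noise amplitude
#'
#' Draws `(lambda, sigma)` pairs from the log-uniform prior, simulates a
#' full synthetic trajectory per draw with the observed series' `dt` and
#' duration (multiple events per interval arise naturally), computes the
#' Euclidean distance between summary statistics of the simulated and
#' observed series, and keeps the closest fraction of draws.
#'
#' Several summary statistics may be supplied at once; each reuses the same
#' simulations, so the returned results differ only in the acceptance set.
#'
#' @param z_obs the observed [angle_series].
#' @param prior a [log_uniform_prior].
#' @param speed running speed used in the simulator, micrometres/second.
#' @param n_sims number of prior simulations.
#' @param keep_fraction fraction of closest draws accepted (default 0.001);
#'   `floor(keep_fraction * n_sims)` must be at least 10.
#' @param stats_list a [summary_statistic] or list of them.
#' @param seed optional integer seed.
#' @param kernel,gamma generating reorientation kernel for the simulator.
#' @return an `abc_result` (or named list of them, one per statistic):
#'   `samples` (accepted `(lambda, sigma)` on the natural scale),
#'   `distances`, `tolerance` (largest accepted distance), `stat`, `seed`.
#' @export
abc_rejection <- function(z_obs, prior = log_uniform_prior(), speed = 50,
                          n_sims = 1e6, keep_fraction = 0.001,
                          stats_list = summary_statistic("transition_matrix"),
                          seed = NULL, kernel = "uniform", gamma = NULL) {
  stopifnot(inherits(z_obs, "angle_series"), keep_fraction > 0,
            keep_fraction <= 1)
  n_keep <- floor(keep_fraction * n_sims)
  if (n_keep < 10)
    stop("keep_fraction * n_sims must be at least 10 accepted samples")
  if (inherits(stats_list, "summary_statistic")) stats_list <- list(stats_list)
  set_seed_if(seed)
  n_obs <- length(z_obs$values) + 1  # intervals; values = intervals - 1
  obs_summaries <- lapply(stats_list, function(s) abc_summary(z_obs, s))
  n_stat <- length(stats_list)
  th <- cbind(stats::runif(n_sims, prior$log_lambda[1], prior$log_lambda[2]),
              stats::runif(n_sims, prior$log_sigma[1], prior$log_sigma[2]))
  D <- matrix(NA_real_, n_sims, n_stat)
  for (i in seq_len(n_sims)) {
    zi <- sim_angle_values(exp(th[i, 1]), exp(th[i, 2]), speed, z_obs$dt,
                           n_obs, kernel, gamma)
    for (s in seq_len(n_stat)) {
      ssim <- abc_summary(zi, stats_list[[s]])
      D[i, s] <- sqrt(sum((ssim - obs_summaries[[s]])^2))
    }
  }
  results <- lapply(seq_len(n_stat), function(s) {
    ord <- order(D[, s])[seq_len(n_keep)]
    structure(list(samples = cbind(lambda = exp(th[ord, 1]),
                                   sigma = exp(th[ord, 2])),
                   log_samples = th[ord, , drop = FALSE],
                   distances = D[ord, s],
                   tolerance = max(D[ord, s]),
                   stat = stats_list[[s]], n_sims = n_sims,
                   keep_fraction = keep_fraction, seed = seed),
              class = "abc_result")
  })
  names(results) <- vapply(stats_list, function(s) s$variant, character(1))
  if (n_stat == 1) results[[1]] else results
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf(paste0("ABC rejection: %d accepted of %d simulations ",
                     "(%s statistic), tolerance %.3g\n"),
              nrow(x$samples), x$n_sims, x$stat$variant, x$tolerance))
  cat(sprintf("  lambda median %.4g, sigma median %.4g\n",
              stats::median(x$samples[, "lambda"]),
              stats::median(x$samples[, "sigma"])))
  invisible(x)
}

#' Write ABC results to delimited text with JSON metadata
#'
#' @param x an `abc_result`.
#' @param path output CSV path (columns lambda, sigma, distance); metadata
#'   goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_abc_result <- function(x, path) {
  stopifnot(inherits(x, "abc_result"))
  utils::write.csv(data.frame(lambda = x$samples[, "lambda"],
                              sigma = x$samples[, "sigma"],
                              distance = x$distances),
                   path, row.names = FALSE)
  meta <- list(statistic = x$stat$variant, h = x$stat$h,
               n_bins = x$stat$n_bins, n_sims = x$n_sims,
               keep_fraction = x$keep_fraction, tolerance = x$tolerance,
               seed = x$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
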