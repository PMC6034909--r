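## Emission densities for the observed angle change of a discretely observed
## velocity jump process, conditional on the hidden-state pattern (i, j) of
## the previous and current observation intervals:
##   p00 = delta at 0 (no reorientation, no noise)
##   p01 = marginal density of the observed change when the only event is in
##         the current interval
##   p10 = conditional density of the correction angle given the previous
##         observed change theta1
##   p11 = circular convolution of p10(.|theta1) with p01
## and their wrapped-normal noise convolutions q_ij. The inference model
## always assumes a uniform reorientation kernel; all closed forms below are
## for that kernel and are independent of the speed c and the interval dt.

#' Hidden-state transition probability
#'
#' Probability that at least one reorientation occurs in an observation
#' interval of length `dt`, for exponential run times at rate `lambda`:
#' \eqn{\beta = 1 - e^{-\lambda \Delta t}}.
#'
#' @param lambda reorientation rate, per second (`>= 0`).
#' @param dt observation interval, seconds (`> 0`).
#' @return probability in `[0, 1)`.
#' @examples
#' transition_probability(0.2, 1)  # 0.1812692
#' @export
transition_probability <- function(lambda, dt) {
  stopifnot(all(lambda >= 0), all(dt > 0))
  1 - exp(-lambda * dt)
}

#' Wrapped-normal density on the circle
#'
#' Density of a normal\eqn{(0, \sigma^2)} variable reduced modulo
#' \eqn{2\pi} onto \eqn{[-\pi, \pi)}, evaluated by summing wrap images
#' \eqn{|k| \le \lceil 3\sigma/2\pi \rceil + 1}.
#'
#' @param x angles, radians.
#' @param sigma pre-wrap standard deviation, radians (`> 0`).
#' @param mean centre of the distribution, radians.
#' @return density per radian.
#' @export
dwrapnorm <- function(x, sigma, mean = 0) {
  stopifnot(sigma > 0)
  x <- wrap_angle(x - mean)
  K <- ceiling(3 * sigma / (2 * pi)) + 1
  out <- 0
  for (k in -K:K) out <- out + stats::dnorm(x + 2 * pi * k, 0, sigma)
  out
}

## Exact bin masses of the wrapped normal on circle_grid(G), via normal CDF
## differences summed over wrap images.
wrapnorm_masses <- function(G, sigma) {
  stopifnot(sigma > 0)
  grid <- circle_grid(G)
  edges <- c(grid$theta - grid$dtheta / 2, pi - grid$dtheta / 2)
  K <- ceiling(4 * sigma / (2 * pi)) + 2
  cdf <- 0
  for (k in -K:K) cdf <- cdf + stats::pnorm(edges + 2 * pi * k, 0, sigma)
  diff(cdf)
}

#' Marginal density of the observed angle change after a single reorientation
#'
#' Closed-form density of the observed angle change for the hidden-state
#' pattern (0, 1) under a uniform reorientation kernel:
#' \deqn{f(\theta) = -\frac{\cos\theta + \log(1 - \cos\theta)}{2\pi
#'   \cos^2\theta},}
#' independent of the speed and the observation interval. The removable
#' singularity at \eqn{|\theta| = \pi/2} is evaluated by a series in
#' \eqn{u = \cos\theta}; the integrable log divergence at \eqn{\theta = 0}
#' returns `Inf` there.
#'
#' @param theta angles in \eqn{[-\pi, \pi]}, radians.
#' @return density per radian.
#' @examples
#' theta1_density(pi)      # (1 - log(2)) / (2 * pi)
#' theta1_density(pi / 2)  # 1 / (4 * pi)
#' @export
theta1_density <- function(theta) {
  if (any(abs(theta) > pi)) stop("theta must lie in [-pi, pi]")
  u <- cos(theta)
  out <- numeric(length(theta))
  near <- abs(u) < 1e-4
  ## series: -(u + log(1-u)) / u^2 = 1/2 + u/3 + u^2/4 + u^3/5 + ...
  out[near] <- (0.5 + u[near] / 3 + u[near]^2 / 4 + u[near]^3 / 5) / (2 * pi)
  uf <- u[!near]
  out[!near] <- -(uf + log1p(-uf)) / (2 * pi * uf^2)
  out[theta == 0] <- Inf
  out
}

#' Joint density of the radial-coordinate displacement and observed angle
#'
#' Joint density of the chord length `r` and the observed angle change
#' for a single reorientation in an interval of length `dt` at speed
#' `speed`, under a uniform reorientation kernel:
#' \eqn{f(r, \theta_1) = r / (2\pi c\Delta t (c\Delta t - r\cos\theta_1))}
#' for \eqn{0 \le r \le c\Delta t}, 0 otherwise. Integrating over `r`
#' recovers [theta1_density], which is the standard cross-check.
#'
#' @param r chord length, micrometres.
#' @param theta1 observed angle change, radians.
#' @param speed running speed, micrometres per second.
#' @param dt observation interval, seconds.
#' @return density.
#' @export
joint_r_theta1_density <- function(r, theta1, speed, dt) {
  cdt <- speed * dt
  out <- r / (2 * pi * cdt * (cdt - r * cos(theta1)))
  out[r < 0 | r > cdt] <- 0
  out
}

#' Joint density of consecutive observed angle changes around one event
#'
#' Joint density of the observed angle change \eqn{\theta_1} in the interval
#' containing a reorientation and the correction angle \eqn{\theta_2}
#' observed in the following (event-free) interval, under a uniform
#' reorientation kernel. With \eqn{\phi = \theta_1 + \theta_2} the true
#' turning angle, the density is
#' \deqn{\frac{|\sin\phi|}{2\pi(\sin\phi\cos\theta_1 +
#'   \sin\theta_1(1 - \cos\phi))^2}}
#' on the geometric support where \eqn{\theta_1} lies between 0 and
#' \eqn{\phi} and \eqn{\phi \in [-\pi, \pi)}; 0 elsewhere.
#'
#' @param theta1,theta2 angles in \eqn{[-\pi, \pi)}, radians (recycled).
#' @return density.
#' @export
joint_theta1_theta2_density <- function(theta1, theta2) {
  n <- max(length(theta1), length(theta2))
  theta1 <- rep_len(theta1, n)
  theta2 <- rep_len(theta2, n)
  phi <- theta1 + theta2
  d <- sin(phi) * cos(theta1) + sin(theta1) * (1 - cos(phi))
  out <- abs(sin(phi)) / (2 * pi * d^2)
  ## support: phi in [-pi, pi) and theta1 between 0 and phi
  ok <- phi >= -pi & phi < pi &
    ((theta1 >= 0 & theta2 >= 0) | (theta1 <= 0 & theta2 <= 0)) &
    d != 0
  out[!ok] <- 0
  out
}

#' Conditional density of the correction angle given the previous change
#'
#' The emission density for the hidden-state pattern (1, 0):
#' the correction angle \eqn{\theta_2} observed in an event-free interval
#' immediately after an interval whose observed angle change was
#' `theta1`. Computed as [joint_theta1_theta2_density] divided by
#' [theta1_density] at `theta1`.
#'
#' @param theta2 angles at which to evaluate, radians.
#' @param theta1 conditioning observed angle change, radians; values with
#'   magnitude below `1e-4` are clamped (the conditional degenerates as
#'   `theta1` approaches 0).
#' @return density per radian.
#' @export
conditional_theta2_density <- function(theta2, theta1) {
  stopifnot(length(theta1) == 1, abs(theta1) <= pi)
  theta1 <- clamp_theta1(theta1)
  joint_theta1_theta2_density(theta1, theta2) / theta1_density(theta1)
}

clamp_theta1 <- function(theta1) {
  if (abs(theta1) < 1e-4) theta1 <- if (theta1 < 0) -1e-4 else 1e-4
  theta1
}

## ---- gridded bin masses -------------------------------------------------

## 7-point Gauss-Legendre nodes/weights on [-1, 1]
.gl7 <- list(
  x = c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
        0.4058451513773972, 0.7415311855993945, 0.9491079123427585),
  w = c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
        0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
        0.1294849661688697))

## Gauss-Legendre bin masses of a vectorized density over circle_grid(G).
gl_bin_masses <- function(f, G) {
  grid <- circle_grid(G)
  h <- grid$dtheta / 2
  m <- numeric(G)
  for (k in seq_along(.gl7$x)) {
    m <- m + .gl7$w[k] * f(grid$theta + h * .gl7$x[k])
  }
  m * h
}

## Adaptive re-integration of selected bins (singularities, support edges).
refine_bins <- function(m, f, G, centers, split_at = numeric(0)) {
  grid <- circle_grid(G)
  h <- grid$dtheta / 2
  for (j in centers) {
    lo <- grid$theta[j] - h
    hi <- grid$theta[j] + h
    cuts <- sort(unique(c(lo, hi, split_at[split_at > lo & split_at < hi])))
    tot <- 0
    for (i in seq_len(length(cuts) - 1)) {
      tot <- tot + tryCatch(
        stats::integrate(f, cuts[i], cuts[i + 1], rel.tol = 1e-9,
                         abs.tol = 1e-12, subdivisions = 400L)$value,
        error = function(e) {
          ## fall back to midpoint on a fine sub-grid if the adaptive rule
          ## stalls on the singular bin
          xs <- seq(cuts[i], cuts[i + 1], length.out = 4001)
          xs <- (xs[-1] + xs[-length(xs)]) / 2
          mean(f(xs)) * (cuts[i + 1] - cuts[i])
        })
    }
    m[j] <- tot
  }
  m
}

## Bin masses of p01 = theta1_density on circle_grid(G). The bins within
## two cells of the log divergence at 0 are integrated adaptively.
theta1_bin_masses <- function(G) {
  grid <- circle_grid(G)
  f <- function(x) theta1_density(wrap_angle(x))
  m <- gl_bin_masses(f, G)
  near0 <- which(abs(grid$theta) <= 2 * grid$dtheta + 1e-12)
  refine_bins(m, f, G, near0, split_at = 0)
}

## Bin masses of p10(. | theta1) on circle_grid(G). Support-edge bins (the
## boundary at theta2 = 0 and at the |phi| = pi edge) are integrated
## adaptively; for small |theta1| the density has integrable spikes at both
## edges.
p10_bin_masses <- function(theta1, G) {
  theta1 <- clamp_theta1(theta1)
  grid <- circle_grid(G)
  f <- function(x) conditional_theta2_density(wrap_angle(x), theta1)
  m <- gl_bin_masses(f, G)
  edge <- if (theta1 > 0) pi - theta1 else -pi - theta1
  sel <- which(abs(grid$theta) <= 2 * grid$dtheta + 1e-12 |
                 abs(grid$theta - edge) <= 2 * grid$dtheta + 1e-12)
  refine_bins(m, f, G, sel, split_at = c(0, edge))
}

#' Density of the observed angle change after two consecutive reorientations
#'
#' The emission density for the hidden-state pattern (1, 1): the observed
#' change is the sum (on the circle) of the correction angle for the
#' previous event and a fresh single-event angle change, so its density is
#' the circular convolution of [conditional_theta2_density] given `theta1`
#' with [theta1_density]. Evaluated on an internal grid of `G` bins and
#' interpolated.
#'
#' @param theta angles at which to evaluate, radians.
#' @param theta1 previous observed angle change, radians.
#' @param G grid size (power of two).
#' @return density per radian.
#' @export
double_reorientation_density <- function(theta, theta1, G = 4096) {
  m <- clean_masses(conv_masses(theta1_bin_masses(G), p10_bin_masses(theta1, G)))
  interp_density(m, theta)
}

## ---- emission tables ----------------------------------------------------

#' Gridded emission densities with and without measurement noise
#'
#' Builds all emission densities for the observed angle change on a grid of
#' `G` equispaced bins on \eqn{[-\pi, \pi)}: the noiseless densities
#' `p01`, `p10`, `p11` (conditioned on the previous observed change
#' `theta1`), and their circular convolutions `q01`, `q10`, `q11` with a
#' wrapped-normal noise kernel of s.d. `sigma`; `q00` is the wrapped-normal
#' density itself. Densities are stored as bin masses obtained by
#' per-bin quadrature of the closed forms (this tames the integrable log
#' singularity of `p01` at 0), convolved spectrally, clipped and
#' renormalized.
#'
#' With `sigma = 0` the noisy densities equal the noiseless ones and the
#' (0,0) emission is a point mass at 0, flagged in `point_mass`.
#'
#' @param lambda reorientation rate, per second.
#' @param dt observation interval, seconds.
#' @param sigma measurement noise s.d., radians (`>= 0`).
#' @param theta1 previous observed angle change conditioning `p10`/`p11`,
#'   radians.
#' @param G grid size: a power of two, at least 256.
#' @return an object of class `emission_table` with the angle grid, bin
#'   masses (`*_mass`), densities, the transition probability `beta`, and
#'   `lambda_dt`.
#' @examples
#' tab <- emission_table(0.2, 1, sigma = 0.04, theta1 = 0.1, G = 512)
#' sum(tab$q01_mass)  # 1
#' @export
emission_table <- function(lambda, dt, sigma, theta1, G = 4096) {
  stopifnot(sigma >= 0, G >= 256, bitwAnd(G, G - 1L) == 0)
  grid <- circle_grid(G)
  p01 <- theta1_bin_masses(G)
  p10 <- p10_bin_masses(theta1, G)
  p11 <- clean_masses(conv_masses(p01, p10))
  if (sigma > 0) {
    wn <- wrapnorm_masses(G, sigma)
    q00 <- clean_masses(wn)
    q01 <- clean_masses(conv_masses(p01, wn))
    q10 <- clean_masses(conv_masses(p10, wn))
    q11 <- clean_masses(conv_masses(p11, wn))
    point_mass <- FALSE
  } else {
    q00 <- numeric(G)
    q00[which.min(abs(grid$theta))] <- 1
    q01 <- p01
    q10 <- p10
    q11 <- p11
    point_mass <- TRUE
  }
  structure(list(theta = grid$theta, dtheta = grid$dtheta, G = G,
                 p01_mass = p01, p10_mass = p10, p11_mass = p11,
                 q00_mass = q00, q01_mass = q01, q10_mass = q10,
                 q11_mass = q11,
                 beta = transition_probability(lambda, dt),
                 lambda_dt = lambda * dt, sigma = sigma, theta1 = theta1,
                 point_mass = point_mass),
            class = "emission_table")
}

#' @export
print.emission_table <- function(x, ...) {
  cat(sprintf(paste0("Emission table: G = %d, lambda*dt = %g, beta = %.4f, ",
                     "sigma = %g, theta1 = %g%s\n"),
              x$G, x$lambda_dt, x$beta, x$sigma, x$theta1,
              if (x$point_mass) " (q00 is a point mass)" else ""))
  invisible(x)
}

#' @export
as.data.frame.emission_table <- function(x, ...) {
  d <- x$dtheta
  data.frame(theta = x$theta,
             p01 = x$p01_mass / d, p10 = x$p10_mass / d, p11 = x$p11_mass / d,
             q00 = if (x$point_mass) ifelse(x$q00_mass > 0, Inf, 0) else
               x$q00_mass / d,
             q01 = x$q01_mass / d, q10 = x$q10_mass / d, q11 = x$q11_mass / d)
}

#' Write an emission table to delimited text
#'
#' @param x an [emission_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_emission_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Analytic bin masses of an emission density on a coarse histogram grid
#'
#' Integrates the noiseless emission density for a hidden-state pattern
#' over `bins` equal-width bins on \eqn{[-\pi, \pi)}, by aggregating a fine
#' internal grid. Used to compare analytic densities against Monte Carlo
#' histograms.
#'
#' @param pattern hidden-state pattern: `"01"`, `"10"` or `"11"`.
#' @param theta1 previous observed angle change (required for `"10"` and
#'   `"11"`).
#' @param bins number of histogram bins.
#' @param fine fine grid size used internally.
#' @return numeric vector of `bins` masses summing to ~1.
#' @export
emission_bin_masses <- function(pattern = c("01", "10", "11"), theta1 = NULL,
                                bins = 64, fine = 4096) {
  pattern <- match.arg(pattern)
  if (pattern != "01" && is.null(theta1))
    stop("theta1 is required for patterns 10 and 11")
  m <- switch(pattern,
              "01" = theta1_bin_masses(fine),
              "10" = p10_bin_masses(theta1, fine),
              "11" = clean_masses(conv_masses(theta1_bin_masses(fine),
                                              p10_bin_masses(theta1, fine))))
  grid <- circle_grid(fine)
  idx <- findInterval(grid$theta, seq(-pi, pi, length.out = bins + 1),
                      rightmost.closed = TRUE)
  as.numeric(tapply(m, factor(idx, levels = seq_len(bins)), sum, default = 0))
}

## ---- Monte Carlo oracle -------------------------------------------------

## Observed angle change for a single reorientation at time u within an
## interval of length dt at speed c, turning through phi: the chord of a
## two-leg path with legs c*u and c*(dt-u).
single_event_obs_angle <- function(u, phi, speed, dt) {
  l <- speed * u
  a <- speed * dt - l
  atan2(a * sin(phi), l + a * cos(phi))
}

#' Monte Carlo oracle for the emission densities
#'
#' Simulates observation intervals with a requested hidden-state pattern by
#' direct construction — given a single reorientation in an interval, its
#' time is uniform on the interval (the exact conditional for a Poisson
#' event process) and its turning angle is a kernel draw — and returns a
#' normalized histogram of the observed angle change. Patterns conditioning
#' on previous observed change(s) retain only draws whose simulated
#' previous observed change(s) fall within `tol` of the stated values; a
#' stated change two intervals back implies an event there too, and that
#' stage is rejection-sampled first, with accepted draws resampled and
#' paired with fresh downstream draws.
#'
#' This simulation route shares no code with the closed-form densities and
#' serves as their independent check; run with a wrapped-normal kernel it
#' also quantifies model misspecification.
#'
#' @param params a [vjp_params] (the kernel and speed are used; the event
#'   time within the interval is uniform by conditioning, so `lambda` does
#'   not enter).
#' @param dt observation interval, seconds.
#' @param pattern hidden-state pattern: `"01"`, `"10"` or `"11"`.
#' @param cond conditioning observed angle change(s), radians, earliest
#'   first: one value for `"10"` and `"11"` (the previous observed change),
#'   optionally two for `"11"` (the change before that, then the previous).
#'   Conditioning follows the model's clean-history assumption (the
#'   pattern-0,1,0 convention for observing the previous change directly):
#'   the previous observed change equals the single-event observed angle of
#'   the previous interval, and a stated change two intervals back is the
#'   correction angle of an event one interval earlier still (no event two
#'   intervals back), simulated and windowed to confirm feasibility.
#' @param n number of simulated replicates (`>= 1e4`).
#' @param seed optional integer seed.
#' @param bins histogram bin count.
#' @param tol half-width of the conditioning window, radians.
#' @return a list with `breaks`, `density`, `counts`, `n_accepted`, and the
#'   accepted `samples`.
#' @export
mc_emission_oracle <- function(params, dt, pattern = c("01", "10", "11"),
                               cond = NULL, n = 1e6, seed = NULL, bins = 64,
                               tol = 0.04) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(params, "vjp_params"), n >= 1e4)
  set_seed_if(seed)
  cc <- params$speed
  draw_uphi <- function(m) {
    list(u = stats::runif(m, 0, dt), phi = draw_turns(params, m))
  }
  samples <- switch(
    pattern,
    "01" = {
      d <- draw_uphi(n)
      single_event_obs_angle(d$u, d$phi, cc, dt)
    },
    "10" = {
      if (length(cond) != 1) stop("pattern 10 needs one conditioning angle")
      d <- draw_uphi(n)
      th1 <- single_event_obs_angle(d$u, d$phi, cc, dt)
      keep <- abs(wrap_angle(th1 - cond)) < tol
      wrap_angle(d$phi[keep] - th1[keep])
    },
    "11" = {
      if (!length(cond) %in% 1:2)
        stop("pattern 11 needs one or two conditioning angles")
      if (length(cond) == 2) {
        ## under the clean-history convention the interval two back is
        ## event-free and its stated observed change is the correction
        ## angle of an event one interval earlier; simulate that event and
        ## window its correction to confirm the history is feasible (it is
        ## independent of the (1,1) pair given the event-free interval)
        d0 <- draw_uphi(n)
        th0 <- single_event_obs_angle(d0$u, d0$phi, cc, dt)
        corr0 <- wrap_angle(d0$phi - th0)
        if (!any(abs(wrap_angle(corr0 - cond[1])) < tol))
          stop("conditioning window too narrow: 0 samples at the prior stage")
        prev_target <- cond[2]
      } else {
        prev_target <- cond[1]
      }
      d1 <- draw_uphi(n)
      th1 <- single_event_obs_angle(d1$u, d1$phi, cc, dt)
      keep <- abs(wrap_angle(th1 - prev_target)) < tol
      m <- sum(keep)
      if (m == 0)
        stop("conditioning window too narrow: 0 samples accepted")
      d2 <- draw_uphi(m)
      th_new <- single_event_obs_angle(d2$u, d2$phi, cc, dt)
      wrap_angle(d1$phi[keep] - th1[keep] + th_new)
    })
  n_acc <- length(samples)
  if (n_acc < 1e3)
    stop(sprintf(paste0("conditioning window too narrow: only %d samples ",
                        "accepted (need >= 1000)"), n_acc))
  breaks <- seq(-pi, pi, length.out = bins + 1)
  counts <- graphics::hist(samples, breaks = breaks, plot = FALSE)$counts
  list(breaks = breaks, counts = counts,
       density = counts / (n_acc * diff(breaks)[1]),
       mass = counts / n_acc, n_accepted = n_acc, samples = samples,
       pattern = pattern, cond = cond, tol = tol)
}
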