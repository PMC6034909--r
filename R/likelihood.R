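## Bootstrap particle filter likelihood for the hidden-states formulation.
##
## Hidden states X_1..X_n (one per observation interval covered by the angle
## series) are i.i.d. Bernoulli(beta) because events in disjoint intervals of
## the exponential/Poisson event process are independent. The first series
## value z[1] acts as the conditioning angle for the first emission; emissions
## run over z[2..n], the emission for z[k] depending on the pair
## (X_{k-1}, X_k) and, when X_{k-1} = 1, on the observed previous change
## z[k-1]. Emission shapes depend only on sigma (not lambda, c or dt), so the
## noiseless gridded densities conditioned on each z[k-1] are cached once per
## series and only the noise convolution is redone per parameter value.

#' Particle filter configuration
#'
#' @param m_particles particle count (`>= 2`); 400 by default.
#' @return an object of class `filter_config`. Resampling is multinomial at
#'   every step.
#' @export
filter_config <- function(m_particles = 400) {
  stopifnot(m_particles >= 2, m_particles == round(m_particles))
  structure(list(m_particles = as.integer(m_particles)),
            class = "filter_config")
}

## Per-series cache: FFTs of the noiseless p01 masses and of the p10 masses
## conditioned on each observed previous angle change, plus the evaluation
## matrix E of Fourier phases at each observed angle z_k (the filter only
## needs each conditioned density at the single observed point, so the
## noisy densities are evaluated spectrally there instead of inverting the
## whole grid).
make_emission_cache <- function(z, dt, G = 1024) {
  n <- length(z)
  stopifnot(n >= 2, G >= 256, bitwAnd(as.integer(G), as.integer(G) - 1L) == 0)
  grid <- circle_grid(G)
  m01 <- theta1_bin_masses(G)
  M10 <- vapply(z[-n], function(a) p10_bin_masses(a, G), numeric(G))
  ## half-spectrum (real masses): frequencies 0..G/2, doubling the
  ## interior terms; row k of E carries mult_k * exp(i * s_k * (z + pi)) / G.
  ## The per-sigma evaluation only needs, for each k, the inner product of
  ## a sigma-dependent spectrum vector with E[, k] (times the p10 spectrum
  ## for the conditioned densities), so the data-dependent factors are
  ## pre-multiplied and stored transposed as real/imaginary parts: the
  ## whole emission matrix then reduces to six real matrix-vector products.
  h <- G / 2 + 1
  freqs <- 0:(G / 2)
  mult <- c(1, rep(2, G / 2 - 1), 1)
  E <- exp(1i * outer(freqs, z[-1] + pi)) * (mult / G)
  F01 <- stats::fft(m01)
  F10 <- stats::mvfft(M10)
  EF10 <- E * F10[1:h, , drop = FALSE]
  structure(list(z = z, dt = dt, n = n, G = G, grid = grid,
                 m01 = m01, F01 = F01, F10 = F10, S = conv_shift_sign(G),
                 Fh01 = F01[1:h], Sh = conv_shift_sign(G)[1:h],
                 ERt = t(Re(E)), EIt = t(Im(E)),
                 TRt = t(Re(EF10)), TIt = t(Im(EF10))),
            class = "emission_cache")
}

## Evaluate a G x m matrix of column mass vectors at one angle per column
## (linear interpolation, periodic), returning densities.
col_interp_density <- function(M, x, grid) {
  pos <- (wrap_angle(x) + pi) / grid$dtheta  # 0-based real index
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- (i0 %% grid$G) + 1
  i1 <- (i0 %% grid$G) + 1
  cols <- seq_len(ncol(M))
  (M[cbind(i0, cols)] * (1 - frac) + M[cbind(i1, cols)] * frac) / grid$dtheta
}

## (n-1) x 4 matrix of emission densities q_ij(z_k | z_{k-1}) for k = 2..n,
## columns ordered (00, 01, 10, 11). sigma > 0. The convolved densities are
## evaluated at each observed angle by trigonometric interpolation of the
## product spectra (one spectral half-grid shift per convolution; the
## double convolution for q11 carries S^2 = 1); the zero-frequency
## coefficient supplies the normalizing mass.
emission_matrix <- function(cache, sigma) {
  stopifnot(inherits(cache, "emission_cache"), sigma > 0)
  G <- cache$G
  h <- G / 2 + 1
  dtheta <- cache$grid$dtheta
  zk <- cache$z[-1]
  Fw <- stats::fft(wrapnorm_masses(G, sigma))[1:h]
  FwS <- Fw * cache$Sh
  w01 <- cache$Fh01 * FwS          # spectrum factor for q01 (against E)
  w11 <- cache$Fh01 * Fw           # extra factor for q11 (against E*F10)
  ## column masses for normalization are the zero-frequency coefficients
  ## (E's first row carries a 1/G factor, undone here)
  n10 <- cache$TRt[, 1] * G * Re(FwS[1])
  n11 <- cache$TRt[, 1] * G * Re(w11[1])
  q01 <- drop(cache$ERt %*% Re(w01) - cache$EIt %*% Im(w01))
  q10 <- drop(cache$TRt %*% Re(FwS) - cache$TIt %*% Im(FwS))
  q11 <- drop(cache$TRt %*% Re(w11) - cache$TIt %*% Im(w11))
  cbind(q00 = dwrapnorm(zk, sigma),
        q01 = pmax(q01, 0) / dtheta / Re(w01[1]),
        q10 = pmax(q10, 0) / dtheta / n10,
        q11 = pmax(q11, 0) / dtheta / n11)
}

## Noiseless emission matrix for the sigma = 0 oracle: the (0,0) entry is a
## point mass (weight 1 iff the observed change is exactly 0), the others are
## gridded noiseless densities.
emission_matrix_noiseless <- function(cache) {
  G <- cache$G
  grid <- cache$grid
  zk <- cache$z[-1]
  M10 <- Re(stats::mvfft(cache$F10, inverse = TRUE)) / G  # p10 masses again
  M11 <- Re(stats::mvfft(cache$F10 * cache$F01 * cache$S, inverse = TRUE)) / G
  M10[M10 < 0] <- 0
  M11[M11 < 0] <- 0
  M10 <- sweep(M10, 2, colSums(M10), "/")
  M11 <- sweep(M11, 2, colSums(M11), "/")
  cbind(q00 = as.numeric(abs(zk) < 1e-12),
        q01 = interp_density(cache$m01, zk, grid),
        q10 = col_interp_density(M10, zk, grid),
        q11 = col_interp_density(M11, zk, grid))
}

series_values <- function(z) {
  if (inherits(z, "angle_series")) z$values else as.numeric(z)
}

series_dt <- function(z, dt) {
  if (inherits(z, "angle_series")) z$dt else dt
}

#' Bootstrap particle filter estimate of the marginal likelihood
#'
#' Runs the bootstrap particle filter over the binary hidden states of an
#' observed angle-change series: particles carry the hidden pair
#' \eqn{(X_{k-1}, X_k)}, propagation draws the next state
#' Bernoulli(\eqn{\beta}) with \eqn{\beta = 1 - e^{-\lambda\Delta t}},
#' weights are the noisy emission densities \eqn{q_{ij}} (conditioned on
#' the previous observed change when the previous state is 1), and
#' multinomial resampling is applied after every step. The marginal
#' likelihood estimate is the product over steps of the mean unnormalized
#' weight, which is unbiased for the true marginal likelihood.
#'
#' @param z an [angle_series] (or numeric vector, with `dt` supplied).
#' @param lambda reorientation rate, per second (`> 0`).
#' @param sigma measurement noise s.d., radians (`> 0`; for noiseless data
#'   use [exact_forward_loglik], which handles the point-mass emission).
#' @param config a [filter_config].
#' @param seed optional integer seed.
#' @param dt observation interval; only needed when `z` is a bare vector.
#' @param cache optional precomputed emission cache (internal reuse).
#' @return an object of class `vjp_loglik`: `loglik` (log marginal
#'   likelihood estimate; `-Inf` when degenerate), `step_means` (per-step
#'   mean unnormalized weights), `degenerate` flag.
#' @export
bootstrap_filter <- function(z, lambda, sigma, config = filter_config(),
                             seed = NULL, dt = NULL, cache = NULL) {
  if (sigma <= 0)
    stop("sigma = 0 makes the (0,0) emission a point mass; use exact_forward_loglik")
  stopifnot(lambda > 0)
  set_seed_if(seed)
  zv <- series_values(z)
  dt <- series_dt(z, dt)
  if (is.null(dt)) stop("supply `dt` when z is a bare numeric vector")
  if (is.null(cache)) cache <- make_emission_cache(zv, dt)
  Q <- emission_matrix(cache, sigma)
  run_filter(Q, transition_probability(lambda, dt), config$m_particles,
             lambda = lambda, sigma = sigma)
}

run_filter <- function(Q, beta, M, lambda = NA, sigma = NA) {
  n_steps <- nrow(Q)
  xprev <- stats::rbinom(M, 1, beta)
  xcur <- stats::rbinom(M, 1, beta)
  ## all propagation draws up front; resampling is multinomial by
  ## inverse-CDF lookup on the cumulative weights
  prop <- matrix(stats::rbinom(n_steps * M, 1, beta), n_steps, M)
  logml <- 0
  step_means <- numeric(n_steps)
  degenerate <- FALSE
  for (k in seq_len(n_steps)) {
    Qk <- Q[k, ]
    w <- Qk[1L + 2L * xprev + xcur]
    mw <- mean(w)
    step_means[k] <- mw
    if (!is.finite(mw) || mw <= 0) {
      degenerate <- TRUE
      logml <- -Inf
      break
    }
    logml <- logml + log(mw)
    cw <- cumsum(w)
    idx <- findInterval(stats::runif(M) * cw[M], cw) + 1L
    xprev <- xcur[idx]
    xcur <- prop[k, ]
  }
  structure(list(loglik = logml, step_means = step_means,
                 degenerate = degenerate, m_particles = M,
                 lambda = lambda, sigma = sigma),
            class = "vjp_loglik")
}

#' @export
print.vjp_loglik <- function(x, ...) {
  cat(sprintf("Particle filter log-likelihood estimate: %.4f (M = %d%s)\n",
              x$loglik, x$m_particles,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Exact forward-recursion log-likelihood
#'
#' Exact marginal log-likelihood of an angle-change series under the
#' hidden-states model, by the forward algorithm over the binary hidden
#' chain (states i.i.d. Bernoulli(\eqn{\beta}), emissions depending on the
#' consecutive state pair), using the same gridded emissions and previous
#' observed-change conditioning as [bootstrap_filter]. Serves as the exact
#' oracle the particle filter is checked against. For `sigma = 0` the
#' (0,0) emission is treated as a point mass at zero observed change.
#'
#' @inheritParams bootstrap_filter
#' @param sigma measurement noise s.d., radians (`>= 0`).
#' @return log-likelihood (a scalar; `-Inf` if the data are impossible
#'   under the model).
#' @export
exact_forward_loglik <- function(z, lambda, sigma, dt = NULL, cache = NULL) {
  stopifnot(lambda > 0, sigma >= 0)
  zv <- series_values(z)
  dt <- series_dt(z, dt)
  if (is.null(dt)) stop("supply `dt` when z is a bare numeric vector")
  if (is.null(cache)) cache <- make_emission_cache(zv, dt)
  Q <- if (sigma > 0) emission_matrix(cache, sigma) else
    emission_matrix_noiseless(cache)
  beta <- transition_probability(lambda, dt)
  p <- c(1 - beta, beta)
  a <- p  # alpha_1(x), x in {0, 1}
  loglik <- 0
  for (k in seq_len(nrow(Q))) {
    Qk <- Q[k, ]
    ## W[x_prev + 1, x_cur + 1]
    a <- p * c(a[1] * Qk[1] + a[2] * Qk[3],
               a[1] * Qk[2] + a[2] * Qk[4])
    s <- a[1] + a[2]
    if (s <= 0) return(-Inf)
    loglik <- loglik + log(s)
    a <- a / s
  }
  as.numeric(loglik)
}

#' Variance of the particle filter log-likelihood versus particle count
#'
#' Repeats the bootstrap filter on fixed data for a range of particle
#' counts and reports the variance of the non-degenerate log-likelihood
#' estimates together with the degenerate fraction.
#'
#' @inheritParams bootstrap_filter
#' @param m_values integer vector of particle counts.
#' @param repeats filter runs per particle count (`>= 50`).
#' @return a data frame with columns `m_particles`, `variance`,
#'   `mean_loglik`, `degenerate_fraction`, `n_nondegenerate`.
#' @export
loglik_variance_profile <- function(z, lambda, sigma, m_values, repeats,
                                    seed = NULL, dt = NULL) {
  if (repeats < 50) stop("need repeats >= 50 for a stable variance estimate")
  set_seed_if(seed)
  zv <- series_values(z)
  dt <- series_dt(z, dt)
  cache <- make_emission_cache(zv, dt)
  Q <- emission_matrix(cache, sigma)
  beta <- transition_probability(lambda, dt)
  rows <- lapply(m_values, function(M) {
    ll <- vapply(seq_len(repeats), function(i)
      run_filter(Q, beta, as.integer(M))$loglik, numeric(1))
    ok <- is.finite(ll)
    if (!any(ok))
      stop(sprintf("all %d filter runs degenerate at M = %d", repeats, M))
    data.frame(m_particles = as.integer(M),
               variance = stats::var(ll[ok]),
               mean_loglik = mean(ll[ok]),
               degenerate_fraction = mean(!ok),
               n_nondegenerate = sum(ok))
  })
  do.call(rbind, rows)
}
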