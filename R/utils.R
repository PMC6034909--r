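#' Wrap angles onto the circle
#'
#' Reduce angles modulo \eqn{2\pi} into the half-open interval
#' \eqn{[-\pi, \pi)}. All angles handled by the package live on this
#' convention.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length with values in \eqn{[-\pi, \pi)}.
#' @examples
#' wrap_angle(c(0, pi, -pi, 3.2, -3.2))
#' @export
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

## Equispaced grid of G points t_j = -pi + (j-1) * dtheta on [-pi, pi).
## Bin j is the half-open cell of width dtheta centred at t_j; densities are
## stored as bin masses so that circular convolution is exact on the grid.
circle_grid <- function(G) {
  stopifnot(G >= 2)
  dtheta <- 2 * pi / G
  list(theta = -pi + (0:(G - 1)) * dtheta, dtheta = dtheta, G = G)
}

## Circular convolution of two bin-mass vectors on circle_grid(G).
## Because grid point 1 sits at -pi (not 0), a plain FFT convolution is
## rotated by half the grid; in the frequency domain the correction is a
## multiplication by (-1)^(k-1).
conv_shift_sign <- function(G) {
  rep_len(c(1, -1), G)
}

conv_masses <- function(a, b) {
  G <- length(a)
  stopifnot(length(b) == G)
  Re(stats::fft(stats::fft(a) * stats::fft(b) * conv_shift_sign(G),
                inverse = TRUE)) / G
}

## Clip tiny negative masses (FFT roundoff) and renormalize to unit mass.
clean_masses <- function(m) {
  m[m < 0] <- 0
  s <- sum(m)
  if (s <= 0) stop("mass vector has no positive mass")
  m / s
}

## Linear interpolation of a periodic bin-mass vector, returning density
## (mass / bin width) at arbitrary angles.
interp_density <- function(masses, x, grid = circle_grid(length(masses))) {
  dens <- masses / grid$dtheta
  # periodic extension: append the first point at +pi
  tt <- c(grid$theta, pi)
  dd <- c(dens, dens[1])
  stats::approx(tt, dd, xout = wrap_angle(x), rule = 2)$y
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
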