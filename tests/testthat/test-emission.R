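test_that("transition probability is 1 - exp(-lambda dt) and monotone", {
  expect_equal(transition_probability(0.2, 1), 1 - exp(-0.2))
  expect_equal(transition_probability(0, 1), 0)
  expect_equal(transition_probability(0.2, 1e-12), 0, tolerance = 1e-10)
  lam <- seq(0.1, 2, length.out = 8)
  expect_true(all(diff(transition_probability(lam, 1)) > 0))
  expect_true(all(diff(transition_probability(0.3, lam)) > 0))
})

test_that("theta1 density matches its closed-form limits and symmetry", {
  expect_equal(theta1_density(pi), (1 - log(2)) / (2 * pi), tolerance = 1e-12)
  expect_equal(theta1_density(pi / 2), 1 / (4 * pi), tolerance = 1e-10)
  expect_equal(theta1_density(-pi / 2), 1 / (4 * pi), tolerance = 1e-10)
  th <- seq(0.05, 3.1, length.out = 40)
  expect_equal(theta1_density(th), theta1_density(-th))
  expect_true(is.infinite(theta1_density(0)))
  expect_error(theta1_density(3.5), "\\[-pi, pi\\]")
  # continuity across the removable singularity at pi/2
  eps <- 10^seq(-3, -6)
  expect_true(all(abs(theta1_density(pi / 2 + eps) - 1 / (4 * pi)) < 1e-3))
})

test_that("theta1 density equals quadrature of the joint over r", {
  for (th in seq(-3, 3, length.out = 16)) {
    q <- integrate(function(r) joint_r_theta1_density(r, th, 50, 1),
                   0, 50, rel.tol = 1e-12)$value
    expect_lt(abs(theta1_density(th) - q), 1e-6)
  }
})

test_that("joint theta1/theta2 density has the geometric support and symmetry", {
  expect_equal(joint_theta1_theta2_density(0.5, -0.2), 0)
  expect_equal(joint_theta1_theta2_density(-0.5, 0.2), 0)
  expect_equal(joint_theta1_theta2_density(2, 2), 0)  # phi out of [-pi, pi)
  th1 <- c(0.3, 1.1, 2.2); th2 <- c(0.4, 0.9, 0.1)
  expect_equal(joint_theta1_theta2_density(th1, th2),
               joint_theta1_theta2_density(-th1, -th2))
  # marginalizing over theta2 recovers the theta1 marginal
  for (t1 in c(0.1, 1.0, -2.0)) {
    m <- integrate(function(t2) joint_theta1_theta2_density(t1, t2),
                   -pi, pi, rel.tol = 1e-9, subdivisions = 500)$value
    expect_lt(abs(m - theta1_density(t1)), 1e-3)
  }
})

test_that("conditional theta2 density integrates to one and respects support", {
  q <- integrate(function(t2) conditional_theta2_density(t2, 0.1),
                 0, pi - 0.1, rel.tol = 1e-8, subdivisions = 500)$value
  expect_lt(abs(q - 1), 1e-3)
  # zero wherever theta1 + theta2 leaves [-pi, pi) or flips sign
  expect_equal(conditional_theta2_density(c(-0.2, pi), 0.1), c(0, 0))
})

test_that("gridded p11 agrees with direct double quadrature", {
  theta1 <- 0.1
  p11_direct <- function(theta) {
    f <- function(x) {
      v <- theta1_density(wrap_angle(theta - x))
      v[!is.finite(v)] <- 0  # measure-zero log singularity
      v * conditional_theta2_density(x, theta1)
    }
    # split at the log singularity of the p01 factor (x = theta)
    s <- wrap_angle(theta)
    integrate(f, -pi, s, rel.tol = 1e-8, subdivisions = 1000)$value +
      integrate(f, s, pi, rel.tol = 1e-8, subdivisions = 1000)$value
  }
  test_angles <- c(-2.8, -1.7, -0.9, -0.3, 0.25, 0.8, 1.6, 2.9)
  got <- double_reorientation_density(test_angles, theta1)
  want <- vapply(test_angles, p11_direct, numeric(1))
  expect_lt(max(abs(got - want)), 1e-3)
})

test_that("wrapped normal density and masses are a unit-mass circular kernel", {
  for (s in c(0.04, 0.32, 2.5)) {
    q <- integrate(function(x) dwrapnorm(x, s), -pi, pi, rel.tol = 1e-10)$value
    expect_lt(abs(q - 1), 1e-6)
    expect_lt(abs(sum(vjpinfer:::wrapnorm_masses(512, s)) - 1), 1e-12)
  }
  expect_equal(dwrapnorm(0, 0.04), 1 / (0.04 * sqrt(2 * pi)), tolerance = 1e-8)
})

test_that("emission tables are nonnegative, unit mass, with correct q00", {
  tab <- emission_table(0.2, 1, sigma = 0.04, theta1 = 0.1, G = 1024)
  for (nm in c("p01_mass", "p10_mass", "p11_mass", "q00_mass", "q01_mass",
               "q10_mass", "q11_mass")) {
    expect_true(all(tab[[nm]] >= 0), info = nm)
    expect_lt(abs(sum(tab[[nm]]) - 1), 1e-3)
  }
  expect_equal(tab$beta, 1 - exp(-0.2))
  # q00 is the wrapped normal: peak density ~ 1/(sigma sqrt(2 pi))
  peak <- max(tab$q00_mass) / tab$dtheta
  expect_equal(peak, dwrapnorm(0, 0.04), tolerance = 5e-3)
  # sigma = 0 flags the point mass and leaves p unchanged
  tab0 <- emission_table(0.2, 1, sigma = 0, theta1 = 0.1, G = 512)
  expect_true(tab0$point_mass)
  expect_identical(tab0$q01_mass, tab0$p01_mass)
  expect_error(emission_table(0.2, 1, 0.04, 0.1, G = 300), "G")
})

test_that("noise convolution converges to the noiseless density as sigma -> 0", {
  G <- 1024
  tab <- emission_table(0.2, 1, sigma = 0.005, theta1 = 0.1, G = G)
  away <- abs(tab$theta) > 0.3  # away from the log spike at 0
  d01 <- abs(tab$q01_mass - tab$p01_mass) / tab$dtheta
  expect_lt(max(d01[away]), 5e-3)
})

test_that("noise convolution commutes with the sign-flip symmetry", {
  tab_p <- emission_table(0.2, 1, sigma = 0.3, theta1 = 0.7, G = 512)
  tab_m <- emission_table(0.2, 1, sigma = 0.3, theta1 = -0.7, G = 512)
  # q10(theta | theta1) = q10(-theta | -theta1): masses reverse up to the
  # half-open grid's edge bin
  flip <- function(m) c(m[1], rev(m[-1]))
  expect_equal(tab_p$q10_mass, flip(tab_m$q10_mass), tolerance = 1e-10)
  expect_equal(tab_p$q11_mass, flip(tab_m$q11_mass), tolerance = 1e-10)
})

test_that("emission tables export to delimited text", {
  tab <- emission_table(0.2, 1, sigma = 0.04, theta1 = 0.1, G = 256)
  path <- withr::local_tempfile(fileext = ".csv")
  write_emission_table(tab, path)
  back <- read.csv(path)
  expect_named(back, c("theta", "p01", "p10", "p11", "q00", "q01", "q10",
                       "q11"))
  expect_equal(back$q01, tab$q01_mass / tab$dtheta, tolerance = 1e-8)
})

test_that("Monte Carlo oracle histograms are symmetric and c/dt invariant", {
  p <- ref_params()
  o_a <- mc_emission_oracle(p, 1, "01", n = 2e5, seed = 21)
  # symmetry of the (0,1) histogram under theta -> -theta
  expect_lt(sum(abs(o_a$mass - rev(o_a$mass))), 0.06)
  # independence of speed and interval
  o_b <- mc_emission_oracle(vjp_params(0.2, 3), 0.25, "01", n = 2e5, seed = 22)
  expect_lt(sum(abs(o_a$mass - o_b$mass)), 0.05)
  # too-narrow conditioning windows error with the achieved count
  expect_error(mc_emission_oracle(p, 1, "10", cond = 3.12, n = 1e4,
                                  seed = 23, tol = 1e-4),
               "conditioning window")
})

test_that("an event two intervals back measurably contaminates the (1,1) emission", {
  # The derived p11 conditions on the previous observed change as if the
  # history were clean (no event two back). Simulate the contaminated
  # alternative - an event in that interval, whose correction shifts the
  # conditioning angle - with independent code, and check the gap to the
  # derived density is of the size the model knowingly neglects.
  set.seed(25)
  n <- 4e5
  obs1 <- function(u, phi) atan2((1 - u) * sin(phi), u + (1 - u) * cos(phi))
  u0 <- runif(n); phi0 <- runif(n, -pi, pi)
  delta0 <- wrap_angle(phi0 - obs1(u0, phi0))
  keep0 <- abs(wrap_angle(obs1(u0, phi0) + 1.0)) < 0.04  # prior change -1.0
  delta0 <- sample(delta0[keep0], n, replace = TRUE)
  u1 <- runif(n); phi1 <- runif(n, -pi, pi)
  a1 <- obs1(u1, phi1)
  keep <- abs(wrap_angle(a1 + delta0 - 0.1)) < 0.04      # observed prev 0.1
  m <- sum(keep)
  u2 <- runif(m); phi2 <- runif(m, -pi, pi)
  theta <- wrap_angle(phi1[keep] - a1[keep] + obs1(u2, phi2))
  h <- hist(theta, breaks = seq(-pi, pi, length.out = 65), plot = FALSE)
  l1 <- sum(abs(h$counts / m - emission_bin_masses("11", theta1 = 0.1)))
  expect_gt(m, 1e3)
  expect_gt(l1, 0.10)
})

test_that("misspecified wrapped-normal kernels converge to the uniform one", {
  m01 <- emission_bin_masses("01", bins = 64)
  l1 <- vapply(c(0.4, 1, 6.4), function(g) {
    o <- mc_emission_oracle(vjp_params(0.2, 50, "wrapped_normal", gamma = g),
                            1, "01", n = 2e5, seed = 24)
    sum(abs(o$mass - m01))
  }, numeric(1))
  expect_true(all(diff(l1) < 0))
  expect_gt(l1[1], 0.2)   # strongly misspecified at small dispersion
  expect_lt(l1[3], 0.06)  # nearly uniform at large dispersion
})
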