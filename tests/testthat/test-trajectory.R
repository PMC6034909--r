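test_that("lambda = 0 gives a single straight run along the initial heading", {
  traj <- simulate_trajectory(vjp_params(0, 50), t_final = 10, seed = 1)
  expect_length(traj$event_times, 0)
  expect_equal(traj$end, c(x = 500, y = 0))
  traj2 <- simulate_trajectory(vjp_params(0, 50, initial_heading = pi / 2),
                               t_final = 10, seed = 1)
  expect_equal(traj2$end, c(x = 0, y = 500), tolerance = 1e-12)
})

test_that("run segments have chord length speed * duration, times increasing", {
  traj <- simulate_trajectory(ref_params(), t_final = 200, seed = 2)
  expect_true(all(diff(traj$event_times) > 0))
  expect_true(all(traj$headings >= -pi & traj$headings < pi))
  seg <- sqrt(diff(traj$knot_x)^2 + diff(traj$knot_y)^2)
  expect_equal(seg, 50 * diff(traj$knot_times), tolerance = 1e-10)
})

test_that("reorientation counts are Poisson(lambda * T) in mean and variance", {
  n_rep <- 4000
  counts <- vapply(seq_len(n_rep), function(i)
    length(simulate_trajectory(ref_params(), 64, seed = 1000 + i)$event_times),
    numeric(1))
  mu <- 0.2 * 64
  se <- sqrt(mu / n_rep)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # Poisson: variance equals mean; var of sample variance ~ 2 mu^2 / n
  expect_lt(abs(var(counts) - mu), 4 * sqrt((2 * mu^2 + mu) / n_rep))
})

test_that("run durations pass a KS test against exponential(lambda)", {
  traj <- simulate_trajectory(ref_params(), t_final = 5.2e4, seed = 3)
  dur <- diff(c(0, traj$event_times))[1:1e4]
  expect_gt(ks.test(dur, "pexp", 0.2)$p.value, 0.01)
})

test_that("observe_positions lies on the path and is deterministic", {
  traj <- simulate_trajectory(ref_params(), t_final = 64, seed = 4)
  grid <- observation_grid(0.5, 128)
  pos <- observe_positions(traj, grid)
  expect_equal(nrow(pos), 129)
  # straight-run check: along +x at speed c
  tr0 <- simulate_trajectory(vjp_params(0, 50), 10, seed = 1)
  p0 <- observe_positions(tr0, observation_grid(1, 10))
  expect_equal(p0[, "x"], 50 * (0:10))
  expect_equal(p0[, "y"], rep(0, 11))
  # observation coinciding with a reorientation returns the event position
  trm <- manual_trajectory(c(1, 2.5), c(0, pi / 2, pi), 2, 4)
  pm <- observe_positions(trm, observation_grid(1, 4))
  expect_equal(unname(pm[2, c("x", "y")]),
               unname(trm$event_positions[1, ]))
  # determinism under the same seed
  traj_b <- simulate_trajectory(ref_params(), t_final = 64, seed = 4)
  expect_identical(pos, observe_positions(traj_b, grid))
  # grid past t_final errors
  expect_error(observe_positions(tr0, observation_grid(1, 11)), "past")
})

test_that("extract_angle_changes matches geometry and the complex-argument oracle", {
  collinear <- cbind(x = c(0, 1, 2, 3), y = c(0, 1, 2, 3))
  expect_equal(extract_angle_changes(collinear, dt = 1)$values, c(0, 0))
  right <- cbind(x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(extract_angle_changes(right, dt = 1)$values, pi / 2)
  # direction sequence crossing the +/- pi boundary
  d1 <- 3.1; d2 <- -3.1
  pos <- cbind(x = cumsum(c(0, cos(c(d1, d2)))),
               y = cumsum(c(0, sin(c(d1, d2)))))
  z <- extract_angle_changes(pos, dt = 1)$values
  expect_equal(z, Arg(exp(1i * (d2 - d1))), tolerance = 1e-12)
  expect_equal(z, 2 * pi - 6.2, tolerance = 1e-12)
  expect_error(extract_angle_changes(cbind(x = c(0, 0, 1), y = c(0, 0, 1)),
                                     dt = 1), "coincident")
})

test_that("events on grid times make angle changes recover the kernel draws", {
  turns <- c(0.7, -2.1, 2.9)
  headings <- cumsum(c(0.3, turns))
  trm <- manual_trajectory(c(1, 2, 3), headings, 5, 5)
  z <- extract_angle_changes(observe_positions(trm, observation_grid(1, 5)))
  expect_equal(z$values[1:3], wrap_angle(turns), tolerance = 1e-10)
  expect_equal(z$values[4], 0)
})

test_that("measurement noise wraps, is exact for sigma 0, and has the right resultant length", {
  s <- short_series(seed = 5, sigma = 0)
  expect_identical(add_measurement_noise(s, 0)$values, s$values)
  big <- angle_series(rep(0, 1e5), dt = 1)
  noisy <- add_measurement_noise(big, 0.8, seed = 6)
  expect_true(all(noisy$values >= -pi & noisy$values < pi))
  r <- Mod(mean(exp(1i * noisy$values)))
  se <- sqrt((1 - exp(-2 * 0.8^2)) / (2 * 1e5))  # delta-method scale
  expect_lt(abs(r - exp(-0.8^2 / 2)), 4 * se + 3e-3)
})

test_that("angle changes are invariant to global rotation of the trajectory", {
  base <- simulate_angle_dataset(ref_params(), 1, 64, 0.04, seed = 7)
  rot <- simulate_angle_dataset(ref_params(initial_heading = 1.9),
                                1, 64, 0.04, seed = 7)
  expect_equal(base$values, rot$values, tolerance = 1e-9)
})

test_that("interval event counts match Poisson interval probabilities", {
  # lambda * dt = 0.2 over ~1e5 intervals
  traj <- simulate_trajectory(ref_params(), t_final = 1e5, seed = 8)
  ev <- interval_event_counts(traj, observation_grid(1, 1e5))
  p2 <- mean(ev$counts >= 2)
  p2_true <- 1 - exp(-0.2) * (1 + 0.2)
  expect_lt(abs(p2 - p2_true), 3 * sqrt(p2_true * (1 - p2_true) / 1e5))
  p1 <- mean(ev$states)
  p1_true <- 1 - exp(-0.2)
  expect_lt(abs(p1 - p1_true), 3 * sqrt(p1_true * (1 - p1_true) / 1e5))
  expect_equal(sum(ev$counts), length(traj$event_times))
  # lambda = 0: all counts zero
  ev0 <- interval_event_counts(simulate_trajectory(vjp_params(0, 50), 10),
                               observation_grid(1, 10))
  expect_identical(ev0$counts, integer(10))
})

test_that("synthetic datasets round-trip through delimited text", {
  z <- simulate_angle_dataset(ref_params(), 0.5, 16, 0.04, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_angle_dataset(z, path, seed = 9)
  back <- read_angle_dataset(path)
  expect_equal(back$values, z$values, tolerance = 1e-12)
  expect_equal(back$dt, 0.5)
  expect_equal(back$sigma, 0.04)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$lambda, 0.2)
  expect_equal(meta$seed, 9)
})
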