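# Shared fixtures: all synthetic, built in code at test time.

ref_params <- function(...) vjp_params(lambda = 0.2, speed = 50, ...)

# short noisy series used by the likelihood tests (T = 8 intervals -> 7 values)
short_series <- function(seed = 11, sigma = 0.1, dt = 1) {
  simulate_angle_dataset(ref_params(), dt = dt, t_final = 8 * dt,
                         sigma = sigma, seed = seed)
}

# hand-built continuous trajectory with events at known times/headings
manual_trajectory <- function(event_times, headings, speed, t_final) {
  stopifnot(length(headings) == length(event_times) + 1)
  knots <- c(0, event_times, t_final)
  dur <- diff(knots)
  xs <- cumsum(c(0, speed * dur * cos(headings)))
  ys <- cumsum(c(0, speed * dur * sin(headings)))
  n_ev <- length(event_times)
  structure(list(event_times = event_times, headings = headings,
                 event_positions = cbind(x = xs[seq_len(n_ev) + 1],
                                         y = ys[seq_len(n_ev) + 1]),
                 start = c(x = 0, y = 0),
                 end = c(x = xs[length(xs)], y = ys[length(ys)]),
                 knot_times = knots, knot_x = xs, knot_y = ys,
                 t_final = t_final,
                 params = vjp_params(0, speed)),
            class = "vjp_trajectory")
}

# brute-force likelihood by enumeration over all 2^n hidden sequences,
# sharing only the emission matrix with the implementation under test
enumerate_loglik <- function(Q, beta) {
  n <- nrow(Q) + 1
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  total <- 0
  for (r in seq_len(nrow(states))) {
    x <- states[r, ]
    pr <- prod(ifelse(x == 1, beta, 1 - beta))
    w <- 1
    for (k in 2:n) w <- w * Q[k - 1, 1 + 2 * x[k - 1] + x[k]]
    total <- total + pr * w
  }
  as.numeric(log(total))
}

l1_mass_distance <- function(oracle, analytic_mass) {
  sum(abs(oracle$mass - analytic_mass))
}
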