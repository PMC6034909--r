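test_that("prior box and proposal kernel validate their inputs", {
  expect_error(log_uniform_prior(log_lambda = c(1, -1)))
  expect_error(proposal_kernel(matrix(c(1, 2, 0, 1), 2)))
  pk <- proposal_kernel()
  expect_equal(pk$Sigma, diag(c(0.5, 0.05)))
})

test_that("sampler with an exact surrogate likelihood recovers the target", {
  # correlated Gaussian surrogate posterior restricted to the prior box
  mu <- c(-0.5, -2); sds <- c(0.35, 0.3); rho <- 0.4
  loglik_fn <- function(lambda, sigma) {
    x <- (log(lambda) - mu[1]) / sds[1]
    y <- (log(sigma) - mu[2]) / sds[2]
    -(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))
  }
  ch <- run_pmcmc(z = NULL, n_steps = 50000, thin = 2, seed = 31,
                  loglik_fn = loglik_fn)
  d <- chain_draws(ch)
  # compare 1-D marginal histograms against the grid-computed target
  for (j in 1:2) {
    lim <- if (j == 1) c(-1.70, 1.30) else c(-5, 1)
    breaks <- seq(lim[1], lim[2], length.out = 51)
    p_hat <- tabulate(findInterval(d[, j], breaks, rightmost.closed = TRUE),
                      nbins = 50) / nrow(d)
    mids <- (breaks[-1] + breaks[-51]) / 2
    dens <- dnorm(mids, mu[j], sds[j])
    p_true <- dens / sum(dens)
    expect_lt(sum(abs(p_hat - p_true)) / 2, 0.05)
  }
  expect_equal(unname(colMeans(d)), mu, tolerance = 0.1)
  expect_equal(unname(cor(d)[1, 2]), rho, tolerance = 0.15)
})

test_that("likelihood estimate of the current state is stored and reused", {
  calls <- 0
  loglik_fn <- function(lambda, sigma) { calls <<- calls + 1; 0 }
  ch <- run_pmcmc(z = NULL, n_steps = 500, thin = 1, seed = 32,
                  loglik_fn = loglik_fn)
  # one call at the initial state plus one per in-box proposal, never more
  expect_lte(calls, 501)
  expect_gt(calls, 300)
})

test_that("effective sample size calibrates on white noise and AR(1)", {
  set.seed(33)
  x <- rnorm(1e4)
  expect_gt(effective_sample_size(x) / 1e4, 0.8)
  expect_lt(effective_sample_size(x) / 1e4, 1.2)
  rho <- 0.5
  ar <- as.numeric(arima.sim(list(ar = rho), 1e4))
  expect_equal(effective_sample_size(ar), 1e4 * (1 - rho) / (1 + rho),
               tolerance = 0.15)
  const <- effective_sample_size(rep(2, 200))
  expect_equal(as.numeric(const), 1)
  expect_true(attr(const, "degenerate"))
})

test_that("posterior summaries exponentiate and match a sort-based oracle", {
  v <- 0.4
  one <- summarize_posterior(matrix(v, 150, 2))
  expect_equal(one$median, rep(exp(v), 2))
  expect_equal(one$lower, rep(exp(v), 2))
  expect_equal(one$upper, rep(exp(v), 2))
  set.seed(34)
  draws <- cbind(rnorm(1001, -1.6, 0.3), rnorm(1001, -3.2, 0.2))
  ps <- summarize_posterior(draws)
  for (j in 1:2) {
    s <- sort(exp(draws[, j]))
    expect_equal(ps$median[j], s[501])
    expect_equal(ps$lower[j], s[26])
    expect_equal(ps$upper[j], s[976])
  }
  # quantiles commute with the monotone exp transform
  expect_equal(ps$median, exp(apply(draws, 2, median)))
})

test_that("consensus combination is exact for Gaussian shards", {
  set.seed(35)
  # single shard: identity
  m <- cbind(rnorm(500), rnorm(500))
  expect_equal(consensus_combine(list(m)), m)
  # two Gaussian shards: combined mean matches the precision-weighted form
  n <- 1e4
  mu1 <- c(0, 0); mu2 <- c(1, 0.5)
  s1 <- cbind(rnorm(n, mu1[1], 0.5), rnorm(n, mu1[2], 0.3))
  s2 <- cbind(rnorm(n, mu2[1], 0.25), rnorm(n, mu2[2], 0.6))
  comb <- consensus_combine(list(s1, s2))
  W1 <- solve(cov(s1)); W2 <- solve(cov(s2))
  want <- solve(W1 + W2) %*% (W1 %*% colMeans(s1) + W2 %*% colMeans(s2))
  expect_equal(unname(colMeans(comb)), as.numeric(want), tolerance = 0.02)
  # S identical shards shrink the covariance like 1/S
  shards <- lapply(1:4, function(i) cbind(rnorm(n, 0, 0.4), rnorm(n, 0, 0.4)))
  comb4 <- consensus_combine(shards)
  expect_equal(mean(diag(cov(comb4))), 0.4^2 / 4, tolerance = 0.05)
})

test_that("chains serialize to delimited text with JSON metadata", {
  ch <- run_pmcmc(z = NULL, n_steps = 400, thin = 2, seed = 36,
                  loglik_fn = function(lambda, sigma) 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chain(ch, path, seed = 36)
  d <- read.csv(path)
  expect_named(d, c("step", "log_lambda", "log_sigma", "loglik", "accepted"))
  expect_equal(nrow(d), 200)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$n_steps, 400)
  expect_equal(meta$proposal_scale, "log")
})
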