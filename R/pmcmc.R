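## Pseudo-marginal Metropolis-Hastings over (log lambda, log sigma), with
## the bootstrap particle filter supplying an unbiased likelihood estimate.
## The estimate attached to the current state is stored and reused, never
## recomputed, which is what makes the sampler target the exact posterior.

#' Log-uniform prior box for (lambda, sigma)
#'
#' Uniform prior on the logs of the reorientation rate and the noise
#' amplitude over a rectangular box.
#'
#' @param log_lambda bounds on `log(lambda)`; default `c(-1.70, 1.30)`.
#' @param log_sigma bounds on `log(sigma)`; default `c(-5, 1)`.
#' @return an object of class `log_uniform_prior`.
#' @export
log_uniform_prior <- function(log_lambda = c(-1.70, 1.30),
                              log_sigma = c(-5, 1)) {
  stopifnot(length(log_lambda) == 2, log_lambda[1] < log_lambda[2],
            length(log_sigma) == 2, log_sigma[1] < log_sigma[2])
  structure(list(log_lambda = log_lambda, log_sigma = log_sigma),
            class = "log_uniform_prior")
}

prior_contains <- function(prior, th) {
  th[1] >= prior$log_lambda[1] && th[1] <= prior$log_lambda[2] &&
    th[2] >= prior$log_sigma[1] && th[2] <= prior$log_sigma[2]
}

prior_draw <- function(prior) {
  c(stats::runif(1, prior$log_lambda[1], prior$log_lambda[2]),
    stats::runif(1, prior$log_sigma[1], prior$log_sigma[2]))
}

#' Random-walk proposal kernel
#'
#' Gaussian random-walk proposal \eqn{N(\theta, \Sigma)} acting on
#' (log lambda, log sigma).
#'
#' @param Sigma 2x2 symmetric positive-definite covariance; default
#'   `diag(c(0.5, 0.05))`.
#' @return an object of class `proposal_kernel` carrying `Sigma` and its
#'   Cholesky factor.
#' @export
proposal_kernel <- function(Sigma = diag(c(0.5, 0.05))) {
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == 2, ncol(Sigma) == 2,
            isTRUE(all.equal(Sigma, t(Sigma))))
  R <- chol(Sigma)  # errors if not positive definite
  structure(list(Sigma = Sigma, chol = R), class = "proposal_kernel")
}

propose <- function(kernel, th) {
  as.numeric(th + drop(stats::rnorm(2) %*% kernel$chol))
}

#' Particle MCMC over (log lambda, log sigma)
#'
#' Pseudo-marginal Metropolis-Hastings: at each step a new parameter pair
#' is proposed from a symmetric Gaussian random walk on the log scale, a
#' fresh particle-filter likelihood estimate is computed for the proposal,
#' and the move is accepted with probability
#' \eqn{\min(1, \hat p(y|\theta^*) / \hat p(y|\theta))} (the prior is flat
#' on the box and the proposal symmetric, so only the likelihood ratio
#' remains; proposals outside the box are rejected). The likelihood
#' estimate of the retained state is stored and reused.
#'
#' @param z an [angle_series] (or numeric vector with `dt`).
#' @param prior a [log_uniform_prior].
#' @param proposal a [proposal_kernel].
#' @param n_steps total MCMC steps (`>= 100`); 50,000 by default.
#' @param thin thinning interval; every `thin`-th state is retained.
#' @param config a [filter_config] (particle count).
#' @param seed optional integer seed.
#' @param init optional initial `(log lambda, log sigma)`; drawn from the
#'   prior when `NULL`. If the filter is degenerate at the initial state it
#'   is redrawn from the prior, up to 100 attempts.
#' @param burn_frac fraction of retained draws treated as burn-in by
#'   downstream summaries (recorded, not dropped here).
#' @param loglik_fn optional replacement log-likelihood
#'   `function(lambda, sigma) -> scalar` (used for prior-sampling checks
#'   and exact-likelihood surrogates); the particle filter when `NULL`.
#' @param dt observation interval; only needed when `z` is a bare vector.
#' @return an object of class `vjp_chain`: matrix `draws` (retained
#'   `(log_lambda, log_sigma)` states), `loglik` per retained state,
#'   `accept_rate`, `n_steps`, `thin`, `burn`, and the settings.
#' @export
run_pmcmc <- function(z, prior = log_uniform_prior(),
                      proposal = proposal_kernel(), n_steps = 50000,
                      thin = 2, config = filter_config(), seed = NULL,
                      init = NULL, burn_frac = 0.1, loglik_fn = NULL,
                      dt = NULL) {
  stopifnot(n_steps >= 100, thin >= 1)
  set_seed_if(seed)
  if (is.null(loglik_fn)) {
    zv <- series_values(z)
    dt <- series_dt(z, dt)
    if (is.null(dt)) stop("supply `dt` when z is a bare numeric vector")
    cache <- make_emission_cache(zv, dt)
    loglik_fn <- function(lambda, sigma)
      bootstrap_filter(zv, lambda, sigma, config, dt = dt, cache = cache)$loglik
  }
  eval_ll <- function(th) loglik_fn(exp(th[1]), exp(th[2]))

  th <- if (is.null(init)) prior_draw(prior) else as.numeric(init)
  if (!prior_contains(prior, th)) stop("initial state outside the prior box")
  ll <- eval_ll(th)
  attempts <- 0
  while (!is.finite(ll)) {
    attempts <- attempts + 1
    if (attempts > 100)
      stop("degenerate likelihood at 100 prior-drawn initial states")
    th <- prior_draw(prior)
    ll <- eval_ll(th)
  }

  n_keep <- floor(n_steps / thin)
  draws <- matrix(NA_real_, n_keep, 2,
                  dimnames = list(NULL, c("log_lambda", "log_sigma")))
  ll_trace <- numeric(n_keep)
  acc_trace <- logical(n_keep)
  n_acc <- 0
  kept <- 0
  for (j in seq_len(n_steps)) {
    th_star <- propose(proposal, th)
    accepted <- FALSE
    if (prior_contains(prior, th_star)) {
      ll_star <- eval_ll(th_star)
      ## flat prior in the box + symmetric proposal: likelihood ratio only
      if (is.finite(ll_star) &&
          log(stats::runif(1)) < (ll_star - ll)) {
        th <- th_star
        ll <- ll_star
        accepted <- TRUE
      }
    }
    n_acc <- n_acc + accepted
    if (j %% thin == 0) {
      kept <- kept + 1
      draws[kept, ] <- th
      ll_trace[kept] <- ll
      acc_trace[kept] <- accepted
    }
  }
  structure(list(draws = draws, loglik = ll_trace, accepted = acc_trace,
                 accept_rate = n_acc / n_steps, n_steps = n_steps,
                 thin = thin, burn = floor(burn_frac * n_keep),
                 prior = prior, proposal = proposal,
                 m_particles = config$m_particles),
            class = "vjp_chain")
}

#' @export
print.vjp_chain <- function(x, ...) {
  cat(sprintf("pMCMC chain: %d retained draws (N = %d, thin = %d), acceptance %.1f%%\n",
              nrow(x$draws), x$n_steps, x$thin, 100 * x$accept_rate))
  invisible(x)
}

#' Retained post-burn-in draws of a chain
#'
#' @param chain a `vjp_chain`.
#' @return matrix of `(log_lambda, log_sigma)` draws after burn-in.
#' @export
chain_draws <- function(chain) {
  stopifnot(inherits(chain, "vjp_chain"))
  if (chain$burn > 0) chain$draws[-seq_len(chain$burn), , drop = FALSE]
  else chain$draws
}

#' Effective sample size by initial positive sequence truncation
#'
#' \eqn{n_{\mathrm{eff}} = n / (1 + 2\sum_k \rho_k)} with the empirical
#' autocorrelations summed up to (not including) the first non-positive
#' estimate.
#'
#' @param x numeric vector of chain draws for one coordinate (`>= 100`).
#' @return effective sample size; a constant chain returns 1 with
#'   attribute `degenerate = TRUE`.
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 100)
  if (stats::var(x) == 0)
    return(structure(1, degenerate = TRUE))
  rho <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE)$acf[-1]
  stop_at <- which(rho <= 0)[1]
  keep <- if (is.na(stop_at)) rho else rho[seq_len(stop_at - 1)]
  n / (1 + 2 * sum(keep))
}

#' Posterior summary on the natural scale
#'
#' Exponentiates the post-burn-in draws and reports, per parameter, the
#' median, the central 95% credible interval (2.5 and 97.5 percentiles) and
#' the effective sample size.
#'
#' @param chain a `vjp_chain`, or a matrix of `(log_lambda, log_sigma)`
#'   draws.
#' @return an object of class `vjp_posterior`: a data frame with rows
#'   `lambda`, `sigma` and columns `median`, `lower`, `upper`, `ess`.
#' @export
summarize_posterior <- function(chain) {
  draws <- if (inherits(chain, "vjp_chain")) chain_draws(chain) else
    as.matrix(chain)
  stopifnot(nrow(draws) >= 1, ncol(draws) == 2)
  nat <- exp(draws)
  qs <- apply(nat, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  ess <- if (nrow(draws) >= 100)
    apply(draws, 2, effective_sample_size) else c(NA_real_, NA_real_)
  out <- data.frame(parameter = c("lambda", "sigma"),
                    median = qs[1, ], lower = qs[2, ], upper = qs[3, ],
                    ess = as.numeric(ess))
  class(out) <- c("vjp_posterior", "data.frame")
  out
}

#' @export
print.vjp_posterior <- function(x, ...) {
  cat("Posterior summary (natural scale, 95% credible intervals):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-7s median %.4g, CI [%.4g, %.4g], ESS %.0f\n",
                x$parameter[i], x$median[i], x$lower[i], x$upper[i], x$ess[i]))
  }
  invisible(x)
}

#' Consensus Monte Carlo combination of subposterior draws
#'
#' Combines equal-length draw sets from independent per-shard (e.g.
#' per-track) posteriors by covariance-weighted averaging: each shard gets
#' weight equal to the inverse of its sample covariance of
#' `(log lambda, log sigma)`, and combined draw j is
#' \eqn{(\sum_s W_s)^{-1} \sum_s W_s x_{s,j}}.
#'
#' @param chains a list of `vjp_chain` objects or draw matrices; retained
#'   lengths are truncated to the minimum.
#' @return a matrix of combined `(log_lambda, log_sigma)` draws.
#' @export
consensus_combine <- function(chains) {
  stopifnot(length(chains) >= 1)
  mats <- lapply(chains, function(ch)
    if (inherits(ch, "vjp_chain")) chain_draws(ch) else as.matrix(ch))
  n <- min(vapply(mats, nrow, integer(1)))
  stopifnot(n >= 2)
  mats <- lapply(mats, function(m) m[seq_len(n), , drop = FALSE])
  if (length(mats) == 1) return(mats[[1]])
  Ws <- lapply(mats, function(m) {
    V <- stats::cov(m)
    W <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(W)) {
      warning("singular shard covariance; ridge-regularizing")
      W <- solve(V + diag(1e-8, 2))
    }
    W
  })
  Wsum_inv <- solve(Reduce(`+`, Ws))
  acc <- matrix(0, n, 2)
  for (s in seq_along(mats)) acc <- acc + mats[[s]] %*% t(Ws[[s]])
  out <- acc %*% t(Wsum_inv)
  colnames(out) <- c("log_lambda", "log_sigma")
  out
}

#' Write a chain to delimited text with JSON metadata
#'
#' @param chain a `vjp_chain`.
#' @param path output CSV path; metadata is written to `paste0(path, ".json")`.
#' @param seed,extra optional metadata fields.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path, seed = NULL, extra = list()) {
  stopifnot(inherits(chain, "vjp_chain"))
  d <- data.frame(step = seq_len(nrow(chain$draws)) * chain$thin,
                  log_lambda = chain$draws[, 1],
                  log_sigma = chain$draws[, 2],
                  loglik = chain$loglik,
                  accepted = as.integer(chain$accepted))
  utils::write.csv(d, path, row.names = FALSE)
  meta <- c(list(n_steps = chain$n_steps, thin = chain$thin,
                 burn = chain$burn, m_particles = chain$m_particles,
                 accept_rate = chain$accept_rate,
                 prior_log_lambda = chain$prior$log_lambda,
                 prior_log_sigma = chain$prior$log_sigma,
                 proposal_sigma = as.numeric(chain$proposal$Sigma),
                 proposal_scale = "log",
                 seed = seed), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
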