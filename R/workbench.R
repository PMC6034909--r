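## Experimental-design utilities and the multi-track inference pipeline.
## Units are fixed throughout: seconds, micrometres, radians in [-pi, pi).

#' Noise amplitude implied by the sampling interval under a photon budget
#'
#' With a fixed photon budget the signal-to-noise ratio grows like the
#' square root of the frame interval, giving an inverse square-root
#' relationship between the angular noise and the interval:
#' \eqn{\sigma = K / \sqrt{\Delta t}}.
#'
#' @param K photon-budget proportionality constant, rad s^(1/2) (`> 0`).
#' @param dt sampling interval, seconds (`> 0`).
#' @return noise s.d. sigma, radians.
#' @examples
#' noise_for_interval(0.08, 4)  # 0.04
#' @export
noise_for_interval <- function(K, dt) {
  stopifnot(all(K > 0), all(dt > 0))
  K / sqrt(dt)
}

#' Signal-to-noise ratio implied by the sampling interval
#'
#' Companion of [noise_for_interval]: \eqn{\mathrm{SNR} = \kappa\sqrt{\Delta t}}.
#'
#' @param kappa imaging constant, per s^(1/2) (`> 0`).
#' @param dt sampling interval, seconds.
#' @return SNR (dimensionless).
#' @export
snr_for_interval <- function(kappa, dt) {
  stopifnot(all(kappa > 0), all(dt > 0))
  kappa * sqrt(dt)
}

#' Reorientation rate from speed and effective diffusion coefficient
#'
#' For a velocity jump process whose long-time behaviour matches Brownian
#' motion with diffusion coefficient `D` at running speed `c`:
#' \eqn{\lambda = c^2 / (2D)}.
#'
#' @param speed running speed c, micrometres per second (`> 0`).
#' @param D diffusion coefficient, square micrometres per second (`> 0`).
#' @return lambda, per second.
#' @examples
#' lambda_from_diffusion(0.5, 1)  # 0.125
#' @export
lambda_from_diffusion <- function(speed, D) {
  stopifnot(all(speed > 0), all(D > 0))
  speed^2 / (2 * D)
}

#' Sweep the sampling-interval / noise trade-off
#'
#' For each setting, the same underlying continuous trajectory (per seed)
#' is discretised at that setting's `dt`, wrapped-normal noise of that
#' setting's `sigma` is added, and a scaled particle MCMC run summarizes
#' the posterior. Settings are processed with independent derived seeds, so
#' results are invariant to sweep ordering.
#'
#' @param settings a data frame with columns `dt` and `sigma` (at least 2
#'   rows), or a numeric `dt` vector combined with `K` via
#'   [noise_for_interval].
#' @param truth a [vjp_params] object: the generative ground truth.
#' @param t_final trajectory duration, seconds.
#' @param K photon-budget constant; used when `settings` is a `dt` vector.
#' @param n_steps,thin,config pMCMC settings (see [run_pmcmc]).
#' @param prior,proposal pMCMC prior and proposal.
#' @param seed integer seed; each setting derives its own seed from `seed`
#'   and the setting's `(dt, sigma)` values, so per-setting results do not
#'   depend on sweep order.
#' @return a data frame with one row per setting: `dt`, `sigma`,
#'   `n_values`, posterior medians and 95% intervals for lambda and sigma,
#'   and the lambda interval width.
#' @export
design_sweep <- function(settings, truth, t_final = 64, K = NULL,
                         n_steps = 2500, thin = 2,
                         config = filter_config(100),
                         prior = log_uniform_prior(),
                         proposal = proposal_kernel(), seed = 1) {
  if (is.numeric(settings) && is.null(dim(settings))) {
    if (is.null(K)) stop("supply K when `settings` is a dt vector")
    settings <- data.frame(dt = settings,
                           sigma = noise_for_interval(K, settings))
  }
  settings <- as.data.frame(settings)
  stopifnot(all(c("dt", "sigma") %in% names(settings)),
            nrow(settings) >= 1)
  traj <- simulate_trajectory(truth, t_final, seed = seed)
  rows <- lapply(seq_len(nrow(settings)), function(i) {
    dt <- settings$dt[i]
    sigma <- settings$sigma[i]
    ## per-setting seed from the setting values, not the row index
    off <- (round(1e3 * dt) * 7919L + round(1e5 * sigma)) %% 1000003L
    grid <- observation_grid(dt, floor(t_final / dt + 1e-9))
    s <- extract_angle_changes(observe_positions(traj, grid), dt = dt)
    z <- add_measurement_noise(s, sigma, seed = seed + off)
    ch <- run_pmcmc(z, prior = prior, proposal = proposal,
                    n_steps = n_steps, thin = thin, config = config,
                    seed = seed + off + 1L)
    ps <- summarize_posterior(ch)
    data.frame(dt = dt, sigma = sigma, n_values = length(z$values),
               lambda_median = ps$median[1], lambda_lower = ps$lower[1],
               lambda_upper = ps$upper[1],
               lambda_width = ps$upper[1] - ps$lower[1],
               sigma_median = ps$median[2], sigma_lower = ps$lower[2],
               sigma_upper = ps$upper[2])
  })
  do.call(rbind, rows)
}

## ---- track tables -------------------------------------------------------

#' Read single-particle tracks from delimited text
#'
#' Expects a CSV with header `track_id,t,x,y` (times in seconds, positions
#' in micrometres). Each track is validated: at least 4 points, strictly
#' increasing times, equispaced within 1% of the median interval. Tracks
#' failing validation are rejected (with a recorded reason), not padded or
#' repaired.
#'
#' @param path CSV path.
#' @return an object of class `track_table`: `tracks` (a named list of
#'   per-track data frames), `dt` (named vector of inferred sampling
#'   intervals) and `rejected` (data frame of track id + reason).
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "t", "x", "y")
  if (!all(need %in% names(d)))
    stop("track file must have columns track_id,t,x,y")
  ids <- unique(d$track_id)
  tracks <- list()
  dts <- numeric(0)
  rejected <- data.frame(track_id = character(0), reason = character(0))
  for (id in ids) {
    tr <- d[d$track_id == id, need]
    tr <- tr[order(tr$t), ]
    reason <- NULL
    if (nrow(tr) < 4) {
      reason <- "fewer than 4 observations"
    } else {
      gaps <- diff(tr$t)
      med <- stats::median(gaps)
      if (any(gaps <= 0)) reason <- "non-increasing times"
      else if (any(abs(gaps - med) > 0.01 * med)) reason <- "irregular sampling"
    }
    if (is.null(reason)) {
      tracks[[as.character(id)]] <- tr
      dts[as.character(id)] <- stats::median(diff(tr$t))
    } else {
      rejected <- rbind(rejected,
                        data.frame(track_id = as.character(id),
                                   reason = reason))
      message(sprintf("track %s rejected: %s", id, reason))
    }
  }
  structure(list(tracks = tracks, dt = dts, rejected = rejected),
            class = "track_table")
}

#' Write a track table to delimited text
#'
#' @param tracks a `track_table` or a data frame with columns
#'   `track_id,t,x,y`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  d <- if (inherits(tracks, "track_table"))
    do.call(rbind, tracks$tracks) else as.data.frame(tracks)
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(d)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("Track table: %d valid tracks, %d rejected\n",
              length(x$tracks), nrow(x$rejected)))
  invisible(x)
}

#' Per-track inference with consensus combination
#'
#' Extracts the observed angle-change series of each valid track, runs an
#' independent particle MCMC subposterior per track (shared prior, proposal
#' and filter settings), combines the subposterior draws with consensus
#' Monte Carlo on the log scale, and summarizes the combined posterior on
#' the natural scale.
#'
#' @param tracks a `track_table` (see [read_tracks]).
#' @param n_steps,thin,config,prior,proposal pMCMC settings.
#' @param seed integer seed; track `i` uses `seed + 104729 * i`.
#' @return a list with `chains` (per-track `vjp_chain`s), `combined`
#'   (combined log-scale draws) and `summary` (a `vjp_posterior`).
#' @export
multi_track_inference <- function(tracks, n_steps = 5000, thin = 2,
                                  config = filter_config(200),
                                  prior = log_uniform_prior(),
                                  proposal = proposal_kernel(), seed = 1) {
  stopifnot(inherits(tracks, "track_table"))
  if (length(tracks$tracks) == 0) stop("no valid tracks to analyse")
  chains <- list()
  for (i in seq_along(tracks$tracks)) {
    tr <- tracks$tracks[[i]]
    z <- extract_angle_changes(cbind(t = tr$t, x = tr$x, y = tr$y))
    chains[[names(tracks$tracks)[i]]] <-
      run_pmcmc(z, prior = prior, proposal = proposal, n_steps = n_steps,
                thin = thin, config = config, seed = seed + 104729L * i)
  }
  combined <- consensus_combine(chains)
  list(chains = chains, combined = combined,
       summary = summarize_posterior(combined))
}

## ---- datasets, config, provenance ---------------------------------------

#' Write a synthetic angle-change dataset to delimited text
#'
#' Writes the per-interval records (`k, t, x, y, theta_true, z, X_true`) as
#' CSV plus a JSON sidecar (`paste0(path, ".json")`) holding the generating
#' parameters.
#'
#' @param series an [angle_series] from [simulate_angle_dataset].
#' @param path output CSV path.
#' @param seed the generating seed, recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_angle_dataset <- function(series, path, seed = NULL) {
  stopifnot(inherits(series, "angle_series"))
  pos <- attr(series, "positions")
  params <- attr(series, "params")
  n <- length(series$values)
  d <- data.frame(k = seq_len(n),
                  t = if (!is.null(pos)) pos[2 + seq_len(n), "t"] else
                    (1 + seq_len(n)) * series$dt,
                  x = if (!is.null(pos)) pos[2 + seq_len(n), "x"] else NA,
                  y = if (!is.null(pos)) pos[2 + seq_len(n), "y"] else NA,
                  theta_true = if (!is.null(series$theta_true))
                    series$theta_true else NA,
                  z = series$values,
                  X_true = if (!is.null(series$states_true))
                    series$states_true[1 + seq_len(n)] else NA)
  utils::write.csv(d, path, row.names = FALSE)
  meta <- list(lambda = if (!is.null(params)) params$lambda else NULL,
               c = if (!is.null(params)) params$speed else NULL,
               kernel = if (!is.null(params)) params$kernel else NULL,
               gamma = if (!is.null(params)) params$gamma else NULL,
               sigma = series$sigma, dt = series$dt,
               t_final = (n + 1) * series$dt, seed = seed)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synthetic angle-change dataset written by [write_angle_dataset]
#'
#' @param path CSV path (the JSON sidecar is read when present).
#' @return an [angle_series] with available ground truth attached.
#' @export
read_angle_dataset <- function(path) {
  d <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  dt <- if (!is.null(meta$dt)) meta$dt else stats::median(diff(d$t))
  sigma <- if (!is.null(meta$sigma)) meta$sigma else NA_real_
  states <- if (!all(is.na(d$X_true))) c(NA_integer_, d$X_true) else NULL
  angle_series(d$z, dt = dt, sigma = sigma,
               theta_true = if (!all(is.na(d$theta_true))) d$theta_true else
                 NULL,
               states_true = states)
}

#' Read / write a structured configuration file
#'
#' YAML-backed configuration used by the command-line workbench; the
#' parse -> serialize -> parse round trip is the identity.
#'
#' @param path YAML path.
#' @return `read_config`: a named list. `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config a named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a machine-readable provenance record
#'
#' Records everything needed to reproduce a run bit-for-bit for the
#' deterministic stages: all parameters, the seed, and the package and R
#' versions.
#'
#' @param path output JSON path.
#' @param params named list of run parameters.
#' @param seed integer seed used for the run.
#' @param command optional command name.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, params, seed, command = NULL) {
  rec <- list(command = command,
              package = "vjpinfer",
              version = as.character(utils::packageVersion("vjpinfer")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed,
              params = params)
  jsonlite::write_json(rec[!vapply(rec, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
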