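# vjpinfer

Bayesian parameter inference for velocity jump process (VJP) models of
biological transport, from discretely and noisily observed single-particle
tracks.

Many transport processes — RNA–protein complexes stepping between
microtubules, bacterial run-and-tumble, cell migration — alternate straight
"runs" at roughly constant speed `c` with near-instantaneous reorientations
arriving at rate `λ`. Imaging gives positions only every `Δt` seconds, with
noise, so the moments of reorientation are never observed directly: a large
observed angle change may be a real reorientation, the lingering geometric
"correction" from an event in the *previous* frame interval, or just noise.
`vjpinfer` resolves this with a hidden-states formulation: each frame
interval carries a binary state `X_k` (reorientation or not), i.i.d.
Bernoulli(`β`) with `β = 1 − exp(−λΔt)`, and the observed angle change `z_k`
is emitted with a density `q_{X_{k−1}X_k}(z_k)` — derived in closed form for
the uniform reorientation kernel and convolved with wrapped-normal
measurement noise of s.d. `σ`. A bootstrap particle filter turns this into
an unbiased marginal-likelihood estimate, and pseudo-marginal
Metropolis–Hastings (particle MCMC) over `(log λ, log σ)` samples the exact
posterior. Rejection ABC with summary statistics (full series, threshold
count, transition matrix) is included for method comparison, along with
experimental-design utilities for the photon-budget trade-off
`σ = K/√Δt` and consensus Monte Carlo combination of per-track
subposteriors.

Intended users: quantitative biologists and methodologists fitting
run-and-reorient models to tracking data, and anyone planning imaging
experiments who needs to know how sampling interval, noise and track length
trade off against parameter identifiability.

## Worked example

Simulate a track at the reference conditions (`λ = 0.2 s⁻¹`, `c = 50 µm/s`,
`Δt = 0.25 s`, `T_final = 64 s`, `σ = 0.04 rad`) and re-infer the
parameters:

```r
library(vjpinfer)

params <- vjp_params(lambda = 0.2, speed = 50)
z <- simulate_angle_dataset(params, dt = 0.25, t_final = 64,
                            sigma = 0.04, seed = 1)
z
#> Angle-change series: 255 values at dt = 0.25 s (noise sd 0.04 rad)
sum(z$states_true)
#> [1] 13

ll <- bootstrap_filter(z, lambda = 0.2, sigma = 0.04,
                       filter_config(400), seed = 2)
ll
#> Particle filter log-likelihood estimate: 353.8946 (M = 400)

chain <- run_pmcmc(z, n_steps = 5000, thin = 2,
                   config = filter_config(200), seed = 3)
summarize_posterior(chain)
#> Posterior summary (natural scale, 95% credible intervals):
#>   lambda  median 0.2195, CI [0.183, 0.3446], ESS 98
#>   sigma   median 0.03913, CI [0.03568, 0.04251], ESS 127
```

Of 256 frame intervals, 13 truly contained a reorientation; the 95%
credible intervals recover both the rate (`0.2` in `[0.18, 0.34]`) and the
noise amplitude (`0.04` in `[0.036, 0.043]`) from a single noisy track.
Production-scale runs would use `n_steps = 50000` and 400 particles; the
short chain here is for illustration.

Multi-track data go through `read_tracks()` → `multi_track_inference()`,
which fits a subposterior per track and combines them by consensus Monte
Carlo. `design_sweep()` compares candidate `Δt` under a photon budget, and
`abc_rejection()` runs the ABC comparison. A thin command-line wrapper with
YAML configs and JSON provenance lives at `inst/scripts/vjpinfer.R`
(subcommands `simulate`, `infer-pmcmc`, `infer-abc`, `design-sweep`,
`tracks-infer`).

## Scientific background

The model, the emission-density derivations, all numerical choices and the
known limitations are documented in the methods vignette,
`vignettes/vjp-inference-methods.Rmd`.
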