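# rloopwalk

Kinetic modelling of R-loop formation by the type I CRISPR-Cas **Cascade**
surveillance complex, for single-molecule biophysicists and CRISPR
specificity researchers. Cascade finds its 32-bp target by zipping a
crRNA-DNA hybrid one base pair at a time; whether it commits to a target
— or to an off-target — is decided by the kinetics of that zipping.
`rloopwalk` implements the quantitative version of that picture: the
R-loop length is a continuous-time random walk on a one-dimensional
free-energy landscape, and everything measurable follows from first
passage on the resulting birth-death chain.

## The model

The landscape over R-loop length `n = 0..N` (energies in kBT) is

    G_0 = 0
    G_1 = dG_ini - ln(c/c0) + b
    G_{n+1} - G_n = b  (+ dG_MM if n+1 is a penalized mismatch position)

with per-base-pair bias `b = dG_bias + tau * dphi / kBT`, where `tau` is
the DNA torque (pN nm) and `dphi = 0.515` rad is the untwisting per
hybrid base pair. Rates obey detailed balance around a single stepping
rate `k_step`:

    k_n+ / k_{n+1}- = exp(-(G_{n+1} - G_n))
    k_0+ = k_step * exp(-dG_ini)
    k_m- = k_step * exp(+dG_MM)   at a penalized mismatch m

with the bias split half onto each direction. Mismatches at positions
6, 12, 18, 24, 30 carry no penalty (base pairing is disrupted there by
the Cas7 thumbs); a PAM-distal mismatch stretch truncates the chain; the
full-length locked R-loop is absorbing.

On top of the chain the package provides exact mean-first-passage-time,
splitting-probability, occupancy and coarse-rate solvers; kinetic
Monte-Carlo plus bead Brownian-dynamics simulation of the
magnetic-tweezers readout; hidden-Markov trajectory segmentation with
dwell-time rate extraction and the fast-transition correction;
triple-exponential analysis of bulk fluorescence kinetics; global
parameter fitting with profile confidence intervals; and prediction
surfaces for off-target recognition (mismatch position scans,
supercoiling-dependent seed lengths, double-mismatch proximity
matrices, in vivo torque estimates).

## Worked example

```r
library(rloopwalk)

params <- model_params(k_step = 2000, dG_ini = 8.5, dG_bias = 0.14)
target <- target_spec(32, mismatches = c("17" = 6.9))   # C:C at position 17

landscape <- build_landscape(target, params, torque = -6.7)
chain     <- landscape_to_rates(landscape, target, params)
verify_detailed_balance(chain, landscape)$ok
#> [1] TRUE

formation_time(target, params, torque = -6.7)
#> [1] 4.178597
formation_time(target_spec(32), params, torque = -6.7)  # matched target
#> [1] 3.467481

scan <- position_scan(6.9, params, torques = c(-6.7, -3.4))
seed_length(scan, -6.7)
#> [1] 6
seed_length(scan, -3.4)
#> [1] 16
```

A single C:C mismatch at position 17 slows locked R-loop formation from
3.5 s to 4.2 s at -6.7 pN nm — barely, because strong negative torque
drives the walk over the barrier. Reading the full position scan with a
10-fold slow-down threshold gives the effective seed: about 6 bp at
-6.7 pN nm, widening to about 16 bp at the weaker torque -3.4 pN nm.
Supercoiling, not protein architecture, sets the seed length.

The virtual instrument closes the loop on analysis code:

```r
truth <- model_params(k_step = 1900, dG_ini = 8.5, dG_bias = 0.14)
tgt   <- target_spec(32, distal_cutoff = 13, lock_competent = FALSE)
des   <- experiment_design(list(L12 = tgt), torques = -5, duration = 600, seed = 42)
traj  <- make_trajectories(des, truth)[[1]]
seg   <- segment_states(smooth_trace(traj$extension_nm, 120, 7.5)[seq(1, 72000, 16)],
                        K = 2, n_restarts = 5, seed = 7)
dwell_rates(seg, sample_rate = 7.5)[, 1:5]
#>   from_state to_state      rate        sem n_events
#> 1          1        2 0.2022519 0.02053557       97
#> 2          2        1 0.8400693 0.08529611       97
```

against model predictions k1 = 0.190 /s and k2 = 1.071 /s for this
target and torque (k2 comes out slightly low at 7.5 Hz bandwidth — the
missed-transition effect the correction procedure addresses).

## Layout

- `R/`, `src/` — model, solvers, simulators, analysis (R + Rcpp)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/rloop-random-walk.Rmd` — the methods vignette
- `inst/scripts/` — thin CLI wrappers (`predict.R`, `synth.R`)
- `scripts/acceptance.R` — end-to-end reproduction script
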