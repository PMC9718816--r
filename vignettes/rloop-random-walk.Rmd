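---
title: "Modelling Cascade R-loop formation as a biased random walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Cascade R-loop formation as a biased random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopwalk)
```

## The model

Type I CRISPR-Cas Cascade recognises a DNA target by forming an R-loop: the
crRNA invades the duplex next to the PAM and base-pairs with the target
strand one base pair at a time, up to the full 32-bp hybrid. `rloopwalk`
treats the R-loop length $n$ as a one-dimensional random walk on
$n = 0, 1, \dots, N$ over a free-energy landscape $G_n$ (in units of
$k_BT$) built from four ingredients:

* an initiation penalty $\Delta G_{\mathrm{ini}}$ paid with the first base
  pair (PAM binding and nucleation have no separate kinetic barrier), with
  a chemical-potential correction $-\ln(c/c_0)$ for the Cascade
  concentration $c$;
* a per-base-pair bias: the work $\tau\,\Delta\varphi_{bp}$ done against
  the applied torque $\tau$, with $\Delta\varphi_{bp} = 0.515$ rad of DNA
  untwisting per hybrid base pair, plus an intrinsic zero-torque bias
  $\Delta G_{\mathrm{bias}}$ per bp;
* a penalty $\Delta G_{\mathrm{MM}}$ added to every state at and beyond a
  mismatched position (mismatches at positions 6, 12, 18, 24 and 30
  contribute nothing because the Cas7 thumbs disrupt base pairing there
  anyway);
* locking of the full-length R-loop, treated as absorbing on the
  experimental timescale, so the locking free energy never enters a rate.

Rates come from detailed balance around a single stepping rate
$k_{\mathrm{step}}$: all interior transitions occur at $k_{\mathrm{step}}$
modified by half the step free-energy difference in each direction (the
transition barrier sits midway between lattice positions). Initiation is
$k_0^+ = k_{\mathrm{step}} e^{-\Delta G_{\mathrm{ini}}}$; at a mismatch the
forward step keeps the plain stepping rate — the rate-limiting event is
disruption of the DNA base pair — and the entire penalty accelerates the
backward step, $k_m^- = k_{\mathrm{step}} e^{+\Delta G_{\mathrm{MM}}}$.
Targets with a continuous PAM-distal mismatch stretch are cut off at the
first mismatched position (infinite free energy beyond).

Every measured quantity is a first-passage property of this chain:

* locked-R-loop formation times are mean first-passage times (MFPTs) from
  $0$ to $N$;
* the two-to-four discrete states seen in supercoiling traces are
  free-energy basins delimited by mismatch barriers, with the
  lowest-energy microstate as the state position; dwell times and
  splitting probabilities of the chain give the coarse rates
  $k_1, k_2, \dots$;
* occupancy histograms are Boltzmann weights summed per basin.

## Numerical choices

MFPTs are computed three ways and cross-checked in the tests: a dense
linear solve of the first-passage system (default), the transposed
occupancy-time system (the steady-state single-particle-flux formulation
with transmissive boundaries, solved as a linear system rather than by
iterating the master equation), and a vectorised nested-sum closed form
for one-sided problems, which the fitting code uses because it is an
order of magnitude faster on 32-state chains. Agreement is required to
1e-9 relative. Boltzmann weights subtract the minimum energy before
exponentiation; basins below 1e-12 relative weight report occupancy 0.

Two conventions were genuinely open and are resolved as follows.

* **Bias on the initiation step.** The torque/bias half-split is applied
  to every step including initiation ($0 \to 1$) and collapse
  ($1 \to 0$), since the rate equations hold for "any valid position";
  the measured initiation rate is indeed only weakly torque-dependent
  because the half-split is small compared to the initiation penalty. A
  `bias_on_initiation = FALSE` flag moves the first step's full bias
  onto the backward rate instead; detailed balance holds either way.
* **Basin boundaries.** The microstate at a penalized mismatch position
  — the state that has already paid the penalty — opens the next basin,
  so an intermediate before a mismatch at $m$ spans $1 \dots m-1$ and has
  representative $m-1$ under net negative bias.

## The virtual instrument

The magnetic-tweezers readout is simulated in two tiers. The latent
R-loop length is simulated either by exact-event (Gillespie) sampling or
by a fixed-step scheme taking a $\pm 1$ bp step per $\Delta t$ with
probability $k^\pm \Delta t$ (valid when $\Delta t \cdot k \le 0.1$; the
two agree by a two-sample test on dwell distributions). The length is
mapped instantaneously to an equilibrium DNA extension — an R-loop of $n$
bp absorbs $n \Delta\varphi_{bp} / 2\pi$ turns, each worth
`slope_nm_per_turn` of extension on the linear flank of the supercoiling
curve — and a bead relaxes toward it by overdamped Brownian dynamics with
stiffness $\kappa$ and Stokes drag $\gamma = 6\pi\eta R$, sampled as
per-frame averages at 120 Hz. Defaults are $\kappa = 0.01$ pN/nm and $R =
800$ nm; the separate $\kappa = 1.25\times10^{-3}$ pN/nm appears only in
the analytic detection-resolution formula
$\tau = \mathrm{SNR}^2 k_BT \gamma / (\kappa \Delta z)^2$, whose default
inputs give $\tau \approx 0.14$ s, a bandwidth of roughly 7 Hz. The
slope of the supercoiling curve is not a published number; the default of
55 nm/turn is typical for kilobase-scale DNA at sub-piconewton force, and
simulation-based tests avoid depending on its value (it scales signal and
noise together).

What the generator deliberately does not emulate: camera noise beyond
bead diffusion, instrument drift, bead loss, torque fluctuation, and the
positive-supercoiling removal cycles between locking events. Passing
closure tests therefore demonstrate correctness of the analysis chain
under the model's own statistical assumptions, not robustness to
instrumental artefacts of real traces.

## Trajectory analysis

Recorded traces are smoothed by a sliding average from 120 Hz to 7.5 Hz
and segmented with a maximum-likelihood Gaussian-emission hidden Markov
model with the state count fixed in advance (2, 3 or 4 by target design),
EM-fitted from several deterministic and jittered initialisations
(k-means centers, quantiles, an equispaced grid) with the Viterbi path
returned; a half-amplitude threshold detector is kept as an independent
cross-check for two-state traces. Fixing $K$ makes variational
model-selection machinery unnecessary, which is why a plain maximum-likelihood HMM
is used instead of variational-Bayes segmentation tools; equivalence is
established on simulated data only. Rates come from mean dwell times per state and
observed transition fractions, $k_{r\to d} = P(d)/\bar\tau_r$, with SEM
$= k/\sqrt{n}$; a single-exponential fit to each dwell survival function
is reported alongside and must agree with the mean within 10% for an
estimate to be marked confident. Dwells truncated by the trace ends are
discarded rather than modelled as censored: traces in this regime hold
on the order of a thousand transitions, so the loss is negligible.

Transitions faster than the detection bandwidth are systematically
missed. The package reproduces this: in a two-mismatch design the
detected count of intermediate-to-intermediate transitions falls well
short of the latent truth. The correction procedure raises the full
R-loop collapse rate $k_4$ to the level measured for strong mismatches
(0.8-1.2 s$^{-1}$) and scales $k_3$ by the same factor, preserving
$k_3/k_4$ — the equilibrium constant across the mismatch, which is what
penalty estimation uses. Validation on the virtual instrument shows the
correction restores $k_4$ within sampling error and moves $k_3$ toward
the truth; when the under-counting is severe the proportional rule still
under-corrects $k_3$ itself, which is why the package reports the
corrected flag rather than silently replacing estimates.

## Bulk fluorescence

Zero-torque formation kinetics are analysed by control subtraction and a
least-squares fit of $F(t) = F_0 + \sum_{i=1}^3 A_i(1 - e^{-k_i t})$ with
non-negative amplitudes capped at 1.5 times the observed amplitude and
rates in $[10^{-5}, 10^3]$ s$^{-1}$, from multiple log-spaced rate starts.
Two summary times are reported: the sequential-step mean
$\langle t\rangle = 1/k_1 + 1/k_2 + 1/k_3$, and an amplitude-weighted
mixture mean $\sum A_i/k_i / \sum A_i$ over components actually resolved
within the fitted window (rise above 1% of the total). The distinction
matters for model-generated data: the chain's first-passage distribution
at zero torque is initiation-limited and close to single-exponential, so
two of three fitted components are degenerate there and the sequential
reading would add their arbitrary time constants; the weighted mean is
the mean of the fitted rise treated as a CDF and tracks the chain's MFPT
within 20% across mismatch positions in the tested regime. The additive
offset is floated and reported.

## Global fitting

`fit_global()` minimises weighted squared residuals on $\log_{10}$ of the
observables (rates span three orders of magnitude; SEMs are propagated to
the log scale), with a linear-scale objective selectable. Optimisation is
L-BFGS-B from multiple starts — log-uniform in $k_{\mathrm{step}}$ over
$[10^2, 10^5]$ s$^{-1}$, uniform in the energies over $[0, 15]\,k_BT$ and
the bias over $[-1, 1]\,k_BT$/bp — deterministic given a seed. Parameter
standard deviations come from the inverse Hessian of the chi-square
objective; `confidence_intervals()` walks the profile likelihood
(re-optimising the other parameters) to the 0.67 chi-square quantile,
flagging profiles that run into the bounds. Torque uncertainty
(about 0.25 pN nm per condition) is treated as abscissa error and not
propagated — a known limitation of ordinary weighted least squares here.

## Synthetic experiment designs

The generator's defaults mirror the study conditions: 32-bp hybrid,
excluded positions {6, 12, 18, 24, 30}, initiation penalty 8.5 $k_BT$ at
the 0.5 nM reference concentration, intrinsic bias 0.14 $k_BT$/bp,
mismatch penalty 6.9 $k_BT$ for the strong (C:C) mismatch, stepping rate
1900-2000 s$^{-1}$, torques within $[-10, 0]$ pN nm, and 27 events per
locked-formation condition, matching the event counts of the formation-
time experiments. Rate tables perturb exact model predictions with the
sampling noise of an $n$-event exponential mean, so the reported SEM
structure ($\bar\tau/\sqrt{n}$) is exact by construction. The
parameter-recovery checks run the full designs — six matched lengths by
five torques with the stepping rate free, and fifteen single-mismatch
targets plus the matched target over six torques with penalty, stepping
rate and bias free — at 10 seeds in the acceptance script and 3 in the
test suite; closure and bandwidth demonstrations use 400-900 s
trajectories, long enough for roughly a hundred slow-state transitions
while keeping the default test run around a minute.

## Worked example

```{r example, eval = FALSE}
params <- model_params(k_step = 2000, dG_ini = 8.5, dG_bias = 0.14)
target <- target_spec(32, mismatches = c("17" = 6.9))

landscape <- build_landscape(target, params, torque = -6.7)
chain <- landscape_to_rates(landscape, target, params)
verify_detailed_balance(chain, landscape)$ok

formation_time(target, params, torque = -6.7)       # seconds
scan <- position_scan(6.9, params, torques = c(-6.7, -3.4))
seed_length(scan, -6.7)                             # ~6 bp
seed_length(scan, -3.4)                             # ~15-16 bp
```

## Known limitations

* Mismatches are characterised only by a free-energy penalty; there is no
  sequence-to-penalty prediction and no nearest-neighbour thermodynamics.
* No periodic 6-bp modulation of the landscape beyond the zero-penalty
  excluded positions.
* The stepping rate is sequence-independent by construction.
* Relaxation spectra of the chain are not computed; only means, splitting
  probabilities and stationary weights are used.
* The locking free energy is carried but never constrained: none of the
  modelled observables depend on it once locking is absorbing.
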