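#' Simulation configuration
#'
#' @param duration Simulated time, seconds.
#' @param dt Integrator time step, seconds. Required for the fixed-step
#'   kinetic Monte-Carlo method and for the bead Brownian dynamics; ignored
#'   by the exact-event method.
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @param method `"exact-event"` (Gillespie, default) or `"fixed-step"`.
#' @param record_every For fixed-step runs, record the state every this many
#'   steps (thins the output; statistics are unaffected).
#' @param max_events Guard against runaway event storage.
#' @return An object of class `rloop_sim_config`.
#' @export
sim_config <- function(duration, dt = NULL, seed = NULL,
                       method = c("exact-event", "fixed-step"),
                       record_every = 1L, max_events = 5e7) {
  method <- match.arg(method)
  stopifnot(duration > 0)
  if (method == "fixed-step" && is.null(dt))
    stop("fixed-step simulation requires dt")
  structure(list(duration = duration, dt = dt, seed = seed, method = method,
                 record_every = as.integer(record_every),
                 max_events = max_events),
            class = "rloop_sim_config")
}

#' Magnetic-tweezers bead and DNA readout model
#'
#' Parameters of the virtual instrument: the supercoiled-DNA stretch
#' stiffness `kappa`, the axial drag `gamma` of the bead (derived from the
#' Stokes formula `6 pi eta R` when not given), and the slope of the
#' supercoiling curve converting absorbed turns into extension.
#'
#' @param kappa Stretch stiffness of the supercoiled DNA, pN/nm.
#' @param radius Effective hydrodynamic bead radius, nm.
#' @param viscosity Medium viscosity, Pa s.
#' @param gamma Axial drag coefficient, pN s/nm. Defaults to Stokes drag.
#' @param slope_nm_per_turn Extension gained per turn of supercoiling
#'   absorbed by the R-loop, nm/turn.
#' @param sample_rate Camera sampling rate, Hz.
#' @param kBT Thermal energy, pN nm.
#' @return An object of class `rloop_bead_model`.
#' @export
bead_model <- function(kappa = 0.01, radius = 800, viscosity = 1e-3,
                       gamma = NULL, slope_nm_per_turn = 55,
                       sample_rate = 120, kBT = 4.114) {
  if (is.null(gamma)) gamma <- 6 * pi * viscosity * radius * 1e-6
  stopifnot(kappa > 0, gamma > 0, slope_nm_per_turn > 0, sample_rate > 0)
  structure(list(kappa = kappa, radius = radius, viscosity = viscosity,
                 gamma = gamma, slope_nm_per_turn = slope_nm_per_turn,
                 sample_rate = sample_rate, kBT = kBT),
            class = "rloop_bead_model")
}

#' Simulate the R-loop length random walk
#'
#' Stochastic simulation of the latent R-loop length process on a rate
#' chain. The exact-event method draws exponential waiting times
#' (Gillespie); the fixed-step method takes a +-1 bp step per time step
#' `dt` with probabilities `k_plus * dt` / `k_minus * dt`, which requires
#' `dt * max(rate) <= 0.1`.
#'
#' @param chain An `rloop_rate_chain`.
#' @param config An [sim_config()] object.
#' @param start Initial microstate (default 0, unbound).
#' @return An object of class `rloop_sim`: a list with `events` (data.frame
#'   `time`, `state`; for fixed-step runs a regular time grid), `method`,
#'   `seed`, `duration` and `chain`.
#' @export
simulate_rloop <- function(chain, config, start = 0L) {
  stopifnot(inherits(chain, "rloop_rate_chain"),
            inherits(config, "rloop_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$method == "fixed-step") {
    rmax <- max(chain$k_plus, chain$k_minus)
    if (config$dt * rmax > 0.1)
      stop(sprintf("dt = %g too large for fixed-step: max rate %g /s needs dt <= %g",
                   config$dt, rmax, 0.1 / rmax))
    n_steps <- floor(config$duration / config$dt)
    states <- cpp_fixed_step(chain$k_plus, chain$k_minus, as.integer(start),
                             config$dt, n_steps, chain$absorbing_top,
                             config$record_every)
    events <- data.frame(
      time = seq(0, by = config$dt * config$record_every,
                 length.out = length(states)),
      state = states)
  } else {
    res <- cpp_gillespie(chain$k_plus, chain$k_minus, as.integer(start),
                         config$duration, chain$absorbing_top,
                         config$max_events)
    if (isTRUE(res$truncated))
      warning("simulation truncated at max_events before reaching duration")
    events <- data.frame(time = res$time, state = res$state)
  }
  structure(list(events = events, method = config$method, seed = config$seed,
                 duration = config$duration, chain = chain),
            class = "rloop_sim")
}

#' Convert R-loop length to equilibrium DNA extension offset
#'
#' An R-loop of n base pairs absorbs `n * dphi_bp / (2 pi)` turns of the
#' applied negative supercoiling; on the linear flank of the supercoiling
#' curve each absorbed turn changes the DNA extension by
#' `slope_nm_per_turn`.
#'
#' @param rloop_bp R-loop length(s), bp.
#' @param bead An [bead_model()] object.
#' @param dphi_bp Untwisting angle per bp, radians.
#' @return Extension offset(s) in nm (0 for no R-loop).
#' @export
rloop_to_extension <- function(rloop_bp, bead, dphi_bp = 0.515) {
  stopifnot(inherits(bead, "rloop_bead_model"))
  bead$slope_nm_per_turn * rloop_bp * dphi_bp / (2 * pi)
}

#' Brownian-dynamics simulation of the tethered bead
#'
#' Simulates the camera-sampled bead position tracking a time-dependent DNA
#' equilibrium extension. Per step the bead drifts by
#' `dt * (-kappa (z_bead - z_dna)) / gamma` and diffuses with variance
#' `2 (kBT/gamma) dt`; the output is block-averaged per camera frame at
#' `bead$sample_rate`.
#'
#' @param z_dna Either a numeric vector of equilibrium extensions paired
#'   with `times`, or an `rloop_sim` object (converted through
#'   [rloop_to_extension()]).
#' @param bead An [bead_model()] object.
#' @param config An [sim_config()] object; `config$dt` defaults to
#'   `gamma / kappa / 50` and must satisfy `dt <= 0.1 * gamma / kappa`.
#' @param times Event times for a vector `z_dna` (step function).
#' @param dphi_bp Untwisting angle used for `rloop_sim` input.
#' @return Data frame with `time` and `extension` (nm) at the sample rate.
#' @export
simulate_bead <- function(z_dna, bead, config, times = NULL,
                          dphi_bp = 0.515) {
  stopifnot(inherits(bead, "rloop_bead_model"),
            inherits(config, "rloop_sim_config"))
  if (inherits(z_dna, "rloop_sim")) {
    times <- z_dna$events$time
    z_dna <- rloop_to_extension(z_dna$events$state, bead, dphi_bp)
  }
  if (is.null(times) || length(times) != length(z_dna))
    stop("z_dna and times must be paired vectors")
  tau_relax <- bead$gamma / bead$kappa
  dt <- if (is.null(config$dt)) tau_relax / 50 else config$dt
  if (dt > 0.1 * tau_relax)
    stop(sprintf("dt = %g too large for bead relaxation time %g s (need dt <= %g)",
                 dt, tau_relax, 0.1 * tau_relax))
  if (!is.null(config$seed)) set.seed(config$seed)
  z <- cpp_bead_bd(times, z_dna, config$duration, dt, bead$kappa, bead$gamma,
                   bead$kBT, bead$sample_rate, z_dna[1])
  data.frame(time = seq_along(z) / bead$sample_rate, extension = z)
}

#' Temporal resolution of the bead-on-supercoiled-DNA detection
#'
#' Minimum dwell time resolvable at a given signal-to-noise ratio:
#' `tau = SNR^2 kBT gamma / (kappa dz)^2`. With the instrument defaults
#' (SNR 3, 50 nm steps, kappa 1.25e-3 pN/nm, gamma 1.5e-5 pN s/nm) this is
#' about 0.14 s, i.e. a detection bandwidth of roughly 7 Hz.
#'
#' @param snr Required signal-to-noise ratio (dimensionless).
#' @param dz Characteristic DNA-length change to resolve, nm.
#' @param kappa Spring constant of the supercoiled DNA, pN/nm.
#' @param gamma Bead drag coefficient, pN s/nm.
#' @param kBT Thermal energy, pN nm.
#' @return Resolution time in seconds.
#' @export
detection_resolution <- function(snr = 3, dz = 50, kappa = 1.25e-3,
                                 gamma = 1.5e-5, kBT = 4.114) {
  stopifnot(snr > 0, dz > 0, kappa > 0, gamma > 0, kBT > 0)
  snr^2 * kBT * gamma / (kappa * dz)^2
}

#' Latent R-loop length at arbitrary times
#'
#' Evaluates the piecewise-constant state path of a simulation on a given
#' time grid (used to attach ground truth to sampled trajectories).
#'
#' @param sim An `rloop_sim` object.
#' @param at Numeric vector of times.
#' @return Integer vector of R-loop lengths at `at`.
#' @export
rloop_at <- function(sim, at) {
  stopifnot(inherits(sim, "rloop_sim"))
  idx <- findInterval(at, sim$events$time)
  idx[idx < 1L] <- 1L
  sim$events$state[idx]
}
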