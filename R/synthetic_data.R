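#' Design of a synthetic single-molecule experiment
#'
#' Describes the conditions under which synthetic observations are
#' generated: which targets, which torques, how many events per condition
#' (27 by default, the scale of the locked-formation experiments), how long
#' each trajectory runs, and the virtual-instrument parameters.
#'
#' @param targets Named list of [target_spec()] objects.
#' @param torques Numeric vector of torques, pN nm.
#' @param events_per_condition Events averaged per condition.
#' @param duration Trajectory duration, seconds.
#' @param bead An [bead_model()] object.
#' @param seed Integer seed.
#' @return An object of class `rloop_design`.
#' @export
experiment_design <- function(targets, torques, events_per_condition = 27L,
                              duration = 3000, bead = bead_model(),
                              seed = 1L) {
  stopifnot(is.list(targets), length(names(targets)) == length(targets),
            events_per_condition >= 1L)
  structure(list(targets = targets, torques = torques,
                 events_per_condition = as.integer(events_per_condition),
                 duration = duration, bead = bead, seed = as.integer(seed)),
            class = "rloop_design")
}

#' Generate synthetic rate / formation-time tables
#'
#' For each target and torque the model's coarse rates (cut-off targets) or
#' locked formation time (lock-competent targets) are computed exactly,
#' then perturbed with the sampling noise of the experiment: the observed
#' value is the reciprocal mean of `n` exponential dwells drawn at the true
#' rate, and the reported SEM is the mean dwell divided by `sqrt(n)`. The
#' generating (truth) value is stored alongside.
#'
#' @param design An [experiment_design()] object.
#' @param truth A [model_params()] object used as ground truth.
#' @param observables Optional character vector restricting which coarse
#'   rates are emitted for cut-off targets (default: all).
#' @return Data frame with columns `target_id`, `torque`, `observable`,
#'   `value`, `sem`, `truth`, `n_events`.
#' @export
make_rate_tables <- function(design, truth, observables = NULL) {
  stopifnot(inherits(design, "rloop_design"),
            inherits(truth, "rloop_params"))
  set.seed(design$seed)
  n <- design$events_per_condition
  rows <- list()
  for (id in names(design$targets)) {
    tg <- design$targets[[id]]
    for (tau in design$torques) {
      if (tg$lock_competent) {
        model <- data.frame(observable = "formation_time",
                            truth = formation_time(tg, truth, tau))
      } else {
        landscape <- build_landscape(tg, truth, tau)
        cr <- coarse_rates(landscape_to_rates(landscape, tg, truth),
                           coarse_states(landscape))
        model <- data.frame(observable = cr$label, truth = cr$rate)
        if (!is.null(observables))
          model <- model[model$observable %in% observables, , drop = FALSE]
      }
      for (i in seq_len(nrow(model))) {
        tr <- model$truth[i]
        is_time <- model$observable[i] == "formation_time"
        true_rate <- if (is_time) 1 / tr else tr
        mean_dwell <- mean(stats::rexp(n, rate = true_rate))
        value <- if (is_time) mean_dwell else 1 / mean_dwell
        sem <- if (is_time) mean_dwell / sqrt(n)
               else (1 / mean_dwell) / sqrt(n)
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = id, torque = tau,
          observable = model$observable[i], value = value, sem = sem,
          truth = tr, n_events = n, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic magnetic-tweezers trajectories
#'
#' Runs the full virtual instrument per condition: exact-event simulation
#' of the R-loop length walk, conversion to equilibrium DNA extension,
#' Brownian dynamics of the bead, and camera sampling at the bead model's
#' sample rate. The latent R-loop length and the true coarse-state label at
#' each sample are stored for detection benchmarking.
#'
#' @inheritParams make_rate_tables
#' @return Named list (one entry per target x torque, named
#'   `"<id>@<torque>"`) of data frames with columns `time_s`,
#'   `extension_nm`, `rloop_bp`, `true_state`, carrying attributes `seed`,
#'   `target_id` and `torque`.
#' @export
make_trajectories <- function(design, truth) {
  stopifnot(inherits(design, "rloop_design"),
            inherits(truth, "rloop_params"))
  out <- list()
  cond <- 0L
  for (id in names(design$targets)) {
    tg <- design$targets[[id]]
    for (tau in design$torques) {
      cond <- cond + 1L
      seed <- design$seed + cond
      landscape <- build_landscape(tg, truth, tau)
      chain <- landscape_to_rates(landscape, tg, truth)
      cfg <- sim_config(duration = design$duration, seed = seed)
      sim <- simulate_rloop(chain, cfg)
      traj <- simulate_bead(sim, design$bead,
                            sim_config(duration = design$duration))
      basins <- coarse_states(landscape)
      lat <- rloop_at(sim, traj$time)
      lab <- basins$label[findInterval(lat, basins$from)]
      df <- data.frame(time_s = traj$time, extension_nm = traj$extension,
                       rloop_bp = lat, true_state = lab,
                       stringsAsFactors = FALSE)
      attr(df, "seed") <- seed
      attr(df, "target_id") <- id
      attr(df, "torque") <- tau
      out[[paste0(id, "@", tau)]] <- df
    }
  }
  out
}

#' Generate synthetic zero-torque fluorescence traces
#'
#' Emulates the bulk donor-quencher assay: for each lock-competent target
#' the first-passage-time distribution of locked R-loop formation at zero
#' torque is sampled by exact-event simulation over a population of
#' molecules; the population signal is the formed fraction versus time,
#' scaled, offset and overlaid with Gaussian noise. A no-protein control
#' (flat noisy baseline) is generated per trace.
#'
#' @inheritParams make_rate_tables
#' @param n_molecules Molecules per trace.
#' @param t_end Trace length, seconds (default: 5x the WT mean formation
#'   time).
#' @param dt Sampling interval, seconds.
#' @param amplitude,offset,noise_sd Signal scale, baseline and noise.
#' @return Named list per target: list with `trace` and `control` data
#'   frames (columns `time`, `signal`) and `fpt` (the sampled
#'   first-passage times).
#' @export
make_fluorescence <- function(design, truth, n_molecules = 200L,
                              t_end = NULL, dt = NULL, amplitude = 1,
                              offset = 0.1, noise_sd = 0.02) {
  stopifnot(inherits(design, "rloop_design"),
            inherits(truth, "rloop_params"))
  set.seed(design$seed)
  out <- list()
  for (id in names(design$targets)) {
    tg <- design$targets[[id]]
    if (!tg$lock_competent) next
    chain <- build_rate_chain(tg, truth, torque = 0)
    mt <- mfpt(chain, 0L, tg$N_eff, method = "closed_form")
    te <- if (is.null(t_end)) 5 * mt else t_end
    step <- if (is.null(dt)) te / 500 else dt
    fpt <- cpp_fpt_sample(chain$k_plus, chain$k_minus, 0L, tg$N_eff,
                          n_molecules, t_max = 100 * mt)
    tt <- seq(0, te, by = step)
    frac <- vapply(tt, function(t0) mean(fpt <= t0), numeric(1))
    trace <- data.frame(
      time = tt,
      signal = offset + amplitude * frac + stats::rnorm(length(tt), 0,
                                                        noise_sd))
    control <- data.frame(
      time = tt,
      signal = offset + stats::rnorm(length(tt), 0, noise_sd))
    out[[id]] <- list(trace = trace, control = control, fpt = fpt)
  }
  out
}
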