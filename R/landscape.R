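#' Physical constants of the R-loop random-walk model
#'
#' Thermal energy and the DNA untwisting angle per base pair of R-loop.
#' The default thermal energy corresponds to 25 degrees C. The untwisting
#' angle of 0.515 rad (29.5 degrees) per hybrid base pair is a fixed model
#' constant: forming one base pair of R-loop unwinds the duplex by one
#' helical step.
#'
#' @param kBT_pNnm Thermal energy in pN nm. Default 4.114 (25 degrees C).
#' @param dphi_bp Untwisting angle per bp of R-loop, radians. Default 0.515.
#' @return An object of class `rloop_constants`.
#' @export
physical_constants <- function(kBT_pNnm = 4.114, dphi_bp = 0.515) {
  stopifnot(is.numeric(kBT_pNnm), length(kBT_pNnm) == 1L, kBT_pNnm > 0,
            is.numeric(dphi_bp), length(dphi_bp) == 1L, dphi_bp > 0)
  structure(list(kBT_pNnm = kBT_pNnm, dphi_bp = dphi_bp),
            class = "rloop_constants")
}

#' Specify a DNA target for R-loop formation
#'
#' A target is described by the length of the crRNA-DNA hybrid (32 bp for
#' Cascade), the internal mismatch positions with their free-energy
#' penalties, and optionally a PAM-distal stretch of continuous mismatches
#' that truncates the landscape. Positions are 1-based, counted from the PAM.
#'
#' Mismatches at positions 6, 12, 18, 24 and 30 contribute no penalty: base
#' pairing in the crRNA-DNA hybrid is disrupted there by the Cas7 thumbs, so
#' a DNA mutation at these positions has no energetic consequence. A
#' `distal_cutoff` marks the first base of a terminal mismatch stretch; the
#' chain then ends at `distal_cutoff - 1` (infinite free energy beyond) and
#' the target cannot lock.
#'
#' @param hybrid_length Full protospacer length in bp. Default 32.
#' @param mismatches Either `NULL`, a data.frame with columns `position` and
#'   `penalty` (kBT), or a named numeric vector `c("17" = 6.9)`.
#' @param distal_cutoff Optional 1-based position of the first base of the
#'   PAM-distal mismatch stretch. Must be >= 2.
#' @param lock_competent Can the full-length R-loop lock? Defaults to `TRUE`
#'   unless a distal cutoff is set (cut-off targets never reach full length).
#' @param excluded_positions Positions with forced zero penalty.
#' @return An object of class `rloop_target`, with element `N_eff`, the last
#'   reachable microstate.
#' @export
target_spec <- function(hybrid_length = 32L, mismatches = NULL,
                        distal_cutoff = NULL,
                        lock_competent = is.null(distal_cutoff),
                        excluded_positions = c(6L, 12L, 18L, 24L, 30L)) {
  hybrid_length <- as.integer(hybrid_length)
  stopifnot(hybrid_length >= 1L)
  if (is.null(mismatches)) {
    mismatches <- data.frame(position = integer(0), penalty = numeric(0))
  } else if (is.numeric(mismatches) && !is.null(names(mismatches))) {
    mismatches <- data.frame(position = as.integer(names(mismatches)),
                             penalty = unname(mismatches))
  }
  stopifnot(is.data.frame(mismatches),
            all(c("position", "penalty") %in% names(mismatches)))
  mismatches$position <- as.integer(mismatches$position)
  if (anyDuplicated(mismatches$position))
    stop("mismatch positions must be unique")
  if (any(mismatches$position < 1L | mismatches$position > hybrid_length))
    stop("mismatch positions must lie in 1..hybrid_length")
  if (any(mismatches$penalty < 0, na.rm = TRUE))
    stop("mismatch penalties must be >= 0")
  if (!is.null(distal_cutoff)) {
    distal_cutoff <- as.integer(distal_cutoff)
    if (distal_cutoff <= 1L)
      stop("distal_cutoff must be >= 2 (no reachable states otherwise)")
    if (distal_cutoff > hybrid_length)
      stop("distal_cutoff beyond hybrid length")
    if (isTRUE(lock_competent))
      stop("a cut-off target cannot be lock-competent")
    lock_competent <- FALSE
  }
  N_eff <- if (is.null(distal_cutoff)) hybrid_length else distal_cutoff - 1L
  structure(list(hybrid_length = hybrid_length,
                 mismatches = mismatches,
                 distal_cutoff = distal_cutoff,
                 lock_competent = isTRUE(lock_competent),
                 excluded_positions = as.integer(excluded_positions),
                 N_eff = N_eff),
            class = "rloop_target")
}

#' Kinetic and energetic parameters of the random-walk model
#'
#' @param k_step Unbiased single base-pair stepping rate, 1/s.
#' @param dG_ini Initiation penalty at the reference concentration `c0`, kBT.
#' @param dG_bias Intrinsic (zero-torque) free-energy bias per bp, kBT/bp.
#'   Positive values tilt the landscape uphill toward the PAM-distal end.
#' @param dG_lock Free-energy decrease upon locking of the full R-loop, kBT.
#'   Locking is treated as absorbing on the experimental timescale, so this
#'   value never enters a rate; it is carried for landscape export only.
#' @param concentration Cascade concentration, molar.
#' @param c0 Reference concentration at which `dG_ini` is quoted, molar.
#' @param constants A [physical_constants()] object.
#' @return An object of class `rloop_params`.
#' @export
model_params <- function(k_step = 2000, dG_ini = 8.5, dG_bias = 0.14,
                         dG_lock = 0, concentration = c0, c0 = 0.5e-9,
                         constants = physical_constants()) {
  stopifnot(k_step > 0, dG_lock >= 0, c0 > 0,
            inherits(constants, "rloop_constants"))
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      concentration <= 0)
    stop("concentration must be a single positive number")
  structure(list(k_step = k_step, dG_ini = dG_ini, dG_bias = dG_bias,
                 dG_lock = dG_lock, concentration = concentration, c0 = c0,
                 constants = constants),
            class = "rloop_params")
}

#' Total free-energy bias per base pair under torque
#'
#' The applied torque tau biases every 1-bp extension step by the work done
#' against the torque, `tau * dphi_bp`, on top of the intrinsic bias. A
#' negative (unwinding) torque gives a negative, downhill bias.
#'
#' @param params An [model_params()] object.
#' @param torque Torque in pN nm (negative = negative supercoiling).
#' @return Bias per bp in kBT.
#' @export
total_bias_per_bp <- function(params, torque) {
  stopifnot(inherits(params, "rloop_params"))
  params$dG_bias +
    torque * params$constants$dphi_bp / params$constants$kBT_pNnm
}

#' Concentration-adjusted initiation penalty
#'
#' The chemical potential of the Cascade complexes shifts the initiation
#' penalty by `-ln(c/c0)`: doubling the concentration lowers the penalty by
#' ln 2 and hence doubles the initiation rate.
#'
#' @inheritParams total_bias_per_bp
#' @return Effective initiation penalty in kBT at `params$concentration`.
#' @export
concentration_adjusted_dG_ini <- function(params) {
  stopifnot(inherits(params, "rloop_params"))
  params$dG_ini - log(params$concentration / params$c0)
}

#' Build the free-energy landscape over R-loop length
#'
#' Constructs the per-base-pair free energies `G_n` (kBT) for
#' `n = 0..N_eff`, with `G_0 = 0` the unbound reference state. The first
#' step carries the concentration-adjusted initiation penalty plus the total
#' per-bp bias; every further step adds the bias, and a penalized mismatch
#' at position m adds its penalty to the step into m, shifting all states at
#' and beyond m equally upward. Penalties at excluded positions are dropped;
#' mismatches beyond the distal cut-off are ignored with a warning.
#'
#' @param target A [target_spec()] object.
#' @param params A [model_params()] object.
#' @param torque Torque in pN nm.
#' @return An object of class `rloop_landscape` with elements `energies`
#'   (numeric, `G_0..G_N_eff`), `N_eff`, `mismatch_steps` (named numeric:
#'   applied penalty by position), `torque`, `bias_per_bp`, `dG_ini_eff`,
#'   and `locked_energy` (`G_N - dG_lock`, lock-competent targets only).
#' @export
build_landscape <- function(target, params, torque = 0) {
  stopifnot(inherits(target, "rloop_target"), inherits(params, "rloop_params"))
  N <- target$N_eff
  b <- total_bias_per_bp(params, torque)
  dG_ini_eff <- concentration_adjusted_dG_ini(params)
  mm <- target$mismatches
  mm <- mm[!(mm$position %in% target$excluded_positions), , drop = FALSE]
  beyond <- mm$position > N
  if (any(beyond)) {
    warning(sprintf("mismatch position(s) %s beyond the cut-off chain (N_eff = %d); ignored",
                    paste(mm$position[beyond], collapse = ", "), N))
    mm <- mm[!beyond, , drop = FALSE]
  }
  steps <- rep(b, N)
  steps[1] <- steps[1] + dG_ini_eff
  if (nrow(mm) > 0) steps[mm$position] <- steps[mm$position] + mm$penalty
  energies <- c(0, cumsum(steps))
  mismatch_steps <- stats::setNames(mm$penalty, mm$position)
  structure(list(energies = energies, N_eff = N,
                 mismatch_steps = mismatch_steps, torque = torque,
                 bias_per_bp = b, dG_ini_eff = dG_ini_eff,
                 locked_energy = if (target$lock_competent)
                   energies[N + 1L] - params$dG_lock else NULL),
            class = "rloop_landscape")
}

#' @export
print.rloop_landscape <- function(x, ...) {
  cat(sprintf("R-loop free-energy landscape: %d states (0..%d), torque %.2f pN nm\n",
              x$N_eff + 1L, x$N_eff, x$torque))
  cat(sprintf("  bias %.3f kBT/bp, initiation %.2f kBT", x$bias_per_bp,
              x$dG_ini_eff))
  if (length(x$mismatch_steps))
    cat(sprintf(", penalties at %s", paste(names(x$mismatch_steps), collapse = ", ")))
  cat("\n")
  invisible(x)
}
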