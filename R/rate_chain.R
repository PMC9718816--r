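#' Convert a free-energy landscape into a detailed-balance rate chain
#'
#' Parameterizes the birth-death chain of R-loop length. At zero torque and
#' zero bias every transition between R-loop states occurs at the single
#' base-pair stepping rate `k_step`; initiation (step 0 -> 1) is slowed by
#' the initiation penalty, `k_plus[0] = k_step * exp(-dG_ini)`. At a
#' penalized mismatch position m the forward step keeps the plain stepping
#' rate (the rate-limiting step is disruption of the DNA base pair) and
#' detailed balance puts the whole penalty into the backward rate,
#' `k_minus[m] = k_step * exp(+penalty)`. The per-bp bias (torque work plus
#' intrinsic bias) is split half onto each direction: every forward rate is
#' multiplied by `exp(-bias/2)` and every backward rate by `exp(+bias/2)`,
#' the transition barrier being centered between adjacent R-loop positions.
#'
#' @param landscape A landscape built by [build_landscape()].
#' @param target The [target_spec()] the landscape was built for.
#' @param params The [model_params()] used.
#' @param bias_on_initiation Apply the bias split factor to the initiation
#'   step 0 -> 1 as well (default). If `FALSE` the initiation forward rate is
#'   torque-independent and detailed balance puts the full bias of the first
#'   step into the collapse rate 1 -> 0.
#' @return An object of class `rloop_rate_chain` with elements `k_plus`
#'   (`k_plus[i]` = rate of step (i-1) -> i, for i = 1..N_eff), `k_minus`
#'   (`k_minus[i]` = rate of step i -> (i-1)), `torque`, `N_eff` and
#'   `absorbing_top` (lock-competent chains absorb at N_eff).
#' @export
landscape_to_rates <- function(landscape, target, params,
                               bias_on_initiation = TRUE) {
  stopifnot(inherits(landscape, "rloop_landscape"),
            inherits(target, "rloop_target"),
            inherits(params, "rloop_params"))
  N <- landscape$N_eff
  if (N != target$N_eff)
    stop("landscape and target have different effective lengths")
  b <- landscape$bias_per_bp
  k <- params$k_step
  k_plus <- rep(k * exp(-b / 2), N)
  k_minus <- rep(k * exp(+b / 2), N)
  if (bias_on_initiation) {
    k_plus[1] <- k * exp(-landscape$dG_ini_eff) * exp(-b / 2)
  } else {
    k_plus[1] <- k * exp(-landscape$dG_ini_eff)
    k_minus[1] <- k * exp(+b)
  }
  mm_pos <- as.integer(names(landscape$mismatch_steps))
  if (length(mm_pos))
    k_minus[mm_pos] <- k_minus[mm_pos] * exp(landscape$mismatch_steps)
  structure(list(k_plus = k_plus, k_minus = k_minus,
                 torque = landscape$torque, N_eff = N,
                 absorbing_top = target$lock_competent),
            class = "rloop_rate_chain")
}

#' Build the rate chain for a target in one call
#'
#' Convenience wrapper: [build_landscape()] followed by
#' [landscape_to_rates()].
#'
#' @inheritParams build_landscape
#' @inheritParams landscape_to_rates
#' @export
build_rate_chain <- function(target, params, torque = 0,
                             bias_on_initiation = TRUE) {
  landscape_to_rates(build_landscape(target, params, torque), target, params,
                     bias_on_initiation = bias_on_initiation)
}

#' Verify detailed balance of a rate chain against its landscape
#'
#' Checks the identity `k_plus[n] / k_minus[n+1] = exp(-(G_{n+1} - G_n))`
#' at every step and reports the worst relative deviation.
#'
#' @param chain An `rloop_rate_chain`.
#' @param landscape The `rloop_landscape` it should balance against.
#' @param tol Relative tolerance (default 1e-10).
#' @return A list with `ok` (logical), `max_deviation` and `worst_step`
#'   (the step index n of the worst deviation, 0-based).
#' @export
verify_detailed_balance <- function(chain, landscape, tol = 1e-10) {
  stopifnot(inherits(chain, "rloop_rate_chain"),
            inherits(landscape, "rloop_landscape"))
  if (chain$N_eff != landscape$N_eff)
    stop("chain and landscape have different lengths")
  ratio <- chain$k_plus / chain$k_minus
  expected <- exp(-diff(landscape$energies))
  dev <- abs(ratio / expected - 1)
  worst <- which.max(dev)
  list(ok = all(dev <= tol), max_deviation = max(dev),
       worst_step = worst - 1L)
}

#' @export
print.rloop_rate_chain <- function(x, ...) {
  cat(sprintf("R-loop rate chain: states 0..%d, torque %.2f pN nm%s\n",
              x$N_eff, x$torque,
              if (x$absorbing_top) ", absorbing at top" else ""))
  cat(sprintf("  k_plus[0] = %.4g /s, interior forward %.4g /s, max backward %.4g /s\n",
              x$k_plus[1], x$k_plus[min(2L, length(x$k_plus))],
              max(x$k_minus)))
  invisible(x)
}
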