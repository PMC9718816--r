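# Shared fixtures and independent oracles for the test suite.

kBT_25C <- 4.114
dphi <- 0.515

default_params <- function(...) {
  model_params(k_step = 2000, dG_ini = 8.5, dG_bias = 0.14, ...)
}

# a bare rate chain built directly (bypasses the landscape machinery) for
# exercising the solvers on arbitrary birth-death chains
raw_chain <- function(k_plus, k_minus, absorbing_top = FALSE) {
  structure(list(k_plus = k_plus, k_minus = k_minus,
                 N_eff = length(k_plus), torque = 0,
                 absorbing_top = absorbing_top),
            class = "rloop_rate_chain")
}

# Independent discrete-event Monte-Carlo walker (embedded chain +
# exponential clocks), deliberately written without any package internals.
mc_first_passage <- function(k_plus, k_minus, start, absorb, n_walks) {
  N <- length(k_plus)
  vapply(seq_len(n_walks), function(i) {
    t <- 0; n <- start
    while (!(n %in% absorb)) {
      up <- if (n < N) k_plus[n + 1] else 0
      down <- if (n > 0) k_minus[n] else 0
      tot <- up + down
      t <- t + stats::rexp(1, tot)
      n <- if (stats::runif(1) < up / tot) n + 1 else n - 1
    }
    t
  }, numeric(1))
}

# which boundary is hit first (TRUE = lower boundary a)
mc_hits_lower <- function(k_plus, k_minus, start, a, b, n_walks) {
  N <- length(k_plus)
  vapply(seq_len(n_walks), function(i) {
    n <- start
    while (n != a && n != b) {
      up <- if (n < N) k_plus[n + 1] else 0
      down <- if (n > 0) k_minus[n] else 0
      n <- if (stats::runif(1) < up / (up + down)) n + 1 else n - 1
    }
    n == a
  }, logical(1))
}

# decimate a 120 Hz trace smoothed to 7.5 Hz down to one sample per window
decimate16 <- function(x) x[seq(1, length(x), by = 16L)]
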