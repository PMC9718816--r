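#' Sliding-average smoothing of an extension trace
#'
#' Boxcar average reducing the effective bandwidth from `from_rate` to
#' `to_rate` with a centred window of `round(from_rate / to_rate)` samples
#' (120 -> 7.5 Hz gives a 16-sample window). Edges use the partial window.
#'
#' @param x Numeric extension trace.
#' @param from_rate Original sampling rate, Hz.
#' @param to_rate Target bandwidth, Hz.
#' @return Smoothed trace of the same length.
#' @export
smooth_trace <- function(x, from_rate = 120, to_rate = 7.5) {
  stopifnot(from_rate >= to_rate)
  w <- round(from_rate / to_rate)
  if (w < 2) {
    warning("smoothing window < 2 samples; returning trace unchanged")
    return(x)
  }
  n <- length(x)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment an extension trace into K discrete states
#'
#' Maximum-likelihood Gaussian-emission hidden-Markov segmentation with a
#' fixed number of states, fitted by EM (Baum-Welch) from multiple seeded
#' restarts, returning the most probable (Viterbi) state path. States are
#' relabelled in order of increasing mean extension, so state 1 is the
#' unbound (lowest-extension) state. The trace is standardized internally,
#' making the segmentation invariant under affine rescaling.
#'
#' @param x Numeric extension trace (smoothed to the detection bandwidth).
#' @param K Number of states (2, 3 or 4 for targets with 0, 1 or 2 internal
#'   mismatch barriers).
#' @param n_restarts Number of EM restarts with jittered initial means.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed Optional seed for the restart jitter.
#' @param method `"ghmm"` (default) or `"threshold"`, a half-amplitude
#'   threshold crossing detector available for K = 2 as a cross-check.
#' @return An object of class `rloop_state_path`: list with `states`
#'   (integer path, 1 = lowest), `means` (state mean extensions, original
#'   scale), `sds`, `loglik`, `converged` and `method`.
#' @export
segment_states <- function(x, K, n_restarts = 10L, max_iter = 200L,
                           tol = 1e-6, seed = NULL,
                           method = c("ghmm", "threshold")) {
  method <- match.arg(method)
  stopifnot(K %in% 2:4, length(x) > 100 * K)
  if (method == "threshold") {
    if (K != 2L) stop("threshold segmentation supports K = 2 only")
    return(threshold_segment(x))
  }
  if (!is.null(seed)) set.seed(seed)
  mu0 <- mean(x); sd0 <- stats::sd(x)
  z <- (x - mu0) / sd0
  best <- NULL
  # two deterministic initializations (k-means centers, which find rare
  # high-extension states, and equispaced quantiles), then jittered restarts
  km <- sort(stats::kmeans(z, centers = K, nstart = 5)$centers[, 1])
  qs <- as.numeric(stats::quantile(z, probs = seq(0.1, 0.9,
                                                  length.out = K)))
  spread <- seq(min(z), max(z), length.out = K)
  inits <- list(km, qs, spread)
  for (r in seq_len(max(n_restarts, length(inits)))) {
    mu <- if (r <= length(inits)) inits[[r]]
          else sort(km + stats::rnorm(K, 0, 0.3))
    fit <- ghmm_em(z, K, mu, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  relabel <- match(seq_len(K), ord)
  path <- relabel[ghmm_viterbi(z, best)]
  structure(list(states = path,
                 means = mu0 + sd0 * best$mu[ord],
                 sds = sd0 * best$sigma[ord],
                 loglik = best$loglik, converged = best$converged,
                 method = "ghmm"),
            class = "rloop_state_path")
}

threshold_segment <- function(x) {
  # half-amplitude: threshold midway between the two modes (k-means centers)
  km <- stats::kmeans(x, centers = 2L, nstart = 5L)
  cts <- sort(km$centers[, 1])
  thr <- mean(cts)
  path <- ifelse(x >= thr, 2L, 1L)
  structure(list(states = path, means = cts,
                 sds = tapply(x, path, stats::sd),
                 loglik = NA_real_, converged = TRUE, method = "threshold"),
            class = "rloop_state_path")
}

# Baum-Welch for a K-state Gaussian HMM on standardized data; the
# forward-backward pass runs compiled, the M-step updates live here.
ghmm_em <- function(z, K, mu, max_iter = 200L, tol = 1e-6) {
  sigma <- rep(0.5, K)
  A <- matrix(0.02 / (K - 1), K, K); diag(A) <- 0.98
  init <- rep(1 / K, K)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    fb <- cpp_ghmm_fb(z, mu, sigma, A, init)
    gamma <- fb$gamma
    A <- fb$xi / rowSums(fb$xi)
    init <- gamma[1, ]
    Ng <- colSums(gamma)
    mu <- colSums(gamma * z) / Ng
    sigma <- sqrt(colSums(gamma * (outer(z, mu, "-")^2)) / Ng)
    sigma <- pmax(sigma, 1e-4)
    if (is.finite(fb$loglik) &&
        abs(fb$loglik - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE; ll_old <- fb$loglik; break
    }
    ll_old <- fb$loglik
  }
  list(mu = mu, sigma = sigma, A = A, init = init, loglik = ll_old,
       converged = converged)
}

ghmm_viterbi <- function(z, fit) {
  cpp_ghmm_viterbi(z, fit$mu, fit$sigma, fit$A, fit$init)
}

#' Dwell-time based transition rates from a state path
#'
#' Extracts per-state dwell times from the discrete path and converts the
#' mean dwell to per-destination rates using the observed transition
#' fractions: `k_{r->d} = P(d) / tau_r`. The standard error of a rate is
#' `rate / sqrt(n_events)`, the SEM of an exponential mean. Dwells
#' truncated by the trace ends are excluded. As a consistency check the
#' survival (complementary cumulative) distribution of each state's dwells
#' is also fitted to a single exponential by unweighted least squares (for
#' exponential dwells the fitted time constant estimates the same mean);
#' estimates where fit and mean disagree by more than 10% or with fewer
#' than `min_events` transitions are flagged low-confidence (never
#' dropped).
#'
#' @param path An `rloop_state_path` (or integer vector of state labels).
#' @param sample_rate Sampling rate of the path, Hz.
#' @param min_events Minimum transitions per state pair for a confident
#'   estimate.
#' @return A data.frame with columns `from_state`, `to_state`, `rate`,
#'   `sem`, `n_events`, `tau`, `tau_mean`, `low_confidence`, `corrected`.
#' @export
dwell_rates <- function(path, sample_rate, min_events = 10L) {
  states <- if (inherits(path, "rloop_state_path")) path$states else path
  r <- rle(states)
  if (length(r$lengths) < 3L)
    stop("fewer than two transitions in the path")
  # drop first and last run (censored by the trace ends)
  keep <- 2:(length(r$lengths) - 1L)
  dw <- r$lengths[keep] / sample_rate
  from <- r$values[keep]
  to <- r$values[keep + 1L]
  out <- list()
  for (s in sort(unique(from))) {
    i <- from == s
    d <- dw[i]
    tau_mean <- mean(d)
    tau <- fit_exp_survival(d, tau_mean)
    dests <- to[i]
    for (dst in sort(unique(dests))) {
      n_sd <- sum(dests == dst)
      rate <- (n_sd / length(d)) / tau_mean
      out[[length(out) + 1L]] <- data.frame(
        from_state = s, to_state = dst, rate = rate,
        sem = rate / sqrt(n_sd), n_events = n_sd, tau = tau,
        tau_mean = tau_mean,
        low_confidence = n_sd < min_events ||
          abs(tau / tau_mean - 1) > 0.1,
        corrected = FALSE)
    }
  }
  do.call(rbind, out)
}

# Least-squares single-exponential fit of the empirical survival function.
fit_exp_survival <- function(d, tau0) {
  d <- sort(d)
  n <- length(d)
  surv <- 1 - (seq_len(n) - 1L) / n        # S(t) just before each dwell ends
  df <- data.frame(t = d, s = surv)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ exp(-t / tau), data = df,
                      start = list(tau = tau0),
                      lower = 1e-12, control = list(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) tau0 else stats::coef(fit)[["tau"]]
}

#' Correct rates across a fast mismatch barrier for missed transitions
#'
#' Transitions over a weak mismatch can be faster than the ~7 Hz detection
#' bandwidth, so segmentation under-counts them and both the barrier
#' crossing rate (k3) and the full R-loop collapse rate (k4) are biased
#' low. Since the collapse of the full R-loop should not depend on the
#' mismatch identity, k4 is raised to the reference level measured for
#' strong mismatches, and k3 is scaled by the same factor, preserving the
#' equilibrium constant k3/k4 across the barrier.
#'
#' @param estimates A data.frame from [dwell_rates()]; the topmost state
#'   pair is taken as the k3/k4 pair.
#' @param reference_k4 Reference collapse-rate range, 1/s (default
#'   0.8-1.2, the level measured for C:C and C:T mismatches).
#' @return The estimates with k3/k4 rescaled and `corrected = TRUE` where a
#'   correction was applied. A measured k4 already inside the reference
#'   range is left unchanged; a k4 above the range cannot result from
#'   missed transitions, so the call warns and returns the input.
#' @export
correct_fast_transitions <- function(estimates, reference_k4 = c(0.8, 1.2)) {
  stopifnot(is.data.frame(estimates),
            all(c("from_state", "to_state", "rate") %in% names(estimates)))
  top <- max(estimates$from_state, estimates$to_state)
  i4 <- which(estimates$from_state == top & estimates$to_state == top - 1L)
  i3 <- which(estimates$from_state == top - 1L & estimates$to_state == top)
  if (length(i4) != 1L || length(i3) != 1L)
    stop("estimates must contain the topmost transition pair (k3, k4)")
  k4 <- estimates$rate[i4]
  if (k4 >= reference_k4[1] && k4 <= reference_k4[2]) return(estimates)
  if (k4 > reference_k4[2]) {
    warning("measured k4 above the reference range; no correction applied")
    return(estimates)
  }
  target <- mean(reference_k4)
  f <- target / k4
  for (i in c(i3, i4)) {
    estimates$rate[i] <- estimates$rate[i] * f
    estimates$sem[i] <- estimates$sem[i] * f
    estimates$corrected[i] <- TRUE
  }
  estimates
}
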