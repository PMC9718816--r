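test_that("sliding-average smoothing has boxcar statistics", {
  expect_equal(smooth_trace(rep(5, 100), 120, 7.5), rep(5, 100))
  set.seed(1)
  x <- rnorm(60000)
  sm <- smooth_trace(x, 120, 7.5)
  # interior samples average 16 points: variance sigma^2/16
  expect_equal(stats::var(sm[17:59984]), 1 / 16, tolerance = 0.1)
  # a step edge becomes a ramp one window wide
  step <- c(rep(0, 50), rep(1, 50))
  sms <- smooth_trace(step, 120, 7.5)
  ramp <- which(sms > 0.001 & sms < 0.999)
  expect_equal(length(ramp), 15)
  expect_true(all(diff(sms[ramp]) > 0))
  expect_warning(out <- smooth_trace(1:10, 120, 100), "unchanged")
  expect_equal(out, 1:10)
})

test_that("segmentation recovers a noiseless two-level square wave exactly", {
  x <- rep(rep(c(0, 50), 25), each = 60)
  seg <- segment_states(x + rnorm(length(x), 0, 1e-3), K = 2,
                        n_restarts = 3, seed = 2)
  truth <- rep(rep(c(1L, 2L), 25), each = 60)
  expect_lt(mean(seg$states != truth), 1e-3)
  expect_equal(seg$means, c(0, 50), tolerance = 0.01)
  # threshold cross-check method agrees for K = 2
  thr <- segment_states(x + rnorm(length(x), 0, 1e-3), K = 2,
                        method = "threshold")
  expect_equal(thr$states, seg$states)
})

test_that("segmentation is invariant under affine rescaling", {
  set.seed(14)
  x <- rep(sample(c(0, 40), 100, replace = TRUE), each = 40) +
    rnorm(4000, 0, 8)
  s1 <- segment_states(x, 2, n_restarts = 4, seed = 5)
  s2 <- segment_states(3.7 * x - 120, 2, n_restarts = 4, seed = 5)
  expect_equal(s1$states, s2$states)
})

test_that("segmentation recovers generating rates of a noisy two-state trace", {
  # semi-Markov two-state signal, rates 0.5 /s each, separation 3x noise sd
  set.seed(42)
  rate <- 0.5; sr <- 100; dur <- 2500
  times <- cumsum(stats::rexp(3000, rate))
  times <- times[times < dur]
  grid <- seq(1 / sr, dur, by = 1 / sr)
  state <- (findInterval(grid, times) %% 2L) + 1L
  x <- c(0, 30)[state] + rnorm(length(grid), 0, 10)
  seg <- segment_states(x, K = 2, n_restarts = 5, seed = 6)
  dr <- dwell_rates(seg, sr)
  for (i in seq_len(nrow(dr)))
    expect_equal(dr$rate[i], rate, tolerance = 0.15)
})

test_that("dwell rates follow splitting arithmetic and SEM convention", {
  # alternating two-state path with all dwells exactly 1 s
  path <- rep(rep(c(1L, 2L), 40), each = 50)    # 50 samples at 50 Hz = 1 s
  dr <- dwell_rates(path, 50)
  expect_equal(dr$rate, c(1, 1), tolerance = 0.03)
  expect_equal(dr$sem, dr$rate / sqrt(dr$n_events))
  # a state leaving 70/30 to two neighbours with tau = 0.5 s
  set.seed(8)
  mids <- sample(rep(c(1L, 3L), times = c(70, 30)))
  path3 <- integer(0)
  for (m in mids) path3 <- c(path3, rep(2L, 25), rep(m, 25))  # 0.5 s dwells
  path3 <- c(1L, path3, 1L)
  dr3 <- dwell_rates(path3, 50)
  k21 <- dr3$rate[dr3$from_state == 2 & dr3$to_state == 1]
  k23 <- dr3$rate[dr3$from_state == 2 & dr3$to_state == 3]
  expect_equal(k21, 0.7 / 0.5, tolerance = 0.05)
  expect_equal(k23, 0.3 / 0.5, tolerance = 0.05)
})

test_that("SEM shrinks as one over the square root of the event count", {
  set.seed(9)
  mk <- function(n_events) {
    d <- stats::rexp(n_events, 1)
    path <- integer(0)
    for (i in seq_len(n_events))
      path <- c(path, rep(c(1L, 2L)[1 + i %% 2], max(1, round(d[i] * 20))))
    mean(dwell_rates(path, 20)$sem)
  }
  s1 <- mean(replicate(6, mk(60)))
  s2 <- mean(replicate(6, mk(240)))
  expect_equal(s2 / s1, 0.5, tolerance = 0.2)
})

test_that("virtual instrument closes the loop back to the model's coarse rates", {
  truth <- model_params(k_step = 1900, dG_ini = 8.5, dG_bias = 0.14)
  tg <- target_spec(32, distal_cutoff = 13, lock_competent = FALSE)
  tau <- -5
  ls <- build_landscape(tg, truth, tau)
  cr <- coarse_rates(landscape_to_rates(ls, tg, truth), coarse_states(ls))
  des <- experiment_design(list(L12 = tg), torques = tau, duration = 600,
                           seed = 42)
  tr <- make_trajectories(des, truth)[[1]]
  x <- decimate16(smooth_trace(tr$extension_nm, 120, 7.5))
  seg <- segment_states(x, K = 2, n_restarts = 5, seed = 7)
  dr <- dwell_rates(seg, 7.5)
  k1_hat <- dr[dr$from_state == 1 & dr$to_state == 2, ]
  k2_hat <- dr[dr$from_state == 2 & dr$to_state == 1, ]
  expect_lt(abs(k1_hat$rate - cr$rate[cr$label == "k1"]), 3 * k1_hat$sem)
  expect_lt(abs(k2_hat$rate - cr$rate[cr$label == "k2"]), 3 * k2_hat$sem)
})

test_that("transitions faster than the detection bandwidth are under-counted", {
  truth <- model_params(k_step = 1900, dG_ini = 8.5, dG_bias = 0.14)
  tg <- target_spec(32, mismatches = c("11" = 6.9, "17" = 6.9),
                    distal_cutoff = 27, lock_competent = FALSE)
  des <- experiment_design(list(dm = tg), torques = -8, duration = 400,
                           seed = 17)
  tr <- make_trajectories(des, truth)[[1]]
  # true I <-> I* flicker happens at ~15 /s, far above the ~7 Hz bandwidth
  r_true <- rle(tr$true_state)
  n_true <- sum((r_true$values[-length(r_true$values)] == "I" &
                   r_true$values[-1] == "I*") |
                  (r_true$values[-length(r_true$values)] == "I*" &
                     r_true$values[-1] == "I"))
  x <- decimate16(smooth_trace(tr$extension_nm, 120, 7.5))
  seg <- segment_states(x, K = 4, n_restarts = 5, seed = 19)
  r_det <- rle(seg$states)
  n_det <- sum((r_det$values[-length(r_det$values)] == 2L &
                  r_det$values[-1] == 3L) |
                 (r_det$values[-length(r_det$values)] == 3L &
                    r_det$values[-1] == 2L))
  expect_gt(n_true, 0)
  expect_lt(n_det, 0.8 * n_true)
})

test_that("the k4 correction restores the collapse rate and preserves k3/k4", {
  # weak mismatch: I <-> F* exchange above bandwidth, so both k3 and k4
  # are measured low; raising k4 to the strong-mismatch reference level
  # restores it and moves k3 toward truth without changing k3/k4
  truth <- model_params(k_step = 1900, dG_ini = 8.5, dG_bias = 0.14)
  tg <- target_spec(32, mismatches = c("14" = 4.0), distal_cutoff = 27,
                    lock_competent = FALSE)
  tau <- -5
  ls <- build_landscape(tg, truth, tau)
  cr <- coarse_rates(landscape_to_rates(ls, tg, truth), coarse_states(ls))
  k3_true <- cr$rate[cr$label == "k3"]; k4_true <- cr$rate[cr$label == "k4"]
  des <- experiment_design(list(w = tg), torques = tau, duration = 900,
                           seed = 31)
  tr <- make_trajectories(des, truth)[[1]]
  x <- decimate16(smooth_trace(tr$extension_nm, 120, 7.5))
  seg <- segment_states(x, K = 3, n_restarts = 6, seed = 9)
  dr <- dwell_rates(seg, 7.5)
  corr <- correct_fast_transitions(dr, reference_k4 = c(0.8, 1.2))
  i4 <- which(dr$from_state == 3 & dr$to_state == 2)
  i3 <- which(dr$from_state == 2 & dr$to_state == 3)
  # uncorrected collapse rate is biased low beyond its own error bar
  expect_gt(abs(dr$rate[i4] - k4_true), 3 * dr$sem[i4])
  expect_true(corr$corrected[i4] && corr$corrected[i3])
  expect_lt(abs(corr$rate[i4] - k4_true), 3 * corr$sem[i4])
  expect_lt(abs(corr$rate[i3] - k3_true), abs(dr$rate[i3] - k3_true))
  expect_equal(corr$rate[i3] / corr$rate[i4], dr$rate[i3] / dr$rate[i4])
})

test_that("the correction is a guarded no-op outside its regime", {
  est <- data.frame(from_state = c(1L, 2L, 2L, 3L),
                    to_state = c(2L, 1L, 3L, 2L),
                    rate = c(0.2, 0.5, 1.5, 0.3),
                    sem = c(0.02, 0.05, 0.15, 0.03),
                    n_events = c(50L, 50L, 80L, 80L),
                    corrected = FALSE)
  out <- correct_fast_transitions(est, c(0.8, 1.2))
  expect_equal(out$rate[4], 1.0)                 # midpoint of the range
  expect_equal(out$rate[3], 1.5 * (1.0 / 0.3))   # proportional k3 scaling
  est_in <- est; est_in$rate[4] <- 0.9
  expect_identical(correct_fast_transitions(est_in, c(0.8, 1.2)), est_in)
  est_hi <- est; est_hi$rate[4] <- 2.0
  expect_warning(out_hi <- correct_fast_transitions(est_hi, c(0.8, 1.2)),
                 "no correction")
  expect_equal(out_hi$rate, est_hi$rate)
})
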