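test_that("MFPT matches hand solutions on small chains", {
  # pure forward chain: N sequential Poisson steps of rate k
  ch <- raw_chain(rep(500, 6), rep(1e-9, 6))
  expect_equal(mfpt(ch, 0, 6), 6 / 500, tolerance = 1e-6)
  # symmetric chain on {0,1,2}, k = 1000/s, reflecting at 2, absorb {0}:
  # T2 = 1/k + T1, T1 = 1/(2k) + T2/2  =>  T2 = 3/k = 3 ms
  ch3 <- raw_chain(rep(1000, 2), rep(1000, 2))
  expect_equal(mfpt(ch3, 2, 0), 3e-3)
  # unbiased walk 0..N, reflect 0, absorb N: N(N+1)/(2k)
  for (N in c(4, 9, 15)) {
    ch <- raw_chain(rep(800, N), rep(800, N))
    expect_equal(mfpt(ch, 0, N), N * (N + 1) / (2 * 800), tolerance = 1e-12)
  }
})

test_that("linear-solve, flux and closed-form MFPT backends agree", {
  p <- default_params()
  cases <- list(
    list(tg = target_spec(32), tau = -6.7, start = 0, absorb = 32),
    list(tg = target_spec(32, mismatches = c("17" = 6.9)), tau = -3.4,
         start = 0, absorb = 32),
    list(tg = target_spec(32, distal_cutoff = 13, lock_competent = FALSE),
         tau = -5, start = 12, absorb = 0))
  for (cs in cases) {
    ch <- build_rate_chain(cs$tg, p, cs$tau)
    a <- mfpt(ch, cs$start, cs$absorb, method = "solve")
    b <- mfpt(ch, cs$start, cs$absorb, method = "flux")
    d <- mfpt(ch, cs$start, cs$absorb, method = "closed_form")
    expect_equal(b / a, 1, tolerance = 1e-9)
    expect_equal(d / a, 1, tolerance = 1e-9)
  }
  ch <- build_rate_chain(target_spec(32), p, -5)
  expect_error(mfpt(ch, 0, integer(0)), "non-empty")
  expect_error(mfpt(ch, 5, 5), "absorbing")
})

test_that("MFPT agrees with independent Monte-Carlo sampling", {
  set.seed(4711)
  kp <- c(2, rep(60, 7)); km <- rep(40, 8)       # mildly biased 8-state chain
  ch <- raw_chain(kp, km)
  t_model <- mfpt(ch, 0, 8)
  walks <- mc_first_passage(kp, km, 0, 8, 2000)
  se <- stats::sd(walks) / sqrt(length(walks))
  expect_lt(abs(mean(walks) - t_model), 3 * se)
})

test_that("splitting probabilities obey symmetry, bias and limits", {
  # symmetric walk from the midpoint
  ch <- raw_chain(rep(1000, 10), rep(1000, 10))
  expect_equal(splitting_probability(ch, 5, 0, 10), 0.5)
  expect_equal(splitting_probability(ch, 0, 0, 10), 1)
  expect_equal(splitting_probability(ch, 10, 0, 10), 0)
  # uniform forward/backward ratio e: gambler's-ruin product formula
  kp <- rep(1000 * exp(0.5), 10); km <- rep(1000 * exp(-0.5), 10)
  chb <- raw_chain(kp, km)
  q <- exp(-1)                                    # km/kp per step
  p_lower <- (q^5 - q^10) / (1 - q^10)            # reach 0 before 10 from 5
  expect_equal(splitting_probability(chb, 5, 0, 10), p_lower,
               tolerance = 1e-12)
  set.seed(99)
  hits <- mc_hits_lower(kp, km, 5, 0, 10, 4000)
  se <- sqrt(p_lower * (1 - p_lower) / 4000)
  expect_lt(abs(mean(hits) - p_lower), 3.5 * se)
  # start adjacent to the lower boundary with dominant backward rate
  chl <- raw_chain(rep(1, 10), rep(1e6, 10))
  expect_gt(splitting_probability(chl, 1, 0, 10), 0.999)
  # complements sum to one by construction on an asymmetric chain
  pa <- splitting_probability(chb, 3, 0, 10)
  pb <- 1 - pa
  expect_equal(pa + pb, 1)
})

test_that("coarse basins are tiled by mismatch barriers with lowest-G representatives", {
  p <- default_params()
  tg <- target_spec(32, mismatches = c("11" = 6.9, "17" = 6.9),
                    distal_cutoff = 27, lock_competent = FALSE)
  ls <- build_landscape(tg, p, -6.7)
  cs <- coarse_states(ls)
  expect_equal(cs$label, c("U", "I", "I*", "F*"))
  expect_equal(cs$from, c(0L, 1L, 11L, 17L))
  expect_equal(cs$to, c(0L, 10L, 16L, 26L))
  # net downhill landscape: representative sits just before the next barrier
  expect_equal(cs$rep, c(0L, 10L, 16L, 26L))
  # basins tile 0..N_eff without overlap
  covered <- unlist(Map(seq, cs$from, cs$to))
  expect_equal(sort(covered), 0:26)
})

test_that("occupancies are Boltzmann weights normalized over microstates", {
  # two-level system, G_I - G_U = -1 kBT -> P_I = e/(1+e)
  p1 <- model_params(k_step = 1000, dG_ini = -1, dG_bias = 0)
  tg1 <- target_spec(1, excluded_positions = integer(0),
                     lock_competent = FALSE)
  occ <- occupancies(build_landscape(tg1, p1, 0))
  expect_equal(occ$occupancy[occ$label == "I"], exp(1) / (1 + exp(1)))
  # flat landscape: P_I / P_U = N * exp(-dG_ini)
  p2 <- model_params(k_step = 1000, dG_ini = 2.5, dG_bias = 0)
  tg2 <- target_spec(12, distal_cutoff = NULL, lock_competent = FALSE)
  occ2 <- occupancies(build_landscape(tg2, p2, 0))
  ratio <- occ2$occupancy[2] / occ2$occupancy[1]
  expect_equal(ratio, 12 * exp(-2.5), tolerance = 1e-12)
  expect_equal(sum(occ2$occupancy), 1)
})

test_that("more negative torque populates the deepest basin", {
  p <- default_params()
  tg <- target_spec(32, mismatches = c("17" = 6.9), distal_cutoff = 27,
                    lock_competent = FALSE)
  occ_f <- vapply(c(-3, -4, -5, -6, -7), function(tau) {
    o <- occupancies(build_landscape(tg, p, tau))
    o$occupancy[o$label == "F*"]
  }, numeric(1))
  expect_true(all(diff(occ_f) > 0))
})

test_that("coarse rates reduce correctly and follow torque and length laws", {
  p <- default_params()
  # two-basin reduction on an intermediate-only target
  tg <- target_spec(32, distal_cutoff = 13, lock_competent = FALSE)
  ls <- build_landscape(tg, p, -5)
  ch <- landscape_to_rates(ls, tg, p)
  cs <- coarse_states(ls)
  cr <- coarse_rates(ch, cs)
  rI <- cs$rep[cs$label == "I"]
  expect_equal(cr$rate[cr$label == "k1"], 1 / mfpt(ch, 0, rI))
  expect_equal(cr$rate[cr$label == "k2"], 1 / mfpt(ch, rI, 0))
  # longer intermediates collapse slower at fixed negative torque
  k2_for <- function(L) {
    tgl <- target_spec(32, distal_cutoff = L + 1, lock_competent = FALSE)
    lsl <- build_landscape(tgl, p, -4.7)
    crl <- coarse_rates(landscape_to_rates(lsl, tgl, p), coarse_states(lsl))
    crl$rate[crl$label == "k2"]
  }
  expect_lt(k2_for(22), k2_for(12))
  # single mismatch at 17: k3 rises and k4 falls with more negative torque
  tgm <- target_spec(32, mismatches = c("17" = 6.9), distal_cutoff = 27,
                     lock_competent = FALSE)
  k34 <- vapply(c(-4, -5, -6), function(tau) {
    lsm <- build_landscape(tgm, p, tau)
    crm <- coarse_rates(landscape_to_rates(lsm, tgm, p), coarse_states(lsm))
    c(crm$rate[crm$label == "k3"], crm$rate[crm$label == "k4"])
  }, numeric(2))
  expect_true(all(diff(k34[1, ]) > 0))
  expect_true(all(diff(k34[2, ]) < 0))
})

test_that("coarse-rate ratios reflect basin free-energy differences", {
  p <- default_params()
  tg <- target_spec(32, mismatches = c("17" = 6.9), distal_cutoff = 27,
                    lock_competent = FALSE)
  ls <- build_landscape(tg, p, -5)
  ch <- landscape_to_rates(ls, tg, p)
  cs <- coarse_states(ls)
  cr <- coarse_rates(ch, cs)
  occ <- occupancies(ls, cs)
  # k3/k4 should match the I <-> F* partition-function ratio
  k3 <- cr$rate[cr$label == "k3"]; k4 <- cr$rate[cr$label == "k4"]
  expect_equal(k3 / k4,
               occ$occupancy[occ$label == "F*"] /
                 occ$occupancy[occ$label == "I"],
               tolerance = 0.05)
})

test_that("formation time behaves as an added-barrier first-passage time", {
  p <- default_params()
  wt <- target_spec(32)
  # initiation-limited limit at strong negative torque: the mean time is
  # one initiation waiting time per committed attempt, T ~ 1/(k0+ * P),
  # with P the probability an initiated R-loop completes before collapsing
  ch <- build_rate_chain(wt, p, -9)
  P_commit <- 1 - splitting_probability(ch, 1, 0, 32)
  expect_equal(formation_time(wt, p, -9) * ch$k_plus[1] * P_commit, 1,
               tolerance = 0.02)
  ch20 <- build_rate_chain(wt, p, -20)
  expect_lt(formation_time(wt, p, -20) * ch20$k_plus[1], 1.15)
  # an added mismatch can never accelerate formation, at any torque
  mm <- target_spec(32, mismatches = c("17" = 6.9))
  taus <- seq(-8, -1, by = 1)
  t_wt <- vapply(taus, function(tau) formation_time(wt, p, tau), numeric(1))
  t_mm <- vapply(taus, function(tau) formation_time(mm, p, tau), numeric(1))
  expect_true(all(t_mm > t_wt))
  # ratio decreases monotonically and plateaus at the WT level
  ratio <- t_mm / t_wt
  expect_true(all(diff(ratio) > 0))              # less negative -> larger
  expect_lt(ratio[1], 1.3)                       # plateau near WT at -8
  expect_error(formation_time(
    target_spec(32, distal_cutoff = 13, lock_competent = FALSE), p, -5),
    "lock-competent")
})
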