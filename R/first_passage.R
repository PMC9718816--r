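#' Mean first-passage time on the rate chain
#'
#' Expected time for the R-loop length walk started at `start` to first
#' reach any state in `absorb`. Boundaries of the chain not in `absorb` are
#' reflecting. Three equivalent backends are provided: `"solve"` sets up the
#' standard linear first-passage system (one equation per transient state)
#' and solves it densely; `"flux"` solves the transposed occupancy-time
#' system, i.e. the steady-state single-particle-flux formulation with
#' transmissive boundaries at the end states; `"closed_form"` evaluates the
#' nested-sum solution for birth-death chains (available when all absorbing
#' states lie on one side of `start`).
#'
#' @param chain An `rloop_rate_chain` from [landscape_to_rates()].
#' @param start Starting microstate (0-based R-loop length).
#' @param absorb Integer vector of absorbing microstates.
#' @param method One of `"solve"`, `"flux"`, `"closed_form"`.
#' @return Mean first-passage time in seconds.
#' @export
mfpt <- function(chain, start, absorb,
                 method = c("solve", "flux", "closed_form")) {
  method <- match.arg(method)
  stopifnot(inherits(chain, "rloop_rate_chain"))
  N <- chain$N_eff
  start <- as.integer(start); absorb <- as.integer(absorb)
  if (length(absorb) == 0L) stop("absorb must be non-empty")
  if (start %in% absorb) stop("start must not be absorbing")
  if (start < 0L || start > N || any(absorb < 0L | absorb > N))
    stop("states must lie in 0..N_eff")
  if (method == "closed_form") return(mfpt_closed_form(chain, start, absorb))
  trans <- setdiff(0:N, absorb)
  idx <- rep(NA_integer_, N + 1L)
  idx[trans + 1L] <- seq_along(trans)
  m <- length(trans)
  A <- matrix(0, m, m)
  for (j in seq_len(m)) {
    i <- trans[j]
    up <- if (i < N) chain$k_plus[i + 1L] else 0
    down <- if (i > 0L) chain$k_minus[i] else 0
    A[j, j] <- up + down
    if (i < N && !is.na(idx[i + 2L])) A[j, idx[i + 2L]] <- -up
    if (i > 0L && !is.na(idx[i]))     A[j, idx[i]] <- -down
  }
  if (method == "solve") {
    tt <- solve(A, rep(1, m))
    tt[idx[start + 1L]]
  } else {
    # occupancy-time form: A^T p = e_start; total occupancy = MFPT
    p <- solve(t(A), as.numeric(seq_len(m) == idx[start + 1L]))
    sum(p)
  }
}

# Nested-sum closed form for a single-sided absorbing boundary.
# For start < a (all absorbing states above start, nearest a): walk on
# 0..a with reflecting bottom. Mirrored for start > a.
mfpt_closed_form <- function(chain, start, absorb) {
  below <- absorb[absorb < start]; above <- absorb[absorb > start]
  if (length(below) && length(above))
    stop("closed_form requires all absorbing states on one side of start")
  if (length(above)) {
    a <- min(above)
    kp <- chain$k_plus[1:a]          # rates j -> j+1 for j = 0..a-1
    km <- chain$k_minus[1:a]         # rates j -> j-1 for j = 1..a
    # stationary measure pi_j on 0..a-1 (reflecting at 0)
    pi <- cumprod(c(1, kp[-a] / km[-a]))
    total <- sum(cumsum(pi) / (kp * pi))
    if (start == 0L) return(total)
    total - mfpt_closed_form_sub(kp, km, start)
  } else {
    a <- max(below)
    # mirror: states a..N become 0..N-a with forward/backward swapped
    kp <- rev(chain$k_minus[(a + 1L):chain$N_eff])
    km <- rev(chain$k_plus[(a + 1L):chain$N_eff])
    chain2 <- structure(list(k_plus = kp, k_minus = km,
                             N_eff = length(kp), torque = chain$torque,
                             absorbing_top = FALSE),
                        class = "rloop_rate_chain")
    mfpt_closed_form(chain2, chain$N_eff - start, chain$N_eff - a)
  }
}

# MFPT from 0 to `s` on the reflecting-bottom sub-chain given by kp, km.
mfpt_closed_form_sub <- function(kp, km, s) {
  kp <- kp[1:s]; km <- km[1:s]
  pi <- cumprod(c(1, kp[-s] / km[-s]))
  sum(cumsum(pi) / (kp * pi))
}

#' Splitting probability between two absorbing states
#'
#' Probability that the walk started at `start` reaches `absorb_a` before
#' `absorb_b`, with `absorb_a < start < absorb_b`. Degenerate starts at a
#' boundary return 1/0.
#'
#' @inheritParams mfpt
#' @param absorb_a,absorb_b The two absorbing microstates, `absorb_a` below
#'   `start` and `absorb_b` above.
#' @return Probability of reaching `absorb_a` first.
#' @export
splitting_probability <- function(chain, start, absorb_a, absorb_b) {
  stopifnot(inherits(chain, "rloop_rate_chain"))
  start <- as.integer(start)
  a <- as.integer(absorb_a); b <- as.integer(absorb_b)
  if (!(a <= start && start <= b) || a >= b)
    stop("need absorb_a <= start <= absorb_b with absorb_a < absorb_b")
  if (start == a) return(1)
  if (start == b) return(0)
  # committor u_i = P(reach b before a); u_a = 0, u_b = 1; the increments
  # d_i = u_{i+1} - u_i satisfy d_i = d_{i-1} * (rate i->i-1)/(rate i->i+1)
  j <- if (b - a >= 2L) (a + 1L):(b - 1L) else integer(0)
  rho <- cumprod(c(1, chain$k_minus[j] / chain$k_plus[j + 1L]))
  u_start <- sum(rho[1:(start - a)]) / sum(rho)
  1 - u_start
}

#' Partition a landscape into coarse experimental states
#'
#' The observable states of the magnetic-tweezers experiment are free-energy
#' basins of the landscape separated by penalized mismatch barriers. The
#' unbound state U is microstate 0; each penalized mismatch at position m
#' starts a new basin at m (the state that has paid the penalty). The
#' representative position of a basin is its lowest-free-energy microstate
#' (ties broken toward larger R-loop length). Basins past U are labelled
#' I, I*, F* following the experimental conventions (a single basin past U
#' is I; the last basin of a multi-basin cut-off chain is the full-length
#' unlocked state F*).
#'
#' @param landscape An `rloop_landscape`.
#' @return An object of class `rloop_coarse_states`: a data.frame with
#'   columns `label`, `from`, `to` (microstate interval) and `rep`
#'   (representative position).
#' @export
coarse_states <- function(landscape) {
  stopifnot(inherits(landscape, "rloop_landscape"))
  N <- landscape$N_eff
  mm <- sort(as.integer(names(landscape$mismatch_steps)))
  mm <- mm[mm <= N]
  starts <- c(1L, mm)
  ends <- c(mm - 1L, N)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  K <- length(starts)
  labels <- if (K == 1L) "I"
            else if (K == 2L) c("I", "F*")
            else if (K == 3L) c("I", "I*", "F*")
            else c("I", paste0("I", strrep("*", seq_len(K - 2L))), "F*")
  reps <- vapply(seq_len(K), function(i) {
    g <- landscape$energies[(starts[i]:ends[i]) + 1L]
    cand <- which(g <= min(g) + 1e-12)
    starts[i] + cand[length(cand)] - 1L
  }, integer(1))
  out <- data.frame(label = c("U", labels),
                    from = c(0L, starts), to = c(0L, ends),
                    rep = c(0L, reps), stringsAsFactors = FALSE)
  class(out) <- c("rloop_coarse_states", "data.frame")
  out
}

#' Coarse-grained transition rates between basins
#'
#' Reduces the microscopic chain to the rates between adjacent coarse
#' basins, mirroring the experimental dwell-time analysis: for an interior
#' basin with representative r and neighbouring representatives a (left)
#' and b (right), the mean dwell is `mfpt(r -> {a, b})` and the exit rates
#' are the splitting probabilities divided by the dwell. Terminal basins use
#' the single-boundary MFPT. Rates are labelled k1, k2, ... outward from U
#' (k1 = U -> I, k2 = I -> U, k3 = I -> next, ...), matching the
#' experimental three- and four-state conventions.
#'
#' @param chain An `rloop_rate_chain`.
#' @param basins An `rloop_coarse_states` partition of the same chain.
#' @return A data.frame with columns `label`, `from`, `to` (basin labels)
#'   and `rate` (1/s).
#' @export
coarse_rates <- function(chain, basins) {
  stopifnot(inherits(chain, "rloop_rate_chain"),
            inherits(basins, "rloop_coarse_states"))
  K <- nrow(basins)
  if (K < 2L) stop("need at least two basins")
  reps <- basins$rep
  out <- list()
  lab <- 1L
  for (i in seq_len(K - 1L)) {
    # forward rate basin i -> i+1 and backward i+1 -> i
    r <- reps[i]; rn <- reps[i + 1L]
    fwd <- if (i == 1L) 1 / mfpt(chain, r, rn)
           else {
             tau <- mfpt(chain, r, c(reps[i - 1L], rn))
             (1 - splitting_probability(chain, r, reps[i - 1L], rn)) / tau
           }
    bwd <- if (i + 1L == K) 1 / mfpt(chain, rn, r)
           else {
             tau <- mfpt(chain, rn, c(r, reps[i + 2L]))
             splitting_probability(chain, rn, r, reps[i + 2L]) / tau
           }
    out[[i]] <- data.frame(
      label = paste0("k", c(lab, lab + 1L)),
      from = basins$label[c(i, i + 1L)],
      to = basins$label[c(i + 1L, i)],
      rate = c(fwd, bwd), stringsAsFactors = FALSE)
    lab <- lab + 2L
  }
  do.call(rbind, out)
}

#' Boltzmann occupancies of the coarse basins
#'
#' Equilibrium probability of each basin from the Boltzmann weights
#' `exp(-G_n)` of its microstates, normalized over all microstates of the
#' (non-absorbing) chain. The minimum energy is subtracted before
#' exponentiation to guard against overflow; basins with relative weight
#' below 1e-12 are reported as occupancy 0.
#'
#' @param landscape An `rloop_landscape`.
#' @param basins An `rloop_coarse_states` partition (defaults to
#'   [coarse_states()] of the landscape).
#' @return A data.frame with columns `label` and `occupancy` (sums to 1).
#' @export
occupancies <- function(landscape, basins = coarse_states(landscape)) {
  stopifnot(inherits(landscape, "rloop_landscape"))
  g <- landscape$energies
  w <- exp(-(g - min(g)))
  occ <- vapply(seq_len(nrow(basins)), function(i)
    sum(w[(basins$from[i]:basins$to[i]) + 1L]), numeric(1))
  occ <- occ / sum(occ)
  occ[occ < 1e-12] <- 0
  data.frame(label = basins$label, occupancy = occ,
             stringsAsFactors = FALSE)
}

#' Mean time to locked R-loop formation
#'
#' The model's prediction for the measured R-loop formation time: the mean
#' first-passage time of the walk from the unbound state to the full-length
#' state `N`, where locking makes the R-loop effectively irreversible.
#'
#' @inheritParams build_landscape
#' @param bias_on_initiation Passed to [landscape_to_rates()].
#' @param method MFPT backend; the closed form is fastest and exact for this
#'   one-sided problem.
#' @return Formation time in seconds.
#' @export
formation_time <- function(target, params, torque = 0,
                           bias_on_initiation = TRUE,
                           method = "closed_form") {
  stopifnot(inherits(target, "rloop_target"))
  if (!target$lock_competent)
    stop("formation_time requires a lock-competent target (no distal cut-off)")
  chain <- build_rate_chain(target, params, torque,
                            bias_on_initiation = bias_on_initiation)
  mfpt(chain, 0L, target$N_eff, method = method)
}
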