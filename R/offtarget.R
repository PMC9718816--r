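#' Supercoiling context for in vivo torque estimates
#'
#' @param sigma Superhelical density (added superhelical turns per helical
#'   turn of relaxed DNA); negative in vivo.
#' @param twist_fraction Fraction of sigma partitioned into twist (the
#'   remainder goes into writhe); 0.2 for plasmid DNA.
#' @param p_tor Torsional persistence length, nm.
#' @param h Helical pitch of B-form DNA, nm.
#' @return An object of class `rloop_supercoiling`.
#' @export
supercoiling_context <- function(sigma, twist_fraction = 0.2, p_tor = 100,
                                 h = 3.5) {
  stopifnot(twist_fraction > 0, twist_fraction <= 1, p_tor > 0, h > 0)
  structure(list(sigma = sigma, twist_fraction = twist_fraction,
                 p_tor = p_tor, h = h),
            class = "rloop_supercoiling")
}

#' Torque on DNA at a given superhelical density
#'
#' Torque in a twisted semiflexible polymer from the twist-partitioned
#' superhelical density: `tau = (kBT p_tor / h) 2 pi sigma_Tw` with
#' `sigma_Tw = twist_fraction * sigma`. With the defaults, the typical
#' E. coli superhelical densities -0.06 and -0.029 give torques of about
#' -8.9 and -4.3 pN nm.
#'
#' @param ctx Either an [supercoiling_context()] object or a numeric
#'   superhelical density (defaults applied to the other fields).
#' @param constants A [physical_constants()] object.
#' @return Torque in pN nm.
#' @export
ecoli_torque <- function(ctx, constants = physical_constants()) {
  if (is.numeric(ctx)) ctx <- supercoiling_context(ctx)
  stopifnot(inherits(ctx, "rloop_supercoiling"),
            inherits(constants, "rloop_constants"))
  constants$kBT_pNnm * ctx$p_tor / ctx$h * 2 * pi *
    ctx$twist_fraction * ctx$sigma
}

#' Relative formation time across single-mismatch positions
#'
#' For each torque and each mismatch position, the ratio of the mean
#' locked-R-loop formation time of the single-mismatch target to the
#' matched (WT) target. Positions with disrupted hybrid base pairing
#' (excluded positions) carry no penalty and get ratio 1.
#'
#' @param penalty Mismatch penalty, kBT (e.g. the fitted C:C value 6.9).
#' @param params A [model_params()] object.
#' @param torques Numeric vector of torques, pN nm.
#' @param hybrid_length Protospacer length, bp.
#' @param excluded_positions Zero-penalty positions.
#' @return An object of class `rloop_scan`: data.frame with columns
#'   `torque`, `position` and `ratio` (T_MM / T_WT).
#' @export
position_scan <- function(penalty, params, torques,
                          hybrid_length = 32L,
                          excluded_positions = c(6L, 12L, 18L, 24L, 30L)) {
  stopifnot(penalty >= 0, inherits(params, "rloop_params"))
  wt <- target_spec(hybrid_length,
                    excluded_positions = excluded_positions)
  out <- do.call(rbind, lapply(torques, function(tau) {
    t_wt <- formation_time(wt, params, tau)
    ratio <- vapply(seq_len(hybrid_length), function(p) {
      if (p %in% excluded_positions) return(1)
      tg <- target_spec(hybrid_length,
                        mismatches = data.frame(position = p,
                                                penalty = penalty),
                        excluded_positions = excluded_positions)
      formation_time(tg, params, tau) / t_wt
    }, numeric(1))
    data.frame(torque = tau, position = seq_len(hybrid_length),
               ratio = ratio)
  }))
  class(out) <- c("rloop_scan", "data.frame")
  out
}

#' Seed length from a position scan
#'
#' The seed is read as the PAM-proximal extent over which a single mismatch
#' slows formation at least `threshold`-fold: the largest position p such
#' that every penalized position up to p has ratio >= threshold, excluded
#' positions being skipped (default contiguity rule). The alternative
#' `"count"` rule simply counts positions above threshold.
#'
#' @param scan An `rloop_scan` from [position_scan()] (or a data.frame with
#'   `torque`, `position`, `ratio`).
#' @param torque Which torque of the scan to read (default: the single one
#'   present).
#' @param threshold Fold-increase threshold (default 10).
#' @param excluded_positions Positions skipped by the contiguity rule.
#' @param rule `"contiguous"` (default) or `"count"`.
#' @return Seed length in bp (0 if no position reaches the threshold).
#' @export
seed_length <- function(scan, torque = NULL, threshold = 10,
                        excluded_positions = c(6L, 12L, 18L, 24L, 30L),
                        rule = c("contiguous", "count")) {
  rule <- match.arg(rule)
  if (is.null(torque)) {
    tq <- unique(scan$torque)
    if (length(tq) != 1L)
      stop("scan contains several torques; specify `torque`")
    torque <- tq
  }
  row <- scan[scan$torque == torque, ]
  row <- row[order(row$position), ]
  if (!nrow(row)) stop("no scan rows at the requested torque")
  if (rule == "count")
    return(sum(row$ratio >= threshold &
                 !(row$position %in% excluded_positions)))
  seed <- 0L
  for (p in row$position) {
    if (p %in% excluded_positions) {
      if (seed == p - 1L) seed <- p
      next
    }
    if (row$ratio[row$position == p] >= threshold && seed == p - 1L)
      seed <- p
    else break
  }
  seed
}

#' Double-mismatch relative formation-time matrix
#'
#' Relative formation time for every ordered pair of mismatch positions,
#' either from the full random walk on the two-mismatch chain or from the
#' penalty-addition comparator, which composes the two single-mismatch
#' fold-changes multiplicatively (adding apparent free-energy penalties)
#' and therefore carries no mismatch-proximity dependence. Mismatches at
#' excluded positions contribute nothing, so a pair with one excluded
#' position reduces exactly to the single-mismatch case.
#'
#' @inheritParams position_scan
#' @param torque Torque, pN nm.
#' @param model `"random-walk"` or `"penalty-addition"`.
#' @return A `hybrid_length` x `hybrid_length` matrix of T_MM / T_WT, rows
#'   and columns named by position.
#' @export
double_mismatch_matrix <- function(penalty, params, torque,
                                   model = c("random-walk",
                                             "penalty-addition"),
                                   hybrid_length = 32L,
                                   excluded_positions = c(6L, 12L, 18L,
                                                          24L, 30L)) {
  model <- match.arg(model)
  scan <- position_scan(penalty, params, torque,
                        hybrid_length = hybrid_length,
                        excluded_positions = excluded_positions)
  single <- scan$ratio[order(scan$position)]
  n <- hybrid_length
  M <- matrix(NA_real_, n, n, dimnames = list(seq_len(n), seq_len(n)))
  if (model == "penalty-addition") {
    M <- outer(single, single)
    diag(M) <- single       # i = j is a single mismatch, not two
  } else {
    wt <- target_spec(hybrid_length,
                      excluded_positions = excluded_positions)
    t_wt <- formation_time(wt, params, torque)
    for (i in seq_len(n)) {
      for (j in i:n) {
        pos <- setdiff(unique(c(i, j)), excluded_positions)
        r <- if (!length(pos)) 1
        else {
          tg <- target_spec(hybrid_length,
                            mismatches = data.frame(position = pos,
                                                    penalty = penalty),
                            excluded_positions = excluded_positions)
          formation_time(tg, params, torque) / t_wt
        }
        M[i, j] <- r; M[j, i] <- r
      }
    }
  }
  dimnames(M) <- list(seq_len(n), seq_len(n))
  M
}
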