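#' Read and write model configuration
#'
#' Targets and parameter sets serialize to a structured-text (YAML)
#' configuration so that analyses are reproducible from plain files.
#'
#' @param x A [target_spec()] or [model_params()] object.
#' @param path File path.
#' @name rloop_io
NULL

#' @rdname rloop_io
#' @export
write_target <- function(x, path) {
  stopifnot(inherits(x, "rloop_target"))
  obj <- list(hybrid_length = x$hybrid_length,
              mismatches = if (nrow(x$mismatches))
                lapply(seq_len(nrow(x$mismatches)), function(i)
                  list(position = x$mismatches$position[i],
                       penalty = x$mismatches$penalty[i]))
              else list(),
              distal_cutoff = x$distal_cutoff,
              lock_competent = x$lock_competent,
              excluded_positions = as.list(x$excluded_positions))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname rloop_io
#' @export
read_target <- function(path) {
  obj <- yaml::read_yaml(path)
  mm <- if (length(obj$mismatches))
    data.frame(position = vapply(obj$mismatches, `[[`, numeric(1),
                                 "position"),
               penalty = vapply(obj$mismatches, `[[`, numeric(1),
                                "penalty"))
  else NULL
  target_spec(hybrid_length = obj$hybrid_length, mismatches = mm,
              distal_cutoff = obj$distal_cutoff,
              lock_competent = obj$lock_competent,
              excluded_positions = unlist(obj$excluded_positions))
}

#' @rdname rloop_io
#' @export
write_params <- function(x, path) {
  stopifnot(inherits(x, "rloop_params"))
  yaml::write_yaml(list(k_step = x$k_step, dG_ini = x$dG_ini,
                        dG_bias = x$dG_bias, dG_lock = x$dG_lock,
                        concentration = x$concentration, c0 = x$c0,
                        kBT_pNnm = x$constants$kBT_pNnm,
                        dphi_bp = x$constants$dphi_bp), path)
  invisible(path)
}

#' @rdname rloop_io
#' @export
read_params <- function(path) {
  o <- yaml::read_yaml(path)
  model_params(k_step = o$k_step, dG_ini = o$dG_ini, dG_bias = o$dG_bias,
               dG_lock = o$dG_lock, concentration = o$concentration,
               c0 = o$c0,
               constants = physical_constants(kBT_pNnm = o$kBT_pNnm,
                                              dphi_bp = o$dphi_bp))
}

#' Export a landscape as two-column text
#'
#' Columns `n` (R-loop length, bp) and `G` (free energy, kBT).
#'
#' @param landscape An `rloop_landscape`.
#' @param path File path.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "rloop_landscape"))
  utils::write.table(
    data.frame(n = 0:landscape$N_eff, G = landscape$energies),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a rate chain as three-column text
#'
#' Columns `n`, `k_plus` (rate n -> n+1) and `k_minus` (rate n -> n-1,
#' `NA` for n = 0).
#'
#' @param chain An `rloop_rate_chain`.
#' @param path File path.
#' @export
write_rate_chain <- function(chain, path) {
  stopifnot(inherits(chain, "rloop_rate_chain"))
  utils::write.table(
    data.frame(n = 0:(chain$N_eff - 1L),
               k_plus = chain$k_plus,
               k_minus = c(NA, chain$k_minus[-chain$N_eff])),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a trajectory CSV
#'
#' Trajectories are written as CSV (`time_s`, `extension_nm` and, when
#' present, `rloop_bp`, `true_state`) preceded by `#`-prefixed metadata
#' lines (seed, target, torque).
#'
#' @param traj A trajectory data frame (as from [make_trajectories()]).
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("seed", "target_id", "torque")) {
    v <- attr(traj, key)
    if (!is.null(v)) writeLines(sprintf("# %s: %s", key, v), con)
  }
  utils::write.csv(traj, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  df <- utils::read.csv(text = lines[setdiff(seq_along(lines), meta_idx)])
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^# ([^:]+): (.*)$", ln))[[1]]
    if (length(m) == 3L) {
      v <- suppressWarnings(as.numeric(m[3]))
      attr(df, m[2]) <- if (is.na(v)) m[3] else v
    }
  }
  df
}

#' Write / read an observation table CSV
#'
#' Plain CSV of the tidy observation format used by [fit_problem()].
#'
#' @param obs Observation data frame.
#' @param path File path.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
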