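#' Assemble a global fitting problem
#'
#' Couples a table of measured observables (coarse rates or formation times
#' across targets and torques) to the random-walk model. Mismatch penalties
#' given as `NA` in a target are shared and tied to the fit parameter
#' `dG_MM`; numeric penalties stay fixed.
#'
#' @param observations Data frame with columns `target_id`, `torque`,
#'   `observable` (`"formation_time"` or a coarse-rate label `"k1"`,
#'   `"k2"`, ...), `value` and `sem` (both positive).
#' @param targets Named list of [target_spec()] objects keyed by
#'   `target_id`.
#' @param free Character vector naming the free parameters, a subset of
#'   `c("k_step", "dG_ini", "dG_MM", "dG_bias")`.
#' @param fixed Named list giving values for the parameters not in `free`.
#' @param concentration,c0 Cascade concentration and reference, molar.
#' @param bias_on_initiation Passed to [landscape_to_rates()].
#' @return An object of class `rloop_fit_problem`.
#' @export
fit_problem <- function(observations, targets, free, fixed = list(),
                        concentration = 0.5e-9, c0 = 0.5e-9,
                        bias_on_initiation = TRUE) {
  stopifnot(is.data.frame(observations),
            all(c("target_id", "torque", "observable", "value", "sem") %in%
                  names(observations)),
            all(observations$value > 0), all(observations$sem > 0))
  all_par <- c("k_step", "dG_ini", "dG_MM", "dG_bias")
  stopifnot(all(free %in% all_par),
            all(setdiff(all_par, free) %in% c(names(fixed), "dG_MM")))
  miss <- setdiff(unique(observations$target_id), names(targets))
  if (length(miss))
    stop("observations reference unknown targets: ",
         paste(miss, collapse = ", "))
  if (nrow(observations) < length(free))
    stop("fewer observations than free parameters")
  structure(list(observations = observations, targets = targets,
                 free = free, fixed = fixed,
                 concentration = concentration, c0 = c0,
                 bias_on_initiation = bias_on_initiation),
            class = "rloop_fit_problem")
}

# Fill shared-penalty (NA) mismatches of a target with the current dG_MM.
fill_target <- function(target, dG_MM) {
  if (!any(is.na(target$mismatches$penalty))) return(target)
  target$mismatches$penalty[is.na(target$mismatches$penalty)] <- dG_MM
  target
}

#' Model prediction for one observable
#'
#' @param target A [target_spec()] (NA penalties already filled).
#' @param params A [model_params()].
#' @param torque Torque, pN nm.
#' @param observable `"formation_time"` or a coarse-rate label.
#' @param bias_on_initiation Passed to [landscape_to_rates()].
#' @return Predicted value (seconds or 1/s).
#' @export
predict_observable <- function(target, params, torque, observable,
                               bias_on_initiation = TRUE) {
  if (observable == "formation_time")
    return(formation_time(target, params, torque,
                          bias_on_initiation = bias_on_initiation))
  landscape <- build_landscape(target, params, torque)
  chain <- landscape_to_rates(landscape, target, params,
                              bias_on_initiation = bias_on_initiation)
  cr <- coarse_rates(chain, coarse_states(landscape))
  i <- match(observable, cr$label)
  if (is.na(i)) stop("observable ", observable,
                     " not defined for this target (labels: ",
                     paste(cr$label, collapse = ", "), ")")
  cr$rate[i]
}

fit_par_bounds <- list(k_step = c(2, 5),       # log10 scale
                       dG_ini = c(0, 15),
                       dG_MM = c(0, 15),
                       dG_bias = c(-1, 1))

theta_to_params <- function(theta, problem) {
  get <- function(nm)
    if (nm %in% names(theta)) unname(theta[[nm]])
    else unname(problem$fixed[[nm]])
  list(k_step = if ("k_step" %in% names(theta)) 10^theta[["k_step"]]
       else problem$fixed$k_step,
       dG_ini = get("dG_ini"),
       dG_MM = if ("dG_MM" %in% names(theta)) unname(theta[["dG_MM"]])
       else problem$fixed$dG_MM,
       dG_bias = get("dG_bias"))
}

fit_objective <- function(theta, problem, scale) {
  p <- theta_to_params(theta, problem)
  params <- model_params(k_step = p$k_step, dG_ini = p$dG_ini,
                         dG_bias = p$dG_bias,
                         concentration = problem$concentration,
                         c0 = problem$c0)
  obs <- problem$observations
  pred <- vapply(seq_len(nrow(obs)), function(i) {
    tg <- fill_target(problem$targets[[obs$target_id[i]]], p$dG_MM)
    predict_observable(tg, params, obs$torque[i], obs$observable[i],
                       bias_on_initiation = problem$bias_on_initiation)
  }, numeric(1))
  if (scale == "log10") {
    s <- obs$sem / (obs$value * log(10))
    sum(((log10(pred) - log10(obs$value)) / s)^2)
  } else {
    sum(((pred - obs$value) / obs$sem)^2)
  }
}

#' Global weighted least-squares fit of the random-walk model
#'
#' Minimizes the weighted sum of squared residuals over the free
#' parameters, rebuilding the rate chain for every target and torque at
#' each evaluation. Because the measured rates span orders of magnitude,
#' the default objective works on log10 of the observables with SEMs
#' propagated to the log scale; linear-scale weighting is selectable.
#' Optimization uses L-BFGS-B from multiple random starts (log-uniform in
#' `k_step`), deterministic given `seed`. Parameter standard deviations are
#' taken from the inverse Hessian of the chi-square objective at the
#' optimum.
#'
#' @param problem An [fit_problem()] object.
#' @param scale `"log10"` (default) or `"linear"` residual scale.
#' @param n_starts Number of optimization starts.
#' @param seed Seed for the random starts.
#' @return An object of class `rloop_fit_result`: list with `par`
#'   (best-fit values, natural scale), `sd` (1-sigma standard deviations,
#'   natural scale), `objective`, `convergence`, `identifiable` and the
#'   transformed-scale internals used by [confidence_intervals()].
#' @export
fit_global <- function(problem, scale = c("log10", "linear"),
                       n_starts = 20L, seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(inherits(problem, "rloop_fit_problem"))
  free <- problem$free
  lower <- vapply(free, function(p) fit_par_bounds[[p]][1], numeric(1))
  upper <- vapply(free, function(p) fit_par_bounds[[p]][2], numeric(1))
  set.seed(seed)
  mids <- (lower + upper) / 2
  starts <- rbind(mids,
                  matrix(stats::runif(length(free) * (n_starts - 1L),
                                      rep(lower, each = n_starts - 1L),
                                      rep(upper, each = n_starts - 1L)),
                         ncol = length(free)))
  colnames(starts) <- free
  obj <- function(th) {
    names(th) <- free
    v <- tryCatch(fit_objective(th, problem, scale),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimization starts failed")
  theta <- best$par; names(theta) <- free
  H <- stats::optimHess(theta, obj)
  cov <- tryCatch(2 * solve(H), error = function(e) NULL)
  identifiable <- !is.null(cov) && all(diag(cov) > 0)
  sd_theta <- if (identifiable) sqrt(diag(cov))
              else rep(NA_real_, length(free))
  names(sd_theta) <- free
  par_nat <- vapply(free, function(p)
    if (p == "k_step") 10^theta[[p]] else theta[[p]], numeric(1))
  sd_nat <- vapply(free, function(p)
    if (p == "k_step") sd_theta[[p]] * 10^theta[[p]] * log(10)
    else sd_theta[[p]], numeric(1))
  structure(list(par = par_nat, sd = sd_nat, objective = best$value,
                 convergence = best$convergence,
                 identifiable = identifiable,
                 theta = theta, sd_theta = sd_theta,
                 lower = lower, upper = upper, scale = scale),
            class = "rloop_fit_result")
}

#' Profile-likelihood confidence intervals for a global fit
#'
#' For each free parameter, walks the profile of the weighted objective
#' (re-optimizing the remaining parameters) until it rises by the
#' chi-square quantile for `level` with one degree of freedom, and locates
#' the crossing by interpolation. Profiles running into the parameter
#' bounds give one-sided intervals and are flagged open-ended.
#'
#' @param problem The [fit_problem()].
#' @param result The [fit_global()] result.
#' @param level Confidence level (default 0.67, a "single" 1-sigma-style
#'   interval).
#' @return Data frame with columns `parameter`, `lower`, `upper`,
#'   `open_lower`, `open_upper` (natural scale).
#' @export
confidence_intervals <- function(problem, result, level = 0.67) {
  stopifnot(inherits(problem, "rloop_fit_problem"),
            inherits(result, "rloop_fit_result"))
  free <- names(result$theta)
  dchi <- stats::qchisq(level, df = 1)
  target_obj <- result$objective + dchi
  out <- lapply(seq_along(free), function(j) {
    step0 <- result$sd_theta[[j]]
    if (!is.finite(step0) || step0 <= 0)
      step0 <- 0.05 * max(abs(result$theta[[j]]), 1)
    bnds <- c(result$lower[[j]], result$upper[[j]])
    prof <- function(val) {
      others <- setdiff(free, free[j])
      if (!length(others)) {
        th <- result$theta; th[j] <- val
        names(th) <- free
        return(tryCatch(fit_objective(th, problem, result$scale),
                        error = function(e) Inf))
      }
      objo <- function(tho) {
        th <- stats::setNames(numeric(length(free)), free)
        th[others] <- tho; th[free[j]] <- val
        tryCatch(fit_objective(th, problem, result$scale),
                 error = function(e) 1e12)
      }
      o <- stats::optim(result$theta[others], objo, method = "L-BFGS-B",
                        lower = result$lower[match(others, free)],
                        upper = result$upper[match(others, free)],
                        control = list(maxit = 300))
      o$value
    }
    walk <- function(dir) {
      val <- result$theta[[j]]; f_prev <- result$objective
      for (i in 1:40) {
        nxt <- val + dir * step0
        if (nxt < bnds[1] || nxt > bnds[2])
          return(list(bound = if (dir < 0) bnds[1] else bnds[2],
                      open = TRUE))
        f <- prof(nxt)
        if (f >= target_obj) {
          w <- (target_obj - f_prev) / (f - f_prev)
          return(list(bound = val + w * dir * step0, open = FALSE))
        }
        val <- nxt; f_prev <- f
      }
      list(bound = val, open = TRUE)
    }
    lo <- walk(-1); hi <- walk(+1)
    to_nat <- function(v) if (free[j] == "k_step") 10^v else v
    data.frame(parameter = free[j],
               lower = to_nat(lo$bound), upper = to_nat(hi$bound),
               open_lower = lo$open, open_upper = hi$open,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.rloop_fit_result <- function(x, ...) {
  cat("Global random-walk model fit\n")
  for (p in names(x$par))
    cat(sprintf("  %-8s = %.4g +/- %.3g\n", p, x$par[[p]], x$sd[[p]]))
  cat(sprintf("  objective = %.4g (%s scale)%s\n", x$objective, x$scale,
              if (!x$identifiable) "  [flat/unidentifiable]" else ""))
  invisible(x)
}
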