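# Profile-likelihood identifiability analysis: per-parameter profiles with
# nuisance re-optimization, finite-interval classification, and
# prediction-profile confidence bands for the observables.

#' Likelihood-ratio threshold offset
#'
#' Chi-square quantile used to convert the profile of the calibration
#' objective into a confidence region: 3.84 at alpha 0.95 with 1 degree of
#' freedom.  When the residual standard deviation is unknown (the usual
#' case), the offset is scaled by the variance estimate `L* / (N - p)` of
#' the max-normalized residuals before being added to the optimum; pass the
#' raw value through the `delta` arguments of [profile_parameter()] /
#' [observable_band()] to use the unit-variance convention instead.
#'
#' @param alpha Confidence level.
#' @param df Degrees of freedom (1 for pointwise per-parameter intervals).
#' @return Scalar chi-square quantile.
#' @export
pl_delta <- function(alpha = 0.95, df = 1) qchisq(alpha, df = df)

# default threshold offset for a fit: chi-square quantile scaled by the
# residual-variance estimate of the normalized residuals
fit_delta <- function(fit, alpha) {
  n <- nrow(fit$obs$points)
  p <- length(fit$theta)
  s2 <- max(fit$objective / max(n - p, 1), 1e-12)
  pl_delta(alpha) * s2
}

# Profile an arbitrary objective: fn(value) must return the re-optimized
# objective with the profiled parameter fixed at `value`.  Walks outward from
# the optimum in `n_steps` increments per side; the threshold crossing is
# located by bisection to absolute parameter tolerance `tol`.
profile_objective <- function(fn, opt_value, opt_objective, scan_range,
                              delta, n_steps = 8, tol = 1e-4) {
  thr <- opt_objective + delta
  scan_one_side <- function(bound) {
    pts_v <- numeric(0); pts_f <- numeric(0)
    if (abs(bound - opt_value) < tol)
      return(list(endpoint = bound, bounded = FALSE, v = pts_v, f = pts_f))
    grid <- seq(opt_value, bound, length.out = n_steps + 1)[-1]
    lo_v <- opt_value; lo_f <- opt_objective
    hit <- FALSE
    for (v in grid) {
      f <- fn(v)
      pts_v <- c(pts_v, v); pts_f <- c(pts_f, f)
      if (f > thr) { hi_v <- v; hit <- TRUE; break }
      lo_v <- v; lo_f <- f
    }
    if (!hit)
      return(list(endpoint = bound, bounded = FALSE, v = pts_v, f = pts_f))
    while (abs(hi_v - lo_v) > tol) {
      mid <- (lo_v + hi_v) / 2
      f <- fn(mid)
      pts_v <- c(pts_v, mid); pts_f <- c(pts_f, f)
      if (f > thr) hi_v <- mid else lo_v <- mid
    }
    endpoint <- (lo_v + hi_v) / 2
    # an endpoint landing on the scan bound is classified unbounded
    bounded <- abs(endpoint - bound) > tol
    list(endpoint = endpoint, bounded = bounded, v = pts_v, f = pts_f)
  }
  left <- scan_one_side(scan_range[1])
  right <- scan_one_side(scan_range[2])
  curve <- tibble(value = c(rev(left$v), opt_value, right$v),
                  objective = c(rev(left$f), opt_objective, right$f))
  curve <- curve[order(curve$value), ]
  list(curve = curve,
       lower = left$endpoint, upper = right$endpoint,
       lower_bounded = left$bounded, upper_bounded = right$bounded)
}

#' Profile likelihood of one estimated parameter
#'
#' Fixes the profiled parameter on a sequence of values and re-optimizes all
#' remaining free parameters (warm-started from the neighboring solution);
#' the confidence-interval endpoint on each side is where the profile crosses
#' the optimum plus [pl_delta()], located by bisection.  An endpoint with no
#' crossing inside the scan range -- or sitting exactly on the range bound --
#' is reported unbounded.  The equilibration lag `tau_g`, when present, is
#' re-optimized as a nuisance parameter but is never itself profiled.
#'
#' @param fit An `edes_fit` from [calibrate_response()].
#' @param which One of `"k1"`, `"k5"`, `"k6"`.
#' @param scan_range Numeric length-2; defaults to the calibration search
#'   range for the parameter.
#' @param alpha Confidence level (default 0.95).
#' @param delta Threshold offset added to the optimal objective; defaults to
#'   the variance-scaled chi-square quantile (see [pl_delta()]).
#' @param n_steps Coarse outward scan steps per side.
#' @param tol Absolute parameter tolerance of the bisection.
#' @return An object of class `profile_curve`: the scan curve, CI endpoints
#'   with boundedness flags, and every nuisance-optimized parameter vector
#'   visited (reused by [observable_band()]).
#' @export
profile_parameter <- function(fit, which = c("k1", "k5", "k6"),
                              scan_range = NULL, alpha = 0.95, delta = NULL,
                              n_steps = 8, tol = 1e-4) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "edes_fit"))
  if (isTRUE(fit$failed))
    abort("fit carries a penalty objective and cannot be profiled",
          class = "glucodyn_not_profilable")
  rng <- fit$config$ranges
  if (is.null(scan_range))
    scan_range <- unlist(rng[rng$parameter == which, c("lower", "upper")])
  free <- setdiff(rng$parameter, which)
  lower <- setNames(rng$lower, rng$parameter)[free]
  upper <- setNames(rng$upper, rng$parameter)[free]

  visited <- list()
  warm <- fit$theta[free]
  prev_value <- fit$theta[[which]]
  # complementary secretion/sensitivity gain: along the weakly identified
  # direction these two trade off as a near-constant product, so a
  # valley-tracking start rescales the partner when one of them is profiled
  partner <- if (which %in% c("k5", "k6"))
    intersect(setdiff(c("k5", "k6"), which), free) else character(0)
  reopt <- function(value) {
    obj_free <- function(th) {
      theta <- c(setNames(value, which), setNames(th, free))
      calib_objective(theta_to_est(theta, fit$mode), fit$obs, fit$fixed,
                      fit$ctx, penalty = fit$config$penalty)
    }
    starts <- list(warm, fit$theta[free])
    if (length(partner) && value > 0 && prev_value > 0) {
      tracked <- warm
      tracked[partner] <- pmin(pmax(warm[partner] * prev_value / value,
                                    lower[partner]), upper[partner])
      starts <- c(starts, list(tracked))
    }
    best <- NULL
    for (x0 in starts) {
      res <- tryCatch(
        optim(x0, obj_free, method = "L-BFGS-B", lower = lower,
              upper = upper,
              control = list(factr = 1e6, maxit = 150,
                             ndeps = (upper - lower) * 1e-6)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
    }
    if (is.null(best)) return(fit$config$penalty)
    warm <<- setNames(best$par, free)
    prev_value <<- value
    visited[[length(visited) + 1]] <<-
      c(setNames(value, which), warm, objective = best$value)
    best$value
  }
  delta <- delta %||% fit_delta(fit, alpha)
  prof <- profile_objective(reopt, fit$theta[[which]], fit$objective,
                            scan_range, delta, n_steps, tol)
  structure(list(parameter = which,
                 curve = prof$curve,
                 optimum = fit$theta[[which]],
                 optimum_objective = fit$objective,
                 lower = unname(prof$lower), upper = unname(prof$upper),
                 lower_bounded = prof$lower_bounded,
                 upper_bounded = prof$upper_bounded,
                 scan_range = unname(scan_range),
                 alpha = alpha, delta = delta,
                 visited = visited),
            class = "profile_curve")
}

#' Classify practical identifiability from profile curves
#'
#' A parameter is identifiable when both confidence-interval endpoints lie
#' strictly inside its scan range; the model is practically identifiable only
#' when every profiled parameter is.
#'
#' @param profiles List of `profile_curve` objects.
#' @return An object of class `identifiability_report`: a tibble (one row per
#'   parameter: `parameter`, `lower`, `upper`, `lower_bounded`,
#'   `upper_bounded`, `identifiable`) with attribute `identifiable` for the
#'   overall model flag.
#' @export
classify_identifiability <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "profile_curve")))
  tab <- purrr::map_dfr(profiles, function(p) {
    tibble(parameter = p$parameter,
           lower = p$lower, upper = p$upper,
           lower_bounded = p$lower_bounded, upper_bounded = p$upper_bounded,
           identifiable = p$lower_bounded && p$upper_bounded)
  })
  structure(tab, identifiable = all(tab$identifiable),
            class = c("identifiability_report", class(tab)))
}

#' Prediction-profile confidence band of an observable
#'
#' At each of a coarse set of times the band is the envelope (min/max) of the
#' observable's prediction over parameter vectors whose objective lies within
#' [pl_delta()] of the optimum; the envelope is then interpolated onto the
#' requested grid.  Candidate vectors are the nuisance-optimized points
#' visited during profiling plus the fitted optimum, so the band always
#' contains the point simulation and is monotone in the confidence level.
#'
#' @param fit An `edes_fit`.
#' @param observable `"glucose"` or `"insulin"`.
#' @param times Times (min) at which the band is reported.
#' @param alpha Confidence level.
#' @param delta Threshold offset; defaults to the variance-scaled chi-square
#'   quantile (see [pl_delta()]).
#' @param profiles List of `profile_curve`s for this fit; computed (coarsely)
#'   when omitted.
#' @param n_coarse Number of coarse evaluation times.
#' @return A tibble of class `confidence_band` with columns `time`, `fit`,
#'   `lower`, `upper`.
#' @export
observable_band <- function(fit, observable = c("glucose", "insulin"),
                            times = seq(0, 120, by = 5), alpha = 0.95,
                            delta = NULL, profiles = NULL, n_coarse = 9) {
  observable <- match.arg(observable)
  stopifnot(inherits(fit, "edes_fit"))
  if (is.null(profiles)) {
    pars <- intersect(c("k1", "k5", "k6"), fit$config$ranges$parameter)
    profiles <- lapply(pars, function(p)
      profile_parameter(fit, p, alpha = alpha, n_steps = 6, tol = 1e-3))
  }
  thr <- fit$objective + (delta %||% fit_delta(fit, alpha))
  cand <- purrr::map(profiles, "visited") |> purrr::flatten()
  keep <- purrr::keep(cand, ~ .x[["objective"]] <= thr)
  thetas <- c(list(c(fit$theta, objective = fit$objective)), keep)

  col <- c(glucose = if (fit$mode == "cgm") "interstitial_glucose"
                     else "plasma_glucose",
           insulin = "plasma_insulin")[[observable]]
  t_coarse <- unique(sort(c(0, seq(min(times), max(times),
                                   length.out = n_coarse))))
  sims <- purrr::map(thetas, function(th) {
    est <- theta_to_est(th[setdiff(names(th), "objective")], fit$mode)
    tr <- tryCatch(simulate_response(est, fit$fixed, fit$ctx, t_coarse),
                   glucodyn_simulation_error = function(e) NULL)
    if (is.null(tr)) NULL else tr[[col]]
  }) |> purrr::compact()
  mat <- do.call(rbind, sims)
  lo <- apply(mat, 2, min); hi <- apply(mat, 2, max)
  point <- sims[[1]]
  band <- tibble(
    time = times,
    fit = approx(t_coarse, point, xout = times, rule = 2)$y,
    lower = approx(t_coarse, lo, xout = times, rule = 2)$y,
    upper = approx(t_coarse, hi, xout = times, rule = 2)$y)
  # interpolation cannot let the band cross its own center
  band$lower <- pmin(band$lower, band$fit)
  band$upper <- pmax(band$upper, band$fit)
  structure(band, observable = observable, alpha = alpha,
            class = c("confidence_band", class(band)))
}
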