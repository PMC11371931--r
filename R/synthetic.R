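# Synthetic cohort generator: draws ground-truth parameters and contexts,
# simulates simultaneous OGTT plasma + CGM responses, applies measurement
# noise and missingness, and enforces the study-design exclusion rules.

OGTT_TIMES <- c(0, 15, 30, 45, 60, 90, 120)
CGM_TIMES <- seq(0, 130, by = 5)

#' Measurement noise model
#'
#' Plasma channels carry multiplicative log-normal noise with the given
#' coefficients of variation; the CGM channel carries proportional log-normal
#' error plus one additive bias per trace (Gaussian), emulating sensor
#' calibration offset.  Noise is applied after simulation and values are
#' floored at a small positive bound.
#'
#' @param cv_glucose Plasma glucose CV (default 0.02).
#' @param cv_insulin Plasma insulin CV (default 0.07).
#' @param cgm_proportional CGM proportional error (default 0.05).
#' @param cgm_bias_mean,cgm_bias_sd Per-trace CGM bias (mmol/L); the positive
#'   default mean reproduces the tendency of interstitial readings to sit
#'   above plasma glucose.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_glucose = 0.02, cv_insulin = 0.07,
                        cgm_proportional = 0.05,
                        cgm_bias_mean = 0.3, cgm_bias_sd = 0.2) {
  vals <- c(cv_glucose, cv_insulin, cgm_proportional, cgm_bias_sd)
  if (any(vals < 0)) abort("noise magnitudes must be non-negative")
  structure(list(cv_glucose = cv_glucose, cv_insulin = cv_insulin,
                 cgm_proportional = cgm_proportional,
                 cgm_bias_mean = cgm_bias_mean, cgm_bias_sd = cgm_bias_sd),
            class = "noise_model")
}

#' Cohort specification
#'
#' Defines the population the generator draws from and the measurement
#' designs it emulates: a 75 g, 7-point OGTT (t = 0, 15, 30, 45, 60, 90,
#' 120 min) with a CGM trace on a 5-min grid over 0-130 min.  Subject-level
#' parameters are log-normal; the defaults center the equilibration lag at a
#' median of 2.5 min and spread the remaining parameters widely enough to
#' span normoglycemic through impaired-glucose-tolerant response shapes.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer RNG seed; the cohort is fully reproducible from
#'   `(spec, seed)`.
#' @param params Named list of log-normal `(meanlog, sdlog)` pairs for `k1`,
#'   `k5`, `k6`, `tau_g`, `body_mass`, `basal_glucose`, `basal_insulin`.
#' @param compensation Sensitivity-secretion compensation exponent: the
#'   medians of `k6` and basal insulin are scaled by
#'   `(median_k5 / k5)^compensation` for each subject, encoding the
#'   hyperbolic compensation of declining insulin sensitivity by
#'   hyperinsulinemia seen in real populations (0 = independent draws).
#' @param noise A [noise_model()].
#' @param missing_prob Per-sample probability of a missing plasma OGTT value
#'   (default 0: complete designs; pass a positive value to emulate missed
#'   draws).
#' @param p_irregular_cgm Probability that a trace is written on an irregular
#'   (non 5-min) grid, which the exclusion rules later reject.
#' @param dose Glucose dose (g).
#' @param fixed [fixed_parameters()] used for simulation.
#' @param max_retries Redraws allowed when a draw fails to simulate.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, seed = 1L,
                        params = list(
                          k1 = c(meanlog = log(0.018), sdlog = 0.30),
                          k5 = c(meanlog = log(0.006), sdlog = 0.45),
                          k6 = c(meanlog = log(1.2), sdlog = 0.50),
                          tau_g = c(meanlog = log(2.5), sdlog = 1.0),
                          body_mass = c(meanlog = log(85), sdlog = 0.12),
                          basal_glucose = c(meanlog = log(5.3), sdlog = 0.06),
                          basal_insulin = c(meanlog = log(12), sdlog = 0.35)),
                        compensation = 0.5,
                        noise = noise_model(), missing_prob = 0,
                        p_irregular_cgm = 0, dose = 75,
                        fixed = fixed_parameters(), max_retries = 5L) {
  stopifnot(n_subjects >= 1, missing_prob >= 0, missing_prob <= 1,
            p_irregular_cgm >= 0, p_irregular_cgm <= 1)
  needed <- c("k1", "k5", "k6", "tau_g", "body_mass", "basal_glucose",
              "basal_insulin")
  stopifnot(all(needed %in% names(params)))
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 params = params, compensation = compensation,
                 noise = noise, missing_prob = missing_prob,
                 p_irregular_cgm = p_irregular_cgm, dose = dose,
                 fixed = fixed, max_retries = as.integer(max_retries)),
            class = "cohort_spec")
}

draw_lnorm <- function(p) rlnorm(1, meanlog = p[["meanlog"]],
                                 sdlog = p[["sdlog"]])

#' Draw one synthetic subject
#'
#' Draws true parameters and context from the spec's distributions, simulates
#' the OGTT with the ODE model, samples the plasma channels at the 7-point
#' design and interstitial glucose on the 5-min grid, and applies the noise
#' model.  Draws whose simulation fails or goes negative are redrawn (bounded
#' retries).  Uses the current RNG stream; seed at the cohort level via
#' [sample_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @param id Identifier for the generated response.
#' @return A list of class `synthetic_subject` with elements `truth`
#'   (named true parameter vector), `context`, `clean` (noise-free sampled
#'   trajectory), and `response` (a [subject_response()] with noisy data).
#' @export
sample_subject <- function(spec, id = "S1") {
  for (attempt in seq_len(spec$max_retries)) {
    k5 <- draw_lnorm(spec$params$k5)
    # hyperbolic sensitivity-secretion compensation: less sensitive subjects
    # run higher basal insulin and a higher secretion gain
    comp <- spec$compensation *
      (spec$params$k5[["meanlog"]] - log(k5))
    est <- estimable_parameters(
      k1 = draw_lnorm(spec$params$k1),
      k5 = k5,
      k6 = rlnorm(1, spec$params$k6[["meanlog"]] + comp,
                  spec$params$k6[["sdlog"]]),
      tau_g = draw_lnorm(spec$params$tau_g))
    ctx <- subject_context(
      body_mass = draw_lnorm(spec$params$body_mass),
      basal_glucose = draw_lnorm(spec$params$basal_glucose),
      basal_insulin = rlnorm(1, spec$params$basal_insulin[["meanlog"]] + comp,
                             spec$params$basal_insulin[["sdlog"]]),
      glucose_dose = spec$dose)
    t_all <- sort(unique(c(OGTT_TIMES, CGM_TIMES)))
    traj <- tryCatch(simulate_response(est, spec$fixed, ctx, t_all),
                     glucodyn_simulation_error = function(e) NULL)
    if (is.null(traj) || isTRUE(attr(traj, "negative"))) next

    nm <- spec$noise
    io <- match(OGTT_TIMES, traj$time)
    ic <- match(CGM_TIMES, traj$time)
    g_pl <- traj$plasma_glucose[io]
    i_pl <- traj$plasma_insulin[io]
    g_if <- traj$interstitial_glucose[ic]
    bias <- rnorm(1, nm$cgm_bias_mean, nm$cgm_bias_sd)
    noisy_g <- pmax(g_pl * exp(rnorm(length(g_pl), 0, nm$cv_glucose)), 0.1)
    noisy_i <- pmax(i_pl * exp(rnorm(length(i_pl), 0, nm$cv_insulin)), 0.1)
    noisy_c <- pmax(g_if * exp(rnorm(length(g_if), 0, nm$cgm_proportional)) +
                      bias, 0.1)

    ctx$basal_interstitial <- noisy_c[1]
    ctx$basal_glucose <- noisy_g[1]
    ctx$basal_insulin <- noisy_i[1]
    response <- subject_response(
      id = id,
      ogtt = tibble(time = OGTT_TIMES, glucose = noisy_g, insulin = noisy_i),
      cgm = tibble(time = CGM_TIMES, glucose = noisy_c),
      context = ctx)
    return(structure(list(truth = unlist(est), context = ctx,
                          clean = traj, response = response, id = id),
                     class = "synthetic_subject"))
  }
  abort(paste0("failed to simulate a valid subject after ",
               spec$max_retries, " redraws"),
        class = "glucodyn_generation_error")
}

#' Generate a reproducible synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of `synthetic_subject` objects of length
#'   `spec$n_subjects`; identical for identical `(spec, seed)`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)
  subjects <- lapply(seq_len(spec$n_subjects), function(i)
    sample_subject(spec, id = sprintf("S%03d", i)))
  if (spec$missing_prob > 0 || spec$p_irregular_cgm > 0)
    subjects <- lapply(subjects, function(s) {
      s$response <- inject_missingness(s$response, spec)
      s
    })
  subjects
}

#' Remove samples to emulate missed draws and irregular CGM files
#'
#' Post-baseline plasma samples are dropped independently with probability
#' `spec$missing_prob` (set values to `NA`); with probability
#' `spec$p_irregular_cgm` the CGM grid is perturbed to an irregular spacing,
#' which [apply_exclusions()] later rejects.  Uses the current RNG stream.
#'
#' @param response A [subject_response()].
#' @param spec A [cohort_spec()].
#' @return The response with gaps.
#' @export
inject_missingness <- function(response, spec) {
  stopifnot(inherits(response, "subject_response"))
  if (spec$missing_prob > 0) {
    drop <- runif(nrow(response$ogtt)) < spec$missing_prob
    response$ogtt$glucose[drop] <- NA_real_
    response$ogtt$insulin[drop] <- NA_real_
  }
  if (spec$p_irregular_cgm > 0 && runif(1) < spec$p_irregular_cgm &&
      !is.null(response$cgm)) {
    n <- nrow(response$cgm)
    response$cgm$time <- response$cgm$time +
      c(0, cumsum(sample(c(-1, 1), n - 1, replace = TRUE)))
  }
  response
}

#' Apply the study's response exclusion rules
#'
#' A response is excluded when it has more than two missing plasma samples,
#' a missing baseline (t = 0) or 2-hour post-load sample, a CGM grid whose
#' spacing is not uniformly 5 min, or a missing glucose channel (no CGM
#' trace at all).  Exactly two missing interior samples are tolerated.
#'
#' @param cohort A list of [subject_response()] or `synthetic_subject`
#'   objects.
#' @param require_cgm Enforce the CGM-channel rules (default `TRUE`, the
#'   paired plasma-vs-CGM design).
#' @return A list with `kept` (subset of `cohort`) and `excluded`
#'   (tibble: `id`, `reason`).
#' @export
apply_exclusions <- function(cohort, require_cgm = TRUE) {
  get_resp <- function(x) if (inherits(x, "synthetic_subject")) x$response else x
  reasons <- purrr::map_chr(cohort, function(x) {
    r <- get_resp(x)
    miss <- !stats::complete.cases(r$ogtt[c("glucose", "insulin")])
    t0 <- r$ogtt$time == 0
    t120 <- r$ogtt$time == 120
    if (!any(t0) || any(miss[t0])) return("missing baseline sample")
    if (!any(t120) || any(miss[t120])) return("missing 2-hour post-load sample")
    if (sum(miss) > 2) return("more than two missing samples")
    if (require_cgm) {
      if (is.null(r$cgm) || nrow(r$cgm) == 0 || all(!is.finite(r$cgm$glucose)))
        return("missing glucose channel")
      dt <- diff(r$cgm$time)
      if (length(dt) == 0 || any(dt != 5)) return("irregular CGM grid")
    }
    NA_character_
  })
  keep <- is.na(reasons)
  ids <- purrr::map_chr(cohort, function(x) get_resp(x)$id)
  list(kept = cohort[keep],
       excluded = tibble(id = ids[!keep], reason = reasons[!keep]))
}
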