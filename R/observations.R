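#' Assemble the fitted observation set for one calibration mode
#'
#' In plasma mode the fitted points are the post-baseline OGTT plasma glucose
#' samples plus plasma insulin at the same design times; in CGM mode the
#' glucose channel is the interstitial trace on its 5-min grid (t > 0) with
#' the same plasma insulin points.  The t = 0 samples never enter the fitted
#' set -- they are model inputs -- and each metabolite carries a
#' normalization weight equal to the maximum of its measured values.
#'
#' @param response A [subject_response()].
#' @param mode `"plasma"` or `"cgm"`.
#' @return An object of class `observation_set`: a list with `points`
#'   (tibble: `metabolite`, `time`, `value`), `weights` (named max per
#'   metabolite), `mode`, and the mode-matched `context` whose basal glucose
#'   input is the t = 0 sample of the fitted glucose channel.
#' @examples
#' \donttest{
#' spec <- cohort_spec(n_subjects = 1, seed = 1)
#' subj <- sample_cohort(spec)[[1]]
#' build_observations(subj$response, "plasma")
#' }
#' @export
build_observations <- function(response, mode = c("plasma", "cgm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(response, "subject_response"))
  ogtt <- response$ogtt[stats::complete.cases(response$ogtt), ]
  ins <- ogtt[ogtt$time > 0, c("time", "insulin")]
  if (mode == "plasma") {
    glu <- ogtt[ogtt$time > 0, c("time", "glucose")]
    basal_glu <- ogtt$glucose[ogtt$time == 0]
  } else {
    if (is.null(response$cgm) || nrow(response$cgm) == 0)
      abort("response has no CGM trace; cannot build cgm-mode observations",
            class = "glucodyn_unusable_response")
    cgm <- response$cgm[stats::complete.cases(response$cgm), ]
    glu <- cgm[cgm$time > 0, c("time", "glucose")]
    basal_glu <- cgm$glucose[cgm$time == 0]
  }
  if (nrow(glu) == 0 || nrow(ins) == 0)
    abort("empty observable after removing baseline samples",
          class = "glucodyn_unusable_response")
  if (length(basal_glu) != 1)
    abort("fitted glucose channel lacks a t = 0 sample",
          class = "glucodyn_unusable_response")
  basal_ins <- ogtt$insulin[ogtt$time == 0]
  if (length(basal_ins) != 1)
    abort("plasma insulin lacks a t = 0 sample",
          class = "glucodyn_unusable_response")

  ctx0 <- response$context
  ctx <- subject_context(
    body_mass = ctx0$body_mass,
    basal_glucose = if (mode == "plasma") basal_glu else ctx0$basal_glucose,
    basal_insulin = basal_ins,
    glucose_dose = ctx0$glucose_dose,
    basal_interstitial = if (mode == "cgm") basal_glu
                         else ctx0$basal_interstitial)
  if (mode == "plasma") ctx$basal_glucose <- basal_glu

  points <- dplyr::bind_rows(
    tibble(metabolite = "glucose", time = glu$time, value = glu$glucose),
    tibble(metabolite = "insulin", time = ins$time, value = ins$insulin))
  weights <- c(glucose = max(glu$glucose), insulin = max(ins$insulin))
  if (any(weights <= 0))
    abort("normalization weights must be strictly positive",
          class = "glucodyn_unusable_response")
  structure(list(points = points, weights = weights, mode = mode, ctx = ctx),
            class = "observation_set")
}

#' Drop one metabolite from an observation set
#'
#' Utility for identifiability experiments, e.g. profiling the secretion gain
#' with the insulin channel removed.
#'
#' @param obs An `observation_set`.
#' @param metabolite Metabolite to drop.
#' @return The reduced `observation_set`.
#' @export
drop_metabolite <- function(obs, metabolite = c("insulin", "glucose")) {
  metabolite <- match.arg(metabolite)
  obs$points <- obs$points[obs$points$metabolite != metabolite, ]
  obs$weights <- obs$weights[setdiff(names(obs$weights), metabolite)]
  if (nrow(obs$points) == 0)
    abort("cannot drop the only metabolite",
          class = "glucodyn_unusable_response")
  obs
}
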