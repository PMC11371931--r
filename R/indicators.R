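# Fasting- and OGTT-derived indicators of insulin sensitivity and beta-cell
# function computed from a 7-point plasma response.
#
# Unit conventions are localized here: glucose enters the formulas in mg/dL
# where the literature forms demand it (conversion 18.016 mg/dL per mmol/L);
# insulin in mU/L (numerically equal to uU/mL).

MGDL_PER_MMOL <- 18.016

#' Trapezoidal area under a sampled segment
#'
#' @param times Sample times (min).
#' @param values Sampled values.
#' @param t_start,t_end Segment endpoints; samples at both must be present,
#'   otherwise the result is `NA`.
#' @return Trapezoidal area over `[t_start, t_end]` (value units x min), or
#'   `NA_real_` when an endpoint sample is missing.
#' @examples
#' auc_segment(c(0, 15, 30), c(4, 5, 6), 0, 30)
#' @export
auc_segment <- function(times, values, t_start, t_end) {
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  inside <- times >= t_start & times <= t_end
  if (!any(times == t_start) || !any(times == t_end)) return(NA_real_)
  t <- times[inside]; v <- values[inside]
  o <- order(t)
  t <- t[o]; v <- v[o]
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Metabolic indicators from a 7-point OGTT response
#'
#' Computes the fasting indices (HOMA-IR, HOMA-beta), the whole-OGTT Matsuda
#' index, the early-phase indices (glucose and insulin areas under the curve
#' over 0-30 min, insulinogenic index, hepatic insulin resistance index
#' HIRI), the muscle insulin sensitivity index MISI from the post-peak
#' glucose decline normalized by mean insulin, and the oral disposition index
#' (insulinogenic index x Matsuda).  Any index whose input samples are
#' missing -- or whose ratio is undefined, e.g. no glucose excursion at
#' 30 min for the insulinogenic index -- yields an explicit `NA` with the
#' reason recorded, never a silent zero.
#'
#' Formulas (G in mmol/L unless marked mg/dL, I in mU/L):
#' * `HOMA-IR = G0 * I0 / 22.5`; `HOMA-beta = 20 * I0 / (G0 - 3.5)`
#' * `Matsuda = 10000 / sqrt(G0[mg/dL] * I0 * Gmean[mg/dL] * Imean)` with
#'   means over all available 0-120 min samples
#' * `AUC30` by [auc_segment()] over 0-30 min (glucose mmol/L.min, insulin
#'   mU/L.min)
#' * `IGI = (I30 - I0) / (G30 - G0)`
#' * `HIRI = AUC30_glu[mg/dL.min] * AUC30_ins`
#' * `MISI = decline slope peak -> post-peak nadir [mg/dL/min] / Imean`
#'   (0 when the response never declines)
#' * `DI = IGI * Matsuda`
#'
#' @param response A [subject_response()] or a data frame with columns
#'   `time`, `glucose`, `insulin`.
#' @return A one-row tibble with the indicator columns
#'   (`matsuda`, `homa_ir`, `homa_beta`, `misi`, `hiri`, `auc30_glu`,
#'   `auc30_ins`, `insulinogenic_index`, `disposition_index`) and attribute
#'   `reasons` naming any indices that are `NA` and why.
#' @export
compute_indicators <- function(response) {
  d <- if (inherits(response, "subject_response")) response$ogtt
       else as_tibble(response)
  stopifnot(all(c("time", "glucose", "insulin") %in% names(d)))
  d <- d[order(d$time), ]
  reasons <- character()
  need <- function(t) {
    i <- which(d$time == t)
    if (length(i) == 1 && is.finite(d$glucose[i]) && is.finite(d$insulin[i]))
      i else NA_integer_
  }
  i0 <- need(0); i30 <- need(30)
  g <- d$glucose; ins <- d$insulin; tt <- d$time
  ok <- is.finite(g) & is.finite(ins)

  homa_ir <- homa_beta <- matsuda <- NA_real_
  if (!is.na(i0)) {
    homa_ir <- g[i0] * ins[i0] / 22.5
    if (g[i0] > 3.5) homa_beta <- 20 * ins[i0] / (g[i0] - 3.5)
    else reasons["homa_beta"] <- "fasting glucose at or below 3.5 mmol/L"
    win <- ok & tt <= 120
    if (sum(win) >= 2) {
      matsuda <- 10000 / sqrt(g[i0] * MGDL_PER_MMOL * ins[i0] *
                                mean(g[win]) * MGDL_PER_MMOL * mean(ins[win]))
    } else reasons["matsuda"] <- "too few samples in the 0-120 min window"
  } else {
    reasons[c("homa_ir", "homa_beta", "matsuda")] <- "missing t = 0 sample"
  }

  auc30_glu <- auc_segment(tt[ok], g[ok], 0, 30)
  auc30_ins <- auc_segment(tt[ok], ins[ok], 0, 30)
  if (is.na(auc30_glu)) reasons["auc30_glu"] <- "missing 0 or 30 min sample"
  if (is.na(auc30_ins)) reasons["auc30_ins"] <- "missing 0 or 30 min sample"

  igi <- NA_real_
  if (!is.na(i0) && !is.na(i30)) {
    if (g[i30] != g[i0]) igi <- (ins[i30] - ins[i0]) / (g[i30] - g[i0])
    else reasons["insulinogenic_index"] <- "no glucose excursion at 30 min"
  } else reasons["insulinogenic_index"] <- "missing t = 0 or 30 min sample"

  hiri <- if (!is.na(auc30_glu) && !is.na(auc30_ins))
    auc30_glu * MGDL_PER_MMOL * auc30_ins else NA_real_
  if (is.na(hiri) && is.na(reasons["hiri"]))
    reasons["hiri"] <- "missing early-phase AUC"

  misi <- NA_real_
  if (sum(ok) >= 2) {
    gp <- g[ok]; tp <- tt[ok]; ip <- ins[ok]
    ipk <- which.max(gp)
    if (ipk < length(gp)) {
      ind <- ipk - 1 + which.min(gp[ipk:length(gp)])
      slope <- if (ind > ipk) (gp[ipk] - gp[ind]) / (tp[ind] - tp[ipk]) else 0
      misi <- slope * MGDL_PER_MMOL / mean(ip)
    } else misi <- 0  # monotone rise: no post-peak decline
  } else reasons["misi"] <- "too few complete samples"

  di <- if (!is.na(igi) && !is.na(matsuda)) igi * matsuda else NA_real_
  if (is.na(di)) reasons["disposition_index"] <- "IGI or Matsuda unavailable"

  out <- tibble(matsuda = matsuda, homa_ir = homa_ir, homa_beta = homa_beta,
                misi = misi, hiri = hiri, auc30_glu = auc30_glu,
                auc30_ins = auc30_ins, insulinogenic_index = igi,
                disposition_index = di)
  attr(out, "reasons") <- reasons[!is.na(reasons)]
  out
}

#' Indicator table for a cohort of responses
#'
#' @param cohort A list of [subject_response()] or `synthetic_subject`
#'   objects (e.g. the `kept` element of [apply_exclusions()]).
#' @return A tibble with one row per response: `id` plus all indicator
#'   columns, `NA` where inputs are missing.
#' @export
cohort_indicators <- function(cohort) {
  purrr::map_dfr(cohort, function(x) {
    r <- if (inherits(x, "synthetic_subject")) x$response else x
    dplyr::bind_cols(tibble(id = r$id), compute_indicators(r))
  })
}
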