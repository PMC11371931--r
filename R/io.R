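# Plain-text interchange: per-response OGTT and CGM CSVs, a subject-context
# table, ground truth for synthetic cohorts, and per-response result records.

#' Write a cohort to CSV files
#'
#' Creates `ogtt/<id>.csv` (columns `time_min`, `plasma_glucose_mmol_per_L`,
#' `plasma_insulin_mU_per_L`), `cgm/<id>.csv` (`time_min`,
#' `interstitial_glucose_mmol_per_L`), `context.csv` (`subject_id`, `visit`,
#' `body_mass_kg`, `dose_g`) and, for synthetic cohorts, `truth.csv` with
#' the true parameter values for recovery scoring.
#'
#' @param cohort List of [subject_response()] or `synthetic_subject` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(file.path(dir, "ogtt"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cgm"), recursive = TRUE, showWarnings = FALSE)
  ctx_rows <- list(); truth_rows <- list()
  for (x in cohort) {
    r <- if (inherits(x, "synthetic_subject")) x$response else x
    readr::write_csv(
      tibble(time_min = r$ogtt$time,
             plasma_glucose_mmol_per_L = r$ogtt$glucose,
             plasma_insulin_mU_per_L = r$ogtt$insulin),
      file.path(dir, "ogtt", paste0(r$id, ".csv")))
    if (!is.null(r$cgm))
      readr::write_csv(
        tibble(time_min = r$cgm$time,
               interstitial_glucose_mmol_per_L = r$cgm$glucose),
        file.path(dir, "cgm", paste0(r$id, ".csv")))
    ctx_rows[[r$id]] <- tibble(subject_id = r$id, visit = 1L,
                               body_mass_kg = r$context$body_mass,
                               dose_g = r$context$glucose_dose)
    if (inherits(x, "synthetic_subject"))
      truth_rows[[r$id]] <- tibble(subject_id = r$id,
                                   k1 = x$truth[["k1"]], k5 = x$truth[["k5"]],
                                   k6 = x$truth[["k6"]],
                                   tau_g = x$truth[["tau_g"]])
  }
  readr::write_csv(dplyr::bind_rows(ctx_rows), file.path(dir, "context.csv"))
  if (length(truth_rows))
    readr::write_csv(dplyr::bind_rows(truth_rows), file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a cohort from CSV files written by [write_cohort_csv()]
#'
#' Baseline values are taken from the t = 0 rows of the data files.
#'
#' @param dir Directory containing `ogtt/`, optional `cgm/`, `context.csv`.
#' @return A list of [subject_response()] objects.
#' @export
read_cohort_csv <- function(dir) {
  ctx_tab <- readr::read_csv(file.path(dir, "context.csv"),
                             show_col_types = FALSE)
  purrr::map(seq_len(nrow(ctx_tab)), function(i) {
    id <- ctx_tab$subject_id[i]
    od <- readr::read_csv(file.path(dir, "ogtt", paste0(id, ".csv")),
                          show_col_types = FALSE)
    ogtt <- tibble(time = od$time_min,
                   glucose = od$plasma_glucose_mmol_per_L,
                   insulin = od$plasma_insulin_mU_per_L)
    cgm_path <- file.path(dir, "cgm", paste0(id, ".csv"))
    cgm <- NULL
    gi0 <- NA_real_
    if (file.exists(cgm_path)) {
      cd <- readr::read_csv(cgm_path, show_col_types = FALSE)
      cgm <- tibble(time = cd$time_min,
                    glucose = cd$interstitial_glucose_mmol_per_L)
      if (any(cgm$time == 0)) gi0 <- cgm$glucose[cgm$time == 0]
    }
    i0 <- which(ogtt$time == 0)
    ctx <- subject_context(
      body_mass = ctx_tab$body_mass_kg[i],
      basal_glucose = if (length(i0)) ogtt$glucose[i0] else NA_real_,
      basal_insulin = if (length(i0)) ogtt$insulin[i0] else NA_real_,
      glucose_dose = ctx_tab$dose_g[i],
      basal_interstitial = gi0)
    subject_response(id, ogtt, ctx, cgm)
  })
}

#' Persist per-response calibration results
#'
#' Writes one JSON record per response x mode plus a cohort-level CSV (one
#' row per response x mode) so every reported statistic can be recomputed
#' from the store.
#'
#' @param results A `cohort_results` table from [run_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(file.path(dir, "fits"), recursive = TRUE, showWarnings = FALSE)
  flat <- results[setdiff(names(results), c("fit", "identifiability"))]
  readr::write_csv(flat, file.path(dir, "results.csv"))
  for (i in seq_len(nrow(results))) {
    f <- results$fit[[i]]
    if (is.null(f)) next
    rec <- list(id = results$id[i], mode = results$mode[i],
                estimates = as.list(unlist(f$estimates)),
                objective = f$objective,
                mse = as.list(f$mse),
                boundary = as.list(f$boundary),
                n_converged = f$n_converged, seed = f$seed,
                residuals = f$residuals)
    idr <- results$identifiability[[i]]
    if (!is.null(idr))
      rec$identifiability <- list(parameters = as.data.frame(idr),
                                  identifiable = attr(idr, "identifiable"))
    jsonlite::write_json(
      rec, file.path(dir, "fits",
                     paste0(results$id[i], "_", results$mode[i], ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(dir)
}
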