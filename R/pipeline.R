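# Cohort-scale driver: calibrate every kept response under both glucose data
# sources, profile identifiability, and assemble the plasma-vs-CGM
# comparison report.

#' Spearman rank correlation with p-value
#'
#' Tie-corrected rank correlation; two-sided p-value (exact for small
#' tie-free samples, asymptotic otherwise).  A constant input vector yields
#' an undefined correlation, reported as `NA` rather than an error.
#'
#' @param x,y Paired numeric vectors, `n >= 3` after removing incomplete
#'   pairs.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) == 1 || length(unique(y)) == 1)
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' is the asymptotic two-sided one.
#'
#' @param a,b Non-empty numeric samples.
#' @return A one-row tibble: `D`, `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) >= 1, length(b) >= 1)
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble(D = unname(kt$statistic), p_value = kt$p.value,
         n_a = length(a), n_b = length(b))
}

#' Calibrate a cohort under one or both glucose data sources
#'
#' For each kept response and each requested mode this runs the full
#' per-response analysis -- calibration, fit metrics and (optionally) the
#' profile-likelihood identifiability report -- and collects everything in a
#' results table.  Individual failures are recorded as flagged rows, never
#' aborting the cohort.
#'
#' @param cohort List of [subject_response()] or `synthetic_subject` objects
#'   that already passed [apply_exclusions()].
#' @param modes Character subset of `c("plasma", "cgm")`.
#' @param configs Named list of [calibration_config()]s per mode; defaults
#'   are built per mode.
#' @param fixed [fixed_parameters()].
#' @param profile Also run profile-likelihood classification per fit
#'   (substantially more compute).
#' @return A tibble of class `cohort_results`, one row per response x mode:
#'   `id`, `mode`, estimate columns, `objective`, `mse_glucose`,
#'   `mse_insulin`, `boundary_k6`, `failed`, `identifiable` (`NA` when
#'   `profile = FALSE`) and list-columns `fit`, `identifiability`.
#' @export
run_cohort <- function(cohort, modes = c("plasma", "cgm"), configs = NULL,
                       fixed = fixed_parameters(), profile = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(configs))
    configs <- setNames(lapply(modes, calibration_config), modes)
  get_resp <- function(x) if (inherits(x, "synthetic_subject")) x$response else x
  rows <- list()
  for (subj in cohort) {
    r <- get_resp(subj)
    for (mode in modes) {
      row <- tryCatch({
        obs <- build_observations(r, mode)
        fit <- calibrate_response(obs, configs[[mode]], fixed)
        ident <- NA
        idr <- NULL
        if (profile && !fit$failed) {
          profs <- lapply(c("k1", "k5", "k6"), function(p)
            profile_parameter(fit, p))
          idr <- classify_identifiability(profs)
          ident <- attr(idr, "identifiable")
        }
        est <- unlist(fit$estimates)
        tibble(id = r$id, mode = mode,
               k1 = est[["k1"]], k5 = est[["k5"]], k6 = est[["k6"]],
               tau_g = if (mode == "cgm") est[["tau_g"]] else NA_real_,
               objective = fit$objective,
               mse_glucose = unname(fit$mse[["glucose"]]),
               mse_insulin = unname(fit$mse[["insulin"]]),
               boundary_k6 = unname(fit$boundary[["k6"]]),
               failed = fit$failed,
               identifiable = ident,
               fit = list(fit), identifiability = list(idr))
      }, error = function(e) {
        tibble(id = r$id, mode = mode, k1 = NA_real_, k5 = NA_real_,
               k6 = NA_real_, tau_g = NA_real_, objective = NA_real_,
               mse_glucose = NA_real_, mse_insulin = NA_real_,
               boundary_k6 = NA, failed = TRUE, identifiable = NA,
               fit = list(NULL), identifiability = list(NULL))
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cohort_results", class(out))
  out
}

#' Assemble the plasma-vs-CGM comparison report
#'
#' Summarizes per-mode MSE distributions (median, mean, count above the
#' reporting threshold), residuals per nominal time point, per-parameter
#' two-sample Kolmogorov-Smirnov tests and cross-mode Spearman correlations,
#' boundary-hit counts, unidentifiable-model counts per mode, and the
#' Spearman correlation table of parameter estimates against metabolic
#' indicators.  Responses whose secretion gain sits on the upper search bound
#' are excluded from the indicator-correlation and parameter-distribution
#' analyses (not from the MSE summaries), with significance flagged at raw
#' p < 0.05.
#'
#' @param results A `cohort_results` table from [run_cohort()] containing
#'   both modes.
#' @param indicators Optional tibble from [cohort_indicators()] (`id` plus
#'   indicator columns).
#' @param mse_threshold Reporting cutoff for the count of high-MSE models
#'   (default 1.5).
#' @return An object of class `comparison_report` (list of tibbles):
#'   `mse_summary`, `residual_summary`, `param_ks`, `param_spearman`,
#'   `boundary`, `identifiability`, `indicator_correlations`, `tau_g_summary`.
#' @export
build_report <- function(results, indicators = NULL, mse_threshold = 1.5) {
  stopifnot(inherits(results, "cohort_results"))
  ok <- results[!results$failed, ]

  mse_long <- tidyr::pivot_longer(
    ok[c("id", "mode", "mse_glucose", "mse_insulin")],
    dplyr::all_of(c("mse_glucose", "mse_insulin")),
    names_to = "observable", values_to = "mse", names_prefix = "mse_")
  mse_summary <- dplyr::summarise(
    dplyr::group_by(mse_long, .data$mode, .data$observable),
    n = dplyr::n(), median_mse = median(.data$mse),
    mean_mse = mean(.data$mse),
    n_above_threshold = sum(.data$mse > mse_threshold), .groups = "drop")

  residual_summary <- purrr::map_dfr(seq_len(nrow(ok)), function(i) {
    f <- ok$fit[[i]]
    dplyr::mutate(f$residuals, id = ok$id[i], mode = ok$mode[i])
  }) |>
    dplyr::group_by(.data$mode, .data$metabolite, .data$time) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_residual = mean(.data$residual),
                     sd_residual = stats::sd(.data$residual),
                     .groups = "drop")

  # boundary-hit exclusion list: responses with k6 on its upper bound in
  # either mode (paired exclusion, as the estimates are compared pairwise)
  excluded_ids <- unique(ok$id[ok$boundary_k6 %in% TRUE])
  kept <- ok[!(ok$id %in% excluded_ids), ]

  wide <- function(tab, col) {
    tidyr::pivot_wider(tab[c("id", "mode", col)], names_from = "mode",
                       values_from = dplyr::all_of(col))
  }
  both <- intersect(unique(ok$id[ok$mode == "plasma"]),
                    unique(ok$id[ok$mode == "cgm"]))

  param_stats <- function(tab) {
    purrr::map_dfr(c("k1", "k5", "k6"), function(p) {
      w <- wide(tab[tab$id %in% both, ], p)
      if (!all(c("plasma", "cgm") %in% names(w)))
        return(tibble(parameter = p, rho = NA_real_, rho_p = NA_real_,
                      D = NA_real_, D_p = NA_real_, n = 0L))
      sp <- spearman_test(w$plasma, w$cgm)
      ks <- ks_compare(w$plasma, w$cgm)
      tibble(parameter = p, rho = sp$rho, rho_p = sp$p_value,
             D = ks$D, D_p = ks$p_value, n = sp$n)
    })
  }
  cross_all <- param_stats(ok)
  cross_kept <- param_stats(kept)
  param_spearman <- dplyr::bind_rows(
    dplyr::mutate(cross_all[c("parameter", "rho", "rho_p", "n")],
                  boundary_excluded = FALSE),
    dplyr::mutate(cross_kept[c("parameter", "rho", "rho_p", "n")],
                  boundary_excluded = TRUE))
  param_ks <- dplyr::bind_rows(
    dplyr::mutate(cross_all[c("parameter", "D", "D_p", "n")],
                  boundary_excluded = FALSE),
    dplyr::mutate(cross_kept[c("parameter", "D", "D_p", "n")],
                  boundary_excluded = TRUE))

  boundary <- dplyr::summarise(
    dplyr::group_by(ok, .data$mode),
    n = dplyr::n(), n_boundary_k6 = sum(.data$boundary_k6 %in% TRUE),
    .groups = "drop")

  identifiability <- dplyr::summarise(
    dplyr::group_by(ok, .data$mode),
    n_profiled = sum(!is.na(.data$identifiable)),
    n_unidentifiable = sum(.data$identifiable %in% FALSE),
    .groups = "drop")

  indicator_correlations <- NULL
  if (!is.null(indicators)) {
    ind_cols <- setdiff(names(indicators), "id")
    indicator_correlations <- purrr::map_dfr(
      unique(kept$mode), function(m) {
        sub <- dplyr::inner_join(kept[kept$mode == m, ], indicators,
                                 by = "id")
        purrr::map_dfr(c("k1", "k5", "k6"), function(p) {
          purrr::map_dfr(ind_cols, function(ic) {
            st <- spearman_test(sub[[p]], sub[[ic]])
            tibble(mode = m, parameter = p, indicator = ic,
                   rho = st$rho, p_value = st$p_value, n = st$n,
                   significant = !is.na(st$p_value) & st$p_value < 0.05)
          })
        })
      })
  }

  tau <- ok$tau_g[ok$mode == "cgm"]
  tau_g_summary <- tibble(median = median(tau, na.rm = TRUE),
                          q25 = quantile(tau, 0.25, na.rm = TRUE),
                          q75 = quantile(tau, 0.75, na.rm = TRUE))

  structure(list(mse_summary = mse_summary,
                 residual_summary = residual_summary,
                 param_spearman = param_spearman,
                 param_ks = param_ks,
                 boundary = boundary,
                 boundary_excluded_ids = excluded_ids,
                 identifiability = identifiability,
                 indicator_correlations = indicator_correlations,
                 tau_g_summary = tau_g_summary,
                 mse_threshold = mse_threshold),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n\nMSE by mode and observable:\n")
  print(x$mse_summary)
  cat("\nCross-mode parameter agreement (Spearman):\n")
  print(x$param_spearman)
  cat("\nBoundary hits:\n"); print(x$boundary)
  if (any(x$identifiability$n_profiled > 0)) {
    cat("\nUnidentifiable models:\n"); print(x$identifiability)
  }
  invisible(x)
}
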