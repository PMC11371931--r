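# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' Tidy a calibrated model
#'
#' @param x An `edes_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`,
#'   `estimate`, `lower`, `upper` (search bounds) and `boundary`.
#' @export
tidy.edes_fit <- function(x, ...) {
  rng <- x$config$ranges
  tibble(term = rng$parameter,
         estimate = unname(x$theta[rng$parameter]),
         lower = rng$lower, upper = rng$upper,
         boundary = unname(x$boundary[rng$parameter]))
}

#' One-row summary of a calibrated model
#'
#' @param x An `edes_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `objective`, `mse_glucose`,
#'   `mse_insulin`, `n_obs`, `n_converged`, `failed`.
#' @export
glance.edes_fit <- function(x, ...) {
  tibble(mode = x$mode, objective = x$objective,
         mse_glucose = unname(x$mse[["glucose"]]),
         mse_insulin = if ("insulin" %in% names(x$mse))
           unname(x$mse[["insulin"]]) else NA_real_,
         n_obs = nrow(x$obs$points),
         n_converged = x$n_converged, failed = x$failed)
}

#' Tidy a profile curve
#'
#' @param x A `profile_curve`.
#' @param ... Unused.
#' @return The scan curve as a tibble with `parameter`, `value`, `objective`.
#' @export
tidy.profile_curve <- function(x, ...) {
  dplyr::mutate(x$curve, parameter = x$parameter, .before = 1)
}

#' One-row summary of a profile curve
#'
#' @param x A `profile_curve`.
#' @param ... Unused.
#' @return Tibble: `parameter`, `estimate`, `lower`, `upper`,
#'   `lower_bounded`, `upper_bounded`, `identifiable`, `alpha`.
#' @export
glance.profile_curve <- function(x, ...) {
  tibble(parameter = x$parameter, estimate = x$optimum,
         lower = x$lower, upper = x$upper,
         lower_bounded = x$lower_bounded, upper_bounded = x$upper_bounded,
         identifiable = x$lower_bounded && x$upper_bounded, alpha = x$alpha)
}

#' Plot a simulated trajectory
#'
#' @param object An `edes_trajectory` from [simulate_response()].
#' @param ... Unused.
#' @return A ggplot object faceted by observable.
#' @export
autoplot.edes_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("time", "plasma_glucose", "plasma_insulin",
                        "interstitial_glucose")],
    -"time", names_to = "observable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL)
}

#' Plot a calibrated model against its data
#'
#' @param object An `edes_fit`.
#' @param ... Unused.
#' @return A ggplot object: simulation lines with measured points.
#' @export
autoplot.edes_fit <- function(object, ...) {
  t_grid <- seq(0, max(object$obs$points$time), by = 2)
  traj <- simulate_response(object$estimates, object$fixed, object$ctx,
                            t_grid)
  gcol <- if (object$mode == "cgm") "interstitial_glucose" else "plasma_glucose"
  sim <- dplyr::bind_rows(
    tibble(time = traj$time, value = traj[[gcol]], metabolite = "glucose"),
    tibble(time = traj$time, value = traj$plasma_insulin,
           metabolite = "insulin"))
  ggplot2::ggplot(sim, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$obs$points,
                        ggplot2::aes(.data$time, .data$value)) +
    ggplot2::facet_wrap(~metabolite, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = paste("calibration on", object$mode, "glucose"))
}

#' Plot a profile-likelihood curve
#'
#' @param object A `profile_curve`.
#' @param ... Unused.
#' @return A ggplot object with the confidence threshold marked.
#' @export
autoplot.profile_curve <- function(object, ...) {
  thr <- object$optimum_objective + (object$delta %||% pl_delta(object$alpha))
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$value, .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$optimum, linetype = 3) +
    ggplot2::labs(x = object$parameter, y = "profile objective")
}

#' Plot an observable confidence band
#'
#' @param object A `confidence_band`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confidence_band <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = attr(object, "observable"))
}
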