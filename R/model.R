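# Core ODE model: basal initialization, meal input, right-hand side,
# and simulation through deSolve's compiled-code interface.

# order must match src/edes.c
edes_parms <- function(est, fixed, ctx) {
  c(fixed$sigma, fixed$k2, fixed$k3, fixed$k4, fixed$k7, fixed$k8, fixed$k9,
    fixed$p_rem, fixed$tau_i, fixed$tau_d, fixed$k_ren, fixed$G_thr,
    fixed$K_M, fixed$V_G, fixed$f_bio, fixed$beta, fixed$egp_b,
    fixed$f_conv,
    est$k1, est$k5, est$k6, est$tau_g,
    ctx$basal_glucose, ctx$basal_insulin, ctx$body_mass, ctx$glucose_dose,
    fixed$sec_smooth)
}

state_names <- c("gut_glucose", "plasma_glucose", "secretion_integral",
                 "plasma_insulin", "remote_insulin", "interstitial_glucose")

#' Basal steady-state initial condition
#'
#' Returns the equilibrium state of the model with zero meal input: empty gut,
#' plasma glucose and insulin at their basal values, remote insulin at its
#' basal balance (equal to basal plasma insulin), and interstitial glucose at
#' its basal value (falling back to basal plasma glucose when no CGM baseline
#' exists).  Steady-state closure constants -- the insulin-independent uptake
#' scale and basal endogenous glucose production -- are fixed algebraically so
#' that all fluxes balance exactly at this state; they are recomputed
#' identically inside the right-hand side.
#'
#' @param ctx A [subject_context()].
#' @param est An [estimable_parameters()].
#' @param fixed A [fixed_parameters()].
#' @return Named numeric state vector (gut glucose mass in mg, concentrations
#'   in mmol/L or mU/L, secretion integral in mmol.min/L).
#' @examples
#' basal_state(subject_context(85, 5.0, 10),
#'             estimable_parameters(0.018, 0.006, 1.2, 2.5),
#'             fixed_parameters())
#' @export
basal_state <- function(ctx, est, fixed) {
  stopifnot(inherits(ctx, "subject_context"),
            inherits(est, "estimable_parameters"),
            inherits(fixed, "fixed_parameters"))
  gi0 <- if (is.na(ctx$basal_interstitial)) ctx$basal_glucose
         else ctx$basal_interstitial
  setNames(c(0, ctx$basal_glucose, 0, ctx$basal_insulin, ctx$basal_insulin,
             gi0),
           state_names)
}

#' Meal glucose flux into the gut
#'
#' Rate of appearance of the ingested glucose dose in the gut compartment
#' (mg/min), a Weibull-shaped pulse whose time scale is set by `k1` and whose
#' time integral equals the bioavailable dose.  The flux delivered onward to
#' plasma is the gut-to-plasma transfer `k2 * gut_glucose`; because the gut
#' empties completely, its integral also equals the bioavailable dose.
#'
#' @inheritParams basal_state
#' @param t Time since dose ingestion (min), non-negative (vectorized).
#' @return Numeric vector of mass flux values (mg/min).
#' @examples
#' meal_input_rate(c(0, 15, 30), subject_context(85, 5, 10),
#'                 estimable_parameters(0.018, 0.006, 1.2), fixed_parameters())
#' @export
meal_input_rate <- function(t, ctx, est, fixed) {
  if (any(t < 0)) abort("t must be non-negative", class = "glucodyn_domain")
  d_mg <- ctx$glucose_dose * 1000 * fixed$f_bio
  if (d_mg == 0) return(rep(0, length(t)))
  u <- est$k1 * t
  ifelse(t > 0,
         d_mg * fixed$sigma * est$k1 * u^(fixed$sigma - 1) * exp(-u^fixed$sigma),
         0)
}

#' Model right-hand side (reference implementation)
#'
#' Evaluates the time derivative of the full state: plasma glucose balances
#' hepatic production (suppressed by glucose and remote-insulin elevation),
#' gut appearance, Michaelis-Menten insulin-independent uptake,
#' insulin-dependent uptake scaled by `k5` and remote-insulin elevation, and renal
#' excretion above the threshold; plasma insulin balances pancreatic secretion
#' (proportional gain `k6` on glucose elevation plus integral and derivative
#' terms, passed through a smoothed non-negativity clamp that is exactly zero
#' at basal) against clearance; remote insulin exchanges with plasma
#' first-order; interstitial glucose follows
#' `dGi/dt = (G_pl - Gi) / tau_g`, with `tau_g = 0` handled as the algebraic
#' limit in which interstitial glucose tracks plasma glucose exactly.
#'
#' This pure-R evaluation mirrors the compiled routine used by
#' [simulate_response()]; the two are asserted equal in the test suite.
#'
#' @inheritParams basal_state
#' @param t Time (min).
#' @param state Named state vector as returned by [basal_state()].
#' @return Named numeric vector of derivatives.
#' @export
edes_derivatives <- function(t, state, est, fixed, ctx) {
  if (!all(is.finite(state))) abort("state must be finite")
  M <- state[[1]]; G <- state[[2]]; Z <- state[[3]]
  I <- state[[4]]; R <- state[[5]]; Gi <- state[[6]]
  Gb <- ctx$basal_glucose; Ib <- ctx$basal_insulin
  m_meal <- meal_input_rate(t, ctx, est, fixed)
  c_non <- fixed$egp_b * (fixed$K_M + Gb) / Gb
  g_liv <- fixed$egp_b - fixed$k3 * (G - Gb) -
    fixed$k4 * est$k5 * fixed$beta * (R - Ib)
  g_gut <- fixed$f_conv / (fixed$V_G * ctx$body_mass) * fixed$k2 * M
  g_non <- c_non * G / (fixed$K_M + G)
  g_it  <- est$k5 * fixed$beta * (R - Ib) * G / (fixed$K_M + G)
  g_ren <- if (G > fixed$G_thr) fixed$k_ren * (G - fixed$G_thr) else 0
  dG <- g_liv + g_gut - g_non - g_it - g_ren
  s_lin <- est$k6 * (G - Gb) + (fixed$k7 / fixed$tau_i) * Z +
    fixed$k8 * fixed$tau_d * dG
  sec <- 0.5 * (s_lin + sqrt(s_lin^2 + fixed$sec_smooth^2)) -
    fixed$sec_smooth / 2
  dI <- sec / fixed$beta - fixed$k9 * (I - Ib)
  dR <- fixed$p_rem * (I - R)
  dGi <- if (est$tau_g > 1e-9) (G - Gi) / est$tau_g else dG
  setNames(c(m_meal - fixed$k2 * M, dG, G - Gb, dI, dR, dGi), state_names)
}

#' Simulate a glucose-insulin response
#'
#' Integrates the model from its basal steady state with an adaptive
#' stiff-capable solver (lsoda, compiled right-hand side) and samples the
#' observables on the requested grid.  Deterministic given identical inputs
#' and tolerances.
#'
#' @inheritParams basal_state
#' @param t_eval Strictly increasing time grid (min) starting at 0.
#' @param rtol,atol Solver tolerances.
#' @param full_state Keep all six state series instead of the three
#'   observables only.
#' @return A tibble of class `edes_trajectory` with columns `time`,
#'   `plasma_glucose`, `plasma_insulin`, `interstitial_glucose` (plus the
#'   remaining states when `full_state = TRUE`).  Attribute `negative` flags
#'   trajectories that left the non-negative orthant.
#' @examples
#' simulate_response(estimable_parameters(0.018, 0.006, 1.2, 2.5),
#'                   fixed_parameters(),
#'                   subject_context(85, 5.3, 12),
#'                   t_eval = seq(0, 120, 5))
#' @export
simulate_response <- function(est, fixed, ctx, t_eval,
                              rtol = 1e-7, atol = 1e-9, full_state = FALSE) {
  if (length(t_eval) < 2 || t_eval[1] != 0 || any(diff(t_eval) <= 0))
    abort("t_eval must be strictly increasing and start at 0")
  y0 <- basal_state(ctx, est, fixed)
  parms <- edes_parms(est, fixed, ctx)
  out <- tryCatch(
    deSolve::lsoda(y = y0, times = t_eval, func = "edes_derivs",
                   parms = parms, dllname = "glucodyn",
                   initfunc = "edes_init", rtol = rtol, atol = atol),
    error = function(e) e, warning = function(w) w)
  failed <- inherits(out, "condition") || nrow(out) < length(t_eval) ||
    any(!is.finite(out))
  if (failed) {
    abort("ODE integration failed", class = "glucodyn_simulation_error",
          parameters = unlist(est))
  }
  df <- as.data.frame(out)
  names(df) <- c("time", state_names)
  neg <- min(df$plasma_glucose, df$plasma_insulin, df$interstitial_glucose,
             df$gut_glucose, df$remote_insulin) < -1e-8
  keep <- if (full_state) c("time", state_names)
          else c("time", "plasma_glucose", "plasma_insulin",
                 "interstitial_glucose")
  traj <- as_tibble(df[keep])
  attr(traj, "negative") <- neg
  class(traj) <- c("edes_trajectory", class(traj))
  traj
}
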