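#' Fixed model parameters and physical constants
#'
#' The non-estimated parameters of the glucose-insulin model, held at
#' population values during calibration.  Rate constants govern suppression of
#' endogenous glucose production (`k3` by glucose elevation; `k4`, the
#' dimensionless hepatic-to-peripheral ratio of insulin action, by remote
#' insulin elevation jointly with the subject's insulin sensitivity `k5`),
#' integral (`k7`) and derivative (`k8`) components of
#' pancreatic insulin secretion, insulin clearance (`k9`), plasma-to-remote
#' insulin exchange (`p_rem`) and gut-to-plasma glucose transfer (`k2`).
#' Physical constants carry explicit units: glucose distribution volume
#' fraction `V_G` (L/kg), bioavailability fraction `f_bio` (dimensionless),
#' Michaelis constant `K_M` (mmol/L), renal spill threshold `G_thr` (mmol/L),
#' secretion time constants `tau_i`, `tau_d` (min), the insulin/glucose
#' unit-conversion factor `beta` ((mU/L)/(mmol/L)), basal endogenous glucose
#' production `egp_b` (mmol/L/min), the mg-to-mmol conversion
#' `f_conv` (1/180.16), and the Weibull shape `sigma` of gut appearance.
#'
#' @param ... Named overrides of the default values.
#'
#' @return An object of class `fixed_parameters` (named list).
#' @examples
#' fixed_parameters()
#' fixed_parameters(G_thr = 10)
#' @export
fixed_parameters <- function(...) {
  defaults <- list(
    sigma = 1.4,        # Weibull shape, gut appearance (-)
    k2 = 0.18,          # gut -> plasma transfer (1/min)
    k3 = 0.005,         # EGP suppression by glucose elevation (1/min)
    k4 = 0.3,           # hepatic/peripheral insulin action ratio (-)
    k7 = 0.01,          # integral secretion gain (1/min)
    k8 = 0.1,           # derivative secretion gain (-)
    k9 = 0.1,           # insulin clearance rate (1/min)
    p_rem = 0.04,       # plasma -> remote insulin exchange (1/min)
    tau_i = 30,         # integral secretion time constant (min)
    tau_d = 10,         # derivative secretion time constant (min)
    k_ren = 0.05,       # renal clearance above threshold (1/min)
    G_thr = 9.0,        # renal glucose threshold (mmol/L)
    K_M = 6.0,          # Michaelis constant, glucose uptake (mmol/L)
    V_G = 0.2,          # glucose distribution volume (L/kg)
    f_bio = 0.9,        # oral glucose bioavailability (-)
    beta = 1.0,         # insulin/glucose unit conversion ((mU/L)/(mmol/L))
    egp_b = 0.043,      # basal endogenous glucose production (mmol/L/min)
    f_conv = 1 / 180.16,# mg glucose -> mmol (mmol/mg)
    sec_smooth = 0.2    # secretion clamp smoothing width (mU/L/min)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) abort(paste0("unknown fixed parameter(s): ",
                                  paste(bad, collapse = ", ")))
    defaults[names(over)] <- over
  }
  validate_fixed(defaults)
  structure(defaults, class = "fixed_parameters")
}

validate_fixed <- function(p) {
  pos <- c("sigma", "k2", "k9", "p_rem", "tau_i", "tau_d", "K_M", "V_G",
           "f_bio", "beta", "egp_b", "f_conv", "G_thr", "sec_smooth")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      abort(paste0("fixed parameter '", nm, "' must be a positive scalar"))
  }
  nonneg <- c("k3", "k4", "k7", "k8", "k_ren")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      abort(paste0("fixed parameter '", nm, "' must be a non-negative scalar"))
  }
  if (p$G_thr < 7)
    abort("renal threshold G_thr must be at least 7 mmol/L")
  invisible(p)
}

#' Write or read fixed parameters as a YAML config
#'
#' The file is a flat key-value mapping with a unit comment per entry, so
#' population values can be versioned and exchanged outside R.
#'
#' @param params A `fixed_parameters` object.
#' @param path File path.
#' @return `write_fixed_parameters()` returns `path` invisibly;
#'   `read_fixed_parameters()` returns a `fixed_parameters` object.
#' @export
write_fixed_parameters <- function(params, path) {
  stopifnot(inherits(params, "fixed_parameters"))
  units <- c(sigma = "-", k2 = "1/min", k3 = "1/min",
             k4 = "-", k7 = "1/min", k8 = "-", k9 = "1/min",
             p_rem = "1/min", tau_i = "min", tau_d = "min", k_ren = "1/min",
             G_thr = "mmol/L", K_M = "mmol/L", V_G = "L/kg", f_bio = "-",
             beta = "(mU/L)/(mmol/L)", egp_b = "mmol/L/min",
             f_conv = "mmol/mg", sec_smooth = "mU/L/min")
  lines <- vapply(names(params), function(nm) {
    sprintf("%s: %.12g  # %s", nm, params[[nm]], units[[nm]])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fixed_parameters
#' @export
read_fixed_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(fixed_parameters, vals)
}

#' Estimable (per-subject) model parameters
#'
#' The quantities calibration recovers for each response: `k1`, the rate of
#' glucose appearance in the gut (1/min); `k5`, the rate of insulin-dependent
#' glucose uptake to peripheral tissues (1/min per mU/L-equivalent); `k6`, the
#' dimensionless gain of glucose-dependent insulin secretion; and `tau_g`,
#' the plasma-to-interstitium equilibration time constant (min), meaningful
#' only when interstitial (CGM) glucose is modeled.
#'
#' @param k1,k5,k6 Non-negative scalars.
#' @param tau_g Non-negative scalar (min); `0` degenerates the interstitial
#'   compartment to track plasma glucose exactly.
#' @return An object of class `estimable_parameters`.
#' @examples
#' estimable_parameters(k1 = 0.018, k5 = 0.006, k6 = 1.2, tau_g = 2.5)
#' @export
estimable_parameters <- function(k1, k5, k6, tau_g = 0) {
  vals <- c(k1 = k1, k5 = k5, k6 = k6, tau_g = tau_g)
  if (!all(is.finite(vals)) || any(vals < 0))
    abort("estimable parameters must be finite and non-negative")
  structure(as.list(vals), class = "estimable_parameters")
}

#' Subject context: inputs the model takes as given
#'
#' Baseline values are model inputs, not fitted data: the t = 0 sample of each
#' calibrated channel initializes the corresponding state.
#'
#' @param body_mass Body mass (kg), positive.
#' @param basal_glucose Fasting plasma glucose (mmol/L), positive.
#' @param basal_insulin Fasting plasma insulin (mU/L), positive.
#' @param glucose_dose Oral glucose dose (g), non-negative; 75 for the
#'   standard OGTT.
#' @param basal_interstitial Fasting interstitial glucose (mmol/L); `NA` when
#'   no CGM trace exists, in which case the interstitial state is initialized
#'   at `basal_glucose`.
#' @return An object of class `subject_context`.
#' @examples
#' subject_context(body_mass = 85, basal_glucose = 5.3, basal_insulin = 12)
#' @export
subject_context <- function(body_mass, basal_glucose, basal_insulin,
                            glucose_dose = 75, basal_interstitial = NA_real_) {
  if (!is.numeric(body_mass) || body_mass <= 0)
    abort("body_mass must be positive", class = "glucodyn_invalid_context")
  if (!is.numeric(glucose_dose) || glucose_dose < 0)
    abort("glucose_dose must be non-negative",
          class = "glucodyn_invalid_context")
  for (v in c(basal_glucose, basal_insulin))
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      abort("basal concentrations must be strictly positive",
            class = "glucodyn_invalid_context")
  if (!is.na(basal_interstitial) && basal_interstitial <= 0)
    abort("basal_interstitial must be strictly positive when given",
          class = "glucodyn_invalid_context")
  structure(list(body_mass = body_mass,
                 glucose_dose = glucose_dose,
                 basal_glucose = basal_glucose,
                 basal_insulin = basal_insulin,
                 basal_interstitial = basal_interstitial),
            class = "subject_context")
}

#' Default parameter search ranges
#'
#' Wide positive boxes covering physiological values; the upper bound of the
#' secretion gain `k6` is 10.0.  In plasma mode `tau_g` is excluded from the
#' decision vector entirely.
#'
#' @param mode `"plasma"` or `"cgm"`.
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
default_search_ranges <- function(mode = c("plasma", "cgm")) {
  mode <- match.arg(mode)
  rng <- tibble(
    parameter = c("k1", "k5", "k6", "tau_g"),
    lower = c(1e-3, 2e-4, 0, 0),
    upper = c(0.1, 0.1, 10, 30)
  )
  if (mode == "plasma") rng <- rng[rng$parameter != "tau_g", ]
  rng
}
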