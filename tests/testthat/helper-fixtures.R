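# Shared fixtures.  Heavy objects (the n = 20 dual-mode calibration run and
# the profile-likelihood set) are computed lazily once per test session and
# memoized, since several files assert different properties of the same run.

fx_default <- fixed_parameters()

make_ctx <- function(...) {
  args <- utils::modifyList(
    list(body_mass = 85, basal_glucose = 5.3, basal_insulin = 12,
         glucose_dose = 75), list(...))
  do.call(subject_context, args)
}

make_est <- function(k1 = 0.018, k5 = 0.006, k6 = 1.2, tau_g = 2.5) {
  estimable_parameters(k1, k5, k6, tau_g)
}

# deterministic 7-point toy OGTT used by the indicator tests; values chosen
# so every index has simple closed-form arithmetic
toy_ogtt <- function() {
  tibble::tibble(
    time = c(0, 15, 30, 45, 60, 90, 120),
    glucose = c(5.0, 7.0, 9.0, 8.5, 8.0, 6.5, 5.5),
    insulin = c(9.0, 40.0, 70.0, 65.0, 60.0, 35.0, 20.0))
}

# all permutations of 1..n as a matrix (n! rows), for exact-null oracles
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# one default-spec synthetic subject used across calibration and
# identifiability tests
fixture_subject <- function() {
  memo("subject21", sample_cohort(cohort_spec(1, seed = 21))[[1]])
}

fixture_fit_plasma <- function() {
  memo("fit21_plasma", {
    obs <- build_observations(fixture_subject()$response, "plasma")
    calibrate_response(obs, calibration_config("plasma"), fx_default)
  })
}

fixture_fit_cgm <- function() {
  memo("fit21_cgm", {
    obs <- build_observations(fixture_subject()$response, "cgm")
    calibrate_response(obs, calibration_config("cgm"), fx_default)
  })
}

fixture_profiles_plasma <- function() {
  memo("prof21_plasma", lapply(c("k1", "k5", "k6"), function(p)
    profile_parameter(fixture_fit_plasma(), p)))
}

# glucose-only (insulin channel removed) fit and its secretion-gain profile
fixture_fit_noins <- function() {
  memo("fit21_noins", {
    obs <- drop_metabolite(build_observations(fixture_subject()$response,
                                              "plasma"), "insulin")
    calibrate_response(obs, calibration_config("plasma"), fx_default)
  })
}

fixture_profile_noins_k6 <- function() {
  memo("prof21_noins_k6", profile_parameter(fixture_fit_noins(), "k6"))
}

# the n = 40 noisy cohort calibrated in both modes, with ground truth; its
# first 20 subjects are exactly the n = 20 cohort of the same seed (draws
# are sequential), which the recovery assertions subset
fixture_cohort_run <- function() {
  memo("cohort40", {
    cohort <- sample_cohort(cohort_spec(40, seed = 101))
    kept <- apply_exclusions(cohort)$kept
    results <- run_cohort(kept, modes = c("plasma", "cgm"),
                          fixed = fx_default)
    truth <- purrr::map_dfr(kept, function(s)
      tibble::tibble(id = s$id, k1_true = s$truth[["k1"]],
                     k5_true = s$truth[["k5"]], k6_true = s$truth[["k6"]],
                     tau_g_true = s$truth[["tau_g"]]))
    list(cohort = kept, results = results, truth = truth,
         first20 = sprintf("S%03d", 1:20))
  })
}

# noise-free subjects for exact parameter recovery
fixture_noisefree_fits <- function() {
  memo("noisefree", {
    spec <- cohort_spec(2, seed = 11, noise = noise_model(0, 0, 0, 0, 0))
    cohort <- sample_cohort(spec)
    purrr::map(cohort, function(s) {
      fits <- purrr::map(c(plasma = "plasma", cgm = "cgm"), function(m) {
        obs <- build_observations(s$response, m)
        calibrate_response(obs, calibration_config(m), fx_default)
      })
      list(truth = s$truth, fits = fits)
    })
  })
}
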