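# Core ODE model: equilibrium, mass conservation, interstitial lag, and
# agreement between the compiled and reference right-hand sides.

test_that("compiled and reference right-hand sides agree", {
  set.seed(42)
  ctx <- make_ctx()
  for (i in 1:20) {
    est <- estimable_parameters(runif(1, 0.005, 0.05), runif(1, 1e-3, 0.05),
                                runif(1, 0.1, 8), runif(1, 0, 15))
    state <- basal_state(ctx, est, fx_default) +
      c(runif(1, 0, 5e4), runif(1, -1, 6), runif(1, 0, 300),
        runif(1, -2, 80), runif(1, -2, 60), runif(1, -1, 6))
    t <- runif(1, 0, 200)
    d_r <- edes_derivatives(t, state, est, fx_default, ctx)
    # compiled side evaluated through a one-step forward difference of lsoda
    # would be indirect; instead call the C routine via a tiny integration
    h <- 1e-6
    tr <- deSolve::lsoda(y = state, times = c(t, t + h),
                         func = "edes_derivs",
                         parms = glucodyn:::edes_parms(est, fx_default, ctx),
                         dllname = "glucodyn", initfunc = "edes_init",
                         rtol = 1e-12, atol = 1e-12)
    d_c <- (tr[2, -1] - tr[1, -1]) / h
    expect_equal(unname(d_c), unname(d_r), tolerance = 1e-4)
  }
})

test_that("basal state is an exact equilibrium with zero meal input", {
  ctx <- make_ctx(basal_glucose = 5.0, basal_insulin = 10, glucose_dose = 0)
  est <- make_est()
  s0 <- basal_state(ctx, est, fx_default)
  d <- edes_derivatives(0, s0, est, fx_default, ctx)
  expect_true(all(abs(d) < 1e-10))
  tr <- simulate_response(est, fx_default, ctx, seq(0, 300, 5))
  expect_lt(max(abs(tr$plasma_glucose - 5.0)), 1e-6)
  expect_lt(max(abs(tr$plasma_insulin - 10)), 1e-6)
  expect_lt(max(abs(tr$interstitial_glucose - 5.0)), 1e-6)
})

test_that("missing CGM baseline falls back to basal plasma glucose", {
  ctx <- make_ctx(basal_glucose = 5.0, basal_interstitial = NA_real_)
  s0 <- basal_state(ctx, make_est(), fx_default)
  expect_identical(unname(s0[["interstitial_glucose"]]), 5.0)
})

test_that("invalid contexts are rejected", {
  expect_error(subject_context(85, -1, 10), class = "glucodyn_invalid_context")
  expect_error(subject_context(85, 5, 0), class = "glucodyn_invalid_context")
  expect_error(subject_context(0, 5, 10), class = "glucodyn_invalid_context")
  expect_error(meal_input_rate(-1, make_ctx(), make_est(), fx_default),
               class = "glucodyn_domain")
})

test_that("gut delivers the bioavailable dose to plasma", {
  ctx <- make_ctx()
  est <- make_est()
  expect_identical(
    meal_input_rate(c(0, 10, 50), make_ctx(glucose_dose = 0), est, fx_default),
    c(0, 0, 0))
  # quadrature of the gut-to-plasma flux k2 * M(t)
  t <- seq(0, 2000, by = 0.5)
  tr <- simulate_response(est, fx_default, ctx, t, full_state = TRUE)
  flux <- fx_default$k2 * tr$gut_glucose
  delivered <- sum(diff(t) * (head(flux, -1) + tail(flux, -1)) / 2)
  bioavailable <- ctx$glucose_dose * 1000 * fx_default$f_bio
  expect_lt(abs(delivered - bioavailable) / bioavailable, 0.01)
  # and the meal input itself integrates to the same mass
  rate <- meal_input_rate(t, ctx, est, fx_default)
  ingested <- sum(diff(t) * (head(rate, -1) + tail(rate, -1)) / 2)
  expect_lt(abs(ingested - bioavailable) / bioavailable, 0.01)
})

test_that("doubling k1 moves the appearance peak earlier", {
  ctx <- make_ctx()
  t <- seq(0, 300, 0.5)
  r1 <- meal_input_rate(t, ctx, make_est(k1 = 0.015), fx_default)
  r2 <- meal_input_rate(t, ctx, make_est(k1 = 0.030), fx_default)
  expect_lt(t[which.max(r2)], t[which.max(r1)])
})

test_that("interstitial lag follows dGi/dt = (G - Gi)/tau exactly", {
  ctx <- make_ctx()
  est <- make_est(tau_g = 2)
  state <- basal_state(ctx, est, fx_default)
  state[["plasma_glucose"]] <- 7
  state[["interstitial_glucose"]] <- 5
  d <- edes_derivatives(0, state, est, fx_default, ctx)
  expect_equal(unname(d[["interstitial_glucose"]]), 1.0, tolerance = 1e-12)
})

test_that("renal excretion is exactly zero below the threshold", {
  ctx <- make_ctx()
  est <- make_est()
  state <- basal_state(ctx, est, fx_default)
  state[["plasma_glucose"]] <- fx_default$G_thr - 0.1
  d_below <- edes_derivatives(10, state, est, fx_default, ctx)
  d_noren <- edes_derivatives(10, state, est,
                              fixed_parameters(k_ren = 0), ctx)
  expect_identical(d_below[["plasma_glucose"]], d_noren[["plasma_glucose"]])
  state[["plasma_glucose"]] <- fx_default$G_thr + 1
  d_above <- edes_derivatives(10, state, est, fx_default, ctx)
  d_above0 <- edes_derivatives(10, state, est,
                               fixed_parameters(k_ren = 0), ctx)
  expect_equal(unname(d_above0[["plasma_glucose"]] -
                        d_above[["plasma_glucose"]]),
               fx_default$k_ren * 1, tolerance = 1e-12)
})

test_that("simulated interstitial glucose is the first-order lag of plasma", {
  ctx <- make_ctx()
  est <- make_est(tau_g = 6)
  t <- seq(0, 180, 0.5)
  tr <- simulate_response(est, fx_default, ctx, t, rtol = 1e-9, atol = 1e-11)
  gi <- glucodyn:::lag_filter(t, tr$plasma_glucose, 6, ctx$basal_glucose)
  expect_lt(max(abs(gi - tr$interstitial_glucose)), 5e-3)
})

test_that("ramp input to the lag equation matches the closed form", {
  # G(t) = Gb + m t  =>  Gi(t) = Gb + m (t - tau (1 - exp(-t / tau)))
  t <- seq(0, 120, 0.5)
  m <- 0.05; Gb <- 5; tau <- 4
  gi <- glucodyn:::lag_filter(t, Gb + m * t, tau, Gb)
  analytic <- Gb + m * (t - tau * (1 - exp(-t / tau)))
  expect_lt(max(abs(gi - analytic)), 1e-6)
})

test_that("tau_g -> 0 degenerates to plasma tracking", {
  ctx <- make_ctx()
  t <- seq(0, 180, 5)
  tr0 <- simulate_response(make_est(tau_g = 0), fx_default, ctx, t)
  expect_lt(max(abs(tr0$interstitial_glucose - tr0$plasma_glucose)), 1e-6)
  sup <- vapply(c(1e-6, 1e-3, 1), function(tg) {
    tr <- simulate_response(make_est(tau_g = tg), fx_default, ctx, t)
    max(abs(tr$interstitial_glucose - tr$plasma_glucose))
  }, numeric(1))
  expect_true(all(diff(sup) > 0))   # smaller tau, closer to plasma
  expect_lt(sup[1], 1e-4)
})

test_that("interstitial peak lags the plasma peak", {
  ctx <- make_ctx()
  t <- seq(0, 240, 1)
  tr <- simulate_response(make_est(tau_g = 5), fx_default, ctx, t)
  expect_gt(t[which.max(tr$interstitial_glucose)],
            t[which.max(tr$plasma_glucose)])
})

test_that("observables are stable under solver refinement", {
  ctx <- make_ctx()
  est <- make_est()
  t <- seq(0, 180, 5)
  a <- simulate_response(est, fx_default, ctx, t)                 # defaults
  b <- simulate_response(est, fx_default, ctx, t, rtol = 1e-8, atol = 1e-10)
  rel <- abs(as.matrix(a[-1]) - as.matrix(b[-1])) /
    pmax(abs(as.matrix(b[-1])), 1)
  expect_lt(max(rel), 1e-5)
})

test_that("fixed parameters round-trip through the YAML config", {
  p <- fixed_parameters(K_M = 7.5)
  path <- withr::local_tempfile(fileext = ".yml")
  write_fixed_parameters(p, path)
  q <- read_fixed_parameters(path)
  expect_equal(unclass(q), unclass(p))
  expect_error(fixed_parameters(G_thr = 5))
  expect_error(fixed_parameters(nonsense = 1))
})
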