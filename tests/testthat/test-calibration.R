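# Observation assembly, the max-normalized objective, and the multistart
# calibration contract.

test_that("observation sets have the design point counts", {
  s <- fixture_subject()
  obs_p <- build_observations(s$response, "plasma")
  counts <- table(obs_p$points$metabolite)
  expect_identical(unname(counts[["glucose"]]), 6L)
  expect_identical(unname(counts[["insulin"]]), 6L)
  expect_false(any(obs_p$points$time == 0))
  obs_c <- build_observations(s$response, "cgm")
  counts <- table(obs_c$points$metabolite)
  expect_identical(unname(counts[["glucose"]]), 26L)
  expect_identical(unname(counts[["insulin"]]), 6L)
  expect_setequal(obs_c$points$time[obs_c$points$metabolite == "glucose"],
                  seq(5, 130, 5))
  # weights are the per-metabolite maxima of the fitted values
  expect_equal(obs_p$weights[["glucose"]],
               max(obs_p$points$value[obs_p$points$metabolite == "glucose"]))
  # basal inputs are mode-matched
  expect_equal(obs_p$ctx$basal_glucose, s$response$ogtt$glucose[1])
  expect_equal(obs_c$ctx$basal_interstitial, s$response$cgm$glucose[1])
})

test_that("a response without a CGM trace is unusable in cgm mode", {
  s <- fixture_subject()
  r <- subject_response(s$id, s$response$ogtt, s$response$context, cgm = NULL)
  expect_error(build_observations(r, "cgm"),
               class = "glucodyn_unusable_response")
})

test_that("objective reproduces hand-computed normalized squared residuals", {
  ctx <- make_ctx()
  est <- make_est()
  times <- c(20, 60, 100)
  traj <- simulate_response(est, fx_default, ctx, c(0, times))
  offs_g <- c(0.4, -0.3, 0.2)
  offs_i <- c(-5, 4, 3)
  y_g <- traj$plasma_glucose[-1] + offs_g
  y_i <- traj$plasma_insulin[-1] + offs_i
  ogtt <- tibble::tibble(time = c(0, times),
                         glucose = c(ctx$basal_glucose, y_g),
                         insulin = c(ctx$basal_insulin, y_i))
  r <- subject_response("toy", ogtt, ctx)
  obs <- build_observations(r, "plasma")
  expected <- sum((offs_g / max(y_g))^2) + sum((offs_i / max(y_i))^2)
  expect_equal(calib_objective(est, obs, fx_default), expected,
               tolerance = 1e-12)
  # exact model reproduction gives zero loss
  ogtt0 <- tibble::tibble(time = c(0, times),
                          glucose = c(ctx$basal_glucose,
                                      traj$plasma_glucose[-1]),
                          insulin = c(ctx$basal_insulin,
                                      traj$plasma_insulin[-1]))
  obs0 <- build_observations(subject_response("t0", ogtt0, ctx), "plasma")
  expect_lt(calib_objective(est, obs0, fx_default), 1e-12)
})

test_that("objective is invariant under an insulin-unit rescaling", {
  # re-expressing insulin in different units (basal and data scaled by c,
  # conversion factor beta scaled by 1/c) multiplies the insulin trajectory
  # by c, leaves glucose unchanged, and must leave the max-normalized loss
  # identical
  cc <- 2.5
  ctx1 <- make_ctx()
  ctx2 <- make_ctx(basal_insulin = ctx1$basal_insulin * cc)
  fx2 <- fixed_parameters(beta = fx_default$beta / cc)
  est <- make_est()
  times <- c(15, 30, 45, 60, 90, 120)
  tr1 <- simulate_response(est, fx_default, ctx1, c(0, times))
  tr2 <- simulate_response(est, fx2, ctx2, c(0, times))
  expect_equal(tr2$plasma_insulin, tr1$plasma_insulin * cc, tolerance = 1e-6)
  expect_equal(tr2$plasma_glucose, tr1$plasma_glucose, tolerance = 1e-6)
  y_g <- tr1$plasma_glucose[-1] * 1.05
  y_i <- tr1$plasma_insulin[-1] * 0.92
  mk <- function(ctx, scale_i) {
    ogtt <- tibble::tibble(time = c(0, times),
                           glucose = c(ctx$basal_glucose, y_g),
                           insulin = c(ctx$basal_insulin, y_i * scale_i))
    build_observations(subject_response("s", ogtt, ctx), "plasma")
  }
  L1 <- calib_objective(est, mk(ctx1, 1), fx_default)
  L2 <- calib_objective(est, mk(ctx2, cc), fx2)
  expect_equal(L1, L2, tolerance = 1e-6)
})

test_that("calibration is deterministic and monotone over the global stage", {
  s <- fixture_subject()
  obs <- build_observations(s$response, "plasma")
  cfg <- calibration_config("plasma", n_global = 32, n_local = 4)
  f1 <- calibrate_response(obs, cfg, fx_default)
  f2 <- calibrate_response(obs, cfg, fx_default)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$objective, f2$objective)
  expect_lte(f1$objective, f1$global_best + 1e-12)
})

test_that("noise-free subjects are recovered within 1 percent in both modes", {
  for (sub in fixture_noisefree_fits()) {
    for (m in c("plasma", "cgm")) {
      fit <- sub$fits[[m]]
      rel <- abs(fit$theta[c("k1", "k5", "k6")] -
                   sub$truth[c("k1", "k5", "k6")]) /
        sub$truth[c("k1", "k5", "k6")]
      expect_lt(max(rel), 0.01)
    }
  }
})

test_that("stored objective and metrics are internally consistent", {
  fit <- fixture_fit_plasma()
  expect_equal(calib_objective(fit$estimates, fit$obs, fit$fixed, fit$ctx),
               fit$objective, tolerance = 1e-9)
  m <- fit_metrics(fit)
  recomputed <- tapply(m$residuals$residual, m$residuals$metabolite,
                       function(r) mean(r^2))
  expect_equal(m$mse$mse[match(names(recomputed), m$mse$metabolite)],
               as.numeric(recomputed), tolerance = 1e-12)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_setequal(td$term, c("k1", "k5", "k6"))
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  gl <- glance(fit)
  expect_identical(gl$mode, "plasma")
  expect_false(gl$failed)
})

test_that("an optimum demanding more secretion than the box allows hits the k6 bound", {
  ctx <- make_ctx()
  est <- make_est(k6 = 9)
  times <- c(15, 30, 45, 60, 90, 120)
  traj <- simulate_response(est, fx_default, ctx, c(0, times))
  # inflate the insulin excursion so the required gain exceeds 10
  y_i <- ctx$basal_insulin + 3 * (traj$plasma_insulin[-1] - ctx$basal_insulin)
  ogtt <- tibble::tibble(time = c(0, times),
                         glucose = c(ctx$basal_glucose,
                                     traj$plasma_glucose[-1]),
                         insulin = c(ctx$basal_insulin, y_i))
  obs <- build_observations(subject_response("hi", ogtt, ctx), "plasma")
  fit <- calibrate_response(obs, calibration_config("plasma"), fx_default)
  expect_true(fit$boundary[["k6"]])
  expect_equal(fit$theta[["k6"]], 10)
})

test_that("per-observable MSE follows its definition", {
  fit <- fixture_fit_plasma()
  res <- fit$residuals
  g <- res$residual[res$metabolite == "glucose"]
  expect_equal(unname(fit$mse[["glucose"]]), mean(g^2), tolerance = 1e-12)
})
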