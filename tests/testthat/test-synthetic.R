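# Synthetic cohort generator: reproducibility, noise model, missingness and
# the study exclusion rules.

test_that("cohorts are fully reproducible from (spec, seed)", {
  spec <- cohort_spec(3, seed = 5)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(purrr::map(a, "truth"), purrr::map(b, "truth"))
  expect_identical(purrr::map(a, ~.x$response$ogtt),
                   purrr::map(b, ~.x$response$ogtt))
  expect_identical(purrr::map(a, ~.x$response$cgm),
                   purrr::map(b, ~.x$response$cgm))
})

test_that("zero-noise subjects sample the clean trajectory exactly", {
  spec <- cohort_spec(1, seed = 3, noise = noise_model(0, 0, 0, 0, 0))
  s <- sample_cohort(spec)[[1]]
  io <- match(s$response$ogtt$time, s$clean$time)
  expect_equal(s$response$ogtt$glucose, s$clean$plasma_glucose[io],
               tolerance = 1e-12)
  expect_equal(s$response$ogtt$insulin, s$clean$plasma_insulin[io],
               tolerance = 1e-12)
  ic <- match(s$response$cgm$time, s$clean$time)
  expect_equal(s$response$cgm$glucose, s$clean$interstitial_glucose[ic],
               tolerance = 1e-12)
  # clean trajectories regenerate exactly from the stored true parameters
  est <- estimable_parameters(s$truth[["k1"]], s$truth[["k5"]],
                              s$truth[["k6"]], s$truth[["tau_g"]])
  re <- simulate_response(est, fx_default, s$context, s$clean$time)
  expect_equal(re$plasma_glucose, s$clean$plasma_glucose, tolerance = 1e-10)
})

test_that("a long lag delays the clean CGM peak", {
  spec <- cohort_spec(1, seed = 8)
  spec$params$tau_g <- c(meanlog = log(10), sdlog = 1e-6)
  s <- sample_cohort(spec)[[1]]
  tpk_pl <- s$clean$time[which.max(s$clean$plasma_glucose)]
  tpk_if <- s$clean$time[which.max(s$clean$interstitial_glucose)]
  expect_gte(tpk_if, tpk_pl)
})

test_that("missingness honors its configured probability", {
  spec0 <- cohort_spec(2, seed = 4)
  s <- sample_cohort(spec0)[[1]]
  same <- inject_missingness(s$response, spec0)   # probability 0
  expect_identical(same$ogtt, s$response$ogtt)

  spec <- cohort_spec(2, seed = 4, missing_prob = 0.15)
  set.seed(99)
  n_pts <- 0; n_miss <- 0
  for (i in 1:143) {  # 143 responses x 7 samples ~ 1000 Bernoulli draws
    r <- inject_missingness(s$response, spec)
    n_pts <- n_pts + nrow(r$ogtt)
    n_miss <- n_miss + sum(is.na(r$ogtt$glucose))
  }
  p_hat <- n_miss / n_pts
  se <- sqrt(0.15 * 0.85 / n_pts)
  expect_lt(abs(p_hat - 0.15), 3 * se)
})

test_that("exclusion rules implement the study boundary cases", {
  spec <- cohort_spec(1, seed = 6)
  s <- sample_cohort(spec)[[1]]
  complete <- s$response

  drop_at <- function(r, tt) {
    r$ogtt$glucose[r$ogtt$time %in% tt] <- NA_real_
    r$ogtt$insulin[r$ogtt$time %in% tt] <- NA_real_
    r
  }
  two_interior <- drop_at(complete, c(30, 60))
  three_interior <- drop_at(complete, c(15, 30, 60))
  no_baseline <- drop_at(complete, 0)
  no_2h <- drop_at(complete, 120)
  irregular <- complete
  irregular$cgm$time[5] <- irregular$cgm$time[5] + 2
  no_cgm <- subject_response(complete$id, complete$ogtt, complete$context,
                             cgm = NULL)

  out <- apply_exclusions(list(complete, two_interior, three_interior,
                               no_baseline, no_2h, irregular, no_cgm))
  expect_length(out$kept, 2)     # complete + two interior gaps survive
  expect_setequal(out$excluded$reason,
                  c("more than two missing samples",
                    "missing baseline sample",
                    "missing 2-hour post-load sample",
                    "irregular CGM grid",
                    "missing glucose channel"))
  # the irregular-grid injection path feeds the same rule
  spec_ir <- cohort_spec(1, seed = 6, p_irregular_cgm = 1)
  set.seed(1)
  r_ir <- inject_missingness(complete, spec_ir)
  expect_identical(apply_exclusions(list(r_ir))$excluded$reason,
                   "irregular CGM grid")
})

test_that("interstitial readings sit above plasma for the default spec", {
  cohort <- sample_cohort(cohort_spec(10, seed = 12))
  auc <- purrr::map_dfr(cohort, function(s) {
    tibble::tibble(
      plasma = auc_segment(s$response$ogtt$time, s$response$ogtt$glucose,
                           0, 120),
      cgm = auc_segment(s$response$cgm$time, s$response$cgm$glucose, 0, 120))
  })
  expect_gte(median(auc$cgm), median(auc$plasma))
})

test_that("generation failures surface as a typed error", {
  spec <- cohort_spec(1, seed = 2, max_retries = 2)
  spec$params$k5 <- c(meanlog = log(20), sdlog = 1e-9)   # uptake drives glucose negative
  spec$params$k6 <- c(meanlog = log(5), sdlog = 1e-9)
  expect_error(sample_cohort(spec), class = "glucodyn_generation_error")
})
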