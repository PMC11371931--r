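# Metabolic indicators: AUC segments, the full index set on a hand-computed
# toy response, and scaling properties.

test_that("trapezoidal segment areas are exact on flat and linear data", {
  expect_equal(auc_segment(c(0, 15, 30), c(5, 5, 5), 0, 30), 150)
  expect_equal(auc_segment(c(0, 15, 30), c(4, 5, 6), 0, 30), 150)
  expect_true(is.na(auc_segment(c(0, 15), c(4, 5), 0, 30)))
  # within 2 percent of fine-grid quadrature on a smooth simulated response
  tr <- simulate_response(make_est(), fx_default, make_ctx(), seq(0, 30, 0.1))
  fine <- sum(0.1 * (head(tr$plasma_glucose, -1) +
                       tail(tr$plasma_glucose, -1)) / 2)
  coarse <- auc_segment(c(0, 15, 30),
                        tr$plasma_glucose[tr$time %in% c(0, 15, 30)], 0, 30)
  expect_lt(abs(coarse - fine) / fine, 0.02)
})

test_that("all indices on the toy 7-point response match hand computations", {
  mg <- 18.016
  out <- compute_indicators(toy_ogtt())
  expect_equal(out$homa_ir, 5 * 9 / 22.5, tolerance = 1e-12)   # = 2.0
  expect_equal(out$homa_beta, 20 * 9 / (5 - 3.5), tolerance = 1e-12)
  g_mean <- mean(c(5, 7, 9, 8.5, 8, 6.5, 5.5))
  i_mean <- mean(c(9, 40, 70, 65, 60, 35, 20))
  expect_equal(out$matsuda,
               10000 / sqrt(5 * mg * 9 * g_mean * mg * i_mean),
               tolerance = 1e-12)
  expect_equal(out$auc30_glu, 15 * (5 + 7) / 2 + 15 * (7 + 9) / 2,
               tolerance = 1e-12)                               # = 210
  expect_equal(out$auc30_ins, 15 * (9 + 40) / 2 + 15 * (40 + 70) / 2,
               tolerance = 1e-12)                               # = 1192.5
  expect_equal(out$insulinogenic_index, (70 - 9) / (9 - 5),
               tolerance = 1e-12)                               # = 15.25
  expect_equal(out$hiri, 210 * mg * 1192.5, tolerance = 1e-12)
  slope <- (9 - 5.5) / (120 - 30)
  expect_equal(out$misi, slope * mg / i_mean, tolerance = 1e-12)
  expect_equal(out$disposition_index, out$insulinogenic_index * out$matsuda,
               tolerance = 1e-12)
})

test_that("degenerate inputs yield explicit missing values with reasons", {
  d <- toy_ogtt()
  flat <- d; flat$glucose <- rep(5, 7)
  out <- compute_indicators(flat)
  expect_identical(out$misi, 0)          # no post-peak decline
  expect_true(is.na(out$insulinogenic_index))  # G30 == G0
  expect_match(attr(out, "reasons")[["insulinogenic_index"]], "excursion")
  no0 <- d[d$time != 0, ]
  out2 <- compute_indicators(no0)
  expect_true(is.na(out2$homa_ir))
  expect_true(is.na(out2$matsuda))
  expect_true(is.na(out2$auc30_glu))
  # monotone rise: peak at the final sample, no decline to score
  rise <- d; rise$glucose <- seq(5, 11, 1)
  expect_identical(compute_indicators(rise)$misi, 0)
})

test_that("doubling insulin halves Matsuda and doubles HOMA-IR", {
  d <- toy_ogtt()
  d2 <- d; d2$insulin <- d$insulin * 2
  a <- compute_indicators(d)
  b <- compute_indicators(d2)
  expect_equal(b$matsuda, a$matsuda / 2, tolerance = 1e-12)
  expect_equal(b$homa_ir, a$homa_ir * 2, tolerance = 1e-12)
  expect_equal(b$auc30_ins, a$auc30_ins * 2, tolerance = 1e-12)
})

test_that("Matsuda and HOMA-IR are anticorrelated across varied insulin", {
  base <- toy_ogtt()
  cohort <- lapply(seq(0.4, 3, length.out = 12), function(s) {
    d <- base
    d$insulin <- d$insulin * s
    d$glucose <- d$glucose * (1 + 0.05 * (s - 1))  # mild covariation
    subject_response(paste0("v", s), d,
                     make_ctx(basal_glucose = d$glucose[1],
                              basal_insulin = d$insulin[1]))
  })
  tab <- cohort_indicators(cohort)
  expect_lt(cor(tab$matsuda, tab$homa_ir, method = "spearman"), 0)
})

test_that("the indicator pipeline is pure", {
  expect_identical(compute_indicators(toy_ogtt()),
                   compute_indicators(toy_ogtt()))
})
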