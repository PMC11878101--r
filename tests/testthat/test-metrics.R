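test_that("PE, aPE and rPE follow their definitions", {
  expect_identical(prediction_error(150, 150), 0)
  expect_identical(prediction_error(150, 244), -94)  # under-prediction
  expect_identical(prediction_error(200, 150), 50)
  expect_identical(absolute_prediction_error(150, 244), 94)
  expect_identical(absolute_prediction_error(200, 250),
                   absolute_prediction_error(300, 250))
  expect_equal(relative_prediction_error(110, 100), 10)
  expect_equal(relative_prediction_error(85, 170), 50)
  expect_equal(relative_prediction_error(100, 100), 0)
  expect_error(prediction_error(NaN, 1), "finite")
  expect_error(relative_prediction_error(100, 0), "undefined")
})

test_that("Bland-Altman margin uses mean +/- 1.96 sample SD", {
  expect_equal(bland_altman_margin(c(0, 0, 0)), 0)
  expect_equal(bland_altman_margin(c(-10, 10)), 1.96 * sqrt(200))
  # translation shifts both limits by the constant
  pe <- c(-12, 3, 8, -5, 20)
  m0 <- mean(pe); s0 <- sd(pe)
  expect_equal(bland_altman_margin(pe + 100),
               max(abs(m0 + 100 + c(-1.96, 1.96) * s0)))
  expect_error(bland_altman_margin(5), "at least 2")
  # SE-of-mean variant is narrower
  expect_lt(bland_altman_margin(pe, se_of_mean = TRUE),
            bland_altman_margin(pe))
})

test_that("mis-prediction tails are strict and percentages round half away from zero", {
  mc <- misprediction_counts(c(-90, -10, 0, 90))
  expect_equal(mc[c("n_under", "n_over")], list(n_under = 1, n_over = 1))
  expect_equal(mc$pct_under, 25.0)
  # exactly -85 and +85 sit in neither tail
  mc2 <- misprediction_counts(c(-85, 85, 0, 0))
  expect_equal(mc2$n_under + mc2$n_over, 0)
  # one under-prediction in 109 records prints as 0.9%
  mc3 <- misprediction_counts(c(-90, rep(0, 108)))
  expect_identical(mc3$pct_under, 0.9)
  expect_error(misprediction_counts(numeric(0)), "no prediction errors")
})

test_that("clinical acceptance requires both the margin and the 95% condition", {
  ok <- clinical_acceptance(rnorm(100, 0, 1e-6))
  expect_true(ok$pass && ok$margin_ok && ok$frac_ok)
  # 6 of 100 aPE above 85 fails condition (ii) only
  pe <- c(rep(100, 6), rep(0, 94))
  res <- clinical_acceptance(pe)
  expect_false(res$frac_ok)
  expect_equal(res$frac_within, 0.94)
  # a margin just above 85 with no large aPE fails condition (i) only
  pe2 <- c(rep(-44, 50), rep(44, 50))  # mean 0, sd ~44.2, margin ~86.7
  res2 <- clinical_acceptance(pe2)
  expect_false(res2$margin_ok)
  expect_true(res2$frac_ok)
  expect_false(res2$pass)
})

test_that("exactness is stricter: 70 margin and no aPE above 85", {
  expect_true(exactness(rep(c(-1, 1), 20))$pass)
  # a single -94 fails the mis-prediction condition regardless of n
  pe <- c(-94, rnorm(50, 0, 2))
  expect_false(exactness(pe)$miss_ok)
  # margin in (70, 85]: exactness margin fails while clinical margin passes
  pe2 <- c(rep(-37.5, 50), rep(37.5, 50))  # margin ~74.2
  e <- exactness(pe2); c <- clinical_acceptance(pe2)
  expect_false(e$margin_ok)
  expect_true(c$margin_ok)
  # nesting: an exactness pass implies a clinical-acceptance pass
  for (seed in 1:25) {
    set.seed(seed)
    pe3 <- rnorm(40, rnorm(1, 0, 20), runif(1, 1, 60))
    if (exactness(pe3)$pass) expect_true(clinical_acceptance(pe3)$pass)
  }
})

test_that("harmonization maps measurements onto the target scale and round-trips", {
  m <- bili_measurements(c(30, 50), c(150, 180), c("TcB", "TSB"))
  h <- harmonize(m, "TSB")
  expect_equal(h$value, c(150 - 14.3, 180))
  expect_true(all(h$method == "TSB"))
  h2 <- harmonize(m, "TcB")
  expect_equal(h2$value, c(150, 180 + 14.3))
  # idempotent on already-harmonized data
  expect_equal(harmonize(h, "TSB")$value, h$value)
  # reverse harmonization restores the originals
  m_tcb <- bili_measurements(c(30, 50), c(150, 180), "TSB")
  expect_equal(harmonize(harmonize(m_tcb, "TcB"), "TSB")$value, m_tcb$value)
  expect_error(harmonize(m, "serum"), "unknown target method")
})

test_that("increase rate converts micromolar differences to mg/dl per hour", {
  expect_equal(increase_rate(184.2, 150, 58, 48), 0.2)
  expect_equal(increase_rate(150, 150, 60, 40), 0)
  expect_lt(increase_rate(130, 150, 60, 40), 0)
  expect_error(increase_rate(200, 150, 48, 48), "strictly after")
})

test_that("summarize assembles all metrics deterministically", {
  rec <- data.frame(b_pred = c(160, 140), b_obs = c(150, 150))
  s <- summarize_validation(rec)
  expect_equal(s$n, 2)
  expect_equal(s$margin_95ci, 1.96 * sqrt(200))
  expect_equal(unname(s$median_iqr_ape["median"]), 10)
  expect_equal(s$n_under + s$n_over, 0)
  expect_true(s$clinical_acceptance$pass)
  # identical records give zero-width IQR
  rec2 <- data.frame(b_pred = rep(170, 5), b_obs = rep(160, 5))
  s2 <- summarize_validation(rec2)
  expect_equal(unname(s2$median_iqr_rpe["q1"]),
               unname(s2$median_iqr_rpe["q3"]))
  # permutation invariance
  set.seed(4)
  rec3 <- data.frame(b_pred = runif(31, 100, 300), b_obs = runif(31, 100, 300))
  s3a <- summarize_validation(rec3)
  s3b <- summarize_validation(rec3[sample(31), ])
  expect_equal(s3a, s3b)
  # redundancy: aPE and rPE derive from the same PE
  pe <- prediction_error(rec3$b_pred, rec3$b_obs)
  expect_equal(absolute_prediction_error(rec3$b_pred, rec3$b_obs), abs(pe))
  expect_equal(relative_prediction_error(rec3$b_pred, rec3$b_obs),
               100 * abs(pe) / rec3$b_obs)
})

test_that("a 109-record set with one tail member each side tabulates as printed", {
  set.seed(12)
  pe <- c(-90, 90, runif(107, -40, 40))
  rec <- data.frame(b_pred = 200 + pe, b_obs = 200)
  s <- summarize_validation(rec)
  expect_equal(s$n_under, 1)
  expect_identical(s$pct_under, 0.9)
  expect_equal(s$n_over, 1)
  expect_identical(s$pct_over, 0.9)
})
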