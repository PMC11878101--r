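test_that("covariate sampling is reproducible, respects inclusion rules and size", {
  cfg <- cohort_config(n_patients = 200, seed = 42)
  a <- sample_covariates(cfg)
  b <- sample_covariates(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 200)
  expect_false(anyDuplicated(a$patient_id) > 0)
  expect_true(all(a$ga_weeks >= 34))
  expect_true(all(a$birth_weight_g >= 1500))
  expect_identical(nrow(sample_covariates(cohort_config(n_patients = 0))), 0L)
  expect_error(cohort_config(p_female = 1.2), "proportions")
})

test_that("demographic targets are hit at large n", {
  cfg <- cohort_config(n_patients = 10000, seed = 7)
  pats <- sample_covariates(cfg)
  expect_lt(abs(median(pats$ga_weeks) - 38.7), 0.3)
  expect_lt(abs(median(pats$birth_weight_g) - 3155), 100)
  expect_lt(abs(mean(pats$sex == "female") - 0.39), 0.02)
  expect_lt(abs(mean(pats$delivery_mode == "cesarean") - 0.35), 0.02)
  # quartile targets within Monte-Carlo + truncation slack
  expect_lt(abs(quantile(pats$ga_weeks, 0.25) - 37.0), 0.3)
  expect_lt(abs(quantile(pats$birth_weight_g, 0.75) - 3510), 100)
})

test_that("schedules obey the policy and scenario construction succeeds broadly", {
  cfg <- cohort_config(n_patients = 1000, seed = 5)
  coh <- generate_cohort(cfg)
  firsts <- tapply(coh$measurements$pna_h, coh$measurements$patient_id, min)
  expect_true(all(firsts > 0 & firsts <= 72))
  counts <- table(coh$measurements$patient_id)
  expect_true(all(counts >= 2 & counts <= 6))
  expect_true(all(coh$measurements$pna_h <= 168))
  gaps <- unlist(tapply(coh$measurements$pna_h, coh$measurements$patient_id,
                        function(x) diff(sort(x))))
  expect_true(all(gaps >= 8))
  # >= 90% of patients admit a Scenario-4 instance under the default policy
  s4 <- build_population(coh, default_scenarios()["s4"])
  expect_gte(s4$accounting$n_accepted[1], 0.9 * 1000)
})

test_that("a policy forcing sub-8h gaps yields no scenario instances", {
  cfg <- cohort_config(n_patients = 50, seed = 9, gap_range = c(2, 5),
                       n_meas_range = c(4, 4))
  coh <- generate_cohort(cfg)
  pops <- build_population(coh, default_scenarios()["s4"])
  expect_identical(pops$accounting$n_accepted[1], 0L)
})

test_that("measurement simulation: noise-free limit equals the true trajectory", {
  pop <- ref_pop()
  cfg <- cohort_config(n_patients = 1, seed = 3, sigma_tsb = 1e-12,
                       sigma_tcb = 1e-12, tcb_offset = 0)
  pat <- sample_covariates(cfg, pop)[1, ]
  sched <- data.frame(pna = c(24, 48, 96), method = c("TSB", "TcB", "TSB"))
  set.seed(1)
  m <- simulate_measurements(pat, sched, pop, cfg)
  cov <- covariates(pat$ga_weeks, pat$birth_weight_g, pat$sex,
                    pat$delivery_mode, pat$hemolytic)
  truth <- trajectory(pop, cov, c(pat$eta1, pat$eta2), sched$pna)
  expect_equal(m$value, truth, tolerance = 1e-6)
})

test_that("paired TcB-TSB simulation reproduces the systematic offset and extra noise", {
  pop <- ref_pop()
  cfg <- cohort_config(n_patients = 1, seed = 8)
  pat <- sample_covariates(cfg, pop)[1, ]
  n <- 10000
  sched_tsb <- data.frame(pna = rep(48, n), method = "TSB")
  sched_tcb <- data.frame(pna = rep(48, n), method = "TcB")
  set.seed(11)
  tsb <- simulate_measurements(pat, sched_tsb, pop, cfg)$value
  set.seed(11)
  tcb <- simulate_measurements(pat, sched_tcb, pop, cfg)$value
  expect_lt(abs(mean(tcb - tsb) - 14.3), 1.0)
  expect_gt(sd(tcb), sd(tsb))
})

test_that("cohort generation is deterministic, order-independent and CSV round-trips", {
  cfg <- cohort_config(n_patients = 25, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$measurements, b$measurements)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(a, d1); write_cohort(b, d2)
  expect_identical(readLines(file.path(d1, "measurements.csv")),
                   readLines(file.path(d2, "measurements.csv")))
  back <- read_cohort(d1)
  expect_equal(nrow(back$patients), 25)
  # per-patient records do not depend on cohort size (independence of patients)
  big <- generate_cohort(cohort_config(n_patients = 40, seed = 77))
  m_small <- a$measurements[a$measurements$patient_id == "P0010", ]
  m_big <- big$measurements[big$measurements$patient_id == "P0010", ]
  expect_equal(m_small$pna_h, m_big$pna_h)
  expect_equal(m_small$value_umol_l, m_big$value_umol_l)
})

test_that("degenerate proportions propagate exactly", {
  cfg <- cohort_config(n_patients = 30, seed = 2, p_hemolytic = 1)
  pats <- sample_covariates(cfg)
  expect_true(all(pats$hemolytic))
})
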