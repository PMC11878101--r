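test_that("scenario specs encode windows, horizons and gap as designed", {
  specs <- default_scenarios()
  expect_equal(vapply(specs, `[[`, numeric(1), "horizon"),
               c(s1 = 30, s2 = 60, s3 = 48, s4 = 48, s5 = 48))
  expect_equal(specs$s2$subsequent_window, c(24, 96))
  expect_equal(specs$s4$subsequent_window, c(24, 120))
  expect_true(all(vapply(specs, `[[`, numeric(1), "min_gap") == 8))
  expect_error(scenario_spec(9, 2, "TSB", 45), "horizon")
})

test_that("a lone measurement before 8 h is rejected for the first window", {
  m <- bili_measurements(6, 120, "TSB")
  res <- select_inputs(m, default_scenarios()$s1)
  expect_false(res$accepted)
  expect_identical(res$reason, "first_window")
  res2 <- select_inputs(bili_measurements(40, 150, "TcB"),
                        default_scenarios()$s1)
  expect_identical(res2$reason, "no_first_measurement")
})

test_that("the 8-h spacing rule skips too-close measurements (hand trace)", {
  # TSB at 30, 36, 40 h; two-TSB scenario: second input must be the 40 h
  # reading (36 h is closer than 8 h), leaving no target -> rejection
  m <- bili_measurements(c(30, 36, 40), c(140, 150, 160), "TSB")
  res <- select_inputs(m, default_scenarios()$s2)
  expect_false(res$accepted)
  expect_identical(res$reason, "no_target")
  # adding a measurement 8 h after 40 h completes the instance
  m2 <- bili_measurements(c(30, 36, 40, 48), c(140, 150, 160, 175), "TSB")
  res2 <- select_inputs(m2, default_scenarios()$s2)
  expect_true(res2$accepted)
  expect_equal(res2$instance$inputs$pna, c(30, 40))
  expect_equal(res2$instance$t_target, 48)
})

test_that("simultaneous TSB and TcB resolve to TcB when both are allowed", {
  m <- bili_measurements(c(50, 50, 60, 80), c(180, 190, 200, 220),
                         c("TSB", "TcB", "TcB", "TSB"))
  res <- select_inputs(m, default_scenarios()$s4)
  expect_true(res$accepted)
  expect_identical(res$instance$inputs$method[1], "TcB")
  # in a pure-TSB scenario the same record selects the TSB reading
  res2 <- select_inputs(m, default_scenarios()$s1)
  expect_true(!res2$accepted || res2$instance$inputs$method[1] == "TSB")
})

test_that("targets beyond the horizon are rejected with the horizon reason", {
  # input at 40 h, only candidate target at 80 h: 40 h gap > 30 h horizon
  m <- bili_measurements(c(40, 80), c(150, 210), "TSB")
  res <- select_inputs(m, default_scenarios()$s1)
  expect_false(res$accepted)
  expect_identical(res$reason, "target_horizon")
  # same record under the 60 h two-TSB horizon has no second input slot filled
  # at 80 h (it becomes the input), leaving no target
  res2 <- select_inputs(m, default_scenarios()$s2)
  expect_identical(res2$reason, "no_target")
})

test_that("the target is the last eligible measurement within the horizon", {
  m <- bili_measurements(c(30, 45, 60, 88), c(140, 160, 180, 210), "TSB")
  res <- select_inputs(m, default_scenarios()$s1)
  expect_true(res$accepted)
  expect_equal(res$instance$t_target, 60)  # 88 h exceeds 30+30
  res2 <- select_inputs(m, scenario_spec(1, 1, "TSB", 60, "A"))
  expect_equal(res2$instance$t_target, 88)
  expect_equal(res2$instance$horizon_used, 58)
})

test_that("rule engine agrees with the independent oracle on random records", {
  specs <- default_scenarios()
  for (seed in 1:150) {
    n_meas <- 2 + (seed %% 5)
    m <- random_record(n_meas, seed)
    for (spec in specs) {
      got <- select_inputs(m, spec)
      want <- oracle_select(m, spec)
      if (is.null(want)) {
        expect_false(got$accepted)
      } else {
        expect_true(got$accepted)
        expect_equal(got$instance$inputs$pna, want$input_pna)
        expect_equal(got$instance$target$pna, want$target_pna)
        expect_identical(got$instance$target$method, want$target_method)
      }
    }
  }
})

test_that("accepted instances always lie in the exhaustively enumerated valid set", {
  specs <- default_scenarios()
  n_checked <- 0
  for (seed in 201:260) {
    m <- random_record(2 + (seed %% 5), seed)
    for (spec in specs) {
      got <- select_inputs(m, spec)
      combos <- enumerate_valid_combos(m, spec)
      if (got$accepted) {
        hit <- any(vapply(combos, function(cb)
          isTRUE(all.equal(cb$input_pna, got$instance$inputs$pna)) &&
            isTRUE(all.equal(cb$target_pna, got$instance$t_target)),
          logical(1)))
        expect_true(hit)
        n_checked <- n_checked + 1
      }
      # every emitted instance satisfies all invariants
      if (got$accepted) {
        ins <- got$instance
        expect_true(all(diff(ins$inputs$pna) >= spec$min_gap))
        expect_gt(ins$horizon_used, 0)
        expect_lte(ins$horizon_used, spec$horizon)
        expect_gte(ins$inputs$pna[1], 8)
        expect_lte(ins$inputs$pna[1], 72)
      }
    }
  }
  expect_gt(n_checked, 20)
})

test_that("population building accounts for every patient exactly once per scenario", {
  coh <- generate_cohort(cohort_config(n_patients = 120, seed = 31))
  pops <- build_population(coh)
  acct <- pops$accounting
  reasons <- c("no_first_measurement", "first_window", "input_gap_window",
               "no_target", "target_horizon")
  expect_true(all(acct$n_accepted + rowSums(acct[, reasons]) ==
                    acct$n_patients))
  # determinism
  pops2 <- build_population(coh)
  expect_identical(instances_table(pops), instances_table(pops2))
  # overlap: patients may appear in several scenarios
  tab <- instances_table(pops)
  expect_gte(nrow(tab), length(unique(tab$patient_id)))
})

test_that("empty dataset yields empty instance lists and zero counts", {
  coh <- generate_cohort(cohort_config(n_patients = 0, seed = 1))
  pops <- build_population(coh)
  expect_true(all(lengths(pops$instances) == 0))
  expect_true(all(pops$accounting$n_accepted == 0))
  expect_identical(nrow(instances_table(pops)), 0L)
})
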