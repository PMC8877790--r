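sched1 <- photoperiod_schedule(n_cycles = 1) # 30 light + 30 dark bins

test_that("light serial-exceedance rule follows the Q3 + 1.5 IQR threshold", {
  # constant light series: IQR 0, threshold = c, nothing strictly above
  tr <- trace_from_values(rep(2, 30), rep(5, 30), sched1)
  res <- light_serial_exceedance_flag(tr)
  expect_false(res$flag)
  expect_equal(res$threshold, 2)

  # 28 quiet bins then two large ones late in the phase:
  # Q3 = 1, IQR = 0, T = 1 < 9, and the 9s sit past the 60-s burn-in
  tr <- trace_from_values(c(rep(1, 28), 9, 9), rep(5, 30), sched1)
  res <- light_serial_exceedance_flag(tr)
  expect_equal(res$threshold, 1)
  expect_true(res$flag)

  # the same two exceedances separated by a sub-threshold bin: no run
  tr <- trace_from_values(c(rep(1, 27), 9, 1, 9), rep(5, 30), sched1)
  expect_false(light_serial_exceedance_flag(tr)$flag)

  # exceedances inside the burn-in window are ignored
  tr <- trace_from_values(c(9, 9, rep(1, 28)), rep(5, 30), sched1)
  expect_false(light_serial_exceedance_flag(tr)$flag)
})

test_that("dark rule fires on two serial dark bins below the light median", {
  # normal scototaxis: dark movement always above light
  tr <- trace_from_values(rep(2, 30), rep(5, 30), sched1)
  expect_false(dark_below_median_flag(tr)$flag)

  # light constant at 5 (median 5), two consecutive dark bins at 4
  dark <- c(4, 4, rep(6, 28))
  tr <- trace_from_values(rep(5, 30), dark, sched1)
  res <- dark_below_median_flag(tr)
  expect_equal(res$light_median, 5)
  expect_true(res$flag)

  # a single isolated dip does not trigger the run rule
  dark <- c(6, 4, 6, rep(6, 27))
  tr <- trace_from_values(rep(5, 30), dark, sched1)
  expect_false(dark_below_median_flag(tr)$flag)
})

test_that("ratio rule removes non-responders at the inclusive 0.9 boundary", {
  tr <- trace_from_values(rep(0.9, 30), rep(1, 30), sched1)
  res <- light_dark_ratio_flag(tr)
  expect_equal(res$ratio, 0.9)
  expect_true(res$flag) # boundary inclusive

  tr <- trace_from_values(rep(0, 30), rep(1, 30), sched1)
  expect_false(light_dark_ratio_flag(tr)$flag)

  tr <- trace_from_values(rep(2, 30), rep(1, 30), sched1)
  expect_true(light_dark_ratio_flag(tr)$flag)

  # a larva that never moves in the dark is a degenerate non-responder
  tr <- trace_from_values(rep(1, 30), rep(0, 30), sched1)
  expect_warning(res <- light_dark_ratio_flag(tr), "degenerate")
  expect_true(res$flag)
})

test_that("rule flags match brute-force window enumeration on random traces", {
  set.seed(41)
  sched <- small_schedule()
  th <- small_thresholds()
  for (i in 1:200) {
    tr <- label_phases(round(exp(rnorm(sched$n_bins, 0, 1)), 2), sched)
    expect_equal(
      light_serial_exceedance_flag(tr, th)$flag,
      oracle_light_flag(tr, k = th$iqr_multiplier, burn_in = th$light_burn_in_s)
    )
    expect_equal(dark_below_median_flag(tr, th)$flag, oracle_dark_flag(tr))
  }
})

test_that("apply_qc is idempotent, local and reports every flag", {
  set.seed(7)
  cohort <- random_cohort(12)
  th <- small_thresholds()
  qc1 <- apply_qc(cohort, th)
  expect_equal(nrow(qc1$report), 12)
  expect_equal(
    qc1$report$excluded,
    qc1$report$light_rule_flag | qc1$report$dark_rule_flag | qc1$report$ratio_flag
  )
  expect_equal(
    sum(qc1$retention$n_retained) + sum(qc1$retention$n_excluded), 12
  )

  # idempotence: re-running on the retained traces removes nothing
  qc2 <- apply_qc(qc1$retained, th)
  expect_equal(sum(qc2$report$excluded), 0)
  expect_equal(qc2$retained, qc1$retained)

  # per-trace locality: flags unchanged when other larvae are dropped
  one <- dplyr::filter(cohort, larva_id == "L03")
  solo <- apply_qc(one, th)$report
  in_cohort <- dplyr::filter(qc1$report, larva_id == "L03")
  expect_equal(solo$excluded, in_cohort$excluded)
  expect_equal(solo$light_dark_ratio, in_cohort$light_dark_ratio)
})

test_that("relaxing thresholds never grows the excluded set", {
  set.seed(11)
  for (i in 1:30) {
    cohort <- random_cohort(6)
    strict <- apply_qc(cohort, small_thresholds())$report
    loose_ratio <- apply_qc(cohort, small_thresholds(ratio_cutoff = 1.5))$report
    expect_true(all(loose_ratio$ratio_flag <= strict$ratio_flag))
    loose_iqr <- apply_qc(cohort, small_thresholds(iqr_multiplier = 4))$report
    expect_true(all(loose_iqr$light_rule_flag <= strict$light_rule_flag))
  }
})

test_that("apply_qc rejects cohorts with mixed schedules", {
  a <- label_phases(rep(1, 20), small_schedule(), larva_id = "a")
  b <- label_phases(
    rep(1, 24),
    photoperiod_schedule(phase_length_s = 36, n_cycles = 2, bin_width_s = 6),
    larva_id = "b"
  )
  expect_error(apply_qc(dplyr::bind_rows(a, b)), "mixed schedules")
})
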