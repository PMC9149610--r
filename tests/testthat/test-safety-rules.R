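test_that("safety gate fires on the stated strict thresholds", {
  v <- evaluate_safety(blood_gas(7.30, 50, 95))
  expect_equal(v$verdict, "ABORT_CALL_PHYSICIAN")
  expect_equal(v$reasons, "ACIDOSIS")

  v <- evaluate_safety(blood_gas(7.40, 50, 84))
  expect_equal(v$verdict, "ABORT_CALL_PHYSICIAN")
  expect_equal(v$reasons, "HYPOXEMIA")

  v <- evaluate_safety(blood_gas(7.56, 40, 95))
  expect_equal(v$verdict, "STOP_AND_PAUSE")
  expect_equal(v$reasons, "ALKALOSIS")

  # boundaries are excluded by the strict inequalities
  expect_equal(evaluate_safety(blood_gas(7.35, 50, 85))$verdict, "CONTINUE")
  expect_equal(evaluate_safety(blood_gas(7.55, 50, 85))$verdict, "CONTINUE")

  v <- evaluate_safety(blood_gas(7.30, 50, 80))
  expect_equal(v$verdict, "ABORT_CALL_PHYSICIAN")
  expect_setequal(v$reasons, c("ACIDOSIS", "HYPOXEMIA"))

  # abort dominates a co-occurring alkalosis flag
  v <- evaluate_safety(blood_gas(7.60, 40, 80))
  expect_equal(v$verdict, "ABORT_CALL_PHYSICIAN")
  expect_true("ALKALOSIS" %in% v$reasons)
})

test_that("safety gate agrees with the rule-enumeration oracle on a grid", {
  for (ph in c(7.0, 7.34, 7.349, 7.35, 7.351, 7.45, 7.549, 7.55, 7.551, 7.7)) {
    for (spo2 in c(70, 84, 84.9, 85, 85.1, 92, 100)) {
      got <- evaluate_safety(blood_gas(ph, 50, spo2))
      want <- oracle_safety(ph, spo2)
      expect_equal(got$verdict, want$verdict,
                   info = sprintf("ph=%g spo2=%g", ph, spo2))
      expect_setequal(got$reasons, want$reasons)
    }
  }
})

test_that("alkalosis resolution includes the boundary", {
  expect_true(alkalosis_resolved(blood_gas(7.55, 40, 95)))
  expect_false(alkalosis_resolved(blood_gas(7.56, 40, 95)))
  expect_true(alkalosis_resolved(blood_gas(7.40, 40, 95)))
})

test_that("bisection recovers the safety boundaries to 1e-6", {
  ph_abort <- bisect_boundary(
    function(ph) evaluate_safety(blood_gas(ph, 50, 95))$verdict == "ABORT_CALL_PHYSICIAN",
    7.0, 7.5)
  expect_equal(ph_abort, 7.35, tolerance = 1e-6)

  spo2_abort <- bisect_boundary(
    function(s) evaluate_safety(blood_gas(7.40, 50, s))$verdict == "ABORT_CALL_PHYSICIAN",
    50, 100)
  expect_equal(spo2_abort, 85, tolerance = 1e-6)

  ph_pause <- bisect_boundary(
    function(ph) evaluate_safety(blood_gas(ph, 50, 95))$verdict == "STOP_AND_PAUSE",
    7.4, 7.8)
  expect_equal(ph_pause, 7.55, tolerance = 1e-6)
})

test_that("safety verdicts are monotone in pH and SpO2", {
  for (ph in seq(7.20, 7.349, by = 0.01)) {
    expect_equal(evaluate_safety(blood_gas(ph, 50, 95))$verdict,
                 "ABORT_CALL_PHYSICIAN")
  }
  for (spo2 in seq(60, 84.9, by = 2)) {
    expect_equal(evaluate_safety(blood_gas(7.40, 50, spo2))$verdict,
                 "ABORT_CALL_PHYSICIAN")
  }
})

test_that("trend rule matches its worked examples", {
  expect_equal(paco2_trend_verdict(48, lowest = 55, previous = 49)$verdict,
               "IMPROVING_TREND")
  expect_equal(paco2_trend_verdict(48, lowest = 51, previous = 49)$verdict,
               "NEEDS_ADJUSTMENT")
  expect_equal(paco2_trend_verdict(44, lowest = 60, previous = 60)$verdict,
               "ADEQUATE")
  expect_equal(paco2_trend_verdict(52, lowest = 60, previous = 60)$verdict,
               "NEEDS_ADJUSTMENT")
  # boundary conventions: 45 counts adequate, 50 enters trend evaluation
  expect_equal(paco2_trend_verdict(45, lowest = 60, previous = 60)$verdict,
               "ADEQUATE")
  expect_equal(paco2_trend_verdict(50, lowest = 60, previous = 60)$verdict,
               "IMPROVING_TREND")
  # "more than 5" is strict
  expect_equal(paco2_trend_verdict(49, lowest = 54, previous = 50)$verdict,
               "NEEDS_ADJUSTMENT")
  expect_equal(paco2_trend_verdict(48.9, lowest = 54, previous = 50)$verdict,
               "IMPROVING_TREND")
  # deltas are signed, current minus comparator
  pv <- paco2_trend_verdict(48, lowest = 55, previous = 49)
  expect_equal(pv$lowest_delta, -7)
  expect_equal(pv$previous_delta, -1)
})

test_that("trend rule without history inside the interval is a configuration error", {
  r <- patient_record("P1", "NEW")
  expect_error(evaluate_paco2_trend(r, 48),
               class = "nivflow_configuration_error")
  # outside the interval no history is needed
  expect_equal(evaluate_paco2_trend(r, 44)$verdict, "ADEQUATE")
  expect_equal(evaluate_paco2_trend(r, 52)$verdict, "NEEDS_ADJUSTMENT")
})

test_that("record-derived trend agrees with brute-force re-derivation on random histories", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    vals <- round(runif(n, 40, 65), 1)
    times <- seq(0, by = 60, length.out = n)
    rec <- record_with_history(vals, times = times)
    cut <- times[sample(seq_len(n), 1)]
    current <- round(runif(1, 42, 55), 2)
    chart <- vals[times < cut]
    if (length(chart) == 0 && current > 45 && current <= 50) next
    got <- evaluate_paco2_trend(rec, current, at = max(times) + 1,
                                history_cutoff = cut)
    want <- oracle_trend(current,
                         lowest = oracle_lowest(chart),
                         previous = oracle_previous(vals))
    expect_equal(got$verdict, want,
                 info = sprintf("vals=%s cut=%g current=%g",
                                paste(vals, collapse = ","), cut, current))
  }
})
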