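tnt_fixture <- function(paco2_night = c(50, 48), baseline = 58,
                        ipap = 18L, settings = niv_protocol()) {
  rec <- patient_record("P1", "NEW")
  cfg <- ventilator_config(ipap, 5, 18)
  st <- tnt_start(rec, cfg, settings)
  s_base <- blood_gas(7.38, baseline, 91, taken_at = 0, on_niv = FALSE)
  rec <- update_paco2_history(rec, s_base)
  st <- tnt_receive_sample(st, s_base, settings)
  times <- c(240, 480)
  for (i in seq_along(paco2_night)) {
    s <- blood_gas(7.42, paco2_night[i], 93, taken_at = times[i], on_niv = TRUE)
    rec <- update_paco2_history(rec, s)
    st <- tnt_receive_sample(st, s, settings)
  }
  list(state = st, record = rec)
}

test_that("TNT plans one off-NIV and two on-NIV samples and keeps the config", {
  cfg <- ventilator_config(18, 5, 18)
  st <- tnt_start(patient_record("P1", "NEW"), cfg)
  expect_equal(st$phase, "BASELINE_BGA")
  expect_equal(st$config$ipap, 18L)
  plan <- Filter(function(e) e$kind == "RECOMMENDATION", st$pending_events)[[1]]
  expect_equal(plan$payload$planned_off_niv_samples, 1L)
  expect_equal(plan$payload$planned_on_niv_samples, 2L)
})

test_that("sample phases are enforced: baseline off NIV, nights on NIV, in order", {
  cfg <- ventilator_config(18, 5, 18)
  st <- tnt_start(patient_record("P1", "NEW"), cfg)
  expect_error(
    tnt_receive_sample(st, blood_gas(7.4, 55, 92, taken_at = 0, on_niv = TRUE)),
    class = "nivflow_protocol_error")
  st <- tnt_receive_sample(st, blood_gas(7.38, 58, 91, taken_at = 0,
                                         on_niv = FALSE))
  expect_equal(st$phase, "NIGHT_BGA_1")
  expect_error(
    tnt_receive_sample(st, blood_gas(7.4, 55, 92, taken_at = 240,
                                     on_niv = FALSE)),
    class = "nivflow_protocol_error")
})

test_that("night samples pass through the day-time safety rules", {
  cfg <- ventilator_config(18, 5, 18)
  st <- tnt_start(patient_record("P1", "NEW"), cfg)
  st <- tnt_receive_sample(st, blood_gas(7.38, 58, 91, taken_at = 0,
                                         on_niv = FALSE))
  ab <- tnt_receive_sample(st, blood_gas(7.33, 60, 92, taken_at = 240,
                                         on_niv = TRUE))
  expect_equal(ab$phase, "ABORTED")

  pz <- tnt_receive_sample(st, blood_gas(7.60, 35, 95, taken_at = 240,
                                         on_niv = TRUE))
  expect_equal(pz$phase, "PAUSED_ALKALOSIS")
  expect_equal(pz$pause_until, 270)
  res <- tnt_resume_after_pause(pz, blood_gas(7.45, 45, 95, taken_at = 270),
                                TRUE)
  expect_equal(res$phase, "NIGHT_BGA_1")       # retake the interrupted sample
  expect_equal(res$config$ipap, 16L)           # lowered by one step
  expect_true(res$changed_overnight)
})

test_that("two safe night samples lead to the morning evaluation with questions", {
  f <- tnt_fixture()
  expect_equal(f$state$phase, "MORNING_EVALUATION")
  qs <- Filter(function(e) e$kind == "QUESTION_ASKED", f$state$pending_events)
  expect_equal(vapply(qs, function(e) e$payload$item, ""), c("Q1", "Q2", "Q3"))
})

test_that("morning evaluation routes to the three outcomes", {
  settings <- niv_protocol()

  # adequate PaCO2, satisfied patient -> discharge
  f <- tnt_fixture(paco2_night = c(48, 44))
  a <- tnt_evaluate(f$state, f$record, satisfied_answers(), settings)
  expect_equal(a$option, "A_DISCHARGE")
  expect_equal(a$rationale, "SATISFIED_AND_ADEQUATE")
  expect_equal(a$final_config$ipap, 18L)

  # improving trend counts as adequate: chart lowest 55, previous 49,
  # current 48 satisfies both criteria
  f <- tnt_fixture(paco2_night = c(49, 48), baseline = 55)
  a2 <- tnt_evaluate(f$state, f$record, satisfied_answers(), settings)
  expect_equal(a2$paco2_verdict$verdict, "IMPROVING_TREND")
  expect_equal(a2$option, "A_DISCHARGE")

  # satisfied pressure but rise-time complaint -> option B, rise level bumped
  f <- tnt_fixture(paco2_night = c(48, 44))
  b <- tnt_evaluate(f$state, f$record,
                    questionnaire_response("ENOUGH", "TOO_FAST", FALSE),
                    settings)
  expect_equal(b$option, "B_REPEAT_TNT")
  expect_equal(b$final_config$rise_time_level, 4L)
  expect_equal(b$final_config$ipap, 18L)
  expect_true("PATIENT_DISSATISFIED" %in% b$rationale)

  # Q1 too little -> inspiratory pressure must change -> option C
  f <- tnt_fixture(paco2_night = c(48, 44))
  cc <- tnt_evaluate(f$state, f$record,
                     questionnaire_response("TOO_LITTLE", "ADEQUATE", FALSE),
                     settings)
  expect_equal(cc$option, "C_REPEAT_TDT_AND_TNT")
  expect_equal(cc$final_config$ipap, 20L)
  expect_true("PRESSURE_CHANGED" %in% cc$rationale)

  # hypercapnia needing adjustment maps to pressure -> option C
  f <- tnt_fixture(paco2_night = c(53, 52))
  c2 <- tnt_evaluate(f$state, f$record, satisfied_answers(), settings)
  expect_equal(c2$option, "C_REPEAT_TDT_AND_TNT")
  expect_true(all(c("PACO2_NEEDS_ADJUSTMENT", "PRESSURE_CHANGED") %in%
                    c2$rationale))
})

test_that("evaluation demands both night samples and the right Q4 presence", {
  cfg <- ventilator_config(18, 5, 18)
  st <- tnt_start(patient_record("P1", "NEW"), cfg)
  rec <- patient_record("P1", "NEW")
  expect_error(tnt_evaluate(st, rec, satisfied_answers()),
               class = "nivflow_protocol_error")
  f <- tnt_fixture()
  expect_error(tnt_evaluate(f$state, f$record, satisfied_answers(q4 = TRUE)),
               class = "nivflow_protocol_error")
})

test_that("the outcome map is total and option A is exactly adequacy + satisfaction", {
  settings <- niv_protocol()
  # paco2 values hitting each verdict against chart lowest 58, previous 50
  paco2_cases <- c(44, 48, 52)   # ADEQUATE / (45,50] trend / above interval
  q1s <- c("ENOUGH", "TOO_MUCH", "TOO_LITTLE")
  q2s <- c("ADEQUATE", "TOO_FAST", "TOO_SLOW")
  for (paco2 in paco2_cases) for (q1 in q1s) for (q2 in q2s)
    for (q3 in c(FALSE, TRUE)) {
      f <- tnt_fixture(paco2_night = c(50, paco2))
      ans <- questionnaire_response(q1, q2, q3)
      out <- tnt_evaluate(f$state, f$record, ans, settings)
      expect_true(out$option %in% c("A_DISCHARGE", "B_REPEAT_TNT",
                                    "C_REPEAT_TDT_AND_TNT"))
      satisfied <- q1 == "ENOUGH" && q2 == "ADEQUATE" && !q3
      pv <- out$paco2_verdict$verdict
      expect_equal(out$option == "A_DISCHARGE",
                   satisfied && pv %in% c("ADEQUATE", "IMPROVING_TREND"),
                   info = sprintf("paco2=%g q1=%s q2=%s q3=%s pv=%s",
                                  paco2, q1, q2, q3, pv))
      # option C exactly when the recommended IPAP differs
      expect_equal(out$option == "C_REPEAT_TDT_AND_TNT",
                   out$final_config$ipap != f$state$config$ipap)
      if (out$option == "A_DISCHARGE") {
        expect_equal(out$rationale, "SATISFIED_AND_ADEQUATE")
      }
      if (out$option == "C_REPEAT_TDT_AND_TNT") {
        expect_true("PRESSURE_CHANGED" %in% out$rationale)
      }
    }
})
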