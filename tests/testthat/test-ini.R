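ini_at_questions <- function(settings = niv_protocol()) {
  st <- ini_start(patient_record("P1", "NEW"), settings)
  nivflow:::ini_on_clock(st, clock = settings$ini_ventilation_minutes, settings)
}

test_that("INI starts a new patient on the initial configuration for 5 minutes", {
  st <- ini_start(patient_record("P1", "NEW"))
  expect_equal(st$phase, "VENTILATING")
  expect_equal(st$config$ipap, 16L)
  expect_equal(st$config$epap, 5L)
  expect_equal(st$config$backup_rate, 18L)
  recs <- Filter(function(e) e$kind == "RECOMMENDATION", st$pending_events)
  expect_equal(recs[[1]]$payload$duration_minutes, 5)
  expect_match(recs[[1]]$payload$text, "mask")
})

test_that("INI refuses recurring patients", {
  rec <- patient_record("P2", "RECURRING",
                        stored_night_config = default_initial_config())
  expect_error(ini_start(rec), class = "nivflow_protocol_error")
})

test_that("questionnaire answers map to the stated adjustments", {
  st <- ini_at_questions()
  up <- ini_apply_answers(st, questionnaire_response("TOO_LITTLE"))
  expect_equal(up$config$ipap, 18L)
  expect_equal(up$phase, "VENTILATING")
  expect_true(up$expects_q4)

  down <- ini_apply_answers(st, questionnaire_response("TOO_MUCH"))
  expect_equal(down$config$ipap, 14L)

  fast <- ini_apply_answers(st, questionnaire_response("ENOUGH", "TOO_FAST"))
  expect_equal(fast$config$rise_time_level, 4L)
  slow <- ini_apply_answers(st, questionnaire_response("ENOUGH", "TOO_SLOW"))
  expect_equal(slow$config$rise_time_level, 2L)

  trig <- ini_apply_answers(st, questionnaire_response("ENOUGH", "ADEQUATE", TRUE))
  expect_equal(trig$config$trigger_level, 2L)
})

test_that("a fully satisfied first pass terminates INI with the default config", {
  st <- ini_at_questions()
  done <- ini_apply_answers(st, satisfied_answers())
  expect_equal(done$phase, "DONE")
  expect_equal(done$config$ipap, 16L)
  expect_equal(done$config$rise_time_level, 3L)
})

test_that("IPAP saturates at the 20 mbar initiation cap with a cap note", {
  settings <- niv_protocol()
  st <- ini_at_questions(settings)
  for (i in 1:2) {
    st <- ini_apply_answers(st, questionnaire_response(
      "TOO_LITTLE", q4_more_comfortable = if (st$expects_q4) TRUE), settings)
    st <- nivflow:::ini_on_clock(st, st$phase_started_at + 5, settings)
  }
  expect_equal(st$config$ipap, 20L)
  at_cap <- ini_apply_answers(st, questionnaire_response(
    "TOO_LITTLE", q4_more_comfortable = TRUE), settings)
  expect_equal(at_cap$config$ipap, 20L)
  expect_equal(at_cap$phase, "DONE")
  notes <- Filter(function(e) identical(e$payload$note, "CAP_REACHED"),
                  at_cap$pending_events)
  expect_length(notes, 1L)
})

test_that("Q4 'no' reverts the last change and freezes the family", {
  st <- ini_at_questions()
  st <- ini_apply_answers(st, questionnaire_response("TOO_LITTLE"))
  expect_equal(st$config$ipap, 18L)
  st <- nivflow:::ini_on_clock(st, st$phase_started_at + 5, niv_protocol())
  st <- ini_apply_answers(st, questionnaire_response(
    "TOO_LITTLE", q4_more_comfortable = FALSE))
  expect_equal(st$config$ipap, 16L)
  expect_true("pressure" %in% st$frozen)
  # further pressure requests are ignored; satisfied answers finish
  st <- nivflow:::ini_on_clock(st, st$phase_started_at + 5, niv_protocol())
  st2 <- ini_apply_answers(st, questionnaire_response("TOO_LITTLE"))
  expect_equal(st2$config$ipap, 16L)
  expect_equal(st2$phase, "DONE")
})

test_that("answers at the wrong phase are protocol errors, Q4 presence is enforced", {
  st <- ini_start(patient_record("P1", "NEW"))
  expect_error(ini_apply_answers(st, satisfied_answers()),
               class = "nivflow_protocol_error")
  stq <- ini_at_questions()
  expect_error(ini_apply_answers(stq, satisfied_answers(q4 = TRUE)),
               class = "nivflow_protocol_error")
  st2 <- ini_apply_answers(stq, questionnaire_response("TOO_LITTLE"))
  st2 <- nivflow:::ini_on_clock(st2, st2$phase_started_at + 5, niv_protocol())
  expect_error(ini_apply_answers(st2, questionnaire_response("TOO_LITTLE")),
               class = "nivflow_protocol_error")
})

test_that("every INI answer sequence terminates within bounds (exhaustive state search)", {
  # exhaustive over the pressure and trigger families here; the rise-time
  # dimension (structurally symmetric to trigger) joins the full-alphabet
  # walk in the acceptance suite
  walk <- ini_exhaustive_walk(q2s = "ADEQUATE")
  # the reachable state graph is exhausted before the depth bound:
  # every answer sequence terminates
  expect_true(walk$exhausted)
  expect_equal(walk$violations, 0L)
  expect_equal(walk$max_ipap, niv_protocol()$ini_ipap_cap)
  expect_gt(walk$n_states, 100L)
})
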