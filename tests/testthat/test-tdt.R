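tdt_at_questioning <- function(ipap = 16L, settings = niv_protocol()) {
  cfg <- ventilator_config(ipap, 5, 18)
  st <- tdt_start(patient_record("P1", "NEW"), "AFTER_INI", cfg, settings)
  st <- nivflow:::tdt_on_clock(st, 15, settings)
  tdt_receive_bga(st, safe_bga(at = 15), settings, clock = 15)
}

test_that("TDT keeps the incoming configuration and schedules the blood gas at minute 15", {
  cfg <- ventilator_config(18, 5, 18)
  st <- tdt_start(patient_record("P1", "NEW"), "AFTER_INI", cfg)
  expect_equal(st$phase, "VENTILATING")
  expect_equal(st$config$ipap, 18L)
  expect_equal(st$bga_due_at, 15)
  recs <- Filter(function(e) e$kind == "RECOMMENDATION", st$pending_events)
  expect_equal(recs[[1]]$payload$bga_at_minute, 15)
  expect_equal(recs[[1]]$payload$cycle_minutes, 20)
})

test_that("control visits load the stored night configuration", {
  night_cfg <- ventilator_config(22, 6, 16)
  rec <- patient_record("P2", "RECURRING", stored_night_config = night_cfg)
  st <- tdt_start(rec, "CONTROL_VISIT_AFTER_FIRST_NIGHT")
  expect_equal(st$config$ipap, 22L)
  expect_equal(st$config$epap, 6L)
  rec_new <- patient_record("P3", "NEW")
  expect_error(tdt_start(rec_new, "CONTROL_VISIT_AFTER_FIRST_NIGHT"),
               class = "nivflow_configuration_error")
})

test_that("unsafe blood gases abort with a physician-call recommendation", {
  cfg <- ventilator_config(16, 5, 18)
  st <- tdt_start(patient_record("P1", "NEW"), "AFTER_INI", cfg)
  st <- nivflow:::tdt_on_clock(st, 15, niv_protocol())
  ab <- tdt_receive_bga(st, blood_gas(7.30, 60, 93, taken_at = 15))
  expect_equal(ab$phase, "ABORTED")
  recs <- Filter(function(e) e$kind == "RECOMMENDATION" &&
                   grepl("physician", e$payload$text), ab$pending_events)
  expect_gte(length(recs), 1L)
})

test_that("alkalosis pauses for 30 minutes and restart lowers IPAP by exactly 2 mbar", {
  cfg <- ventilator_config(18, 5, 18)
  st <- tdt_start(patient_record("P1", "NEW"), "AFTER_INI", cfg)
  st <- nivflow:::tdt_on_clock(st, 15, niv_protocol())
  st <- tdt_receive_bga(st, blood_gas(7.60, 35, 95, taken_at = 15))
  expect_equal(st$phase, "PAUSED_ALKALOSIS")
  expect_equal(st$pause_until, 45)

  # resuming early is a protocol error naming the remaining minutes
  expect_error(
    tdt_resume_after_pause(st, blood_gas(7.45, 45, 95, taken_at = 30), TRUE),
    regexp = "15 minutes remaining", class = "nivflow_protocol_error")

  ok <- tdt_resume_after_pause(st, blood_gas(7.50, 45, 95, taken_at = 45), TRUE)
  expect_equal(ok$phase, "VENTILATING")
  expect_equal(ok$config$ipap, 16L)
  expect_equal(ok$bga_due_at, 60)

  # persisting alkalosis, or a declining patient, aborts
  bad <- tdt_resume_after_pause(st, blood_gas(7.58, 38, 95, taken_at = 45), TRUE)
  expect_equal(bad$phase, "ABORTED")
  declined <- tdt_resume_after_pause(st, blood_gas(7.50, 45, 95, taken_at = 45),
                                     FALSE)
  expect_equal(declined$phase, "ABORTED")
})

test_that("Q1 drives the pressure titration with the stated cycle cap", {
  settings <- niv_protocol()
  st <- tdt_at_questioning(16L, settings)

  done <- tdt_apply_q1(st, questionnaire_response("ENOUGH"))
  expect_equal(done$phase, "DONE")
  expect_equal(done$cycle_count, 0L)

  # always "too little", always approving: exactly 3 adjustment cycles
  st2 <- st
  cycles <- 0L
  while (st2$phase != "DONE") {
    st2 <- tdt_apply_q1(st2, questionnaire_response("TOO_LITTLE"), TRUE,
                        settings)
    if (st2$phase == "VENTILATING") {
      st2 <- nivflow:::tdt_on_clock(st2, st2$bga_due_at, settings)
      st2 <- tdt_receive_bga(st2, safe_bga(at = st2$bga_due_at), settings,
                             clock = st2$bga_due_at)
    }
    cycles <- cycles + 1L
  }
  expect_equal(st2$cycle_count, 3L)
  expect_equal(st2$config$ipap, 22L)

  # declining another cycle stops after the change
  st3 <- tdt_apply_q1(st, questionnaire_response("TOO_LITTLE"), FALSE, settings)
  expect_equal(st3$phase, "DONE")
  expect_equal(st3$config$ipap, 18L)
  expect_equal(st3$cycle_count, 1L)
})

test_that("pressure reduction floors at EPAP plus the minimum gap", {
  st <- tdt_at_questioning(8L)
  dn <- tdt_apply_q1(st, questionnaire_response("TOO_MUCH"), TRUE)
  expect_equal(dn$config$ipap, 7L)   # epap 5 + gap 2
  expect_equal(dn$phase, "VENTILATING")
  # at the floor no change is possible: terminate rather than loop
  st7 <- tdt_at_questioning(7L)
  done <- tdt_apply_q1(st7, questionnaire_response("TOO_MUCH"), TRUE)
  expect_equal(done$config$ipap, 7L)
  expect_equal(done$phase, "DONE")
})

test_that("answers or samples at the wrong phase are protocol errors", {
  cfg <- ventilator_config(16, 5, 18)
  st <- tdt_start(patient_record("P1", "NEW"), "AFTER_INI", cfg)
  expect_error(tdt_apply_q1(st, questionnaire_response("ENOUGH")),
               class = "nivflow_protocol_error")
  stq <- tdt_at_questioning()
  expect_error(tdt_receive_bga(stq, safe_bga(at = 99)),
               class = "nivflow_protocol_error")
  expect_error(tdt_resume_after_pause(stq, safe_bga(at = 99), TRUE),
               class = "nivflow_protocol_error")
})

test_that("every TDT answer/approval/gas sequence terminates; cycles never exceed 3 (exhaustive walk)", {
  walk <- tdt_exhaustive_walk()
  expect_equal(walk$unfinished, 0L)
  expect_equal(walk$violations, 0L)
  expect_equal(walk$max_cycles, 3L)
  expect_gt(walk$paths, 50L)
})
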