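test_that("routing follows patient status", {
  expect_equal(route_patient(patient_record("P1", "NEW")), "INI")
  rec <- patient_record("P2", "RECURRING",
                        stored_night_config = default_initial_config())
  expect_equal(route_patient(rec), "TNT")
})

test_that("a new-patient session runs INI -> TDT -> TNT and discharges", {
  s <- session_at_tnt_baseline()
  expect_equal(s$active_process, "TNT")
  # the whole night, satisfied patient, adequate gases
  s <- advance(s, input_bga(7.38, 58, 91, on_niv = FALSE))
  s <- advance(s, input_advance(240))
  s <- advance(s, input_bga(7.42, 49, 93))
  s <- advance(s, input_advance(240))
  s <- advance(s, input_bga(7.44, 44, 93))
  s <- advance(s, input_answers(satisfied_answers()))
  expect_equal(s$disposition, "DISCHARGED")
  expect_null(s$active_process)
  expect_equal(s$nights_completed, 1L)
  # discharge stores the night configuration and flips status
  expect_equal(s$record$status, "RECURRING")
  expect_equal(s$record$stored_night_config$ipap, 16L)
  # process sequence
  procs <- rle(vapply(Filter(function(e) e$process != "ENGINE", s$events),
                      function(e) e$process, ""))$values
  expect_equal(procs, c("INI", "TDT", "TNT"))
})

test_that("recurring patients start at TNT; control-visit override starts TDT", {
  rec <- patient_record("P2", "RECURRING",
                        stored_night_config = ventilator_config(20, 6, 16))
  s <- new_session(rec)
  expect_equal(s$active_process, "TNT")
  expect_equal(s$process_state$config$ipap, 20L)
  s2 <- new_session(rec, entry = "TDT_CONTROL_VISIT")
  expect_equal(s2$active_process, "TDT")
  expect_equal(s2$process_state$entry_path, "CONTROL_VISIT_AFTER_FIRST_NIGHT")
})

test_that("option C routes back through TDT and then TNT", {
  s <- session_at_tnt_baseline()
  s <- advance(s, input_bga(7.38, 58, 91, on_niv = FALSE))
  s <- advance(s, input_advance(480))
  s <- advance(s, input_bga(7.40, 53, 92))
  s <- advance(s, input_bga(7.41, 52, 92))
  s <- advance(s, input_answers(satisfied_answers()))  # needs adjustment -> C
  expect_equal(s$active_process, "TDT")
  expect_equal(s$process_state$entry_path, "AFTER_NIGHT_NEEDING_ADJUSTMENT")
  expect_equal(s$process_state$config$ipap, 18L)
  expect_equal(s$disposition, "IN_PROGRESS")
})

test_that("unsafe gases anywhere end in physician referral in one transition", {
  s <- session_at_tnt_baseline()
  s <- advance(s, input_bga(7.38, 58, 91, on_niv = FALSE))
  s <- advance(s, input_advance(240))
  n_ev <- length(s$events)
  s <- advance(s, input_bga(7.30, 62, 92))
  expect_equal(s$disposition, "ABORTED_PHYSICIAN")
  expect_error(advance(s, input_advance(10)),
               class = "nivflow_protocol_error")
})

test_that("the alkalosis pause blocks early rechecks and the engine buffers approval", {
  s <- session_at_tnt_baseline()
  s <- advance(s, input_bga(7.38, 58, 91, on_niv = FALSE))
  s <- advance(s, input_advance(240))
  s <- advance(s, input_bga(7.60, 35, 95))
  expect_equal(s$process_state$phase, "PAUSED_ALKALOSIS")
  expect_error(advance(s, input_bga(7.45, 45, 95)),
               regexp = "minutes remaining", class = "nivflow_protocol_error")
  s <- advance(s, input_advance(30))
  s <- advance(s, input_bga(7.45, 45, 95))
  s <- advance(s, input_approval(TRUE))
  expect_equal(s$process_state$phase, "NIGHT_BGA_1")
  expect_equal(s$process_state$config$ipap, 14L)
})

test_that("inadmissible inputs are protocol errors naming what is expected", {
  s <- new_session(patient_record("P1", "NEW"))
  expect_error(advance(s, input_bga(7.4, 50, 92)),
               regexp = "clock advance", class = "nivflow_protocol_error")
  expect_error(advance(s, input_approval(TRUE)),
               class = "nivflow_protocol_error")
  expect_error(input_advance(-5), class = "nivflow_input_error")
})

test_that("advance is a pure step function: the input session is unmodified", {
  s <- new_session(patient_record("P1", "NEW"))
  before <- session_json(s)
  s2 <- advance(s, input_advance(5))
  expect_equal(session_json(s), before)
  expect_gt(length(s2$events), length(s$events))
})

test_that("event sequence numbers are contiguous from 1", {
  s <- session_at_tnt_baseline()
  seqs <- vapply(s$events, function(e) e$seq, integer(1))
  expect_equal(seqs, seq_along(seqs))
})

test_that("an insatiable always-approving patient is escalated, never looped", {
  p <- virtual_patient("VPX", comfort_policy = "WANTS_MORE_PRESSURE",
                       ipap_target = 60L, co2_sensitivity = 0,
                       noise_sd_paco2 = 0, noise_sd_ph = 0,
                       baseline_paco2 = 46, rng_seed = 5)
  run <- run_virtual_patient(p)
  expect_equal(run$session$disposition, "ABORTED_PHYSICIAN")
  expect_lte(run$session$nights_completed, niv_protocol()$max_tnt_nights)
})
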