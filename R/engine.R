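# Session engine: orchestrates INI -> TDT -> TNT for new patients and
# TNT(-centred) follow-up for recurring patients, owns the abstract minute
# clock and the append-only audit log, and is a pure step function over
# (session, input) so sessions replay deterministically.

#' Route a patient to their first process
#'
#' Every new patient undergoes first initiation (INI) before day-time (TDT)
#' and night-time (TNT) titration; a recurring patient goes straight to
#' night-time titration on the stored configuration.
#'
#' @param record A [patient_record()].
#' @return `"INI"` or `"TNT"`.
#' @examples
#' route_patient(patient_record("P1", "NEW"))
#' @export
route_patient <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  if (record$status == "NEW") return("INI")
  if (is.null(record$stored_night_config)) {
    abort_config("a recurring patient needs a stored night-time configuration to route to TNT")
  }
  "TNT"
}

#' Open a titration session
#'
#' Creates a session around a patient record, routes to the first process,
#' and starts it at clock minute 0. The session records every external
#' input it consumes, so [replay_session()] can reproduce it exactly.
#'
#' @param record A [patient_record()].
#' @param settings A [niv_protocol()].
#' @param session_id Identifier string; defaults to one derived from the
#'   patient id.
#' @param entry `"AUTO"` follows the standard routing; recurring patients
#'   may instead be sent to a day-time control visit with
#'   `"TDT_CONTROL_VISIT"`.
#' @return A `niv_session`.
#' @examples
#' s <- new_session(patient_record("P1", "NEW"))
#' s$active_process
#' @export
new_session <- function(record, settings = niv_protocol(),
                        session_id = paste0("session-", record$patient_id),
                        entry = c("AUTO", "TDT_CONTROL_VISIT")) {
  entry <- match.arg(entry)
  stopifnot(inherits(record, "patient_record"),
            inherits(settings, "niv_protocol"))
  session <- structure(
    list(session_id = session_id, record = record, initial_record = record,
         settings = settings, entry = entry, clock = 0,
         active_process = NULL, process_state = NULL,
         disposition = "IN_PROGRESS", events = list(), inputs = list(),
         next_seq = 1L, pending = list(), nights_completed = 0L),
    class = "niv_session"
  )
  if (entry == "TDT_CONTROL_VISIT") {
    if (record$status != "RECURRING") {
      abort_config("the day-time control visit entry is for recurring patients")
    }
    st <- tdt_start(record, "CONTROL_VISIT_AFTER_FIRST_NIGHT",
                    settings = settings, clock = 0)
    session <- install_process(session, "TDT", st)
  } else if (route_patient(record) == "INI") {
    session <- install_process(session, "INI",
                               ini_start(record, settings, clock = 0))
  } else {
    session <- install_process(session, "TNT",
                               tnt_start(record, record$stored_night_config,
                                         settings, clock = 0))
  }
  session
}

install_process <- function(session, name, state) {
  session$active_process <- name
  session <- absorb_events(session, state, name)
  session
}

# drain a state's queued events into the session log, stamping seq and clock
absorb_events <- function(session, state, process = session$active_process) {
  d <- drain_events(state)
  for (ev in d$events) {
    session$events <- c(session$events, list(list(
      seq = session$next_seq, at = session$clock, process = process,
      kind = ev$kind, payload = ev$payload)))
    session$next_seq <- session$next_seq + 1L
  }
  session$process_state <- d$state
  session
}

engine_event <- function(session, kind, payload = list()) {
  session$events <- c(session$events, list(list(
    seq = session$next_seq, at = session$clock, process = "ENGINE",
    kind = kind, payload = payload)))
  session$next_seq <- session$next_seq + 1L
  session
}

## ---- external inputs -------------------------------------------------

#' External inputs accepted by [advance()]
#'
#' A session advances only through explicit external inputs: clock
#' advancement in minutes, a blood-gas measurement, questionnaire answers,
#' or a patient approval. `input_bga()` leaves `on_niv` unset by default,
#' in which case the engine infers it from the phase (off NIV for the
#' nocturnal baseline, on NIV elsewhere).
#'
#' @param minutes Positive number of minutes to advance the session clock.
#' @return A `niv_input` object.
#' @export
input_advance <- function(minutes) {
  if (!is_count1(minutes) || minutes <= 0) {
    abort_input("the clock only moves forward: minutes must be positive")
  }
  structure(list(kind = "advance", minutes = as.numeric(minutes)),
            class = "niv_input")
}

#' @rdname input_advance
#' @inheritParams blood_gas
#' @export
input_bga <- function(ph, paco2, spo2, on_niv = NULL,
                      source = c("arterial", "ptcco2")) {
  source <- match.arg(source)
  # validate eagerly so bad values fail before touching the session
  blood_gas(ph, paco2, spo2, taken_at = 0, on_niv = isTRUE(on_niv),
            source = source)
  structure(list(kind = "bga", ph = ph, paco2 = paco2, spo2 = spo2,
                 on_niv = on_niv, source = source),
            class = "niv_input")
}

#' @rdname input_advance
#' @param answers A [questionnaire_response()].
#' @export
input_answers <- function(answers) {
  stopifnot(inherits(answers, "questionnaire_response"))
  structure(list(kind = "answers", answers = answers), class = "niv_input")
}

#' @rdname input_advance
#' @param value Logical approval.
#' @export
input_approval <- function(value) {
  if (!is.logical(value) || length(value) != 1L || is.na(value)) {
    abort_input("approval must be TRUE or FALSE")
  }
  structure(list(kind = "approval", value = value), class = "niv_input")
}

input_to_plain <- function(input) {
  if (input$kind == "answers") {
    a <- input$answers
    list(kind = "answers", q1 = a$q1_air_amount, q2 = a$q2_air_speed,
         q3 = a$q3_trigger_exhausting, q4 = a$q4_more_comfortable)
  } else {
    unclass(input)
  }
}

plain_to_input <- function(x) {
  switch(x$kind,
    advance = input_advance(x$minutes),
    bga = input_bga(x$ph, x$paco2, x$spo2, on_niv = x$on_niv,
                    source = x$source %||% "arterial"),
    answers = input_answers(questionnaire_response(
      x$q1, x$q2, x$q3, x$q4)),
    approval = input_approval(x$value),
    abort_input(sprintf("unknown input kind '%s'", x$kind))
  )
}

## ---- the step function ----------------------------------------------

#' Advance a session by one external input
#'
#' The single step function of the engine: takes the current session and
#' one [input_advance()]/[input_bga()]/[input_answers()]/[input_approval()]
#' and returns the next session. The input session is never modified.
#' Process hand-offs happen automatically: INI completion starts day-time
#' titration with the optimised configuration, day-time completion starts
#' the night, and the morning evaluation routes to discharge, another
#' night, or back through day-time titration.
#'
#' @param session A `niv_session` with disposition `"IN_PROGRESS"`.
#' @param input A `niv_input`.
#' @return The next `niv_session`.
#' @export
advance <- function(session, input) {
  stopifnot(inherits(session, "niv_session"), inherits(input, "niv_input"))
  if (session$disposition != "IN_PROGRESS") {
    abort_protocol(sprintf("session already terminated with disposition %s",
                           session$disposition))
  }
  session$inputs <- c(session$inputs, list(input_to_plain(input)))
  switch(input$kind,
    advance = step_clock(session, input$minutes),
    bga = step_bga(session, input),
    answers = step_answers(session, input$answers),
    approval = step_approval(session, input$value),
    abort_input("unknown input kind")
  )
}

step_clock <- function(session, minutes) {
  session$clock <- session$clock + minutes
  st <- session$process_state
  settings <- session$settings
  st2 <- switch(session$active_process,
                INI = ini_on_clock(st, session$clock, settings),
                TDT = tdt_on_clock(st, session$clock, settings),
                TNT = st)
  absorb_events(session, st2)
}

expected_inputs <- function(session) {
  st <- session$process_state
  switch(session$active_process,
    INI = if (st$phase == "QUESTIONING") "questionnaire answers"
          else "clock advance",
    TDT = switch(st$phase,
      VENTILATING = "clock advance",
      AWAITING_BGA = "a blood gas",
      PAUSED_ALKALOSIS = if (is.null(session$pending$recheck))
        "clock advance then a recheck blood gas" else "an approval",
      QUESTIONING = if (is.null(session$pending$answers))
        "questionnaire answers" else "an approval for another cycle",
      "none"),
    TNT = switch(st$phase,
      BASELINE_BGA = "an off-NIV baseline blood gas",
      NIGHT_BGA_1 = , NIGHT_BGA_2 = "an on-NIV blood gas (advance the clock as the night progresses)",
      PAUSED_ALKALOSIS = if (is.null(session$pending$recheck))
        "clock advance then a recheck blood gas" else "an approval",
      MORNING_EVALUATION = "questionnaire answers",
      "none")
  )
}

reject_input <- function(session, got) {
  abort_protocol(sprintf("%s not admissible in %s phase %s; expected %s",
                         got, session$active_process,
                         session$process_state$phase,
                         expected_inputs(session)))
}

materialise_sample <- function(session, input, default_on_niv) {
  on_niv <- input$on_niv %||% default_on_niv
  blood_gas(input$ph, input$paco2, input$spo2, taken_at = session$clock,
            on_niv = on_niv, source = input$source)
}

step_bga <- function(session, input) {
  st <- session$process_state
  settings <- session$settings
  proc <- session$active_process
  if (proc == "INI") reject_input(session, "a blood gas")

  if (st$phase == "PAUSED_ALKALOSIS") {
    if (session$clock < st$pause_until) {
      abort_protocol(sprintf("the pause has %g minutes remaining",
                             st$pause_until - session$clock))
    }
    sample <- materialise_sample(session, input, default_on_niv = FALSE)
    session$pending$recheck <- sample
    session <- engine_event(session, "MEASUREMENT_RECORDED",
                            c(sample_payload(sample), list(recheck = TRUE)))
    session <- engine_event(session, "RECOMMENDATION",
                            list(text = "Recheck recorded; does the patient approve restarting ventilation?"))
    return(session)
  }

  if (proc == "TDT") {
    if (!st$phase %in% c("AWAITING_BGA", "VENTILATING")) {
      reject_input(session, "a blood gas")
    }
    sample <- materialise_sample(session, input, default_on_niv = TRUE)
    session$record <- update_paco2_history(session$record, sample)
    st2 <- tdt_receive_bga(st, sample, settings, clock = session$clock)
    session <- absorb_events(session, st2)
    return(finalise_process(session))
  }

  # TNT
  if (!st$phase %in% c("BASELINE_BGA", "NIGHT_BGA_1", "NIGHT_BGA_2")) {
    reject_input(session, "a blood gas")
  }
  sample <- materialise_sample(session, input,
                               default_on_niv = st$phase != "BASELINE_BGA")
  st2 <- tnt_receive_sample(st, sample, settings, clock = session$clock)
  session$record <- update_paco2_history(session$record, sample)
  session <- absorb_events(session, st2)
  finalise_process(session)
}

step_answers <- function(session, answers) {
  st <- session$process_state
  settings <- session$settings
  switch(session$active_process,
    INI = {
      if (st$phase != "QUESTIONING") reject_input(session, "questionnaire answers")
      st2 <- ini_apply_answers(st, answers, settings, clock = session$clock)
      finalise_process(absorb_events(session, st2))
    },
    TDT = {
      if (st$phase != "QUESTIONING" || !is.null(session$pending$answers)) {
        reject_input(session, "questionnaire answers")
      }
      if (answers$q1_air_amount == "ENOUGH") {
        st2 <- tdt_apply_q1(st, answers, TRUE, settings, clock = session$clock)
        finalise_process(absorb_events(session, st2))
      } else {
        session$pending$answers <- answers
        engine_event(session, "RECOMMENDATION",
                     list(text = "Adjustment indicated; does the patient approve another ventilation cycle?"))
      }
    },
    TNT = {
      if (st$phase != "MORNING_EVALUATION") reject_input(session, "questionnaire answers")
      outcome <- tnt_evaluate(st, session$record, answers, settings)
      session <- absorb_events(session, attr(outcome, "state"))
      handle_tnt_outcome(session, outcome)
    }
  )
}

step_approval <- function(session, value) {
  st <- session$process_state
  settings <- session$settings
  if (!is.null(session$pending$recheck) && st$phase == "PAUSED_ALKALOSIS") {
    recheck <- session$pending$recheck
    session$pending$recheck <- NULL
    st2 <- if (session$active_process == "TDT") {
      tdt_resume_after_pause(st, recheck, value, settings, clock = session$clock)
    } else {
      tnt_resume_after_pause(st, recheck, value, settings, clock = session$clock)
    }
    return(finalise_process(absorb_events(session, st2)))
  }
  if (session$active_process == "TDT" && st$phase == "QUESTIONING" &&
      !is.null(session$pending$answers)) {
    answers <- session$pending$answers
    session$pending$answers <- NULL
    st2 <- tdt_apply_q1(st, answers, value, settings, clock = session$clock)
    return(finalise_process(absorb_events(session, st2)))
  }
  reject_input(session, "an approval")
}

# after any process step: hand off on DONE, settle dispositions on ABORTED
finalise_process <- function(session) {
  st <- session$process_state
  settings <- session$settings
  if (st$phase == "ABORTED") {
    session$disposition <- "ABORTED_PHYSICIAN"
    session$active_process <- NULL
    session <- engine_event(session, "TERMINATED",
                            list(disposition = "ABORTED_PHYSICIAN"))
    return(session)
  }
  if (session$active_process == "INI" && st$phase == "DONE") {
    session <- engine_event(session, "RECOMMENDATION",
                            list(text = "Starting day-time titration with the initiation configuration"))
    st2 <- tdt_start(session$record, "AFTER_INI", st$config, settings,
                     clock = session$clock)
    return(install_process(session, "TDT", st2))
  }
  if (session$active_process == "TDT" && st$phase == "DONE") {
    session <- engine_event(session, "RECOMMENDATION",
                            list(text = "Starting night-time titration with the day-time configuration"))
    st2 <- tnt_start(session$record, st$config, settings, clock = session$clock)
    return(install_process(session, "TNT", st2))
  }
  session
}

handle_tnt_outcome <- function(session, outcome) {
  settings <- session$settings
  night_config <- session$process_state$config
  session$nights_completed <- session$nights_completed + 1L

  if (outcome$option == "A_DISCHARGE") {
    session$record$stored_night_config <- outcome$final_config
    session$record$status <- "RECURRING"
    session$disposition <- "DISCHARGED"
    session$active_process <- NULL
    session <- engine_event(session, "TERMINATED",
                            list(disposition = "DISCHARGED",
                                 nights = session$nights_completed))
    return(session)
  }

  # convergence safeguards: identical recommendation, or too many nights,
  # escalates to a physician rather than looping
  exhausted <- config_equal(outcome$final_config, night_config)
  over_cap <- session$nights_completed >= settings$max_tnt_nights
  if (exhausted || over_cap) {
    reason <- if (exhausted) "RECOMMENDATIONS_EXHAUSTED" else "NIGHT_LIMIT_REACHED"
    session$disposition <- "ABORTED_PHYSICIAN"
    session$active_process <- NULL
    session <- engine_event(session, "RECOMMENDATION", list(
      text = "Titration is not converging under the protocol rules; refer the patient to a physician",
      reason = reason))
    session <- engine_event(session, "TERMINATED",
                            list(disposition = "ABORTED_PHYSICIAN",
                                 reason = reason))
    return(session)
  }

  if (outcome$option == "B_REPEAT_TNT") {
    st2 <- tnt_start(session$record, outcome$final_config, settings,
                     clock = session$clock)
    return(install_process(session, "TNT", st2))
  }
  # option C: repeat day-time then night-time titration
  st2 <- tdt_start(session$record, "AFTER_NIGHT_NEEDING_ADJUSTMENT",
                   outcome$final_config, settings, clock = session$clock)
  install_process(session, "TDT", st2)
}

#' Replay a session from its recorded inputs
#'
#' Rebuilds the session from the initial patient record and re-applies
#' every recorded external input through [advance()]. With the engine
#' being a pure step function this reproduces the identical final state
#' and event log.
#'
#' @param session A `niv_session`.
#' @return The replayed `niv_session`.
#' @export
replay_session <- function(session) {
  stopifnot(inherits(session, "niv_session"))
  fresh <- new_session(session$initial_record, session$settings,
                       session_id = session$session_id,
                       entry = session$entry)
  purrr::reduce(session$inputs,
                function(s, x) advance(s, plain_to_input(x)),
                .init = fresh)
}

#' @export
print.niv_session <- function(x, ...) {
  cat(sprintf("<niv_session> %s | patient %s (%s) | clock %g min | %s\n",
              x$session_id, x$record$patient_id, x$record$status,
              x$clock, x$disposition))
  if (!is.null(x$active_process)) {
    cat(sprintf("  active: %s, phase %s, config %s\n", x$active_process,
                x$process_state$phase, format(x$process_state$config)))
  }
  cat(sprintf("  %d events, %d nights completed\n",
              length(x$events), x$nights_completed))
  invisible(x)
}
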