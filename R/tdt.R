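# TDT: titration of NIV during day-time.
#
# 20-minute ventilation cycles with a blood gas drawn at minute 15,
# safety-gated: hypoxemia or acidosis aborts with physician referral;
# alkalosis stops ventilation for 30 minutes, then a recheck blood gas and
# patient approval restart the process with IPAP lowered by 2 mbar.
# Within safe values, the Q1 satisfaction question drives inspiratory
# pressure up or down by one step; the ventilation-and-change cycle repeats
# up to three times if the patient approves.

TDT_ENTRY_PATHS <- c("AFTER_INI", "CONTROL_VISIT_AFTER_FIRST_NIGHT",
                     "AFTER_NIGHT_NEEDING_ADJUSTMENT")

#' Start the day-time titration (TDT) process
#'
#' Follow-up patients (control visit) are ventilated on their stored
#' in-hospital night-time configuration; patients arriving from first
#' initiation or from a night needing adjustment keep the incoming
#' configuration. A blood-gas advisory is scheduled at minute 15 of the
#' 20-minute cycle.
#'
#' @param record A [patient_record()].
#' @param entry_path One of `"AFTER_INI"`,
#'   `"CONTROL_VISIT_AFTER_FIRST_NIGHT"`,
#'   `"AFTER_NIGHT_NEEDING_ADJUSTMENT"`.
#' @param incoming_config The [ventilator_config()] carried into TDT;
#'   ignored for the control-visit path, where the stored night
#'   configuration is loaded.
#' @param settings A [niv_protocol()].
#' @param clock Session-clock minutes at start.
#' @return A `tdt_state`.
#' @export
tdt_start <- function(record, entry_path, incoming_config = NULL,
                      settings = niv_protocol(), clock = 0) {
  stopifnot(inherits(record, "patient_record"))
  entry_path <- match.arg(entry_path, TDT_ENTRY_PATHS)
  config <- if (entry_path == "CONTROL_VISIT_AFTER_FIRST_NIGHT") {
    if (is.null(record$stored_night_config)) {
      abort_config("control-visit entry requires a stored night-time configuration")
    }
    record$stored_night_config
  } else {
    if (is.null(incoming_config)) {
      abort_config(sprintf("entry path %s requires an incoming configuration",
                           entry_path))
    }
    incoming_config
  }
  state <- structure(
    list(process = "TDT", phase = "VENTILATING", config = config,
         cycle_count = 0L, entry_path = entry_path,
         cycle_started_at = clock,
         bga_due_at = clock + settings$tdt_bga_offset_minutes,
         pause_until = NULL, pending_events = list()),
    class = c("tdt_state", "niv_process_state")
  )
  state <- emit(state, "STATE_ENTERED", list(phase = "VENTILATING",
                                             entry_path = entry_path))
  state <- emit(state, "CONFIG_CHANGED", config_payload(config))
  state <- emit(state, "RECOMMENDATION", list(
    text = sprintf("Ventilate for %g minutes; draw a blood gas after %g minutes",
                   settings$tdt_cycle_minutes, settings$tdt_bga_offset_minutes),
    bga_at_minute = settings$tdt_bga_offset_minutes,
    cycle_minutes = settings$tdt_cycle_minutes))
  state
}

tdt_on_clock <- function(state, clock, settings) {
  if (state$phase == "VENTILATING" && clock >= state$bga_due_at) {
    state$phase <- "AWAITING_BGA"
    state <- emit(state, "STATE_ENTERED", list(phase = "AWAITING_BGA"))
    state <- emit(state, "RECOMMENDATION",
                  list(text = "Perform a blood gas analysis now"))
  }
  state
}

#' Feed a day-time blood gas into TDT
#'
#' Applies the safety gate: an abort verdict (hypoxemia or acidosis)
#' terminates the process immediately with advice to call a physician; an
#' alkalosis verdict stops ventilation and pauses the process for 30
#' minutes; otherwise the Q1 satisfaction question is asked.
#'
#' @param state A `tdt_state` awaiting (or still ventilating toward) the
#'   blood gas.
#' @param sample A [blood_gas()].
#' @param settings A [niv_protocol()].
#' @param clock Session-clock minutes.
#' @return The updated `tdt_state`.
#' @export
tdt_receive_bga <- function(state, sample, settings = niv_protocol(),
                            clock = sample$taken_at) {
  stopifnot(inherits(state, "tdt_state"), inherits(sample, "blood_gas"))
  if (!state$phase %in% c("AWAITING_BGA", "VENTILATING")) {
    abort_protocol(sprintf("blood gas submitted in phase %s; expected AWAITING_BGA",
                           state$phase))
  }
  state <- emit(state, "MEASUREMENT_RECORDED", sample_payload(sample))
  sv <- evaluate_safety(sample, settings)
  state <- emit(state, "SAFETY_VERDICT",
                list(verdict = sv$verdict, reasons = as.list(sv$reasons)))
  if (sv$verdict == "ABORT_CALL_PHYSICIAN") {
    state$phase <- "ABORTED"
    state <- emit(state, "RECOMMENDATION", list(
      text = "Process aborted: call a physician immediately",
      reasons = as.list(sv$reasons)))
    state <- emit(state, "TERMINATED", list(outcome = "ABORTED"))
  } else if (sv$verdict == "STOP_AND_PAUSE") {
    state$phase <- "PAUSED_ALKALOSIS"
    state$pause_until <- clock + settings$alkalosis_pause_minutes
    state <- emit(state, "STATE_ENTERED", list(phase = "PAUSED_ALKALOSIS"))
    state <- emit(state, "RECOMMENDATION", list(
      text = sprintf("Alkalosis: stop ventilation and pause for %g minutes, then repeat the blood gas",
                     settings$alkalosis_pause_minutes),
      pause_minutes = settings$alkalosis_pause_minutes))
  } else {
    state$phase <- "QUESTIONING"
    state <- emit(state, "STATE_ENTERED", list(phase = "QUESTIONING"))
    qi <- questionnaire_items()
    state <- emit(state, "QUESTION_ASKED",
                  list(item = "Q1", text = qi$text[qi$item == "Q1"]))
  }
  state
}

#' Resume (or abort) TDT after an alkalosis pause
#'
#' Requires the pause to have elapsed and a fresh recheck blood gas. If the
#' alkalosis has disappeared (pH at or below 7.55) and the patient
#' approves, ventilation restarts with IPAP lowered by 2 mbar (never below
#' EPAP plus the minimum gap) on a fresh 20-minute cycle; otherwise the
#' process is aborted.
#'
#' @param state A `tdt_state` in phase `"PAUSED_ALKALOSIS"`.
#' @param recheck The recheck [blood_gas()].
#' @param patient_approves Logical consent to restart.
#' @param settings A [niv_protocol()].
#' @param clock Session-clock minutes.
#' @return The updated `tdt_state`.
#' @export
tdt_resume_after_pause <- function(state, recheck, patient_approves,
                                   settings = niv_protocol(),
                                   clock = recheck$taken_at) {
  stopifnot(inherits(state, "tdt_state"), inherits(recheck, "blood_gas"))
  if (state$phase != "PAUSED_ALKALOSIS") {
    abort_protocol(sprintf("resume requested in phase %s; expected PAUSED_ALKALOSIS",
                           state$phase))
  }
  if (clock < state$pause_until) {
    abort_protocol(sprintf("the pause has %g minutes remaining",
                           state$pause_until - clock))
  }
  state <- emit(state, "MEASUREMENT_RECORDED", sample_payload(recheck))
  if (alkalosis_resolved(recheck, settings) && isTRUE(patient_approves)) {
    old_ipap <- state$config$ipap
    floor_ipap <- state$config$epap + settings$ipap_floor_gap
    state$config <- config_with(state$config,
                                ipap = max(old_ipap - settings$ipap_step, floor_ipap))
    state$phase <- "VENTILATING"
    state$cycle_started_at <- clock
    state$bga_due_at <- clock + settings$tdt_bga_offset_minutes
    state$pause_until <- NULL
    state <- emit(state, "CONFIG_CHANGED",
                  c(config_payload(state$config),
                    list(reason = "POST_ALKALOSIS_IPAP_REDUCTION")))
    state <- emit(state, "STATE_ENTERED", list(phase = "VENTILATING"))
    state <- emit(state, "RECOMMENDATION", list(
      text = sprintf("Alkalosis resolved; restart ventilation at IPAP %d mbar for a fresh %g-minute cycle",
                     state$config$ipap, settings$tdt_cycle_minutes)))
  } else {
    state$phase <- "ABORTED"
    reason <- if (!alkalosis_resolved(recheck, settings)) "ALKALOSIS_PERSISTS"
              else "PATIENT_DECLINED"
    state <- emit(state, "RECOMMENDATION", list(
      text = "Process aborted after alkalosis pause; physician review required",
      reason = reason))
    state <- emit(state, "TERMINATED", list(outcome = "ABORTED"))
  }
  state
}

#' Apply the Q1 satisfaction answer within TDT
#'
#' "Enough" means the inspiratory pressure is optimal: TDT terminates and
#' the patient proceeds to night-time titration. "Too little" raises IPAP
#' by one step (up to the day-time ceiling), "too much" lowers it (floored
#' at EPAP plus the minimum gap). Each actual configuration change counts
#' one cycle; after three cycles, when the patient declines another cycle,
#' or when no further change is possible, TDT terminates with the current
#' configuration.
#'
#' @param state A `tdt_state` in phase `"QUESTIONING"`.
#' @param answers A [questionnaire_response()] (only Q1 is evaluated here).
#' @param patient_approves_another_cycle Logical consent to a further
#'   ventilation-and-change cycle; ignored when Q1 is `"ENOUGH"`.
#' @param settings A [niv_protocol()].
#' @param clock Session-clock minutes.
#' @return The updated `tdt_state`.
#' @export
tdt_apply_q1 <- function(state, answers, patient_approves_another_cycle = TRUE,
                         settings = niv_protocol(),
                         clock = state$cycle_started_at + settings$tdt_cycle_minutes) {
  stopifnot(inherits(state, "tdt_state"),
            inherits(answers, "questionnaire_response"))
  if (state$phase != "QUESTIONING") {
    abort_protocol(sprintf("Q1 answer submitted in phase %s; expected QUESTIONING",
                           state$phase))
  }
  state <- emit(state, "ANSWER_RECORDED",
                list(q1_air_amount = answers$q1_air_amount))
  if (answers$q1_air_amount == "ENOUGH") {
    return(tdt_finish(state, "pressure judged optimal by the patient"))
  }
  old_ipap <- state$config$ipap
  new_ipap <- if (answers$q1_air_amount == "TOO_LITTLE") {
    min(old_ipap + settings$ipap_step, settings$tdt_ipap_cap)
  } else {
    max(old_ipap - settings$ipap_step,
        state$config$epap + settings$ipap_floor_gap)
  }
  if (new_ipap == old_ipap) {
    return(tdt_finish(state, "inspiratory pressure at its limit; no further change possible"))
  }
  state$config <- config_with(state$config, ipap = new_ipap)
  state$cycle_count <- state$cycle_count + 1L
  state <- emit(state, "CONFIG_CHANGED", config_payload(state$config))
  if (state$cycle_count >= settings$tdt_max_cycles) {
    return(tdt_finish(state, sprintf("completed the maximum of %d adjustment cycles",
                                     settings$tdt_max_cycles)))
  }
  if (!isTRUE(patient_approves_another_cycle)) {
    return(tdt_finish(state, "patient declined a further cycle"))
  }
  state$phase <- "VENTILATING"
  state$cycle_started_at <- clock
  state$bga_due_at <- clock + settings$tdt_bga_offset_minutes
  state <- emit(state, "STATE_ENTERED", list(phase = "VENTILATING"))
  state <- emit(state, "RECOMMENDATION", list(
    text = sprintf("Ventilate for %g minutes on the adjusted configuration; blood gas after %g minutes",
                   settings$tdt_cycle_minutes, settings$tdt_bga_offset_minutes)))
  state
}

tdt_finish <- function(state, why) {
  state$phase <- "DONE"
  state <- emit(state, "TERMINATED",
                c(list(outcome = "DONE", reason = why),
                  config_payload(state$config)))
  state <- emit(state, "RECOMMENDATION", list(
    text = "Day-time titration complete; proceed to night-time titration"))
  state
}
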