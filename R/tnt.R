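# TNT: titration of NIV during night time.
#
# The patient stays overnight; ventilation is evaluated by blood gases once
# before the night without NIV (baseline) and twice during the night with
# NIV. Night samples pass through the same safety gate as day-time
# titration (including the alkalosis stop-pause-retry with a 2-mbar IPAP
# reduction). In the morning the questionnaire plus the PaCO2 trend
# criterion route the patient to one of three outcomes: discharge (a),
# repeat the night titration (b), or repeat day-time and night titration
# (c) when the inspiratory pressure has to be adjusted.

#' Start the night-time titration (TNT) process
#'
#' @param record A [patient_record()].
#' @param config The [ventilator_config()] for the night: the day-time
#'   titration output for patients under initiation, or the stored
#'   night-time configuration for recurring patients.
#' @param settings A [niv_protocol()].
#' @param clock Session-clock minutes at start.
#' @return A `tnt_state` in phase `"BASELINE_BGA"` carrying a measurement
#'   plan of one off-NIV and two on-NIV samples.
#' @export
tnt_start <- function(record, config, settings = niv_protocol(), clock = 0) {
  stopifnot(inherits(record, "patient_record"),
            inherits(config, "ventilator_config"))
  state <- structure(
    list(process = "TNT", phase = "BASELINE_BGA", config = config,
         entry_config = config, samples = list(), resume_phase = NULL,
         pause_until = NULL, changed_overnight = FALSE,
         pending_events = list()),
    class = c("tnt_state", "niv_process_state")
  )
  state <- emit(state, "STATE_ENTERED", list(phase = "BASELINE_BGA"))
  state <- emit(state, "RECOMMENDATION", list(
    text = "Overnight stay: draw one blood gas before the night without NIV and two during the night with NIV",
    planned_off_niv_samples = 1L, planned_on_niv_samples = 2L))
  state
}

#' Feed a nocturnal blood-gas sample into TNT
#'
#' The baseline sample (off NIV) is recorded without safety gating of the
#' titration; the two night samples (on NIV) pass through the same safety
#' rules as day-time titration. PtcCO2-derived values enter through the
#' same sample type.
#'
#' @param state A `tnt_state`.
#' @param sample A [blood_gas()] whose `on_niv` flag must match the phase
#'   (baseline off NIV, night samples on NIV).
#' @param settings A [niv_protocol()].
#' @param clock Session-clock minutes.
#' @return The updated `tnt_state`.
#' @export
tnt_receive_sample <- function(state, sample, settings = niv_protocol(),
                               clock = sample$taken_at) {
  stopifnot(inherits(state, "tnt_state"), inherits(sample, "blood_gas"))
  phase <- state$phase
  if (phase == "BASELINE_BGA") {
    if (sample$on_niv) {
      abort_protocol("the baseline sample must be drawn off NIV, before the night")
    }
    state$samples <- c(state$samples, list(sample))
    state <- emit(state, "MEASUREMENT_RECORDED", sample_payload(sample))
    state$phase <- "NIGHT_BGA_1"
    state <- emit(state, "STATE_ENTERED", list(phase = "NIGHT_BGA_1"))
    state <- emit(state, "RECOMMENDATION", list(
      text = "Start night-time ventilation; draw the first on-NIV blood gas during the night"))
    return(state)
  }
  if (!phase %in% c("NIGHT_BGA_1", "NIGHT_BGA_2")) {
    abort_protocol(sprintf("blood gas submitted in phase %s; expected a measurement phase",
                           phase))
  }
  if (!sample$on_niv) {
    abort_protocol("night samples must be drawn on NIV")
  }
  state$samples <- c(state$samples, list(sample))
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
    state$resume_phase <- phase
    state$phase <- "PAUSED_ALKALOSIS"
    state$pause_until <- clock + settings$alkalosis_pause_minutes
    state <- emit(state, "STATE_ENTERED", list(phase = "PAUSED_ALKALOSIS"))
    state <- emit(state, "RECOMMENDATION", list(
      text = sprintf("Alkalosis: stop ventilation and pause for %g minutes, then repeat the blood gas",
                     settings$alkalosis_pause_minutes),
      pause_minutes = settings$alkalosis_pause_minutes))
  } else if (phase == "NIGHT_BGA_1") {
    state$phase <- "NIGHT_BGA_2"
    state <- emit(state, "STATE_ENTERED", list(phase = "NIGHT_BGA_2"))
  } else {
    state$phase <- "MORNING_EVALUATION"
    state <- emit(state, "STATE_ENTERED", list(phase = "MORNING_EVALUATION"))
    qi <- questionnaire_items()
    items <- c("Q1", "Q2", "Q3", if (state$changed_overnight) "Q4")
    for (it in items) {
      state <- emit(state, "QUESTION_ASKED",
                    list(item = it, text = qi$text[qi$item == it]))
    }
  }
  state
}

#' Resume (or abort) TNT after a nocturnal alkalosis pause
#'
#' Same stop-pause-retry contract as day-time titration, applied on the
#' night clock: after the pause, a resolved recheck plus patient approval
#' restarts night ventilation with IPAP lowered by one step, returning to
#' the interrupted measurement phase; otherwise the process aborts.
#'
#' @inheritParams tdt_resume_after_pause
#' @param state A `tnt_state` in phase `"PAUSED_ALKALOSIS"`.
#' @return The updated `tnt_state`.
#' @export
tnt_resume_after_pause <- function(state, recheck, patient_approves,
                                   settings = niv_protocol(),
                                   clock = recheck$taken_at) {
  stopifnot(inherits(state, "tnt_state"), inherits(recheck, "blood_gas"))
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
    floor_ipap <- state$config$epap + settings$ipap_floor_gap
    state$config <- config_with(state$config,
                                ipap = max(state$config$ipap - settings$ipap_step,
                                           floor_ipap))
    state$changed_overnight <- TRUE
    state$phase <- state$resume_phase
    state$resume_phase <- NULL
    state$pause_until <- NULL
    state <- emit(state, "CONFIG_CHANGED",
                  c(config_payload(state$config),
                    list(reason = "POST_ALKALOSIS_IPAP_REDUCTION")))
    state <- emit(state, "STATE_ENTERED", list(phase = state$phase))
    state <- emit(state, "RECOMMENDATION", list(
      text = sprintf("Alkalosis resolved; resume night ventilation at IPAP %d mbar and repeat the measurement",
                     state$config$ipap)))
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

#' Morning evaluation of the night: route to one of three outcomes
#'
#' Combines the PaCO2 trend verdict on the last on-NIV sample (against the
#' patient's history strictly before that sample) with the questionnaire:
#'
#' * option **a** (discharge): PaCO2 adequate or on an improving trend,
#'   every on-NIV sample safe, and the patient fully satisfied;
#' * option **b** (repeat the night titration): dissatisfaction or
#'   inadequacy resolvable without touching the inspiratory pressure —
#'   rise-time/trigger adjustments and an oxygen-flow advisory;
#' * option **c** (repeat day-time then night titration): the inspiratory
#'   pressure has to be adjusted, driven by Q1 or by a PaCO2 needing
#'   adjustment.
#'
#' @param state A `tnt_state` in phase `"MORNING_EVALUATION"`.
#' @param record The [patient_record()] whose PaCO2 history includes the
#'   night's samples.
#' @param answers A [questionnaire_response()]; Q4 must be present exactly
#'   when the configuration changed during the night.
#' @param settings A [niv_protocol()].
#' @return A `tnt_outcome`: list with `option` (`"A_DISCHARGE"`,
#'   `"B_REPEAT_TNT"`, `"C_REPEAT_TDT_AND_TNT"`), `final_config`,
#'   `rationale` (reason codes) and `paco2_verdict`. The updated state is
#'   attached as attribute `"state"`.
#' @export
tnt_evaluate <- function(state, record, answers, settings = niv_protocol()) {
  stopifnot(inherits(state, "tnt_state"), inherits(record, "patient_record"),
            inherits(answers, "questionnaire_response"))
  if (state$phase != "MORNING_EVALUATION") {
    abort_protocol(sprintf("evaluation requested in phase %s; expected MORNING_EVALUATION",
                           state$phase))
  }
  on_niv <- Filter(function(s) s$on_niv, state$samples)
  if (length(on_niv) < 2L) {
    abort_protocol(sprintf("morning evaluation requires 2 on-NIV samples; %d recorded",
                           length(on_niv)))
  }
  if (state$changed_overnight && is.null(answers$q4_more_comfortable)) {
    abort_protocol("Q4 answer required: the configuration changed during the night")
  }
  if (!state$changed_overnight && !is.null(answers$q4_more_comfortable)) {
    abort_protocol("Q4 answered but the configuration did not change during the night")
  }
  state <- emit(state, "ANSWER_RECORDED", answers_payload(answers))

  last <- on_niv[[length(on_niv)]]
  pv <- evaluate_paco2_trend(record, last$paco2, at = last$taken_at,
                             history_cutoff = on_niv[[1]]$taken_at,
                             settings = settings)
  state <- emit(state, "RECOMMENDATION", list(
    text = sprintf("Nocturnal PaCO2 %.1f mmHg: %s", last$paco2, pv$verdict),
    paco2_verdict = pv$verdict))
  satisfied <- answers_satisfied(answers)
  paco2_ok <- pv$verdict %in% c("ADEQUATE", "IMPROVING_TREND")
  cfg <- state$config
  rationale <- character()

  if (paco2_ok && satisfied) {
    option <- "A_DISCHARGE"
    rationale <- "SATISFIED_AND_ADEQUATE"
    final <- cfg
    advice <- "Adequate ventilation and a satisfied patient: discharge with the current night configuration"
  } else {
    pressure_driven <- answers$q1_air_amount != "ENOUGH" || !paco2_ok
    if (!paco2_ok) rationale <- c(rationale, "PACO2_NEEDS_ADJUSTMENT")
    if (!satisfied) rationale <- c(rationale, "PATIENT_DISSATISFIED")
    if (pressure_driven) {
      new_ipap <- if (answers$q1_air_amount == "TOO_MUCH") {
        max(cfg$ipap - settings$ipap_step, cfg$epap + settings$ipap_floor_gap)
      } else {
        # too little air, or persistent hypercapnia: more pressure support
        min(cfg$ipap + settings$ipap_step, settings$tdt_ipap_cap)
      }
      if (new_ipap != cfg$ipap) {
        final <- config_with(cfg, ipap = new_ipap)
        option <- "C_REPEAT_TDT_AND_TNT"
        rationale <- c(rationale, "PRESSURE_CHANGED")
        advice <- sprintf("Inspiratory pressure has to be adjusted (to %d mbar): repeat day-time then night-time titration",
                          new_ipap)
      } else {
        final <- cfg
        option <- "B_REPEAT_TNT"
        advice <- "Inspiratory pressure already at its limit; repeat the night titration and review oxygen flow"
      }
    } else {
      final <- cfg
      if (answers$q2_air_speed == "TOO_FAST") {
        final <- config_with(final, rise_time_level = clamp(final$rise_time_level + 1L,
                                                            1L, final$scale_max))
      } else if (answers$q2_air_speed == "TOO_SLOW") {
        final <- config_with(final, rise_time_level = clamp(final$rise_time_level - 1L,
                                                            1L, final$scale_max))
      }
      if (isTRUE(answers$q3_trigger_exhausting)) {
        final <- config_with(final, trigger_level = clamp(final$trigger_level - 1L,
                                                          1L, final$scale_max))
      }
      option <- "B_REPEAT_TNT"
      advice <- "Comfort adjustments without a pressure change (consider the oxygen flow); repeat the night titration"
    }
  }

  state$phase <- "COMPLETE"
  if (!config_equal(final, cfg)) {
    state <- emit(state, "CONFIG_CHANGED", config_payload(final))
  }
  state <- emit(state, "RECOMMENDATION", list(text = advice, option = option))
  state <- emit(state, "TERMINATED",
                c(list(outcome = option, rationale = as.list(rationale)),
                  config_payload(final)))
  outcome <- structure(
    list(option = option, final_config = final,
         rationale = rationale, paco2_verdict = pv),
    class = "tnt_outcome"
  )
  attr(outcome, "state") <- state
  outcome
}

#' @export
print.tnt_outcome <- function(x, ...) {
  cat(sprintf("<tnt_outcome> %s [%s]\n  final config: %s\n",
              x$option, paste(x$rationale, collapse = ", "),
              format(x$final_config)))
  invisible(x)
}
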