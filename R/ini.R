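# INI: first initiation of NIV.
#
# Best-practice start (PS 16/5, backup 18), ventilate 5 minutes, then
# questionnaire-driven optimisation of inspiratory pressure, rise time and
# trigger sensitivity, with inspiratory pressure capped at 20 mbar. Each
# parameter family may be adjusted a bounded number of times and a Q4 "no"
# reverts the last change and freezes the families it touched, so every
# answer sequence terminates.

FAMILIES <- c("pressure", "rise", "trigger")

#' Start the first-initiation (INI) process
#'
#' Puts a new patient on the best-practice initial configuration and starts
#' a 5-minute ventilation pass; mask fitting is a physician's manual step
#' and is recorded as an advisory only. Recurring patients are routed to
#' night-time titration instead and are rejected here.
#'
#' @param record A [patient_record()] with status `"NEW"`.
#' @param settings A [niv_protocol()].
#' @param clock Session-clock minutes at start.
#' @return An `ini_state`.
#' @examples
#' st <- ini_start(patient_record("P1", "NEW"))
#' st$phase
#' @export
ini_start <- function(record, settings = niv_protocol(), clock = 0) {
  stopifnot(inherits(record, "patient_record"))
  if (record$status != "NEW") {
    abort_protocol("INI is only for new patients; recurring patients start at night-time titration")
  }
  state <- structure(
    list(process = "INI", phase = "VENTILATING",
         config = default_initial_config(), prior_config = NULL,
         phase_started_at = clock, expects_q4 = FALSE,
         changed_last_round = character(),
         family_changes = stats::setNames(rep(0L, 3L), FAMILIES),
         frozen = character(), pending_events = list()),
    class = c("ini_state", "niv_process_state")
  )
  state <- emit(state, "STATE_ENTERED", list(phase = "VENTILATING"))
  state <- emit(state, "CONFIG_CHANGED", config_payload(state$config))
  state <- emit(state, "RECOMMENDATION", list(
    text = sprintf("Physician chooses a suitable mask; ventilate the patient for %g minutes on the initial configuration",
                   settings$ini_ventilation_minutes),
    duration_minutes = settings$ini_ventilation_minutes))
  state
}

# ventilation pass elapsed -> ask the questionnaire
ini_on_clock <- function(state, clock, settings) {
  if (state$phase == "VENTILATING" &&
      clock >= state$phase_started_at + settings$ini_ventilation_minutes) {
    state$phase <- "QUESTIONING"
    state$phase_started_at <- clock
    state <- emit(state, "STATE_ENTERED", list(phase = "QUESTIONING"))
    items <- c("Q1", "Q2", "Q3", if (state$expects_q4) "Q4")
    for (it in items) {
      qi <- questionnaire_items()
      state <- emit(state, "QUESTION_ASKED",
                    list(item = it, text = qi$text[qi$item == it]))
    }
  }
  state
}

#' Apply questionnaire answers within INI
#'
#' Maps the comfort answers to configuration adjustments: Q1 "too little"
#' raises IPAP by one step (capped at the INI limit), "too much" lowers it
#' (floored at EPAP plus the minimum gap); Q2 "too fast" slows the rise
#' (level +1), "too slow" speeds it (level -1); Q3 "yes" makes the trigger
#' one level more sensitive. A Q4 "no" reverts to the prior configuration
#' and freezes the families changed last round. If any adjustment was made
#' the patient is ventilated for another pass; fully satisfied answers (or
#' nothing left to adjust) terminate INI.
#'
#' @param state An `ini_state` in phase `"QUESTIONING"`.
#' @param answers A [questionnaire_response()]; Q4 must be present exactly
#'   when the previous round changed the configuration.
#' @param settings A [niv_protocol()].
#' @param clock Session-clock minutes.
#' @return The updated `ini_state`.
#' @export
ini_apply_answers <- function(state, answers, settings = niv_protocol(),
                              clock = state$phase_started_at) {
  stopifnot(inherits(state, "ini_state"),
            inherits(answers, "questionnaire_response"))
  if (state$phase != "QUESTIONING") {
    abort_protocol(sprintf("answers submitted in phase %s; expected QUESTIONING",
                           state$phase))
  }
  if (state$expects_q4 && is.null(answers$q4_more_comfortable)) {
    abort_protocol("Q4 answer required: the configuration changed since the last questionnaire")
  }
  if (!state$expects_q4 && !is.null(answers$q4_more_comfortable)) {
    abort_protocol("Q4 answered but no configuration change preceded this questionnaire")
  }
  state <- emit(state, "ANSWER_RECORDED", answers_payload(answers))

  # Q4 "no": the new configuration is less comfortable -- revert and freeze
  if (isFALSE(answers$q4_more_comfortable)) {
    state$config <- state$prior_config
    state$frozen <- union(state$frozen, state$changed_last_round)
    state <- emit(state, "CONFIG_CHANGED", c(config_payload(state$config),
                                             list(reverted = TRUE)))
    state <- emit(state, "RECOMMENDATION", list(
      text = "Reverted to the previous, more comfortable configuration; this parameter family is no longer adjusted"))
    state$changed_last_round <- character()
    if (all(FAMILIES %in% state$frozen)) {
      return(ini_finish(state, settings))
    }
    state$expects_q4 <- FALSE
    state$phase <- "VENTILATING"
    state$phase_started_at <- clock
    state <- emit(state, "STATE_ENTERED", list(phase = "VENTILATING"))
    state <- emit(state, "RECOMMENDATION", list(
      text = sprintf("Ventilate for %g minutes on the restored configuration",
                     settings$ini_ventilation_minutes),
      duration_minutes = settings$ini_ventilation_minutes))
    return(state)
  }

  old <- state$config
  cfg <- state$config
  changed <- character()

  adjustable <- function(fam) {
    !(fam %in% state$frozen) &&
      state$family_changes[[fam]] < settings$ini_family_change_limit
  }

  if (answers$q1_air_amount == "TOO_LITTLE" && adjustable("pressure")) {
    target <- min(cfg$ipap + settings$ipap_step, settings$ini_ipap_cap)
    if (target > cfg$ipap) {
      cfg <- config_with(cfg, ipap = target)
      changed <- c(changed, "pressure")
    } else {
      state <- emit(state, "RECOMMENDATION", list(
        text = sprintf("Inspiratory pressure already at the %d mbar initiation cap; no further increase",
                       settings$ini_ipap_cap),
        note = "CAP_REACHED"))
    }
  } else if (answers$q1_air_amount == "TOO_MUCH" && adjustable("pressure")) {
    floor_ipap <- cfg$epap + settings$ipap_floor_gap
    target <- max(cfg$ipap - settings$ipap_step, floor_ipap)
    if (target < cfg$ipap) {
      cfg <- config_with(cfg, ipap = target)
      changed <- c(changed, "pressure")
    }
  }

  if (answers$q2_air_speed == "TOO_FAST" && adjustable("rise")) {
    lvl <- clamp(cfg$rise_time_level + 1L, 1L, settings$comfort_scale_max)
    if (lvl != cfg$rise_time_level) {
      cfg <- config_with(cfg, rise_time_level = lvl)
      changed <- c(changed, "rise")
    }
  } else if (answers$q2_air_speed == "TOO_SLOW" && adjustable("rise")) {
    lvl <- clamp(cfg$rise_time_level - 1L, 1L, settings$comfort_scale_max)
    if (lvl != cfg$rise_time_level) {
      cfg <- config_with(cfg, rise_time_level = lvl)
      changed <- c(changed, "rise")
    }
  }

  if (isTRUE(answers$q3_trigger_exhausting) && adjustable("trigger")) {
    lvl <- clamp(cfg$trigger_level - 1L, 1L, settings$comfort_scale_max)
    if (lvl != cfg$trigger_level) {
      cfg <- config_with(cfg, trigger_level = lvl)
      changed <- c(changed, "trigger")
    }
  }

  if (length(changed) == 0) {
    return(ini_finish(state, settings))
  }

  for (fam in changed) {
    state$family_changes[[fam]] <- state$family_changes[[fam]] + 1L
    if (state$family_changes[[fam]] >= settings$ini_family_change_limit) {
      state$frozen <- union(state$frozen, fam)
    }
  }
  state$prior_config <- old
  state$config <- cfg
  state$changed_last_round <- changed
  state$expects_q4 <- TRUE
  state$phase <- "VENTILATING"
  state$phase_started_at <- clock
  state <- emit(state, "CONFIG_CHANGED", config_payload(cfg))
  state <- emit(state, "STATE_ENTERED", list(phase = "VENTILATING"))
  state <- emit(state, "RECOMMENDATION", list(
    text = sprintf("Ventilate for %g minutes on the adjusted configuration",
                   settings$ini_ventilation_minutes),
    duration_minutes = settings$ini_ventilation_minutes))
  state
}

ini_finish <- function(state, settings) {
  state$phase <- "DONE"
  state <- emit(state, "TERMINATED",
                c(list(outcome = "DONE"), config_payload(state$config)))
  state <- emit(state, "RECOMMENDATION", list(
    text = "First initiation complete; proceed to day-time titration"))
  state
}
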