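# Audit events. Process state machines queue events on their state object
# (pending_events); the session engine drains the queue, stamping each event
# with a monotone sequence number and the session clock. Events are
# append-only: nothing in the engine ever rewrites one.

EVENT_KINDS <- c("STATE_ENTERED", "CONFIG_CHANGED", "MEASUREMENT_RECORDED",
                 "QUESTION_ASKED", "ANSWER_RECORDED", "SAFETY_VERDICT",
                 "RECOMMENDATION", "TERMINATED")

pending_event <- function(kind, payload = list()) {
  stopifnot(kind %in% EVENT_KINDS)
  list(kind = kind, payload = payload)
}

emit <- function(state, kind, payload = list()) {
  state$pending_events <- c(state$pending_events, list(pending_event(kind, payload)))
  state
}

drain_events <- function(state) {
  ev <- state$pending_events
  state$pending_events <- list()
  list(state = state, events = ev)
}

# payload snapshot of a config, plain scalars for JSON stability
config_payload <- function(config) {
  list(mode = config$mode, ipap = config$ipap, epap = config$epap,
       backup_rate = config$backup_rate,
       rise_time_level = config$rise_time_level,
       trigger_level = config$trigger_level)
}

sample_payload <- function(sample) {
  list(ph = sample$ph, paco2 = sample$paco2, spo2 = sample$spo2,
       taken_at = sample$taken_at, on_niv = sample$on_niv,
       source = sample$source)
}

answers_payload <- function(answers) {
  p <- list(q1_air_amount = answers$q1_air_amount,
            q2_air_speed = answers$q2_air_speed,
            q3_trigger_exhausting = answers$q3_trigger_exhausting)
  if (!is.null(answers$q4_more_comfortable)) {
    p$q4_more_comfortable <- answers$q4_more_comfortable
  }
  p
}
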