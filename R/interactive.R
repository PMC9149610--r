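# Line-oriented interactive driver. Commands are read from a connection
# (stdin by default, a textConnection in tests), every RECOMMENDATION event
# is printed as it is logged, and clock advancement is always explicit, so
# an interactive transcript is replayable.

#' Drive a session interactively from a connection
#'
#' Reads one command per line and applies it to the session:
#'
#' * `advance <minutes>` — move the session clock forward;
#' * `bga <ph> <paco2> <spo2> [on|off]` — submit a blood gas;
#' * `answers <q1> <q2> <q3> [<q4>]` — questionnaire answers
#'   (`enough|too_much|too_little`, `adequate|too_fast|too_slow`,
#'   `yes|no`, optional `yes|no`);
#' * `approve yes|no` — a patient approval;
#' * `save <path>` — persist the session;
#' * `quit` — stop reading.
#'
#' Questions and recommendations are printed verbatim as the engine emits
#' them; input errors are reported and the session is left unchanged.
#'
#' @param session A `niv_session`.
#' @param con A connection to read commands from; default stdin.
#' @param quiet Suppress printing (used by tests).
#' @return The final `niv_session`.
#' @export
run_interactive <- function(session, con = stdin(), quiet = FALSE) {
  stopifnot(inherits(session, "niv_session"))
  say <- function(...) if (!quiet) cat(..., "\n", sep = "")
  show_new_events <- function(before, after) {
    for (ev in after$events[seq(before + 1, length.out = length(after$events) - before)]) {
      if (ev$kind %in% c("RECOMMENDATION", "QUESTION_ASKED")) {
        txt <- ev$payload$text %||% ""
        label <- if (ev$kind == "QUESTION_ASKED")
          paste0(ev$payload$item, ". ") else "=> "
        say(sprintf("[%s min %g] %s%s", ev$process, ev$at, label, txt))
      }
    }
  }
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0 || identical(tolower(trimws(line)), "quit")) break
    line <- trimws(line)
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1]]
    input <- tryCatch(parse_command(tok, session), error = function(e) e)
    if (inherits(input, "error")) {
      say("error: ", conditionMessage(input))
      next
    }
    if (is.character(input)) { # a side command like save
      next
    }
    n_before <- length(session$events)
    next_session <- tryCatch(advance(session, input), error = function(e) e)
    if (inherits(next_session, "error")) {
      say("error: ", conditionMessage(next_session))
      next
    }
    session <- next_session
    show_new_events(n_before, session)
    if (session$disposition != "IN_PROGRESS") {
      say("session terminated: ", session$disposition)
      break
    }
  }
  session
}

parse_command <- function(tok, session) {
  verb <- tolower(tok[1])
  yn <- function(x) tolower(x) %in% c("yes", "y", "true")
  switch(verb,
    advance = input_advance(as.numeric(tok[2])),
    bga = input_bga(as.numeric(tok[2]), as.numeric(tok[3]),
                    as.numeric(tok[4]),
                    on_niv = if (length(tok) >= 5) tolower(tok[5]) == "on"),
    answers = {
      q1 <- toupper(tok[2])
      q2 <- toupper(tok[3])
      input_answers(questionnaire_response(
        q1_air_amount = q1, q2_air_speed = q2,
        q3_trigger_exhausting = yn(tok[4]),
        q4_more_comfortable = if (length(tok) >= 5) yn(tok[5])))
    },
    approve = input_approval(yn(tok[2])),
    save = { save_session(session, tok[2]); "saved" },
    abort_input(sprintf("unknown command '%s'", verb))
  )
}
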