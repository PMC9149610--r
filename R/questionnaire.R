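#' Questionnaire response
#'
#' Answers to the four comfort questions. Q1 (air amount) maps to
#' inspiratory pressure, Q2 (air speed) to rise time, Q3 (exhausting to
#' trigger) to trigger sensitivity. Q4 compares comfort with the previous
#' configuration and must be present exactly when the asking step follows a
#' configuration change.
#'
#' @param q1_air_amount One of `"ENOUGH"`, `"TOO_MUCH"`, `"TOO_LITTLE"`.
#' @param q2_air_speed One of `"ADEQUATE"`, `"TOO_FAST"`, `"TOO_SLOW"`.
#' @param q3_trigger_exhausting Logical: is initiating a breath exhausting?
#' @param q4_more_comfortable Logical or `NULL`; present only when the
#'   current configuration followed a change.
#' @return A `questionnaire_response` object.
#' @examples
#' questionnaire_response("ENOUGH", "ADEQUATE", FALSE)
#' @export
questionnaire_response <- function(q1_air_amount,
                                   q2_air_speed = "ADEQUATE",
                                   q3_trigger_exhausting = FALSE,
                                   q4_more_comfortable = NULL) {
  q1 <- match.arg(q1_air_amount, c("ENOUGH", "TOO_MUCH", "TOO_LITTLE"))
  q2 <- match.arg(q2_air_speed, c("ADEQUATE", "TOO_FAST", "TOO_SLOW"))
  if (!is.logical(q3_trigger_exhausting) || length(q3_trigger_exhausting) != 1L ||
      is.na(q3_trigger_exhausting)) {
    abort_input("q3_trigger_exhausting must be TRUE or FALSE")
  }
  if (!is.null(q4_more_comfortable) &&
      (!is.logical(q4_more_comfortable) || length(q4_more_comfortable) != 1L ||
       is.na(q4_more_comfortable))) {
    abort_input("q4_more_comfortable must be TRUE, FALSE or NULL")
  }
  structure(
    list(q1_air_amount = q1, q2_air_speed = q2,
         q3_trigger_exhausting = q3_trigger_exhausting,
         q4_more_comfortable = q4_more_comfortable),
    class = "questionnaire_response"
  )
}

# fully satisfied answers leave every parameter untouched
answers_satisfied <- function(answers) {
  answers$q1_air_amount == "ENOUGH" &&
    answers$q2_air_speed == "ADEQUATE" &&
    !answers$q3_trigger_exhausting &&
    !isFALSE(answers$q4_more_comfortable)
}

#' @export
print.questionnaire_response <- function(x, ...) {
  cat(sprintf("<questionnaire_response> Q1 %s | Q2 %s | Q3 %s%s\n",
              x$q1_air_amount, x$q2_air_speed,
              if (x$q3_trigger_exhausting) "yes" else "no",
              if (is.null(x$q4_more_comfortable)) "" else
                sprintf(" | Q4 %s", if (x$q4_more_comfortable) "yes" else "no")))
  invisible(x)
}
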