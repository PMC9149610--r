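#' Blood-gas safety gate
#'
#' Evaluates the safety rules applied to every blood gas drawn under
#' ventilation: hypoxemia (SpO2 strictly below 85%) or acidosis (pH
#' strictly below 7.35) aborts the process immediately with advice to call
#' a physician; alkalosis (pH strictly above 7.55) recommends stopping
#' ventilation and pausing. When an abort reason co-occurs with alkalosis
#' the abort dominates.
#'
#' @param sample A [blood_gas()].
#' @param settings A [niv_protocol()].
#' @return A `safety_verdict`: list with `verdict` (one of `"CONTINUE"`,
#'   `"ABORT_CALL_PHYSICIAN"`, `"STOP_AND_PAUSE"`) and `reasons` (character
#'   vector drawn from `"HYPOXEMIA"`, `"ACIDOSIS"`, `"ALKALOSIS"`).
#' @examples
#' evaluate_safety(blood_gas(7.30, 50, 95))$verdict
#' evaluate_safety(blood_gas(7.42, 48, 93))$verdict
#' @export
evaluate_safety <- function(sample, settings = niv_protocol()) {
  stopifnot(inherits(sample, "blood_gas"))
  reasons <- character()
  if (sample$spo2 < settings$spo2_floor) reasons <- c(reasons, "HYPOXEMIA")
  if (sample$ph < settings$ph_acidosis) reasons <- c(reasons, "ACIDOSIS")
  if (sample$ph > settings$ph_alkalosis) reasons <- c(reasons, "ALKALOSIS")
  verdict <- if (any(reasons %in% c("HYPOXEMIA", "ACIDOSIS"))) {
    "ABORT_CALL_PHYSICIAN"
  } else if ("ALKALOSIS" %in% reasons) {
    "STOP_AND_PAUSE"
  } else {
    "CONTINUE"
  }
  structure(list(verdict = verdict, reasons = reasons),
            class = "safety_verdict")
}

#' Has a stop-and-pause alkalosis resolved?
#'
#' After the 30-minute pause a recheck blood gas is drawn; the condition
#' counts as disappeared when pH is at or below 7.55 (boundary included).
#'
#' @param recheck The recheck [blood_gas()].
#' @param settings A [niv_protocol()].
#' @return `TRUE` if the alkalosis has resolved.
#' @export
alkalosis_resolved <- function(recheck, settings = niv_protocol()) {
  stopifnot(inherits(recheck, "blood_gas"))
  recheck$ph <= settings$ph_alkalosis
}

#' Nocturnal PaCO2 adequacy and trend rule (pure form)
#'
#' The two-criterion rule on explicit values. At or below 45 mmHg
#' ventilation is adequate; above 50 mmHg it needs adjustment. Inside the
#' interval (45, 50] the value counts as an improving trend only when it is
#' improved by strictly more than 5 mmHg compared with the patient's
#' lowest historical value AND improved (strictly lower) compared with the
#' previous measured value; otherwise it needs adjustment.
#'
#' @param current Current PaCO2 in mmHg.
#' @param lowest The patient's lowest historical PaCO2 (mmHg) from before
#'   the current night.
#' @param previous The previous measured PaCO2 (mmHg).
#' @param settings A [niv_protocol()].
#' @return A `paco2_verdict`: list with `verdict` (one of `"ADEQUATE"`,
#'   `"IMPROVING_TREND"`, `"NEEDS_ADJUSTMENT"`), and signed deltas
#'   `lowest_delta` (current minus lowest) and `previous_delta` (current
#'   minus previous).
#' @examples
#' paco2_trend_verdict(current = 48, lowest = 55, previous = 49)$verdict
#' @export
paco2_trend_verdict <- function(current, lowest, previous,
                                settings = niv_protocol()) {
  if (!is_count1(current) || current <= 0) {
    abort_input("current PaCO2 must be a positive number of mmHg")
  }
  in_interval <- current > settings$paco2_adequate &&
    current <= settings$paco2_upper
  if (in_interval && (is.na(lowest) || is.na(previous))) {
    abort_config(paste0(
      "PaCO2 ", format(current), " mmHg lies in the trend-evaluation ",
      "interval but the patient has no prior PaCO2 history; record a ",
      "baseline measurement first"))
  }
  verdict <- if (current <= settings$paco2_adequate) {
    "ADEQUATE"
  } else if (current > settings$paco2_upper) {
    "NEEDS_ADJUSTMENT"
  } else if ((lowest - current) > settings$paco2_min_improvement &&
             current < previous) {
    "IMPROVING_TREND"
  } else {
    "NEEDS_ADJUSTMENT"
  }
  structure(list(verdict = verdict,
                 lowest_delta = current - lowest,
                 previous_delta = current - previous),
            class = "paco2_verdict")
}

#' Evaluate the PaCO2 trend against a patient record
#'
#' Derives the rule's two comparators from the record: "lowest" is the
#' minimum over the history strictly before `history_cutoff` — the
#' patient's chart lowest from before the current night, so that a night's
#' own measurements do not mask their improvement — and "previous" is the
#' last measurement strictly before `at`, typically the preceding sample
#' of the same night. Then applies [paco2_trend_verdict()].
#'
#' @param record A [patient_record()] carrying the PaCO2 history.
#' @param current Current PaCO2 in mmHg.
#' @param at Cutoff for the previous measured value: the last history
#'   entry strictly earlier than `at` (default: end of history, i.e. the
#'   record does not yet contain the current sample).
#' @param history_cutoff Cutoff for the historical lowest (default: same
#'   as `at`). The night-time evaluator passes the time of the night's
#'   first on-NIV sample.
#' @param settings A [niv_protocol()].
#' @return A `paco2_verdict`; see [paco2_trend_verdict()].
#' @examples
#' r <- patient_record("P1", "NEW",
#'   paco2_history = data.frame(taken_at = c(0, 240), paco2 = c(55, 49)))
#' # lowest before the night (55), previous measured value (49)
#' evaluate_paco2_trend(r, current = 48, at = 480, history_cutoff = 240)$verdict
#' @export
evaluate_paco2_trend <- function(record, current, at = NULL,
                                 history_cutoff = at,
                                 settings = niv_protocol()) {
  stopifnot(inherits(record, "patient_record"))
  paco2_trend_verdict(current,
                      lowest = lowest_paco2(record, before = history_cutoff),
                      previous = previous_paco2(record, before = at),
                      settings = settings)
}

#' @export
print.safety_verdict <- function(x, ...) {
  cat(sprintf("<safety_verdict> %s%s\n", x$verdict,
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' @export
print.paco2_verdict <- function(x, ...) {
  cat(sprintf("<paco2_verdict> %s (vs lowest %+.1f, vs previous %+.1f mmHg)\n",
              x$verdict, x$lowest_delta, x$previous_delta))
  invisible(x)
}
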