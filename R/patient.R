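#' Patient record
#'
#' Identity, new/recurring status, the PaCO2 measurement history, and the
#' stored night-time ventilator configuration for recurring patients.
#' Derived accessors give the lowest historical PaCO2 and the most recent
#' previous value, both of which the nocturnal trend criterion compares
#' against.
#'
#' @param patient_id Opaque identifier string.
#' @param status `"NEW"` or `"RECURRING"`. Recurring patients must carry a
#'   stored night configuration.
#' @param paco2_history Optional tibble/data.frame with columns `taken_at`
#'   (minutes) and `paco2` (mmHg), ordered by time.
#' @param stored_night_config Optional [ventilator_config()].
#' @return A `patient_record` object.
#' @examples
#' patient_record("P1", "NEW")
#' @export
patient_record <- function(patient_id, status = c("NEW", "RECURRING"),
                           paco2_history = NULL,
                           stored_night_config = NULL) {
  status <- match.arg(status)
  if (!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id)) {
    abort_input("patient_id must be a non-empty string")
  }
  if (status == "RECURRING" && is.null(stored_night_config)) {
    abort_config("a RECURRING patient must have a stored night-time configuration")
  }
  if (is.null(paco2_history)) {
    paco2_history <- tibble::tibble(taken_at = numeric(), paco2 = numeric())
  } else {
    paco2_history <- tibble::as_tibble(paco2_history)[, c("taken_at", "paco2")]
    if (is.unsorted(paco2_history$taken_at)) {
      abort_input("paco2_history must be ordered by taken_at")
    }
  }
  structure(
    list(patient_id = patient_id, status = status,
         paco2_history = paco2_history,
         stored_night_config = stored_night_config),
    class = "patient_record"
  )
}

#' Fold a blood-gas sample into a patient's PaCO2 history
#'
#' Appends the sample's PaCO2 at its timestamp and returns a new record;
#' the input record is left untouched (value semantics). Samples older than
#' the newest history entry are rejected to keep the clock monotone.
#'
#' @param record A [patient_record()].
#' @param sample A [blood_gas()].
#' @return A new `patient_record` with the extended history.
#' @examples
#' r <- patient_record("P1", "NEW")
#' r <- update_paco2_history(r, blood_gas(7.38, 55, 92, taken_at = 0))
#' lowest_paco2(r)
#' @export
update_paco2_history <- function(record, sample) {
  stopifnot(inherits(record, "patient_record"), inherits(sample, "blood_gas"))
  h <- record$paco2_history
  if (nrow(h) > 0 && sample$taken_at < max(h$taken_at)) {
    abort_input(sprintf(
      "sample at minute %g predates the newest history entry (minute %g)",
      sample$taken_at, max(h$taken_at)))
  }
  record$paco2_history <- tibble::add_row(h, taken_at = sample$taken_at,
                                          paco2 = sample$paco2)
  record
}

#' @rdname update_paco2_history
#' @param before Optional session-clock cutoff; only entries strictly
#'   earlier than it are considered.
#' @export
lowest_paco2 <- function(record, before = NULL) {
  v <- history_values(record, before)
  if (length(v) == 0) return(NA_real_)
  min(v)
}

#' @rdname update_paco2_history
#' @export
previous_paco2 <- function(record, before = NULL) {
  v <- history_values(record, before)
  if (length(v) == 0) return(NA_real_)
  v[length(v)]
}

history_values <- function(record, before = NULL) {
  h <- record$paco2_history
  if (!is.null(before)) h <- h[h$taken_at < before, , drop = FALSE]
  h$paco2
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (%s), %d PaCO2 measurements",
              x$patient_id, x$status, nrow(x$paco2_history)))
  if (nrow(x$paco2_history) > 0) {
    cat(sprintf(", lowest %.1f mmHg", lowest_paco2(x)))
  }
  cat("\n")
  if (!is.null(x$stored_night_config)) {
    cat("  stored night config:", format(x$stored_night_config), "\n")
  }
  invisible(x)
}
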