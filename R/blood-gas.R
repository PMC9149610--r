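#' Blood-gas sample
#'
#' A measurement consumed by the safety and adequacy rules: pH, arterial
#' CO2 partial pressure (PaCO2, mmHg) and pulse-oximetry SpO2 (%), stamped
#' on the abstract session clock. Transcutaneous CO2 estimates (PtcCO2),
#' used nocturnally to avoid waking the patient, enter through the same
#' type with `source = "ptcco2"`; no calibration transform is applied.
#'
#' @param ph Arterial pH; values outside 6.5..8.0 are rejected as
#'   implausible input.
#' @param paco2 PaCO2 in mmHg, positive.
#' @param spo2 SpO2 in percent, in (0, 100].
#' @param taken_at Session-clock minutes at which the sample was drawn.
#' @param on_niv Was the sample taken under ventilation?
#' @param source `"arterial"` (default) or `"ptcco2"`.
#' @return A `blood_gas` object.
#' @examples
#' blood_gas(ph = 7.42, paco2 = 48, spo2 = 93)
#' @export
blood_gas <- function(ph, paco2, spo2, taken_at = 0, on_niv = TRUE,
                      source = c("arterial", "ptcco2")) {
  source <- match.arg(source)
  if (!is_count1(ph) || ph < 6.5 || ph > 8.0) {
    abort_input(sprintf("pH %s is outside the plausible range 6.5..8.0",
                        format(ph)))
  }
  if (!is_count1(paco2) || paco2 <= 0) {
    abort_input("paco2 must be a positive number of mmHg")
  }
  if (!is_count1(spo2) || spo2 <= 0 || spo2 > 100) {
    abort_input("spo2 must lie in (0, 100] percent")
  }
  if (!is_count1(taken_at) || taken_at < 0) {
    abort_input("taken_at must be a non-negative session-clock minute")
  }
  structure(
    list(ph = as.numeric(ph), paco2 = as.numeric(paco2),
         spo2 = as.numeric(spo2), taken_at = as.numeric(taken_at),
         on_niv = isTRUE(on_niv), source = source),
    class = "blood_gas"
  )
}

#' @export
print.blood_gas <- function(x, ...) {
  cat(sprintf("<blood_gas> pH %.2f | PaCO2 %.1f mmHg | SpO2 %.1f%% | t=%g min | %s%s\n",
              x$ph, x$paco2, x$spo2, x$taken_at,
              if (x$on_niv) "on NIV" else "off NIV",
              if (x$source == "ptcco2") " (PtcCO2)" else ""))
  invisible(x)
}
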