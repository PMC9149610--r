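#' Protocol settings for the NIV titration engine
#'
#' Collects every tunable constant of the titration protocol in one object.
#' The blood-gas thresholds, pressure deltas, cycle counts and timings
#' default to the published protocol values; changing a threshold away from
#' its default marks the settings as nonconforming (a warning is attached,
#' and the CLI prints it prominently).
#'
#' @param ipap_step Pressure step (mbar) for inspiratory-pressure
#'   adjustments in INI and TDT. Default 2 mbar, the only pressure delta the
#'   protocol states (the post-alkalosis IPAP reduction).
#' @param ini_ipap_cap Maximum IPAP (mbar) reachable during first
#'   initiation. Default 20.
#' @param tdt_ipap_cap Maximum IPAP (mbar) during day-time titration and
#'   night-time recommendations. The 20-mbar cap is stated for INI only;
#'   day-time titration aims for an "optimal" pressure, so a wider
#'   device-level ceiling (default 30) applies.
#' @param ipap_floor_gap Minimum IPAP minus EPAP gap (mbar) preserved when
#'   pressure is reduced. Default 2.
#' @param comfort_scale_max Ordinal scale bound for rise-time and
#'   trigger-sensitivity levels (levels run 1..max; default 5). Level 1 is
#'   the fastest rise / most sensitive trigger.
#' @param ini_family_change_limit Total number of adjustments allowed per
#'   parameter family (pressure, rise time, trigger) within INI before the
#'   family is frozen; guarantees termination. Default 3.
#' @param ini_ventilation_minutes Length of each INI ventilation pass before
#'   the questionnaire. Default 5 minutes.
#' @param tdt_cycle_minutes Length of a day-time ventilation cycle.
#'   Default 20 minutes.
#' @param tdt_bga_offset_minutes Minute within the cycle at which the blood
#'   gas analysis is drawn. Default 15.
#' @param tdt_max_cycles Maximum number of ventilation-and-parameter-change
#'   cycles in one day-time titration. Default 3.
#' @param alkalosis_pause_minutes Pause after an alkalosis stop before the
#'   recheck blood gas. Default 30 minutes.
#' @param spo2_floor Hypoxemia threshold: SpO2 strictly below this aborts.
#'   Default 85 (percent).
#' @param ph_acidosis Acidosis threshold: pH strictly below this aborts.
#'   Default 7.35.
#' @param ph_alkalosis Alkalosis threshold: pH strictly above this stops and
#'   pauses ventilation. Default 7.55.
#' @param paco2_adequate Upper PaCO2 bound (mmHg) counted as adequate
#'   nocturnal ventilation. Default 45.
#' @param paco2_upper Upper bound (mmHg) of the trend-evaluation interval;
#'   above it ventilation needs adjustment outright. Default 50.
#' @param paco2_min_improvement Improvement (mmHg) over the patient's lowest
#'   historical value that must be strictly exceeded for the improving-trend
#'   verdict. Default 5.
#' @param max_tnt_nights Backstop: number of completed night-time titration
#'   nights after which a still-undischarged patient is referred to a
#'   physician. Default 20.
#'
#' @return An object of class `niv_protocol` (a named list).
#' @examples
#' p <- niv_protocol()
#' p$ph_acidosis
#' @export
niv_protocol <- function(ipap_step = 2L,
                         ini_ipap_cap = 20L,
                         tdt_ipap_cap = 30L,
                         ipap_floor_gap = 2L,
                         comfort_scale_max = 5L,
                         ini_family_change_limit = 3L,
                         ini_ventilation_minutes = 5,
                         tdt_cycle_minutes = 20,
                         tdt_bga_offset_minutes = 15,
                         tdt_max_cycles = 3L,
                         alkalosis_pause_minutes = 30,
                         spo2_floor = 85,
                         ph_acidosis = 7.35,
                         ph_alkalosis = 7.55,
                         paco2_adequate = 45,
                         paco2_upper = 50,
                         paco2_min_improvement = 5,
                         max_tnt_nights = 20L) {
  p <- list(
    ipap_step = check_integerish(ipap_step, "ipap_step"),
    ini_ipap_cap = check_integerish(ini_ipap_cap, "ini_ipap_cap"),
    tdt_ipap_cap = check_integerish(tdt_ipap_cap, "tdt_ipap_cap"),
    ipap_floor_gap = check_integerish(ipap_floor_gap, "ipap_floor_gap"),
    comfort_scale_max = check_integerish(comfort_scale_max, "comfort_scale_max"),
    ini_family_change_limit = check_integerish(ini_family_change_limit,
                                               "ini_family_change_limit"),
    ini_ventilation_minutes = ini_ventilation_minutes,
    tdt_cycle_minutes = tdt_cycle_minutes,
    tdt_bga_offset_minutes = tdt_bga_offset_minutes,
    tdt_max_cycles = check_integerish(tdt_max_cycles, "tdt_max_cycles"),
    alkalosis_pause_minutes = alkalosis_pause_minutes,
    spo2_floor = spo2_floor,
    ph_acidosis = ph_acidosis,
    ph_alkalosis = ph_alkalosis,
    paco2_adequate = paco2_adequate,
    paco2_upper = paco2_upper,
    paco2_min_improvement = paco2_min_improvement,
    max_tnt_nights = check_integerish(max_tnt_nights, "max_tnt_nights")
  )
  defaults <- list(spo2_floor = 85, ph_acidosis = 7.35, ph_alkalosis = 7.55,
                   paco2_adequate = 45, paco2_upper = 50,
                   paco2_min_improvement = 5)
  changed <- names(defaults)[vapply(names(defaults),
                                    function(nm) !identical(as.numeric(p[[nm]]),
                                                            as.numeric(defaults[[nm]])),
                                    logical(1))]
  p$nonconforming_thresholds <- changed
  structure(p, class = "niv_protocol")
}

#' @export
print.niv_protocol <- function(x, ...) {
  cat("<niv_protocol>\n")
  cat(sprintf("  safety: SpO2 < %g%% or pH < %g aborts; pH > %g pauses %g min\n",
              x$spo2_floor, x$ph_acidosis, x$ph_alkalosis,
              x$alkalosis_pause_minutes))
  cat(sprintf("  pressure: step %d mbar, INI cap %d, TDT cap %d, floor EPAP+%d\n",
              x$ipap_step, x$ini_ipap_cap, x$tdt_ipap_cap, x$ipap_floor_gap))
  cat(sprintf("  PaCO2 trend: adequate <= %g, interval (%g, %g], improvement > %g mmHg\n",
              x$paco2_adequate, x$paco2_adequate, x$paco2_upper,
              x$paco2_min_improvement))
  if (length(x$nonconforming_thresholds)) {
    cat("  WARNING: thresholds changed from protocol defaults:",
        paste(x$nonconforming_thresholds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Verbatim questionnaire items
#'
#' The four patient-comfort questions driving ventilator adjustments, with
#' their answer alphabets. Q1 reflects inspiratory pressure, Q2 rise time,
#' Q3 trigger sensitivity; Q4 compares the current configuration with the
#' previous one and is asked only after a configuration change.
#'
#' @return A tibble with columns `item`, `text`, `answers`.
#' @export
questionnaire_items <- function() {
  tibble::tibble(
    item = c("Q1", "Q2", "Q3", "Q4"),
    text = c(
      "How much air do you get during ventilation?",
      "How fast does the ventilator deliver the air?",
      "Is it exhausting to initiate a new breath?",
      "Is the ventilation now more comfortable than in the previous configuration?"
    ),
    answers = c("enough/too much/too little", "adequately/too fast/too slow",
                "yes/no", "yes/no")
  )
}
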