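# Virtual hypercapnic COPD patient: a deliberately simple linear
# physiological response model plus answer policies, so every branch of the
# decision logic can be exercised closed-loop with no clinical data. PaCO2
# falls with the delivered pressure support (IPAP - EPAP) in proportion to
# the time spent on NIV; pH tracks the acute deviation of PaCO2 from the
# patient's chronically compensated set point; SpO2 rises mildly with
# pressure support. All randomness is drawn from a per-patient seeded
# stream indexed by draw number, so identical parameters and seed give an
# identical response stream regardless of interleaving.

COMFORT_POLICIES <- c("ALWAYS_SATISFIED", "WANTS_MORE_PRESSURE",
                      "WANTS_LESS_PRESSURE", "RANDOM")
APPROVAL_POLICIES <- c("ALWAYS", "NEVER", "RANDOM")

#' Define a virtual patient
#'
#' @param patient_id Identifier string.
#' @param baseline_paco2 Chronic PaCO2 off ventilation, mmHg. Default 55
#'   (stable hypercapnia).
#' @param co2_sensitivity PaCO2 reduction (mmHg) per mbar of pressure
#'   support delivered over a full 8-hour night; non-negative. Default 0.5.
#' @param ph_coupling pH units per mmHg of acute PaCO2 deviation from the
#'   compensated set point; non-positive. Default -0.008.
#' @param compensated_paco2 The PaCO2 at which the patient's pH sits at
#'   7.40 (chronic metabolic compensation). Defaults to `baseline_paco2`;
#'   set it below baseline to model incomplete compensation (acidotic on
#'   presentation).
#' @param baseline_spo2 SpO2 off ventilation, percent. Default 90.
#' @param spo2_gain SpO2 percent gained per mbar of pressure support while
#'   on NIV. Default 0.3.
#' @param noise_sd_paco2 Gaussian noise SD on PaCO2, mmHg. Default 1.
#' @param noise_sd_ph Gaussian noise SD on pH. Default 0.005.
#' @param comfort_policy How the patient answers the questionnaire:
#'   `"ALWAYS_SATISFIED"`, `"WANTS_MORE_PRESSURE"`,
#'   `"WANTS_LESS_PRESSURE"` (each relative to a private `ipap_target`),
#'   or `"RANDOM"`.
#' @param approval_policy Consent answers: `"ALWAYS"`, `"NEVER"`,
#'   `"RANDOM"`.
#' @param ipap_target Private IPAP (mbar) the pressure-seeking policies aim
#'   for; an unreachable target makes the patient insatiable.
#' @param rng_seed Integer seed of the patient's private random stream.
#' @return A `virtual_patient` object.
#' @examples
#' vp <- virtual_patient("VP1", co2_sensitivity = 1, noise_sd_paco2 = 0)
#' simulate_bga(vp, default_initial_config(), on_niv = TRUE, hours_on_niv = 8)
#' @export
virtual_patient <- function(patient_id = "VP1",
                            baseline_paco2 = 55,
                            co2_sensitivity = 0.5,
                            ph_coupling = -0.008,
                            compensated_paco2 = baseline_paco2,
                            baseline_spo2 = 90,
                            spo2_gain = 0.3,
                            noise_sd_paco2 = 1,
                            noise_sd_ph = 0.005,
                            comfort_policy = "ALWAYS_SATISFIED",
                            approval_policy = "ALWAYS",
                            ipap_target = 18L,
                            rng_seed = 1L) {
  comfort_policy <- match.arg(comfort_policy, COMFORT_POLICIES)
  approval_policy <- match.arg(approval_policy, APPROVAL_POLICIES)
  if (co2_sensitivity < 0 || spo2_gain < 0 || noise_sd_paco2 < 0 ||
      noise_sd_ph < 0) {
    abort_input("gains and noise SDs must be non-negative")
  }
  if (ph_coupling > 0) {
    abort_input("ph_coupling must be non-positive (CO2 retention acidifies)")
  }
  structure(
    list(patient_id = patient_id, baseline_paco2 = baseline_paco2,
         co2_sensitivity = co2_sensitivity, ph_coupling = ph_coupling,
         compensated_paco2 = compensated_paco2,
         baseline_spo2 = baseline_spo2, spo2_gain = spo2_gain,
         noise_sd_paco2 = noise_sd_paco2, noise_sd_ph = noise_sd_ph,
         comfort_policy = comfort_policy, approval_policy = approval_policy,
         ipap_target = as.integer(ipap_target),
         rng_seed = as.integer(rng_seed)),
    class = "virtual_patient"
  )
}

# deterministic per-patient stream: block of draws for index k
patient_draws <- function(params, draw, n) {
  withr::with_seed(params$rng_seed + 7L * draw, rnorm(n))
}

patient_unif <- function(params, draw, n) {
  withr::with_seed(params$rng_seed + 7L * draw + 3L, runif(n))
}

#' Simulate a blood gas for a virtual patient
#'
#' Off NIV the patient sits at baseline; on NIV, PaCO2 falls by
#' `co2_sensitivity` mmHg per mbar of pressure support scaled by the
#' fraction of a full 8-hour night spent ventilated. pH follows the acute
#' PaCO2 deviation from the compensated set point; SpO2 gains
#' `spo2_gain` percent per mbar of support while ventilated.
#'
#' @param params A [virtual_patient()].
#' @param config A [ventilator_config()].
#' @param on_niv Is the patient ventilated when the sample is drawn?
#' @param hours_on_niv Hours of ventilation preceding the sample.
#' @param at Session-clock minutes stamped on the sample.
#' @param draw Draw index of the patient's random stream; the same
#'   (seed, draw) always yields the same sample.
#' @return A [blood_gas()].
#' @export
simulate_bga <- function(params, config, on_niv, hours_on_niv = 8,
                         at = 0, draw = 0L) {
  stopifnot(inherits(params, "virtual_patient"),
            inherits(config, "ventilator_config"))
  support <- config$ipap - config$epap
  eps <- patient_draws(params, draw, 2L)
  paco2 <- params$baseline_paco2 + eps[1] * params$noise_sd_paco2
  if (isTRUE(on_niv)) {
    paco2 <- paco2 - params$co2_sensitivity * support * (hours_on_niv / 8)
  }
  paco2 <- max(paco2, 1)
  ph <- 7.40 + params$ph_coupling * (paco2 - params$compensated_paco2) +
    eps[2] * params$noise_sd_ph
  ph <- clamp(ph, 6.51, 7.99)
  spo2 <- params$baseline_spo2 +
    if (isTRUE(on_niv)) params$spo2_gain * support else 0
  spo2 <- clamp(spo2, 1, 100)
  blood_gas(ph = ph, paco2 = paco2, spo2 = spo2, taken_at = at,
            on_niv = isTRUE(on_niv))
}

#' Answer the questionnaire according to the patient's comfort policy
#'
#' `"WANTS_MORE_PRESSURE"` answers "too little" until IPAP reaches the
#' private target, then "enough" (mirrored for `"WANTS_LESS_PRESSURE"`);
#' `"ALWAYS_SATISFIED"` is content with everything. Q4 is answered "yes"
#' exactly when the current configuration is closer to the private target
#' than the previous one, and only when a previous configuration is given.
#'
#' @inheritParams simulate_bga
#' @param previous_config The configuration before the last change, or
#'   `NULL` when Q4 is not being asked.
#' @return A [questionnaire_response()].
#' @export
answer_questionnaire <- function(params, config, previous_config = NULL,
                                 draw = 0L) {
  stopifnot(inherits(params, "virtual_patient"),
            inherits(config, "ventilator_config"))
  ask_q4 <- !is.null(previous_config)
  if (params$comfort_policy == "RANDOM") {
    u <- patient_unif(params, draw, 4L)
    return(questionnaire_response(
      q1_air_amount = c("ENOUGH", "TOO_MUCH", "TOO_LITTLE")[1L + floor(u[1] * 3)],
      q2_air_speed = c("ADEQUATE", "TOO_FAST", "TOO_SLOW")[1L + floor(u[2] * 3)],
      q3_trigger_exhausting = u[3] < 0.5,
      q4_more_comfortable = if (ask_q4) u[4] < 0.5
    ))
  }
  q1 <- switch(params$comfort_policy,
    ALWAYS_SATISFIED = "ENOUGH",
    WANTS_MORE_PRESSURE = if (config$ipap < params$ipap_target) "TOO_LITTLE" else "ENOUGH",
    WANTS_LESS_PRESSURE = if (config$ipap > params$ipap_target) "TOO_MUCH" else "ENOUGH"
  )
  q4 <- if (!ask_q4) NULL
        else if (params$comfort_policy == "ALWAYS_SATISFIED") TRUE
        else abs(config$ipap - params$ipap_target) <
             abs(previous_config$ipap - params$ipap_target)
  questionnaire_response(q1_air_amount = q1, q2_air_speed = "ADEQUATE",
                         q3_trigger_exhausting = FALSE,
                         q4_more_comfortable = q4)
}

patient_approves <- function(params, draw) {
  switch(params$approval_policy,
    ALWAYS = TRUE,
    NEVER = FALSE,
    RANDOM = patient_unif(params, draw, 1L) < 0.5)
}

#' Run a virtual patient closed-loop through the engine
#'
#' Drives a session with inputs generated by the virtual patient: clock
#' advances through ventilation phases and the night, simulated blood
#' gases at the protocol's measurement points (day-time gas after 15
#' minutes; nocturnal baseline, then on-NIV gases 4 and 8 hours into the
#' night), policy-driven questionnaire answers and approvals.
#'
#' @param params A [virtual_patient()].
#' @param settings A [niv_protocol()].
#' @param record Optional starting [patient_record()]; defaults to a new
#'   patient with the virtual patient's id.
#' @param max_steps Hard ceiling on engine steps (a livelock guard).
#' @return A `niv_virtual_run`: list with `session`, `params`.
#' @examples
#' run <- run_virtual_patient(virtual_patient("VP1", co2_sensitivity = 1,
#'                                            noise_sd_paco2 = 0))
#' run$session$disposition
#' @export
run_virtual_patient <- function(params, settings = niv_protocol(),
                                record = NULL, max_steps = 2000L) {
  stopifnot(inherits(params, "virtual_patient"))
  record <- record %||% patient_record(params$patient_id, "NEW")
  session <- new_session(record, settings)
  draw <- 0L
  steps <- 0L
  night_started_at <- NA_real_

  while (session$disposition == "IN_PROGRESS" && steps < max_steps) {
    steps <- steps + 1L
    st <- session$process_state
    cfg <- st$config
    input <- NULL
    if (st$phase == "PAUSED_ALKALOSIS") {
      if (is.null(session$pending$recheck)) {
        if (session$clock < st$pause_until) {
          input <- input_advance(st$pause_until - session$clock)
        } else {
          draw <- draw + 1L
          s <- simulate_bga(params, cfg, on_niv = FALSE, hours_on_niv = 0,
                            at = session$clock, draw = draw)
          input <- input_bga(s$ph, s$paco2, s$spo2, on_niv = FALSE)
        }
      } else {
        draw <- draw + 1L
        input <- input_approval(patient_approves(params, draw))
      }
    } else if (session$active_process == "INI") {
      if (st$phase == "VENTILATING") {
        input <- input_advance(st$phase_started_at +
                                 settings$ini_ventilation_minutes -
                                 session$clock)
      } else {
        draw <- draw + 1L
        prev <- if (st$expects_q4) st$prior_config
        input <- input_answers(answer_questionnaire(params, cfg, prev, draw))
      }
    } else if (session$active_process == "TDT") {
      if (st$phase == "VENTILATING") {
        input <- input_advance(st$bga_due_at - session$clock)
      } else if (st$phase == "AWAITING_BGA") {
        draw <- draw + 1L
        s <- simulate_bga(params, cfg, on_niv = TRUE,
                          hours_on_niv = settings$tdt_bga_offset_minutes / 60,
                          at = session$clock, draw = draw)
        input <- input_bga(s$ph, s$paco2, s$spo2, on_niv = TRUE)
      } else if (st$phase == "QUESTIONING") {
        if (is.null(session$pending$answers)) {
          draw <- draw + 1L
          input <- input_answers(answer_questionnaire(params, cfg, NULL, draw))
        } else {
          draw <- draw + 1L
          input <- input_approval(patient_approves(params, draw))
        }
      }
    } else { # TNT
      if (st$phase == "BASELINE_BGA") {
        draw <- draw + 1L
        s <- simulate_bga(params, cfg, on_niv = FALSE, hours_on_niv = 0,
                          at = session$clock, draw = draw)
        input <- input_bga(s$ph, s$paco2, s$spo2, on_niv = FALSE)
        night_started_at <- session$clock
      } else if (st$phase %in% c("NIGHT_BGA_1", "NIGHT_BGA_2")) {
        target <- night_started_at +
          if (st$phase == "NIGHT_BGA_1") 240 else 480
        if (session$clock < target) {
          input <- input_advance(target - session$clock)
        } else {
          draw <- draw + 1L
          hours <- min((session$clock - night_started_at) / 60, 8)
          s <- simulate_bga(params, cfg, on_niv = TRUE, hours_on_niv = hours,
                            at = session$clock, draw = draw)
          input <- input_bga(s$ph, s$paco2, s$spo2, on_niv = TRUE)
        }
      } else { # MORNING_EVALUATION
        draw <- draw + 1L
        prev <- if (st$changed_overnight) st$entry_config
        input <- input_answers(answer_questionnaire(params, cfg, prev, draw))
      }
    }
    session <- advance(session, input)
  }
  if (session$disposition == "IN_PROGRESS") {
    abort_protocol(sprintf("virtual run exceeded %d steps without a terminal disposition",
                           max_steps))
  }
  structure(list(session = session, params = params),
            class = "niv_virtual_run")
}

#' @export
print.niv_virtual_run <- function(x, ...) {
  s <- x$session
  cat(sprintf("<niv_virtual_run> %s: %s after %d night(s), final config %s\n",
              x$params$patient_id, s$disposition, s$nights_completed,
              if (is.null(s$record$stored_night_config)) "(none stored)"
              else format(s$record$stored_night_config)))
  invisible(x)
}

#' Run a cohort of virtual patients
#'
#' @param cohort A list of [virtual_patient()] objects, or a data frame of
#'   their parameters (one row per patient).
#' @param seed Integer; offsets every patient's private seed so a whole
#'   batch is reproducible from one number.
#' @param settings A [niv_protocol()].
#' @return A tibble with one row per patient: `patient_id`, `nights`,
#'   `final_ipap`, `disposition`.
#' @export
run_cohort <- function(cohort, seed = 1L, settings = niv_protocol()) {
  if (is.data.frame(cohort)) {
    cohort <- purrr::pmap(cohort, virtual_patient)
  }
  purrr::map_dfr(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    stopifnot(inherits(p, "virtual_patient"))
    p$rng_seed <- (p$rng_seed + as.integer(seed) * 1009L + i) %% .Machine$integer.max
    run <- run_virtual_patient(p, settings)
    s <- run$session
    final_cfg <- if (!is.null(s$record$stored_night_config)) {
      s$record$stored_night_config
    } else if (!is.null(s$process_state)) {
      s$process_state$config
    } else {
      last_config_in_log(s)
    }
    tibble::tibble(patient_id = p$patient_id,
                   nights = s$nights_completed,
                   final_ipap = final_cfg$ipap,
                   disposition = s$disposition)
  })
}

last_config_in_log <- function(session) {
  cfgs <- Filter(function(e) e$kind == "CONFIG_CHANGED", session$events)
  if (length(cfgs) == 0) return(default_initial_config())
  p <- cfgs[[length(cfgs)]]$payload
  ventilator_config(p$ipap, p$epap, p$backup_rate, p$rise_time_level,
                    p$trigger_level)
}
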