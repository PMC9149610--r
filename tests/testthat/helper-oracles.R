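# Independent oracles, coded directly from the rule statements and kept
# separate from the package's implementation paths.

# Safety gate: enumerate each rule firing, union the reasons, then derive
# the verdict by dominance (abort > pause > continue).
oracle_safety <- function(ph, spo2) {
  reasons <- character()
  if (spo2 < 85) reasons <- c(reasons, "HYPOXEMIA")
  if (ph < 7.35) reasons <- c(reasons, "ACIDOSIS")
  if (ph > 7.55) reasons <- c(reasons, "ALKALOSIS")
  verdict <-
    if (length(intersect(reasons, c("HYPOXEMIA", "ACIDOSIS")))) "ABORT_CALL_PHYSICIAN"
    else if (length(reasons)) "STOP_AND_PAUSE"
    else "CONTINUE"
  list(verdict = verdict, reasons = reasons)
}

# Two-criterion trend rule, written out longhand.
oracle_trend <- function(current, lowest, previous) {
  if (current <= 45) return("ADEQUATE")
  if (current > 50) return("NEEDS_ADJUSTMENT")
  improved_vs_lowest <- (lowest - current) > 5
  improved_vs_previous <- current < previous
  if (improved_vs_lowest && improved_vs_previous) "IMPROVING_TREND"
  else "NEEDS_ADJUSTMENT"
}

# Brute-force min / last-element over a raw value list.
oracle_lowest <- function(values) if (length(values)) min(values) else NA_real_
oracle_previous <- function(values) {
  if (length(values)) values[length(values)] else NA_real_
}

# Bisection on a monotone predicate over [lo, hi]; assumes pred(lo) != pred(hi).
bisect_boundary <- function(pred, lo, hi, tol = 1e-9) {
  f_lo <- pred(lo)
  stopifnot(pred(hi) != f_lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pred(mid) == f_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Record whose chart history is exactly `values` at minutes 0, 10, 20, ...
record_with_history <- function(values, id = "PX",
                                times = seq(0, by = 10,
                                            length.out = length(values))) {
  patient_record(id, "NEW", paco2_history = tibble::tibble(
    taken_at = times, paco2 = values))
}

satisfied_answers <- function(q4 = NULL) {
  questionnaire_response("ENOUGH", "ADEQUATE", FALSE, q4)
}

safe_bga <- function(at = 0, on_niv = TRUE, paco2 = 48) {
  blood_gas(ph = 7.42, paco2 = paco2, spo2 = 93, taken_at = at,
            on_niv = on_niv)
}

# Drive a new-patient session from INI start through a completed TDT
# (always-satisfied patient), leaving it at TNT baseline.
session_at_tnt_baseline <- function(id = "P1") {
  s <- new_session(patient_record(id, "NEW"))
  s <- advance(s, input_advance(5))
  s <- advance(s, input_answers(satisfied_answers()))   # INI done -> TDT
  s <- advance(s, input_advance(15))
  s <- advance(s, input_bga(7.42, 54, 93))
  s <- advance(s, input_answers(satisfied_answers()))   # TDT done -> TNT
  s
}

# Exhaustive walk of the INI answer-sequence state graph (deduplicated
# breadth-first search over the full questionnaire alphabet). Returns the
# number of distinct states, whether the frontier exhausted (=> every
# answer sequence terminates), the max IPAP seen, and invariant violations.
ini_exhaustive_walk <- function(settings = niv_protocol(), max_depth = 15L,
                                q2s = c("ADEQUATE", "TOO_FAST", "TOO_SLOW")) {
  q1s <- c("ENOUGH", "TOO_MUCH", "TOO_LITTLE")
  ans_noq4 <- list(); ans_q4 <- list()
  for (q1 in q1s) for (q2 in q2s) for (q3 in c(FALSE, TRUE)) {
    ans_noq4[[length(ans_noq4) + 1L]] <- questionnaire_response(q1, q2, q3)
    for (q4 in c(TRUE, FALSE)) {
      ans_q4[[length(ans_q4) + 1L]] <- questionnaire_response(q1, q2, q3, q4)
    }
  }
  key <- function(st) paste(
    st$config$ipap, st$config$rise_time_level, st$config$trigger_level,
    st$expects_q4, paste(st$family_changes, collapse = "."),
    paste(sort(st$frozen), collapse = "."),
    paste(sort(st$changed_last_round), collapse = "."), sep = "|")
  start <- ini_start(patient_record("WALK", "NEW"), settings)
  start <- nivflow:::ini_on_clock(start, settings$ini_ventilation_minutes,
                                  settings)
  seen <- new.env(parent = emptyenv())
  assign(key(start), TRUE, envir = seen)
  frontier <- list(start)
  depth <- 0L; violations <- 0L; max_ipap <- start$config$ipap
  while (length(frontier) > 0 && depth < max_depth) {
    depth <- depth + 1L
    nxt <- list()
    for (st in frontier) {
      alist <- if (st$expects_q4) ans_q4 else ans_noq4
      for (a in alist) {
        res <- ini_apply_answers(st, a, settings)
        if (res$config$ipap > settings$ini_ipap_cap ||
            res$config$ipap <= res$config$epap) {
          violations <- violations + 1L
        }
        if (res$config$ipap > max_ipap) max_ipap <- res$config$ipap
        if (res$phase == "DONE") next
        res <- nivflow:::ini_on_clock(res, res$phase_started_at +
                                        settings$ini_ventilation_minutes,
                                      settings)
        k <- key(res)
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          nxt <- c(nxt, list(res))
        }
      }
    }
    frontier <- nxt
  }
  list(n_states = length(ls(seen)), exhausted = length(frontier) == 0L,
       depth = depth, max_ipap = max_ipap, violations = violations)
}

# Exhaustive tree walk over TDT answer/approval/blood-gas-class sequences.
# Branches at every decision point; returns violations and whether every
# path reached DONE or ABORTED within the step bound.
tdt_exhaustive_walk <- function(settings = niv_protocol(), start_ipap = 16L,
                                max_steps = 40L) {
  unfinished <- 0L; violations <- 0L; paths <- 0L; max_cycles <- 0L
  bga_classes <- list(
    safe = function(at) blood_gas(7.42, 50, 93, taken_at = at),
    acidotic = function(at) blood_gas(7.30, 60, 93, taken_at = at),
    hypoxemic = function(at) blood_gas(7.42, 50, 80, taken_at = at),
    alkalotic = function(at) blood_gas(7.60, 35, 95, taken_at = at))
  recheck_classes <- list(
    resolved = function(at) blood_gas(7.45, 45, 95, taken_at = at),
    persists = function(at) blood_gas(7.58, 38, 95, taken_at = at))
  # recurrent alkalosis is capped per path: the stop-pause-retry loop is
  # deliberately unbounded in the protocol (it is a safety loop, not a
  # titration loop), so the gas adversary may trigger it at most twice
  explore <- function(st, clock, steps, alk = 0L) {
    if (st$cycle_count > settings$tdt_max_cycles ||
        st$config$ipap <= st$config$epap) {
      violations <<- violations + 1L
    }
    if (st$cycle_count > max_cycles) max_cycles <<- st$cycle_count
    if (st$phase %in% c("DONE", "ABORTED")) {
      paths <<- paths + 1L
      return(invisible())
    }
    if (steps >= max_steps) {
      unfinished <<- unfinished + 1L
      return(invisible())
    }
    if (st$phase == "VENTILATING") {
      clock2 <- st$bga_due_at
      explore(nivflow:::tdt_on_clock(st, clock2, settings), clock2,
              steps + 1L, alk)
    } else if (st$phase == "AWAITING_BGA") {
      classes <- if (alk < 2L) bga_classes
                 else bga_classes[c("safe", "acidotic", "hypoxemic")]
      for (nm in names(classes)) {
        explore(tdt_receive_bga(st, classes[[nm]](clock), settings, clock),
                clock, steps + 1L, alk + (nm == "alkalotic"))
      }
    } else if (st$phase == "PAUSED_ALKALOSIS") {
      clock2 <- st$pause_until
      for (mk in recheck_classes) for (ok in c(TRUE, FALSE)) {
        explore(tdt_resume_after_pause(st, mk(clock2), ok, settings, clock2),
                clock2, steps + 1L, alk)
      }
    } else if (st$phase == "QUESTIONING") {
      for (q1 in c("ENOUGH", "TOO_MUCH", "TOO_LITTLE")) {
        for (ok in c(TRUE, FALSE)) {
          explore(tdt_apply_q1(st, questionnaire_response(q1), ok, settings,
                               clock), clock, steps + 1L, alk)
        }
      }
    } else {
      violations <<- violations + 1L
    }
  }
  cfg <- ventilator_config(start_ipap, 5, 18)
  st <- tdt_start(patient_record("WALK", "NEW"), "AFTER_INI", cfg, settings)
  explore(st, 0, 0L)
  list(paths = paths, unfinished = unfinished, violations = violations,
       max_cycles = max_cycles)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Sequence of process starts as a word over I (INI), D (TDT), N (TNT),
# reconstructed from the audit log: TDT starts carry their entry_path in
# the first STATE_ENTERED payload, TNT starts enter at BASELINE_BGA, and
# INI runs at most once, at the head of the log.
process_word <- function(session) {
  letters <- vapply(session$events, function(e) {
    if (e$kind != "STATE_ENTERED") return("")
    if (e$process == "TDT" && !is.null(e$payload$entry_path)) return("D")
    if (e$process == "TNT" && identical(e$payload$phase, "BASELINE_BGA"))
      return("N")
    ""
  }, "")
  ini <- if (any(vapply(session$events, function(e) e$process == "INI",
                        logical(1)))) "I" else ""
  paste0(ini, paste(letters[letters != ""], collapse = ""))
}

# New-patient routing language: INI, then TDT, then TNT, then any mix of
# repeat-TNT and repeat-TDT-then-TNT; a trailing D is a trajectory that
# ended (aborted) during a repeated day-time titration.
new_patient_routing_ok <- function(word) {
  grepl("^I$|^ID$|^IDN(N|DN)*D?$", word)
}
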