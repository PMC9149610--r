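# JSON session persistence and batch I/O. The session document is plain,
# diff-able JSON with a fixed key order; serialisation is canonical, so
# byte-comparison of two documents is a faithful equality test on sessions
# and the replay-determinism contract can be checked byte-for-byte.

SCHEMA_VERSION <- "1"

ser_config <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  list(mode = cfg$mode, ipap = cfg$ipap, epap = cfg$epap,
       backup_rate = cfg$backup_rate, rise_time_level = cfg$rise_time_level,
       trigger_level = cfg$trigger_level, scale_max = cfg$scale_max)
}

deser_config <- function(x) {
  if (is.null(x)) return(NULL)
  ventilator_config(ipap = x$ipap, epap = x$epap, backup_rate = x$backup_rate,
                    rise_time_level = x$rise_time_level,
                    trigger_level = x$trigger_level, mode = x$mode,
                    scale_max = x$scale_max)
}

ser_sample <- function(s) {
  if (is.null(s)) return(NULL)
  list(ph = s$ph, paco2 = s$paco2, spo2 = s$spo2, taken_at = s$taken_at,
       on_niv = s$on_niv, source = s$source)
}

deser_sample <- function(x) {
  if (is.null(x)) return(NULL)
  blood_gas(ph = x$ph, paco2 = x$paco2, spo2 = x$spo2,
            taken_at = x$taken_at, on_niv = isTRUE(x$on_niv),
            source = x$source)
}

ser_answers <- function(a) {
  if (is.null(a)) return(NULL)
  list(q1 = a$q1_air_amount, q2 = a$q2_air_speed,
       q3 = a$q3_trigger_exhausting, q4 = a$q4_more_comfortable)
}

deser_answers <- function(x) {
  if (is.null(x)) return(NULL)
  questionnaire_response(x$q1, x$q2, x$q3, x$q4)
}

ser_record <- function(r) {
  list(patient_id = r$patient_id, status = r$status,
       paco2_history = list(taken_at = as.list(r$paco2_history$taken_at),
                            paco2 = as.list(r$paco2_history$paco2)),
       stored_night_config = ser_config(r$stored_night_config))
}

deser_record <- function(x) {
  patient_record(
    x$patient_id, x$status,
    paco2_history = tibble::tibble(
      taken_at = as.numeric(unlist(x$paco2_history$taken_at) %||% numeric()),
      paco2 = as.numeric(unlist(x$paco2_history$paco2) %||% numeric())),
    stored_night_config = deser_config(x$stored_night_config))
}

chr_list <- function(x) as.list(x)

chr_vec <- function(x) as.character(unlist(x) %||% character())

ser_state <- function(st) {
  if (is.null(st)) return(NULL)
  base <- list(state_type = class(st)[1], phase = st$phase,
               config = ser_config(st$config))
  extra <- switch(class(st)[1],
    ini_state = list(
      prior_config = ser_config(st$prior_config),
      phase_started_at = st$phase_started_at, expects_q4 = st$expects_q4,
      changed_last_round = chr_list(st$changed_last_round),
      family_changes = as.list(st$family_changes),
      frozen = chr_list(st$frozen)),
    tdt_state = list(
      cycle_count = st$cycle_count, entry_path = st$entry_path,
      cycle_started_at = st$cycle_started_at, bga_due_at = st$bga_due_at,
      pause_until = st$pause_until),
    tnt_state = list(
      entry_config = ser_config(st$entry_config),
      samples = lapply(st$samples, ser_sample),
      resume_phase = st$resume_phase, pause_until = st$pause_until,
      changed_overnight = st$changed_overnight)
  )
  c(base, extra)
}

deser_state <- function(x) {
  if (is.null(x)) return(NULL)
  common <- list(phase = x$phase, config = deser_config(x$config),
                 pending_events = list())
  st <- switch(x$state_type,
    ini_state = c(list(process = "INI"), common, list(
      prior_config = deser_config(x$prior_config),
      phase_started_at = as.numeric(x$phase_started_at),
      expects_q4 = isTRUE(x$expects_q4),
      changed_last_round = chr_vec(x$changed_last_round),
      family_changes = stats::setNames(
        as.integer(unlist(x$family_changes)), names(x$family_changes)),
      frozen = chr_vec(x$frozen))),
    tdt_state = c(list(process = "TDT"), common, list(
      cycle_count = as.integer(x$cycle_count), entry_path = x$entry_path,
      cycle_started_at = as.numeric(x$cycle_started_at),
      bga_due_at = as.numeric(x$bga_due_at),
      pause_until = if (!is.null(x$pause_until)) as.numeric(x$pause_until))),
    tnt_state = c(list(process = "TNT"), common, list(
      entry_config = deser_config(x$entry_config),
      samples = lapply(x$samples, deser_sample),
      resume_phase = x$resume_phase,
      pause_until = if (!is.null(x$pause_until)) as.numeric(x$pause_until),
      changed_overnight = isTRUE(x$changed_overnight))),
    abort_input(sprintf("unknown process state type '%s'", x$state_type))
  )
  # restore canonical field order per constructor
  ord <- switch(x$state_type,
    ini_state = c("process", "phase", "config", "prior_config",
                  "phase_started_at", "expects_q4", "changed_last_round",
                  "family_changes", "frozen", "pending_events"),
    tdt_state = c("process", "phase", "config", "cycle_count", "entry_path",
                  "cycle_started_at", "bga_due_at", "pause_until",
                  "pending_events"),
    tnt_state = c("process", "phase", "config", "entry_config", "samples",
                  "resume_phase", "pause_until", "changed_overnight",
                  "pending_events"))
  st <- st[ord]
  structure(st, class = c(x$state_type, "niv_process_state"))
}

ser_settings <- function(p) {
  u <- unclass(p)
  u$nonconforming_thresholds <- NULL
  u
}

deser_settings <- function(x) do.call(niv_protocol, x)

session_to_document <- function(session, created_at = NULL, updated_at = NULL) {
  list(
    schema_version = SCHEMA_VERSION,
    created_at = created_at %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    updated_at = updated_at %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    session = list(
      session_id = session$session_id,
      entry = session$entry,
      clock = session$clock,
      disposition = session$disposition,
      active_process = session$active_process,
      nights_completed = session$nights_completed,
      next_seq = session$next_seq,
      record = ser_record(session$record),
      initial_record = ser_record(session$initial_record),
      settings = ser_settings(session$settings),
      process_state = ser_state(session$process_state),
      pending = list(answers = ser_answers(session$pending$answers),
                     recheck = ser_sample(session$pending$recheck)),
      events = session$events,
      inputs = session$inputs
    )
  )
}

document_to_session <- function(doc) {
  if (is.null(doc$schema_version) || !identical(doc$schema_version, SCHEMA_VERSION)) {
    abort_input(sprintf(
      "unsupported session schema_version '%s' (this build reads version %s); migrate the document first",
      doc$schema_version %||% "<missing>", SCHEMA_VERSION))
  }
  s <- doc$session
  events <- lapply(s$events, function(e) {
    list(seq = as.integer(e$seq), at = as.numeric(e$at),
         process = e$process, kind = e$kind, payload = e$payload)
  })
  structure(
    list(session_id = s$session_id, record = deser_record(s$record),
         initial_record = deser_record(s$initial_record),
         settings = deser_settings(s$settings), entry = s$entry,
         clock = as.numeric(s$clock), active_process = s$active_process,
         process_state = deser_state(s$process_state),
         disposition = s$disposition, events = events, inputs = s$inputs,
         next_seq = as.integer(s$next_seq),
         pending = list(answers = deser_answers(s$pending$answers),
                        recheck = deser_sample(s$pending$recheck)),
         nights_completed = as.integer(s$nights_completed)),
    class = "niv_session"
  )
}

#' Canonical JSON serialisation of a session
#'
#' Fixed key order, stable number formatting: two sessions are equal
#' exactly when their canonical JSON agrees byte-for-byte (timestamps of
#' the containing document are excluded).
#'
#' @param session A `niv_session`.
#' @return A JSON string.
#' @export
session_json <- function(session) {
  doc <- session_to_document(session)
  as.character(jsonlite::toJSON(doc$session, auto_unbox = TRUE, null = "null",
                                digits = NA, pretty = TRUE))
}

#' Save and load sessions as JSON documents
#'
#' The document embeds a schema version, the full event log and every
#' recorded external input, so a loaded session can continue or be
#' replayed. Writing is atomic (temp file + rename): a crash never leaves
#' a partial document.
#'
#' @param session A `niv_session`.
#' @param path File path.
#' @return `save_session` invisibly returns `path`; `load_session` returns
#'   the `niv_session`.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "niv_session"))
  doc <- session_to_document(session)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
  tmp <- paste0(path, ".tmp")
  writeLines(json, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no session file at '%s'", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort_input(sprintf("malformed session document '%s': %s", path,
                          conditionMessage(e)))
    })
  document_to_session(doc)
}

#' Cohort files for batch runs
#'
#' A cohort file is a JSON array of virtual-patient parameter objects.
#'
#' @param cohort A list of [virtual_patient()] objects.
#' @param path File path.
#' @return `write_cohort` invisibly returns `path`; `read_cohort` returns
#'   a list of `virtual_patient` objects.
#' @export
write_cohort <- function(cohort, path) {
  entries <- lapply(cohort, function(p) {
    stopifnot(inherits(p, "virtual_patient"))
    unclass(p)
  })
  json <- jsonlite::toJSON(entries, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no cohort file at '%s'", path))
  entries <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort_input(sprintf("malformed cohort file '%s': %s", path,
                          conditionMessage(e)))
    })
  lapply(entries, function(e) do.call(virtual_patient, e))
}

#' Batch-run a cohort file and write a disposition table
#'
#' Closes the loop between the engine and the cohort's virtual patients
#' and writes one TSV row per patient (`patient_id`, `nights`,
#' `final_ipap`, `disposition`). Identical seed and cohort give a
#' byte-identical table.
#'
#' @param cohort_path Path to a cohort JSON file.
#' @param seed Integer batch seed.
#' @param out Optional path for the TSV; `NULL` writes to stdout.
#' @param settings A [niv_protocol()].
#' @return The summary tibble, invisibly.
#' @export
run_batch <- function(cohort_path, seed = 1L, out = NULL,
                      settings = niv_protocol()) {
  if (length(settings$nonconforming_thresholds)) {
    message("WARNING: protocol thresholds overridden (",
            paste(settings$nonconforming_thresholds, collapse = ", "),
            "); results do not conform to the published protocol")
  }
  cohort <- read_cohort(cohort_path)
  res <- run_cohort(cohort, seed = seed, settings = settings)
  dest <- out %||% stdout()
  utils::write.table(res, dest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
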