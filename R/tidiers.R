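#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a session into its event log
#'
#' One row per audit event: sequence number, session-clock minute, owning
#' process, event kind, and a compact rendering of the payload.
#'
#' @param x A `niv_session`.
#' @param ... Unused.
#' @return A tibble with columns `seq`, `at`, `process`, `kind`, `detail`.
#' @export
tidy.niv_session <- function(x, ...) {
  purrr::map_dfr(x$events, function(ev) {
    tibble::tibble(
      seq = ev$seq, at = ev$at, process = ev$process, kind = ev$kind,
      detail = payload_detail(ev$payload))
  })
}

payload_detail <- function(p) {
  if (length(p) == 0) return("")
  flat <- purrr::imap_chr(p, function(v, k) {
    val <- if (is.list(v)) paste(unlist(v), collapse = "+")
           else paste(format(v), collapse = "+")
    paste0(k, "=", val)
  })
  paste(flat, collapse = "; ")
}

#' One-row summary of a session
#'
#' @param x A `niv_session`.
#' @param ... Unused.
#' @return A tibble with `session_id`, `patient_id`, `status`,
#'   `disposition`, `clock`, `nights`, `n_events`, `final_ipap`.
#' @export
glance.niv_session <- function(x, ...) {
  cfg <- if (!is.null(x$record$stored_night_config)) {
    x$record$stored_night_config
  } else if (!is.null(x$process_state)) {
    x$process_state$config
  } else {
    NULL
  }
  tibble::tibble(
    session_id = x$session_id, patient_id = x$record$patient_id,
    status = x$record$status, disposition = x$disposition,
    clock = x$clock, nights = x$nights_completed,
    n_events = length(x$events),
    final_ipap = if (is.null(cfg)) NA_integer_ else cfg$ipap)
}

#' Configuration trajectory of a session
#'
#' Every configuration the engine applied, in order, as a tibble — the
#' titration path of the inspiratory pressure and comfort levels.
#'
#' @param session A `niv_session`.
#' @return A tibble with `at`, `process`, `ipap`, `epap`, `backup_rate`,
#'   `rise_time_level`, `trigger_level`.
#' @export
config_trajectory <- function(session) {
  evs <- Filter(function(e) e$kind == "CONFIG_CHANGED", session$events)
  purrr::map_dfr(evs, function(ev) {
    p <- ev$payload
    tibble::tibble(at = ev$at, process = ev$process, ipap = p$ipap,
                   epap = p$epap, backup_rate = p$backup_rate,
                   rise_time_level = p$rise_time_level,
                   trigger_level = p$trigger_level)
  })
}

#' Measurement trajectory of a session
#'
#' All recorded blood gases in order.
#'
#' @param session A `niv_session`.
#' @return A tibble with `at`, `process`, `ph`, `paco2`, `spo2`, `on_niv`.
#' @export
measurement_trajectory <- function(session) {
  evs <- Filter(function(e) e$kind == "MEASUREMENT_RECORDED", session$events)
  purrr::map_dfr(evs, function(ev) {
    p <- ev$payload
    tibble::tibble(at = ev$at, process = ev$process, ph = p$ph,
                   paco2 = p$paco2, spo2 = p$spo2,
                   on_niv = isTRUE(p$on_niv))
  })
}

#' Plot a session's titration course
#'
#' Two panels over the session clock: the inspiratory/expiratory pressures
#' as step lines, and the recorded PaCO2 values with the adequacy band of
#' the nocturnal trend rule shaded.
#'
#' @param object A `niv_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.niv_session <- function(object, ...) {
  cfg <- config_trajectory(object)
  bga <- measurement_trajectory(object)
  cfg_long <- tidyr_pivot(cfg)
  p <- ggplot2::ggplot() +
    ggplot2::geom_step(
      data = cfg_long,
      ggplot2::aes(x = .data$at, y = .data$pressure, colour = .data$which),
      linewidth = 0.6) +
    ggplot2::labs(x = "session clock (min)", y = "pressure (mbar)",
                  colour = NULL,
                  title = sprintf("Titration course: %s (%s)",
                                  object$session_id, object$disposition))
  if (nrow(bga) > 0) {
    sc <- max(cfg_long$pressure) / max(bga$paco2)
    p <- p +
      ggplot2::geom_point(
        data = bga,
        ggplot2::aes(x = .data$at, y = .data$paco2 * sc,
                     shape = .data$on_niv)) +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / sc, name = "PaCO2 (mmHg)")) +
      ggplot2::labs(shape = "on NIV")
  }
  p
}

tidyr_pivot <- function(cfg) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(cfg, "at", pressure = "ipap"), which = "IPAP"),
    dplyr::mutate(dplyr::select(cfg, "at", pressure = "epap"), which = "EPAP"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort disposition summary
#'
#' @param summary A tibble from [run_cohort()].
#' @return A ggplot bar chart of dispositions, filled by nights needed.
#' @export
plot_cohort_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$disposition,
                               fill = factor(.data$nights))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "patients", fill = "nights")
}
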