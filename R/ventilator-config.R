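#' Ventilator configuration
#'
#' The setting vector the engine titrates: pressure-support mode with
#' inspiratory (IPAP) and expiratory (EPAP) positive airway pressure in
#' mbar, a backup breath rate, and ordinal comfort levels for rise time and
#' trigger sensitivity (1..`scale_max`; level 1 = fastest rise / most
#' sensitive trigger).
#'
#' @param ipap Inspiratory positive airway pressure, whole mbar; must
#'   strictly exceed `epap`.
#' @param epap Expiratory positive airway pressure, whole mbar, positive.
#' @param backup_rate Backup breath frequency per minute, positive integer.
#' @param rise_time_level,trigger_level Ordinal levels within
#'   `1..scale_max`.
#' @param mode Ventilation mode; only pressure support (`"PS"`) is in scope.
#' @param scale_max Upper bound of the ordinal comfort scales.
#' @return A `ventilator_config` object.
#' @examples
#' ventilator_config(ipap = 16, epap = 5, backup_rate = 18)
#' @export
ventilator_config <- function(ipap, epap, backup_rate,
                              rise_time_level = 3L, trigger_level = 3L,
                              mode = "PS", scale_max = 5L) {
  if (!identical(mode, "PS")) {
    abort_input("only pressure-support mode ('PS') is supported")
  }
  ipap <- check_integerish(ipap, "ipap")
  epap <- check_integerish(epap, "epap")
  backup_rate <- check_integerish(backup_rate, "backup_rate")
  rise_time_level <- check_integerish(rise_time_level, "rise_time_level")
  trigger_level <- check_integerish(trigger_level, "trigger_level")
  scale_max <- check_integerish(scale_max, "scale_max")
  if (epap <= 0L || ipap <= 0L || backup_rate <= 0L) {
    abort_input("ipap, epap and backup_rate must be strictly positive")
  }
  if (ipap <= epap) {
    abort_input(sprintf("ipap (%d) must strictly exceed epap (%d)", ipap, epap))
  }
  if (rise_time_level < 1L || rise_time_level > scale_max ||
      trigger_level < 1L || trigger_level > scale_max) {
    abort_input(sprintf("comfort levels must lie in 1..%d", scale_max))
  }
  structure(
    list(mode = mode, ipap = ipap, epap = epap, backup_rate = backup_rate,
         rise_time_level = rise_time_level, trigger_level = trigger_level,
         scale_max = scale_max),
    class = "ventilator_config"
  )
}

#' Best-practice initial configuration for first initiation of NIV
#'
#' Pressure-support ventilation at IPAP 16 mbar, EPAP 5 mbar, backup
#' frequency 18/minute — the starting configuration feasible for most
#' patients — with mid-scale rise-time and trigger levels.
#'
#' @return A `ventilator_config`.
#' @examples
#' default_initial_config()
#' @export
default_initial_config <- function() {
  ventilator_config(ipap = 16L, epap = 5L, backup_rate = 18L,
                    rise_time_level = 3L, trigger_level = 3L)
}

#' @export
print.ventilator_config <- function(x, ...) {
  cat(sprintf(
    "<ventilator_config> mode %s | IPAP %d mbar | EPAP %d mbar | backup %d/min | rise %d | trigger %d\n",
    x$mode, x$ipap, x$epap, x$backup_rate, x$rise_time_level, x$trigger_level))
  invisible(x)
}

#' @export
format.ventilator_config <- function(x, ...) {
  sprintf("PS %d/%d mbar, backup %d, rise %d, trigger %d",
          x$ipap, x$epap, x$backup_rate, x$rise_time_level, x$trigger_level)
}

config_equal <- function(a, b) {
  identical(unclass(a)[c("mode", "ipap", "epap", "backup_rate",
                         "rise_time_level", "trigger_level")],
            unclass(b)[c("mode", "ipap", "epap", "backup_rate",
                         "rise_time_level", "trigger_level")])
}

# replace a field, revalidating every invariant
config_with <- function(config, ...) {
  new <- utils::modifyList(unclass(config), list(...))
  ventilator_config(ipap = new$ipap, epap = new$epap,
                    backup_rate = new$backup_rate,
                    rise_time_level = new$rise_time_level,
                    trigger_level = new$trigger_level,
                    mode = new$mode, scale_max = new$scale_max)
}
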