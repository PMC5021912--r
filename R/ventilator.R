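# BIPAP pressure-setpoint waveform. The ventilator is an ideal pressure
# source cycling between two levels; five scalars define the waveform.

#' BIPAP ventilator settings
#'
#' The five controls of a bi-level positive airway pressure ventilator.
#' Within each breath cycle of period `60/BPM` seconds the setpoint ramps
#' linearly from EPAP to IPAP over the rise time `Tr`, holds at IPAP until
#' the end of inspiration `Ti`, then steps down to EPAP for the rest of the
#' cycle.
#'
#' @param IPAP Inspiratory positive airway pressure (cmH2O gauge).
#' @param EPAP Expiratory positive airway pressure (cmH2O gauge).
#' @param BPM Breaths per minute.
#' @param Ti Inspiratory time (s).
#' @param Tr Pressure rise time (s), `0 < Tr <= Ti`.
#' @return An object of class `"ventilator_settings"`.
#' @details Defaults are the reference operating point: IPAP 22, EPAP 4
#'   cmH2O, 20 breaths/min, `Ti` 1 s, `Tr` 0.3 s. `IPAP == EPAP` is allowed
#'   (a constant-pressure source that ventilates nothing).
#' @examples
#' ventilator_settings()
#' ventilator_settings(IPAP = 18, BPM = 25)
#' @export
ventilator_settings <- function(IPAP = 22, EPAP = 4, BPM = 20, Ti = 1, Tr = 0.3) {
  for (nm in c("IPAP", "EPAP", "BPM", "Ti", "Tr")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("'%s' must be a finite numeric scalar", nm), call. = FALSE)
  }
  if (EPAP < 0) stop("'EPAP' must be >= 0 cmH2O", call. = FALSE)
  if (IPAP < EPAP) stop("'IPAP' must be >= 'EPAP'", call. = FALSE)
  if (BPM <= 0) stop("'BPM' must be positive", call. = FALSE)
  if (Tr <= 0) stop("rise time 'Tr' must be positive", call. = FALSE)
  if (Tr > Ti) stop("rise time 'Tr' must not exceed inspiratory time 'Ti'",
                    call. = FALSE)
  if (Ti >= 60 / BPM)
    stop(sprintf("inspiratory time 'Ti' (%g s) must be shorter than the cycle period (%g s)",
                 Ti, 60 / BPM), call. = FALSE)
  structure(list(IPAP = IPAP, EPAP = EPAP, BPM = BPM, Ti = Ti, Tr = Tr),
            class = "ventilator_settings")
}

#' @export
print.ventilator_settings <- function(x, ...) {
  cat(sprintf("BIPAP settings: IPAP %g / EPAP %g cmH2O, %g breaths/min, Ti %g s, Tr %g s\n",
              x$IPAP, x$EPAP, x$BPM, x$Ti, x$Tr))
  invisible(x)
}

#' Breath cycle period
#'
#' @param settings A [ventilator_settings()] object.
#' @return Cycle period `60/BPM` in seconds.
#' @export
cycle_period <- function(settings) {
  stopifnot(inherits(settings, "ventilator_settings"))
  60 / settings$BPM
}

# waveform on [0, T): linear ramp EPAP -> IPAP over Tr, IPAP plateau to Ti,
# EPAP for the remainder; vectorised, no validation
.setpoint <- function(t, IPAP, EPAP, BPM, Ti, Tr) {
  tm <- t %% (60 / BPM)
  ifelse(tm < Tr, EPAP + (IPAP - EPAP) * tm / Tr,
         ifelse(tm < Ti, IPAP, EPAP))
}

#' BIPAP pressure setpoint waveform
#'
#' Evaluates the ventilator's pressure setpoint at time `t` (seconds since
#' a cycle start; the waveform is extended periodically for any real `t`).
#'
#' @param t Time(s) in seconds; vectorised.
#' @param settings A [ventilator_settings()] object.
#' @return Setpoint pressure(s) in cmH2O gauge, within `[EPAP, IPAP]`.
#' @examples
#' s <- ventilator_settings()
#' pressure_setpoint(c(0, 0.15, 0.3, 0.9, 1.5), s)
#' @export
pressure_setpoint <- function(t, settings) {
  stopifnot(inherits(settings, "ventilator_settings"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  .setpoint(t, settings$IPAP, settings$EPAP, settings$BPM,
            settings$Ti, settings$Tr)
}
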