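#' Baseline mediator parameters
#'
#' Parameters of the basal mediator level and the predictive-homeostasis
#' threshold. The mediator (e.g. plasma corticosterone, heart rate)
#' fluctuates seasonally with amplitude `a_s` and angular frequency
#' `b_s`, and daily with amplitude `a_c` and angular frequency `b_c`,
#' about the basal level `y_c`:
#'
#' `y(t) = a_s sin(b_s t + phase_s) + a_c sin(b_c t + phase_c) + s(t) + y_c`
#'
#' The predictive-homeostasis threshold adds the full circadian
#' amplitude (not its instantaneous value) plus an offset `y_act` for
#' predictable activity:
#'
#' `P(t) = a_s sin(b_s t + phase_s) + a_c + y_c + y_act`
#'
#' so that, with no stress schedule, `y(t) <= P(t)` at all times.
#'
#' @param a_s Seasonal amplitude, mediator units, `>= 0`.
#' @param b_s Seasonal angular frequency, radians per time unit.
#' @param a_c Circadian amplitude, mediator units, `>= 0`.
#' @param b_c Circadian angular frequency, radians per time unit
#'   (`2 * pi` for a one-day period when time is in days).
#' @param y_c Basal mediator level, `> 0`; must satisfy
#'   `y_c - a_s - a_c >= 0` so that the stress-free mediator level is
#'   never negative.
#' @param y_act Predictable-activity offset, mediator units, `>= 0`.
#' @param phase_s,phase_c Phase offsets in radians (default 0); used by
#'   scenarios that align the circadian peak with event onset.
#' @param time_unit Label for the time axis (documentation only).
#' @return An object of class `"baseline_params"`.
#' @examples
#' bp <- baseline_params(a_c = 6, b_c = 2 * pi, y_c = 12)
#' mediator_level(c(0, 0.25), bp, stress_schedule())
#' @export
baseline_params <- function(a_s = 0, b_s = 0, a_c = 0, b_c = 0, y_c,
                            y_act = 0, phase_s = 0, phase_c = 0,
                            time_unit = "dimensionless") {
  p <- structure(
    list(a_s = a_s, b_s = b_s, a_c = a_c, b_c = b_c, y_c = y_c,
         y_act = y_act, phase_s = phase_s, phase_c = phase_c,
         time_unit = time_unit),
    class = "baseline_params"
  )
  bad <- validate_baseline(p)
  if (length(bad) > 0)
    stop("invalid baseline parameters:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  p
}

#' Validate baseline parameters
#'
#' @param p A `"baseline_params"` object (or bare list with the same
#'   fields).
#' @return Character vector of violated constraints; empty when valid.
#' @export
validate_baseline <- function(p) {
  bad <- character(0)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("a_s", "b_s", "a_c", "b_c", "y_c", "y_act",
              "phase_s", "phase_c")) {
    if (!num1(p[[f]])) bad <- c(bad, sprintf("`%s` must be a finite number", f))
  }
  if (length(bad) > 0) return(bad)
  if (p$a_s < 0) bad <- c(bad, "seasonal amplitude `a_s` must be >= 0")
  if (p$a_c < 0) bad <- c(bad, "circadian amplitude `a_c` must be >= 0")
  if (p$y_c <= 0) bad <- c(bad, "basal level `y_c` must be > 0")
  if (p$y_act < 0) bad <- c(bad, "activity offset `y_act` must be >= 0")
  if (p$y_c - p$a_s - p$a_c < 0)
    bad <- c(bad, paste0("`y_c` must be large enough that the mediator level ",
                         "stays nonnegative: need y_c - a_s - a_c >= 0"))
  bad
}

#' @export
print.baseline_params <- function(x, ...) {
  cat(sprintf(paste0("<baseline_params: a_s = %g, b_s = %g, a_c = %g, ",
                     "b_c = %g, y_c = %g, y_act = %g (time in %s)>\n"),
              x$a_s, x$b_s, x$a_c, x$b_c, x$y_c, x$y_act, x$time_unit))
  invisible(x)
}

#' Mediator level y(t)
#'
#' Basal seasonal + circadian oscillation about `y_c`, plus the stress
#' schedule contribution `s(t)`.
#'
#' @param t Time(s).
#' @param p A [baseline_params()] object.
#' @param sched A [stress_schedule()]; defaults to the empty schedule.
#' @return Mediator level(s), nonnegative under the parameter invariant.
#' @export
mediator_level <- function(t, p, sched = stress_schedule()) {
  stopifnot(inherits(p, "baseline_params"))
  p$a_s * sin(p$b_s * t + p$phase_s) + p$a_c * sin(p$b_c * t + p$phase_c) +
    eval_schedule(sched, t) + p$y_c
}

#' Predictive-homeostasis threshold P(t)
#'
#' Upper bound of the predictive-homeostasis range: the seasonal
#' oscillation plus the full circadian amplitude, the basal level, and
#' the predictable-activity offset. Rides above the daily maximum of the
#' circadian term, so the stress-free mediator never exceeds it.
#'
#' @inheritParams mediator_level
#' @return Threshold value(s) in mediator units.
#' @export
predictive_threshold <- function(t, p) {
  stopifnot(inherits(p, "baseline_params"))
  p$a_s * sin(p$b_s * t + p$phase_s) + p$a_c + p$y_c + p$y_act +
    0 * t  # recycle to length(t)
}
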