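#' Box (rectangular) stress-event kernel
#'
#' Unit-height indicator of the open interval `(mu, mu + sigma)`. The
#' boundaries themselves evaluate to 0 (strict inequalities), so a box
#' event switches on just after its onset `mu` and off at `mu + sigma`.
#'
#' @param t Time(s) at which to evaluate the kernel (vectorised).
#' @param mu Event onset time, `> 0`.
#' @param sigma Event duration, `> 0`.
#' @return Numeric vector of kernel values in `{0, 1}`.
#' @seealso [kernel_ramp()], [kernel_gaussian()], [stress_event()]
#' @examples
#' kernel_box(c(0.2, 0.25, 0.6), mu = 0.2, sigma = 0.1)
#' @export
kernel_box <- function(t, mu, sigma) {
  check_kernel_params(mu, sigma)
  as.numeric(t > mu & t < mu + sigma)
}

#' Ramp (rise/fall) stress-event kernel
#'
#' Piecewise-linear kernel: 0 at the onset `mu`, rising linearly to 1 at
#' `mu + sigma` (the up-regulation leg), then falling linearly back to 0
#' at `mu + alpha * sigma` (the down-regulation leg). `alpha > 1` encodes
#' the empirical observation that mediator down-regulation takes several
#' times longer than up-regulation (for avian corticosterone roughly 3-4
#' times as long).
#'
#' The default down-leg is the continuity-corrected form
#' `1 - (t - mu - sigma) / ((alpha - 1) * sigma)`, which equals 1 at the
#' peak and 0 at the end of the support, making the kernel continuous.
#' Setting `literal = TRUE` instead evaluates the down-leg as
#' `(t - mu - sigma) / (sigma - alpha * sigma)`, which is 0 at the peak
#' and -1 at the end of the support; it is provided only for comparison
#' and is discontinuous at the peak.
#'
#' @inheritParams kernel_box
#' @param alpha Down-regulation ratio (fall duration / rise duration).
#'   Must exceed 1 unless `strict = FALSE`, in which case any positive
#'   `alpha != 1` is accepted and the shorter leg is taken as the rise:
#'   the kernel rises over `min(1, alpha) * sigma` and falls over the
#'   remainder of the support `[mu, mu + max(1, alpha) * sigma]`.
#' @param literal Use the uncorrected (discontinuous) down-leg formula.
#' @param strict Require `alpha > 1` (the default policy).
#' @return Numeric vector of kernel values in `[0, 1]` (corrected form).
#' @export
kernel_ramp <- function(t, mu, sigma, alpha = 3, literal = FALSE,
                        strict = TRUE) {
  check_kernel_params(mu, sigma)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha == 1) {
    stop("`alpha` must be a single positive number different from 1",
         call. = FALSE)
  }
  if (strict && alpha <= 1) {
    stop("`alpha` must be > 1 (down-regulation slower than up-regulation); ",
         "pass strict = FALSE to allow 0 < alpha < 1", call. = FALSE)
  }
  if (literal) {
    up <- (t - mu) / sigma
    dn <- (t - mu - sigma) / (sigma - alpha * sigma)
    out <- ifelse(t > mu & t < mu + sigma, up,
                  ifelse(t > mu + sigma & t < mu + alpha * sigma, dn, 0))
    return(out)
  }
  rise <- min(1, alpha) * sigma
  fall <- abs(alpha - 1) * sigma
  peak <- mu + rise
  up <- (t - mu) / rise
  dn <- 1 - (t - peak) / fall
  ifelse(t > mu & t <= peak, up,
         ifelse(t > peak & t < peak + fall, dn, 0))
}

#' Gaussian stress-event kernel
#'
#' Smooth bell-shaped kernel `exp(-((t - mu) / sigma)^2)` with maximum 1
#' at `t = mu`. Unlike the box and ramp kernels, `mu` marks the mid-time
#' of the event rather than its onset, and `sigma` sets the width without
#' being the literal event duration.
#'
#' @inheritParams kernel_box
#' @return Numeric vector of kernel values in `(0, 1]`.
#' @export
kernel_gaussian <- function(t, mu, sigma) {
  check_kernel_params(mu, sigma)
  exp(-((t - mu) / sigma)^2)
}

check_kernel_params <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a single strictly positive time", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single strictly positive duration", call. = FALSE)
  invisible(NULL)
}

#' Construct a single stress event
#'
#' A stress event is a magnitude-scaled kernel: `s * psi_[mu,sigma](t)`.
#' Three kernel shapes are supported: `"box"` (instantaneous up/down
#' regulation), `"ramp"` (linear rise over `sigma`, slower linear fall
#' over `(alpha - 1) * sigma`), and `"gaussian"` (smooth, centred on
#' `mu`).
#'
#' @param kind Kernel shape: `"box"`, `"ramp"` or `"gaussian"`.
#' @param s Event magnitude in mediator units, `>= 0`.
#' @param mu Onset time (box, ramp) or mid-time (gaussian), `> 0`.
#' @param sigma Duration (box, ramp up-leg) or width (gaussian), `> 0`.
#' @param alpha Down-regulation ratio, ramp kernel only; see
#'   [kernel_ramp()].
#' @param literal Ramp only: use the uncorrected down-leg formula.
#' @param strict Ramp only: require `alpha > 1`.
#' @return An object of class `"stress_event"`.
#' @examples
#' ev <- stress_event("box", s = 0.4, mu = 0.2, sigma = 0.1)
#' eval_event(ev, c(0.25, 0.45))
#' @export
stress_event <- function(kind = c("box", "ramp", "gaussian"), s, mu, sigma,
                         alpha = 3, literal = FALSE, strict = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s < 0)
    stop("event magnitude `s` must be a single nonnegative number",
         call. = FALSE)
  check_kernel_params(mu, sigma)
  if (kind == "ramp") {
    # trigger the same validation as kernel_ramp up front
    kernel_ramp(mu, mu, sigma, alpha, literal = literal, strict = strict)
  }
  structure(
    list(kind = kind, s = s, mu = mu, sigma = sigma,
         alpha = if (kind == "ramp") alpha else NA_real_,
         literal = literal, strict = strict),
    class = "stress_event"
  )
}

#' Evaluate one stress event at given times
#'
#' @param event A [stress_event()].
#' @param t Time(s).
#' @return `s * psi(t)`, in mediator units.
#' @export
eval_event <- function(event, t) {
  stopifnot(inherits(event, "stress_event"))
  psi <- switch(event$kind,
    box = kernel_box(t, event$mu, event$sigma),
    ramp = kernel_ramp(t, event$mu, event$sigma, event$alpha,
                       literal = event$literal, strict = event$strict),
    gaussian = kernel_gaussian(t, event$mu, event$sigma)
  )
  event$s * psi
}

#' @export
print.stress_event <- function(x, ...) {
  extra <- if (x$kind == "ramp") sprintf(", alpha = %g", x$alpha) else ""
  cat(sprintf("<stress_event: %s, s = %g, mu = %g, sigma = %g%s>\n",
              x$kind, x$s, x$mu, x$sigma, extra))
  invisible(x)
}

#' Construct a stress schedule
#'
#' A stress schedule is the sum of its events:
#' `s(t) = sum_i s_i * psi_[mu_i, sigma_i](t)`. Overlapping events add.
#' An empty schedule evaluates to 0 everywhere.
#'
#' @param ... [stress_event()] objects, or a single list of them.
#' @return An object of class `"stress_schedule"`.
#' @examples
#' sched <- stress_schedule(
#'   stress_event("box", s = 0.4, mu = 0.2, sigma = 0.1),
#'   stress_event("box", s = 0.4, mu = 0.6, sigma = 0.1)
#' )
#' eval_schedule(sched, c(0.25, 0.45, 0.65))
#' @export
stress_schedule <- function(...) {
  events <- list(...)
  if (length(events) == 1L && is.list(events[[1]]) &&
      !inherits(events[[1]], "stress_event")) {
    events <- events[[1]]
  }
  ok <- vapply(events, inherits, logical(1), what = "stress_event")
  if (!all(ok))
    stop("all schedule components must be stress_event objects", call. = FALSE)
  structure(list(events = events), class = "stress_schedule")
}

#' Evaluate a stress schedule at given times
#'
#' @param sched A [stress_schedule()].
#' @param t Time(s).
#' @return Summed event contributions `s(t)` in mediator units (`>= 0`).
#' @export
eval_schedule <- function(sched, t) {
  stopifnot(inherits(sched, "stress_schedule"))
  out <- numeric(length(t))
  for (ev in sched$events) out <- out + eval_event(ev, t)
  out
}

#' @export
print.stress_schedule <- function(x, ...) {
  cat(sprintf("<stress_schedule: %d event(s)>\n", length(x$events)))
  for (ev in x$events) print(ev)
  invisible(x)
}

#' Time support of a stress schedule
#'
#' Smallest closed interval containing the supports of all events. The
#' Gaussian kernel has unbounded support; it is truncated where the
#' kernel value drops below `tol`, i.e. at `mu +/- sigma * sqrt(log(1/tol))`.
#'
#' @param sched A [stress_schedule()].
#' @param tol Truncation tolerance for the Gaussian kernel.
#' @return Length-2 numeric `c(lo, hi)`, or `c(NA, NA)` for an empty
#'   schedule.
#' @export
schedule_support <- function(sched, tol = 1e-8) {
  stopifnot(inherits(sched, "stress_schedule"))
  if (length(sched$events) == 0L) return(c(NA_real_, NA_real_))
  lims <- vapply(sched$events, function(ev) {
    switch(ev$kind,
      box = c(ev$mu, ev$mu + ev$sigma),
      ramp = c(ev$mu, ev$mu + max(1, ev$alpha) * ev$sigma),
      gaussian = {
        half <- ev$sigma * sqrt(log(1 / tol))
        c(ev$mu - half, ev$mu + half)
      })
  }, numeric(2))
  c(min(lims[1, ]), max(lims[2, ]))
}

# Times where the schedule (hence y) is non-smooth or discontinuous;
# these become forced regime boundaries for the event-driven integrator.
schedule_breakpoints <- function(sched) {
  if (length(sched$events) == 0L) return(numeric(0))
  unlist(lapply(sched$events, function(ev) {
    switch(ev$kind,
      box = c(ev$mu, ev$mu + ev$sigma),
      ramp = c(ev$mu, ev$mu + min(1, ev$alpha) * ev$sigma,
               ev$mu + max(1, ev$alpha) * ev$sigma),
      gaussian = numeric(0))
  }))
}
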