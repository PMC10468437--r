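#' Senescence specification
#'
#' Lifetime decline of the maximal threshold `M(t)`, modelled as a drain
#' `A(t) >= 0` subtracted from `dM/dt` at all times (and applied to `R`
#' only through the `R <= M` cap, which drags `R` down with `M`).
#'
#' Two parametric forms are provided besides `"none"`:
#'
#' * `"linear"`: `A(t)` is 0 before age `a1` and after age `a2`, and the
#'   constant `(p_a1 - p_a2) / (a2 - a1)` in between, so that with no
#'   stress `M` declines linearly from `p_a1` at `a1` to `p_a2` at `a2`.
#' * `"sigmoid"`: `A(t)` is the (positive) derivative of the logistic
#'   decline `M(t) = p_i - (p_i - p_f) / (1 + exp(k * (A_bar - t)))`,
#'   i.e. `k * (p_i - p_f) * e / (1 + e)^2` with `e = exp(k * (A_bar - t))`,
#'   giving a smooth transition from `p_i` to `p_f` centred at age
#'   `A_bar` with slope parameter `k`.
#'
#' Note the sign convention: `A(t)` is stored as a nonnegative decline
#' rate; the dynamics subtract it.
#'
#' @param kind `"none"`, `"linear"` or `"sigmoid"`.
#' @param a1,a2 Linear form: transition ages, `0 <= a1 < a2`.
#' @param p_a1,p_a2 Linear form: threshold levels at `a1` and `a2`,
#'   `p_a1 >= p_a2`.
#' @param p_i,p_f Sigmoid form: initial and final threshold levels,
#'   `p_i >= p_f`.
#' @param k Sigmoid form: transition slope, `> 0`, per time unit.
#' @param A_bar Sigmoid form: midpoint age of the transition.
#' @return An object of class `"senescence_spec"`.
#' @examples
#' senescence_spec("linear", a1 = 0.1, a2 = 0.9, p_a1 = 1, p_a2 = 0.6)
#' senescence_spec("sigmoid", p_i = 1, p_f = 0.6, k = 10, A_bar = 0.4)
#' @export
senescence_spec <- function(kind = c("none", "linear", "sigmoid"),
                            a1 = NULL, a2 = NULL, p_a1 = NULL, p_a2 = NULL,
                            p_i = NULL, p_f = NULL, k = NULL, A_bar = NULL) {
  kind <- match.arg(kind)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (kind == "linear") {
    if (!num1(a1) || !num1(a2) || !num1(p_a1) || !num1(p_a2))
      stop("linear senescence needs numeric a1, a2, p_a1, p_a2",
           call. = FALSE)
    if (!(a1 >= 0 && a2 > a1))
      stop("need 0 <= a1 < a2", call. = FALSE)
    if (p_a1 < p_a2)
      stop("senescence declines M: need p_a1 >= p_a2", call. = FALSE)
  } else if (kind == "sigmoid") {
    if (!num1(p_i) || !num1(p_f) || !num1(k) || !num1(A_bar))
      stop("sigmoid senescence needs numeric p_i, p_f, k, A_bar",
           call. = FALSE)
    if (p_i < p_f)
      stop("senescence declines M: need p_i >= p_f", call. = FALSE)
    if (k <= 0) stop("transition slope `k` must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, a1 = a1, a2 = a2, p_a1 = p_a1, p_a2 = p_a2,
                 p_i = p_i, p_f = p_f, k = k, A_bar = A_bar),
            class = "senescence_spec")
}

#' @export
print.senescence_spec <- function(x, ...) {
  desc <- switch(x$kind,
    none = "none",
    linear = sprintf("linear: a1 = %g, a2 = %g, p_a1 = %g, p_a2 = %g",
                     x$a1, x$a2, x$p_a1, x$p_a2),
    sigmoid = sprintf("sigmoid: p_i = %g, p_f = %g, k = %g, A_bar = %g",
                      x$p_i, x$p_f, x$k, x$A_bar))
  cat(sprintf("<senescence_spec: %s>\n", desc))
  invisible(x)
}

#' Senescence decline rate A(t)
#'
#' The nonnegative rate at which senescence drains the maximal
#' threshold `M(t)` at age `t`; see [senescence_spec()] for the two
#' parametric forms. At the sigmoid midpoint `t = A_bar` the rate
#' attains its maximum `k * (p_i - p_f) / 4`.
#'
#' @param t Age(s).
#' @param spec A [senescence_spec()].
#' @return Decline rate(s), mediator units per time unit, `>= 0`.
#' @export
senescence_rate <- function(t, spec) {
  stopifnot(inherits(spec, "senescence_spec"))
  switch(spec$kind,
    none = 0 * t,
    linear = {
      rate <- (spec$p_a1 - spec$p_a2) / (spec$a2 - spec$a1)
      ifelse(t > spec$a1 & t <= spec$a2, rate, 0)
    },
    sigmoid = {
      e <- exp(spec$k * (spec$A_bar - t))
      spec$k * (spec$p_i - spec$p_f) * e / (1 + e)^2
    })
}

# Cumulative senescence drop: integral of A from 0 to t, in closed form.
# The event-driven stepper uses this so senescence costs no accuracy.
senescence_drop <- function(t, spec) {
  switch(spec$kind,
    none = 0 * t,
    linear = {
      rate <- (spec$p_a1 - spec$p_a2) / (spec$a2 - spec$a1)
      rate * (pmin(pmax(t, spec$a1), spec$a2) - spec$a1)
    },
    sigmoid = {
      lg <- function(tt) 1 / (1 + exp(spec$k * (spec$A_bar - tt)))
      (spec$p_i - spec$p_f) * (lg(t) - lg(0))
    })
}

# Ages at which A(t) is discontinuous (forced regime boundaries).
senescence_breakpoints <- function(spec) {
  if (spec$kind == "linear") c(spec$a1, spec$a2) else numeric(0)
}

#' Closed-form stress-free M(t) under linear senescence
#'
#' With no overload (`y(t) < R(t)` throughout), the maximal threshold
#' under the linear senescence form is piecewise linear: constant at
#' `p_a1` up to age `a1`, declining linearly to `p_a2` at `a2`, constant
#' thereafter.
#'
#' @param t Age(s).
#' @param spec A linear [senescence_spec()].
#' @return `M(t)` in mediator units.
#' @export
closed_form_M_linear <- function(t, spec) {
  stopifnot(inherits(spec, "senescence_spec"))
  if (spec$kind != "linear")
    stop("`spec` must be a linear senescence specification", call. = FALSE)
  slope <- (spec$p_a1 - spec$p_a2) / (spec$a1 - spec$a2)
  ifelse(t <= spec$a1, spec$p_a1,
         ifelse(t <= spec$a2, slope * (t - spec$a1) + spec$p_a1, spec$p_a2))
}

#' Closed-form stress-free M(t) under sigmoid senescence
#'
#' With no overload, the maximal threshold under the sigmoid senescence
#' form is the logistic decline
#' `M(t) = p_i - (p_i - p_f) / (1 + exp(k * (A_bar - t)))`,
#' approaching `p_i` for young ages and `p_f` for old ones, with
#' midpoint value `(p_i + p_f) / 2` at `t = A_bar`.
#'
#' @param t Age(s).
#' @param spec A sigmoid [senescence_spec()].
#' @return `M(t)` in mediator units.
#' @export
closed_form_M_sigmoid <- function(t, spec) {
  stopifnot(inherits(spec, "senescence_spec"))
  if (spec$kind != "sigmoid")
    stop("`spec` must be a sigmoid senescence specification", call. = FALSE)
  spec$p_i - (spec$p_i - spec$p_f) / (1 + exp(spec$k * (spec$A_bar - t)))
}

#' Simulate threshold dynamics with senescence
#'
#' Convenience wrapper around [simulate_scope()] that makes the
#' senescence drain explicit. The drain `A(t)` is subtracted from
#' `dM/dt` at all times; `R` feels it only when it would otherwise
#' exceed `M` (the `R <= M` cap), which is what drags `R` down with `M`
#' in stress-free lifetimes.
#'
#' @inheritParams simulate_scope
#' @return A `"scope_trajectory"`; see [simulate_scope()].
#' @examples
#' sen <- senescence_spec("linear", a1 = 0.1, a2 = 0.9, p_a1 = 1, p_a2 = 0.6)
#' bp <- baseline_params(y_c = 0.3, y_act = 0.1)
#' traj <- simulate_with_senescence(bp, stress_schedule(),
#'                                  scope_params(r = 1, M0 = 1), sen, t1 = 1)
#' @export
simulate_with_senescence <- function(baseline, schedule = stress_schedule(),
                                     scope, senescence,
                                     switching = switching_spec("heaviside"),
                                     t0 = 0, t1 = 1,
                                     control = scope_control(),
                                     method = c("auto", "exact", "euler")) {
  simulate_scope(baseline, schedule, scope, switching, senescence,
                 t0 = t0, t1 = t1, control = control, method = method)
}
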