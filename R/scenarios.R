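#' Named scenario fixtures
#'
#' Parameter sets for the configurations used throughout the model's
#' development: conceptual demonstrations on dimensionless axes
#' (kernel comparisons, circadian timing, overload geometry, wear-rate
#' verification, senescence, sigmoid switching) and the corticosterone
#' (CORT) replication of a 25-day elevation experiment in house
#' sparrows. Parameters that the source configuration leaves
#' unspecified (typically the baseline, `M0` and the rates for the
#' qualitative demonstrations) are filled with documented fixture
#' defaults and listed in the scenario's `assumed` field.
#'
#' @param name Scenario name; see [list_scenarios()].
#' @return An object of class `"scope_scenario"`: list with `name`,
#'   `description`, `baseline`, `schedule`, `scope`, `switching`,
#'   `senescence`, `t0`, `t1`, `mediator_unit` and `assumed` (names of
#'   parameters chosen by the fixture rather than printed).
#' @examples
#' sc <- load_scenario("durant-replication")
#' sc$baseline
#' @export
load_scenario <- function(name) {
  builders <- scenario_builders()
  if (!name %in% names(builders))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(builders), collapse = ", "), call. = FALSE)
  sc <- builders[[name]]()
  sc$name <- name
  structure(sc, class = "scope_scenario")
}

#' List available scenario names
#'
#' @return Character vector of names accepted by [load_scenario()].
#' @export
list_scenarios <- function() {
  names(scenario_builders())
}

#' @export
print.scope_scenario <- function(x, ...) {
  cat(sprintf("<scope_scenario '%s': %s>\n", x$name, x$description))
  cat(sprintf("  horizon [%g, %g] (%s), mediator in %s\n", x$t0, x$t1,
              x$baseline$time_unit, x$mediator_unit))
  if (length(x$assumed) > 0)
    cat("  assumed (fixture defaults): ",
        paste(x$assumed, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate a named scenario
#'
#' @param scenario A scenario name or a `"scope_scenario"` object.
#' @param control A [scope_control()] list.
#' @return A `"scope_trajectory"`; see [simulate_scope()].
#' @export
simulate_scenario <- function(scenario, control = scope_control()) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  stopifnot(inherits(scenario, "scope_scenario"))
  simulate_scope(scenario$baseline, scenario$schedule, scenario$scope,
                 scenario$switching, scenario$senescence,
                 t0 = scenario$t0, t1 = scenario$t1, control = control)
}

# The default conceptual baseline: flat basal level 0.3 with activity
# offset 0.1 on dimensionless axes (mediator scaled to maximal effect).
assumed_flat_baseline <- function() {
  baseline_params(y_c = 0.3, y_act = 0.1)
}

scenario_builders <- function() {
  flat <- assumed_flat_baseline
  list(
    "fig1-baseline" = function() list(
      description = "stress-free run with seasonal drift and circadian ripple",
      baseline = baseline_params(a_s = 0.24, b_s = pi / 2, a_c = 0.02,
                                 b_c = 50, y_c = 0.3, y_act = 0.01),
      schedule = stress_schedule(),
      scope = scope_params(r = 1, M0 = 0.8),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("b_s", "b_c", "M0", "r")),
    "fig3-box" = function() list(
      description = "two box events, sub-overload",
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("box", s = 0.4, mu = 0.2, sigma = 0.1),
        stress_event("box", s = 0.4, mu = 0.6, sigma = 0.1)),
      scope = scope_params(r = 1, M0 = 1),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "r")),
    "fig3-ramp" = function() list(
      description = "two ramp events, sub-overload",
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("ramp", s = 0.4, mu = 0.2, sigma = 0.1, alpha = 3),
        stress_event("ramp", s = 0.4, mu = 0.6, sigma = 0.1, alpha = 3)),
      scope = scope_params(r = 1, M0 = 1),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "r")),
    "fig3-gaussian" = function() list(
      description = "two gaussian events, sub-overload",
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("gaussian", s = 0.4, mu = 0.2, sigma = 0.1),
        stress_event("gaussian", s = 0.4, mu = 0.6, sigma = 0.1)),
      scope = scope_params(r = 1, M0 = 1),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "r")),
    "fig4-two-events" = function() list(
      description = paste0("minor then major event: temporary R dip, ",
                           "then overload with permanent M loss"),
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("box", s = 0.3, mu = 0.1, sigma = 0.1),
        stress_event("box", s = 0.6, mu = 0.4, sigma = 0.2)),
      scope = scope_params(r = 1, M0 = 0.95),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "r", "kernel kind")),
    "fig5-circadian" = function() list(
      description = paste0("identical events at circadian peak vs trough: ",
                           "only the peak-timed one causes overload"),
      baseline = baseline_params(a_c = 0.2, b_c = 2 * pi, y_c = 0.3,
                                 y_act = 0.1),
      schedule = stress_schedule(
        stress_event("ramp", s = 0.47, mu = 0.1, sigma = 0.1, alpha = 3),
        stress_event("ramp", s = 0.47, mu = 0.7, sigma = 0.1, alpha = 3)),
      scope = scope_params(r = 1, M0 = 0.8),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("M0", "r")),
    "fig7-box" = function() list(
      description = "box event with y > P exactly on (0.2, 0.5)",
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("box", s = 0.2, mu = 0.2, sigma = 0.3)),
      scope = scope_params(r = 0.8, M0 = 0.9),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "r")),
    "fig7-ramp" = function() list(
      description = paste0("ramp event sharing the (0.2, 0.5) exceedance ",
                           "window of fig7-box (magnitude derived)"),
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("ramp", s = 0.3, mu = 0.15, sigma = 0.15, alpha = 3)),
      scope = scope_params(r = 0.8, M0 = 0.9),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "r", "s1")),
    "fig8-ramp" = function() list(
      description = "ramp event reaching homeostatic overload",
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("ramp", s = 0.6, mu = 0.2, sigma = 0.2, alpha = 3)),
      scope = scope_params(r = 0.8, M0 = 0.95),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0")),
    "fig8-box" = function() list(
      description = "box event reaching homeostatic overload",
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("box", s = 0.75, mu = 0.39474, sigma = 0.42857)),
      scope = scope_params(r = 0.8, M0 = 0.95),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0")),
    "fig9-short-spike" = function() list(
      description = "severe but brief elevation: no overload",
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("box", s = 0.65, mu = 0.1, sigma = 0.05)),
      scope = scope_params(r = 0.8, M0 = 1),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "r", "kernel kind")),
    "fig9-long-mild" = function() list(
      description = "mild but prolonged elevation: overload",
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("box", s = 0.2, mu = 0.1, sigma = 0.7)),
      scope = scope_params(r = 0.8, M0 = 1),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "r", "kernel kind")),
    "fig10-inescapable" = function() list(
      description = paste0("mediator down-regulating slower than r2: ",
                           "overload persists to the end of the event"),
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("ramp", s = 0.5, mu = 0.1, sigma = 0.1, alpha = 8)),
      scope = scope_params(r = 0.8, M0 = 0.8),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "r", "schedule")),
    "fig11-verification" = function() list(
      description = paste0("three overload-inducing, fully recovering ",
                           "events for wear-rate recovery (r = 2)"),
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("box", s = 0.5, mu = 0.1, sigma = 0.25),
        stress_event("box", s = 0.35, mu = 0.6, sigma = 0.1),
        stress_event("box", s = 0.2, mu = 0.8, sigma = 0.08)),
      scope = scope_params(r = 2, M0 = 1),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "schedule")),
    "fig12-senescence-linear" = function() list(
      description = "stress-free lifetime with linear senescent decline",
      baseline = flat(),
      schedule = stress_schedule(),
      scope = scope_params(r = 1, M0 = 1),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("linear", a1 = 0.1, a2 = 0.9,
                                   p_a1 = 1, p_a2 = 0.6),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "r")),
    "fig12-senescence-sigmoid" = function() {
      sen <- senescence_spec("sigmoid", p_i = 1, p_f = 0.6, k = 10,
                             A_bar = 0.4)
      list(
        description = "stress-free lifetime with logistic senescent decline",
        baseline = flat(),
        schedule = stress_schedule(),
        # start M exactly on the logistic curve so the closed form applies
        scope = scope_params(r = 1, M0 = closed_form_M_sigmoid(0, sen)),
        switching = switching_spec("heaviside"),
        senescence = sen,
        t0 = 0, t1 = 1, mediator_unit = "dimensionless",
        assumed = c("baseline", "r"))
    },
    "fig13-sigmoid-switch" = function() list(
      description = paste0("smooth switching with deliberately low c = 10 ",
                           "and r1 > r2 to exaggerate sub-threshold M loss"),
      baseline = flat(),
      schedule = stress_schedule(
        stress_event("ramp", s = 0.3, mu = 0.2, sigma = 0.2, alpha = 3)),
      scope = scope_params(r1 = 2.8, r2 = 0.8, r3 = 0.8, M0 = 0.9,
                           strict = FALSE),
      switching = switching_spec("sigmoid", c = 10),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 1, mediator_unit = "dimensionless",
      assumed = c("baseline", "M0", "schedule")),
    "durant-replication" = function() list(
      description = paste0("replication of a 25-day CORT elevation ",
                           "experiment in house sparrows"),
      baseline = baseline_params(a_s = 0, b_s = 0, a_c = 6, b_c = 2 * pi,
                                 y_c = 12, y_act = 1, time_unit = "days"),
      schedule = stress_schedule(
        stress_event("ramp", s = 140, mu = 1, sigma = 11, alpha = 4)),
      scope = scope_params(r = 1.5, M0 = 165),
      switching = switching_spec("heaviside"),
      senescence = senescence_spec("none"),
      t0 = 0, t1 = 45, mediator_unit = "ng/ml",
      assumed = character(0))
  )
}
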