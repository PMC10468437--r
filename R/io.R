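#' Write a trajectory to CSV
#'
#' Writes the sample table (`time, y, P, R, M, region`) with a header
#' row and 17 significant digits, so that [read_trajectory()] restores
#' the numeric columns bit-identically.
#'
#' @param traj A `"scope_trajectory"` or a compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  s <- if (inherits(traj, "scope_trajectory")) traj$samples else traj
  num <- c("time", "y", "P", "R", "M")
  lines <- c(paste(c(num, "region"), collapse = ","),
             do.call(paste, c(lapply(s[num], function(x)
               sprintf("%.17g", x)), list(s$region, sep = ","))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path File written by [write_trajectory()] (or any CSV with
#'   columns `time, y, P, R, M` and optionally `region`).
#' @return A data frame of samples. Episode detection on such a frame
#'   falls back to sample-level interpolation ([detect_episodes()]).
#' @export
read_trajectory <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "y", "P", "R", "M")
  if (!all(need %in% names(s)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  s
}

#' Write a trajectory's event log to JSON
#'
#' @param traj A `"scope_trajectory"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(traj, path) {
  stopifnot(inherits(traj, "scope_trajectory"))
  jsonlite::write_json(traj$events, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a simulation configuration file
#'
#' A configuration is a single declarative document, YAML
#' (`.yml`/`.yaml`) or JSON (`.json`), auto-detected by extension:
#'
#' ```yaml
#' name: example
#' time_unit: days
#' baseline: {a_s: 0, b_s: 0, a_c: 6, b_c: 6.2832, y_c: 12, y_act: 1}
#' schedule:
#'   - {kind: ramp, s: 140, mu: 1, sigma: 11, alpha: 4}
#' scope: {r: 1.5, M0: 165}
#' switching: {kind: heaviside}
#' senescence: {kind: none}
#' horizon: [0, 45]
#' ```
#'
#' `scope` accepts either a single `r` or `r1`, `r2`, `r3`; `switching`
#' and `senescence` may be omitted (Heaviside, none). Times are in the
#' declared `time_unit`.
#'
#' @param path Config file path.
#' @return A `"scope_scenario"` object ready for [simulate_scenario()].
#' @export
read_scope_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop("config must be .yaml/.yml or .json, got: ", path, call. = FALSE)
  }
  config_to_scenario(cfg)
}

config_to_scenario <- function(cfg) {
  b <- cfg$baseline
  if (is.null(b) || is.null(b$y_c))
    stop("config needs a `baseline` block with at least `y_c`",
         call. = FALSE)
  baseline <- baseline_params(
    a_s = b$a_s %||% 0, b_s = b$b_s %||% 0,
    a_c = b$a_c %||% 0, b_c = b$b_c %||% 0,
    y_c = b$y_c, y_act = b$y_act %||% 0,
    phase_s = b$phase_s %||% 0, phase_c = b$phase_c %||% 0,
    time_unit = cfg$time_unit %||% "dimensionless")
  events <- lapply(cfg$schedule %||% list(), function(ev) {
    stress_event(kind = ev$kind %||% "box", s = ev$s,
                 mu = ev$mu, sigma = ev$sigma,
                 alpha = ev$alpha %||% 3,
                 literal = isTRUE(ev$literal),
                 strict = !isFALSE(ev$strict))
  })
  sc <- cfg$scope
  if (is.null(sc) || is.null(sc$M0))
    stop("config needs a `scope` block with `M0` and rate(s)",
         call. = FALSE)
  scope <- if (!is.null(sc$r)) {
    scope_params(r = sc$r, M0 = sc$M0, strict = !isFALSE(sc$strict))
  } else {
    scope_params(r1 = sc$r1, r2 = sc$r2, r3 = sc$r3, M0 = sc$M0,
                 strict = !isFALSE(sc$strict))
  }
  sw <- cfg$switching %||% list(kind = "heaviside")
  switching <- switching_spec(sw$kind %||% "heaviside", c = sw$c)
  sen <- cfg$senescence %||% list(kind = "none")
  senescence <- senescence_spec(sen$kind %||% "none",
                                a1 = sen$a1, a2 = sen$a2,
                                p_a1 = sen$p_a1, p_a2 = sen$p_a2,
                                p_i = sen$p_i, p_f = sen$p_f,
                                k = sen$k, A_bar = sen$A_bar)
  horizon <- cfg$horizon %||% c(0, 1)
  if (length(horizon) != 2L)
    stop("`horizon` must be [t0, t1]", call. = FALSE)
  structure(list(name = cfg$name %||% "config",
                 description = cfg$description %||% "user configuration",
                 baseline = baseline,
                 schedule = stress_schedule(events),
                 scope = scope, switching = switching,
                 senescence = senescence,
                 t0 = horizon[[1]], t1 = horizon[[2]],
                 mediator_unit = cfg$mediator_unit %||% "dimensionless",
                 assumed = character(0)),
            class = "scope_scenario")
}

#' Export a scenario as a config list
#'
#' Inverse of [read_scope_config()]'s parsing: the returned list can be
#' serialised with [yaml::write_yaml()] or [jsonlite::write_json()] and
#' read back, so named fixtures and user configs share one path.
#'
#' @param scenario A `"scope_scenario"`.
#' @return A plain list mirroring the config schema.
#' @export
scenario_to_config <- function(scenario) {
  stopifnot(inherits(scenario, "scope_scenario"))
  b <- scenario$baseline
  sc <- scenario$scope
  sen <- scenario$senescence
  list(
    name = scenario$name,
    description = scenario$description,
    time_unit = b$time_unit,
    mediator_unit = scenario$mediator_unit,
    baseline = list(a_s = b$a_s, b_s = b$b_s, a_c = b$a_c, b_c = b$b_c,
                    y_c = b$y_c, y_act = b$y_act,
                    phase_s = b$phase_s, phase_c = b$phase_c),
    schedule = lapply(scenario$schedule$events, function(ev) {
      out <- list(kind = ev$kind, s = ev$s, mu = ev$mu, sigma = ev$sigma)
      if (ev$kind == "ramp") {
        out$alpha <- ev$alpha
        if (ev$literal) out$literal <- TRUE
        if (!ev$strict) out$strict <- FALSE
      }
      out
    }),
    scope = list(r1 = sc$r1, r2 = sc$r2, r3 = sc$r3, M0 = sc$M0,
                 strict = sc$r1 <= sc$r2),
    switching = if (scenario$switching$kind == "sigmoid")
      list(kind = "sigmoid", c = scenario$switching$c)
    else list(kind = "heaviside"),
    senescence = Filter(Negate(is.null),
                        unclass(sen)[c("kind", "a1", "a2", "p_a1", "p_a2",
                                       "p_i", "p_f", "k", "A_bar")]),
    horizon = c(scenario$t0, scenario$t1)
  )
}

#' Run a configuration and write its artifacts
#'
#' Simulates the configuration (file path, config list, or scenario)
#' and writes `<prefix>_trajectory.csv` and `<prefix>_events.json`.
#' Outputs are deterministic for a given configuration.
#'
#' @param config Path to a YAML/JSON config, or a `"scope_scenario"`.
#' @param out_prefix Path prefix for the output artifacts.
#' @param control A [scope_control()] list.
#' @return Invisibly, a list with the trajectory and the written paths.
#' @export
run_scope_config <- function(config, out_prefix,
                             control = scope_control()) {
  scenario <- if (is.character(config)) read_scope_config(config)
              else config
  stopifnot(inherits(scenario, "scope_scenario"))
  traj <- simulate_scenario(scenario, control = control)
  traj_path <- paste0(out_prefix, "_trajectory.csv")
  ev_path <- paste0(out_prefix, "_events.json")
  write_trajectory(traj, traj_path)
  write_events(traj, ev_path)
  invisible(list(trajectory = traj, paths = c(trajectory = traj_path,
                                              events = ev_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
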