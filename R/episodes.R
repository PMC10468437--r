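#' Detect reactive/overload episodes in a trajectory
#'
#' An episode is a maximal excursion of the mediator above the
#' predictive threshold (`y > P`). For each episode that reaches
#' homeostatic overload the detector records the quantities used by the
#' wear-rate identities:
#'
#' * `tau`: duration of the reactive phase, from the up-crossing of `P`
#'   to the moment the declining `R` meets `y` (overload onset);
#' * `y_star`: the mediator level at overload onset (equal to `R` at
#'   that instant);
#' * `t_over`: total time spent in overload within the episode;
#' * `recovered`: whether `R` returned to `M` before the next episode.
#'
#' Excursions that never reach overload are returned with
#' `overload = FALSE` and are excluded from rate estimation.
#'
#' For trajectories produced by the exact stepper the boundaries are
#' read from the event log and are exact up to the event-localisation
#' tolerance. For trajectories without an event log (e.g. read from
#' CSV) crossings are interpolated linearly between samples, which is
#' approximate at the sample-spacing scale.
#'
#' @param traj A `"scope_trajectory"`, or a data frame with columns
#'   `time, y, P, R, M`.
#' @return A data frame of class `"scope_episodes"` with one row per
#'   excursion: `onset, overload_onset, tau, y_star, t_over, end,
#'   overload, recovered`.
#' @export
detect_episodes <- function(traj) {
  if (inherits(traj, "scope_trajectory") && !is.null(traj$segments)) {
    eps <- detect_episodes_segments(traj)
  } else {
    s <- if (inherits(traj, "scope_trajectory")) traj$samples else traj
    need <- c("time", "y", "P", "R", "M")
    if (!all(need %in% names(s)))
      stop("trajectory must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    eps <- detect_episodes_grid(s)
  }
  class(eps) <- c("scope_episodes", "data.frame")
  eps
}

# Exact path: walk the regime segments (constant indicators per segment).
detect_episodes_segments <- function(traj) {
  segs <- traj$segments
  out <- list()
  cur <- NULL
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    dur <- s$t1 - s$t0
    if (s$I2p) {
      if (is.null(cur)) {
        cur <- list(onset = s$t0, overload_onset = NA_real_,
                    tau = NA_real_, y_star = NA_real_, t_over = 0,
                    end = s$t1, overload = FALSE, recovered = FALSE)
      }
      cur$end <- s$t1
      if (s$I1) {
        if (!cur$overload) {
          cur$overload <- TRUE
          cur$overload_onset <- s$t0
          cur$tau <- s$t0 - cur$onset
          # y* = R at the meeting point
          cur$y_star <- if (s$tied) s$M0 else s$R0
        }
        cur$t_over <- cur$t_over + dur
      }
    } else {
      if (!is.null(cur)) {
        out[[length(out) + 1L]] <- cur
        cur <- NULL
      }
      # recovery completeness: R back at M at the end of this quiet
      # stretch (i.e. the segment preceding the next episode is tied)
      if (length(out) > 0L && (s$tied || abs(s$M0 - s$R0) <= 0)) {
        out[[length(out)]]$recovered <- TRUE
      }
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  episodes_df(out)
}

# Approximate path: linear interpolation of crossings between samples.
detect_episodes_grid <- function(s) {
  tt <- s$time
  gP <- s$y - s$P
  gR <- s$y - s$R
  above_P <- gP > 0
  runs <- rle(above_P)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  out <- list()
  cross_time <- function(i, g) {
    # zero of g between samples i and i+1
    tt[i] + (tt[i + 1L] - tt[i]) * (0 - g[i]) / (g[i + 1L] - g[i])
  }
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    i0 <- idx_start[k]; i1 <- idx_end[k]
    onset <- if (i0 > 1L) cross_time(i0 - 1L, gP) else tt[i0]
    end <- if (i1 < length(tt)) cross_time(i1, gP) else tt[i1]
    over <- which(gR[i0:i1] > 0) + i0 - 1L
    if (length(over) == 0L) {
      out[[length(out) + 1L]] <- list(onset = onset,
                                      overload_onset = NA_real_,
                                      tau = NA_real_, y_star = NA_real_,
                                      t_over = 0, end = end,
                                      overload = FALSE, recovered = FALSE)
      next
    }
    j0 <- over[1L]
    o_on <- if (j0 > 1L && gR[j0 - 1L] <= 0) cross_time(j0 - 1L, gR) else tt[j0]
    y_star <- stats::approx(tt, s$R, xout = o_on)$y
    # total overload measure within the excursion by interpolation
    t_over <- 0
    ov <- gR[i0:i1] > 0
    tt_e <- tt[i0:i1]; gR_e <- gR[i0:i1]
    for (j in seq_len(length(ov) - 1L)) {
      a <- tt_e[j]; b <- tt_e[j + 1L]
      if (ov[j] && ov[j + 1L]) t_over <- t_over + (b - a)
      else if (ov[j] != ov[j + 1L]) {
        cx <- a + (b - a) * (0 - gR_e[j]) / (gR_e[j + 1L] - gR_e[j])
        t_over <- t_over + if (ov[j]) (cx - a) else (b - cx)
      }
    }
    # recovered: R returns to M after the excursion, before next one
    nxt <- if (k < length(runs$values)) {
      later <- which(runs$values & seq_along(runs$values) > k)
      if (length(later) > 0L) idx_start[later[1L]] else length(tt)
    } else length(tt)
    gap <- seq(i1, nxt)
    recovered <- any(abs(s$M[gap] - s$R[gap]) <=
                       1e-8 * max(abs(s$M[gap]), 1))
    out[[length(out) + 1L]] <- list(onset = onset, overload_onset = o_on,
                                    tau = o_on - onset, y_star = y_star,
                                    t_over = t_over, end = end,
                                    overload = TRUE, recovered = recovered)
  }
  episodes_df(out)
}

episodes_df <- function(out) {
  if (length(out) == 0L) {
    return(data.frame(onset = numeric(0), overload_onset = numeric(0),
                      tau = numeric(0), y_star = numeric(0),
                      t_over = numeric(0), end = numeric(0),
                      overload = logical(0), recovered = logical(0)))
  }
  data.frame(
    onset = vapply(out, `[[`, numeric(1), "onset"),
    overload_onset = vapply(out, `[[`, numeric(1), "overload_onset"),
    tau = vapply(out, `[[`, numeric(1), "tau"),
    y_star = vapply(out, `[[`, numeric(1), "y_star"),
    t_over = vapply(out, `[[`, numeric(1), "t_over"),
    end = vapply(out, `[[`, numeric(1), "end"),
    overload = vapply(out, `[[`, logical(1), "overload"),
    recovered = vapply(out, `[[`, logical(1), "recovered")
  )
}

#' Estimate the wear rate r from overload episodes
#'
#' Under the working assumption `r1 = r2 = r3 = r`, consecutive
#' overload-inducing, fully recovering episodes determine the wear rate
#' through the identity
#'
#' `r_hat_i = (y_star_i - y_star_(i+1)) / (t_i + tau_(i+1) - tau_i)`
#'
#' where `tau_i` is episode `i`'s reactive-phase duration, `t_i` its
#' overload duration, and `y_star_i` the mediator level at which the
#' declining `R` met `y`. `n` qualifying episodes yield `n - 1`
#' estimates; if the model's linear wear assumption holds, all
#' estimates agree.
#'
#' @param episodes A `"scope_episodes"` data frame from
#'   [detect_episodes()].
#' @param tol Denominators smaller than `tol` (in time units) cause the
#'   pair to be skipped with a diagnostic message.
#' @return An object of class `"r_estimate"`: list with `r_hats` (one
#'   per consecutive episode pair), `r` (their mean), `consistency`
#'   (relative spread `(max - min) / mean`), `M0` (reconstructed initial
#'   maximal threshold from the first episode), `episodes` (the
#'   qualifying episodes used), and `skipped` (indices of pairs with
#'   near-zero denominators).
#' @export
estimate_r <- function(episodes, tol = 1e-9) {
  stopifnot(inherits(episodes, "data.frame"))
  qual <- episodes[episodes$overload, , drop = FALSE]
  if (nrow(qual) < 2L)
    stop("rate estimation needs at least two overload-inducing episodes; ",
         "found ", nrow(qual), call. = FALSE)
  not_rec <- which(!qual$recovered[-nrow(qual)])
  if (length(not_rec) > 0L)
    stop("episodes must be spaced far enough apart for R to recover to M ",
         "before the next one; recovery incomplete after episode(s) ",
         paste(not_rec, collapse = ", "), call. = FALSE)
  n <- nrow(qual)
  r_hats <- numeric(0)
  skipped <- integer(0)
  for (i in seq_len(n - 1L)) {
    denom <- qual$t_over[i] + qual$tau[i + 1L] - qual$tau[i]
    if (abs(denom) < tol) {
      message("skipping episode pair ", i, "/", i + 1L,
              ": near-zero denominator (t_i + tau_{i+1} - tau_i = ",
              signif(denom, 3), ")")
      skipped <- c(skipped, i)
      next
    }
    r_hats <- c(r_hats, (qual$y_star[i] - qual$y_star[i + 1L]) / denom)
  }
  if (length(r_hats) == 0L)
    stop("no episode pair had a usable denominator", call. = FALSE)
  r_bar <- mean(r_hats)
  consistency <- if (length(r_hats) > 1L && r_bar != 0)
    (max(r_hats) - min(r_hats)) / abs(r_bar) else 0
  structure(list(r_hats = r_hats, r = r_bar, consistency = consistency,
                 M0 = reconstruct_M0(qual[1L, ], r_bar),
                 episodes = qual, skipped = skipped),
            class = "r_estimate")
}

#' @export
print.r_estimate <- function(x, ...) {
  cat(sprintf("<r_estimate: r = %g from %d pair(s), consistency = %g,",
              x$r, length(x$r_hats), x$consistency),
      sprintf("reconstructed M0 = %g>\n", x$M0))
  invisible(x)
}

#' Reconstruct the initial maximal threshold from the first episode
#'
#' During the first episode's reactive phase `R` declined from `M0` at
#' rate `r` for a duration `tau_1` before meeting the mediator at level
#' `y_star_1`, hence `M0 = y_star_1 + r * tau_1`. The same value must
#' equal `y_star_2 + r * t_1 + r * tau_2` computed from the second
#' episode, which is the basis of the estimator's consistency check.
#'
#' @param episode A one-row episode data frame (or list) with fields
#'   `y_star` and `tau`.
#' @param r The wear rate, `> 0`.
#' @return The reconstructed `M0` in mediator units.
#' @export
reconstruct_M0 <- function(episode, r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    stop("`r` must be a single number", call. = FALSE)
  if (r <= 0)
    warning("wear rate r should be > 0; reconstruction degenerates to y*",
            call. = FALSE)
  episode$y_star + r * episode$tau
}
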