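test_that("stress-free trajectories contain no episodes", {
  traj <- simulate_scenario("fig1-baseline")
  eps <- detect_episodes(traj)
  expect_equal(nrow(eps), 0)
  expect_error(estimate_r(eps), "at least two")
})

test_that("sub-overload excursions are reported but not estimable", {
  traj <- simulate_scenario("fig7-box")
  eps <- detect_episodes(traj)
  expect_equal(nrow(eps), 1)
  expect_false(eps$overload[1])
  expect_equal(eps$onset[1], 0.2, tolerance = 1e-9)
  expect_equal(eps$end[1], 0.5, tolerance = 1e-9)
  expect_error(estimate_r(eps), "at least two")
})

test_that("episode geometry matches the closed-form construction", {
  traj <- simulate_scenario("fig11-verification")
  eps <- detect_episodes(traj)
  expect_equal(nrow(eps), 3)
  expect_true(all(eps$overload))
  expect_true(all(eps$recovered))
  expect_equal(eps$tau, c(0.1, 0.025, 0.025), tolerance = 1e-6)
  expect_equal(eps$y_star, c(0.8, 0.65, 0.5), tolerance = 1e-6)
  expect_equal(eps$t_over, c(0.15, 0.075, 0.055), tolerance = 1e-6)
  # boundaries agree with the simulator's own event log
  ev <- traj$events
  onsets <- ev$time[ev$indicator == "y-R" & ev$direction == 1]
  expect_equal(eps$overload_onset, onsets, tolerance = 1e-9)
})

test_that("the wear rate and M0 are recovered from episode geometry", {
  traj <- simulate_scenario("fig11-verification")
  est <- estimate_r(detect_episodes(traj))
  expect_length(est$r_hats, 2)   # n episodes give n - 1 estimates
  expect_equal(est$r_hats, c(2, 2), tolerance = 1e-4)
  expect_lt(est$consistency, 1e-6)
  expect_equal(est$M0, 1, tolerance = 1e-6)
  # the same M0 is implied by the second episode's bookkeeping
  eps <- est$episodes
  expect_equal(eps$y_star[2] + est$r * eps$t_over[1] + est$r * eps$tau[2],
               1, tolerance = 1e-6)
})

test_that("repeated identical stressors meet R at strictly lower levels", {
  # two identical events, fully recovered in between: wear lowers the
  # second intersection level
  bp <- baseline_params(y_c = 0.3, y_act = 0.1)
  sched <- stress_schedule(
    stress_event("box", s = 0.5, mu = 0.1, sigma = 0.3),
    stress_event("box", s = 0.5, mu = 0.6, sigma = 0.3))
  traj <- simulate_scope(bp, sched, scope_params(r = 1, M0 = 0.9), t1 = 1)
  eps <- detect_episodes(traj)
  expect_equal(nrow(eps), 2)
  expect_true(all(eps$overload))
  expect_true(eps$recovered[1])
  expect_lt(eps$y_star[2], eps$y_star[1])
})

test_that("r is recovered across randomized compliant schedules", {
  set.seed(23)
  y_c <- 0.3; y_act <- 0.1
  for (k in 1:8) {
    r <- runif(1, 0.5, 2.5)
    M0 <- runif(1, 0.9, 1.2)
    lvl1 <- runif(1, 0.75, 0.92) * M0
    lvl2 <- runif(1, 0.6, 0.95) * lvl1
    lvl3 <- runif(1, 0.6, 0.95) * lvl2
    lvls <- pmax(c(lvl1, lvl2, lvl3), y_c + y_act + 0.05)
    # place each event after the previous recovery completes
    mus <- numeric(3); sigmas <- numeric(3)
    t_free <- 0.05
    M_cur <- M0
    for (i in 1:3) {
      mus[i] <- t_free + 0.02
      tau_i <- (M_cur - lvls[i]) / r
      t_over <- runif(1, 0.3, 0.8) * tau_i + 0.02
      sigmas[i] <- tau_i + t_over
      M_next <- M_cur - r * t_over
      R_end <- lvls[i] - r * t_over
      t_free <- mus[i] + sigmas[i] + (M_next - R_end) / r
      M_cur <- M_next
    }
    horizon <- t_free + 0.1
    vs <- make_verification_schedule(lvls, mus, sigmas, y_c, y_act, M0, r)
    bp <- baseline_params(y_c = y_c, y_act = y_act)
    traj <- simulate_scope(bp, vs$schedule, scope_params(r = r, M0 = M0),
                           t1 = horizon)
    est <- estimate_r(detect_episodes(traj))
    expect_equal(est$r_hats, rep(r, 2), tolerance = 1e-4)
    expect_lt(est$consistency, 1e-4)
    expect_equal(est$M0, M0, tolerance = 1e-6 * M0)
  }
})

test_that("incomplete recovery between episodes is a hard error", {
  bp <- baseline_params(y_c = 0.3, y_act = 0.1)
  # second event starts before R climbs back to M
  sched <- stress_schedule(
    stress_event("box", s = 0.5, mu = 0.1, sigma = 0.3),
    stress_event("box", s = 0.5, mu = 0.45, sigma = 0.3))
  traj <- simulate_scope(bp, sched, scope_params(r = 1, M0 = 0.9), t1 = 1)
  eps <- detect_episodes(traj)
  expect_equal(nrow(eps), 2)
  expect_error(estimate_r(eps), "recover")
})

test_that("grid-based detection on CSV trajectories approximates the event log", {
  traj <- simulate_scenario("fig11-verification")
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  eps <- detect_episodes(read_trajectory(path))
  expect_equal(nrow(eps), 3)
  exact <- detect_episodes(traj)
  expect_equal(eps$tau, exact$tau, tolerance = 1e-2)
  expect_equal(eps$y_star, exact$y_star, tolerance = 1e-2)
  est <- estimate_r(eps)
  expect_equal(est$r, 2, tolerance = 0.05)
})

test_that("M0 reconstruction flags degenerate rates", {
  ep <- data.frame(y_star = 0.8, tau = 0.1)
  expect_equal(reconstruct_M0(ep, r = 2), 1)
  expect_warning(out <- reconstruct_M0(ep, r = 0), "r should be")
  expect_equal(out, 0.8)
})
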