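test_that("heaviside convention: exactly 0 switches nothing on", {
  expect_equal(heaviside(0), 0)
  expect_equal(heaviside(-1), 0)
  expect_equal(heaviside(1e-9), 1)
  expect_equal(heaviside(c(-2, 0, 3)), c(0, 0, 1))
})

test_that("sigmoid switch is the logistic and sharpens toward the step", {
  expect_equal(sigmoid_switch(0, c = 3), 0.5)
  expect_equal(sigmoid_switch(1, c = 10), 1 / (1 + exp(-10)))
  x <- c(-0.3, -0.05, 0.05, 0.3)
  for (cc in c(1, 10, 100, 1000)) {
    expect_true(all(abs(sigmoid_switch(x, cc) - heaviside(x)) <=
                      abs(sigmoid_switch(x, cc / 10) - heaviside(x)) + 1e-15))
  }
  expect_error(sigmoid_switch(1, c = -2), "positive")
  expect_error(switching_spec("sigmoid"), "steepness")
})

test_that("rhs reproduces the switched slopes in each configuration", {
  flat <- baseline_params(y_c = 0.3, y_act = 0.1)   # y = 0.3, P = 0.4
  cfg <- function(s, M0 = 1) list(
    baseline = flat,
    schedule = if (s > 0)
      stress_schedule(stress_event("box", s = s, mu = 0.4, sigma = 0.2))
    else stress_schedule(),
    scope = scope_params(r1 = 1, r2 = 2, r3 = 3, M0 = M0),
    switching = switching_spec("heaviside"))
  # y < P, R = M: everything off (theta(0) = 0 blocks recovery)
  expect_equal(unname(scope_rhs(0.5, M = 1, R = 1, cfg(0))), c(0, 0))
  # P < y < R: temporary wear only
  expect_equal(unname(scope_rhs(0.5, M = 1, R = 1, cfg(0.3))), c(0, -2))
  # y > R: permanent and temporary wear together
  expect_equal(unname(scope_rhs(0.5, M = 1, R = 0.5, cfg(0.4))), c(-1, -2))
  # y < P, R < M: recovery at r3
  expect_equal(unname(scope_rhs(0.1, M = 1, R = 0.7, cfg(0.4))), c(0, 3))
})

test_that("stress-free runs keep R = M = M0 at every sample", {
  sc <- load_scenario("fig1-baseline")
  traj <- simulate_scenario(sc)
  expect_true(all(traj$samples$R == sc$scope$M0))
  expect_true(all(traj$samples$M == sc$scope$M0))
  expect_equal(nrow(traj$events), 0)
  expect_true(all(traj$samples$region == "predictive"))
})

test_that("a box event inside the reactive band gives the hand-computed R path", {
  # y = 0.5 on (0.2, 0.5); P = 0.4; R declines at r2 from 0.2, recovers
  # at r3 from 0.5 back to M0 = 0.9 at 0.5 + 0.24/1.2 = 0.7; M untouched
  bp <- baseline_params(y_c = 0.3, y_act = 0.1)
  sched <- stress_schedule(stress_event("box", s = 0.2, mu = 0.2, sigma = 0.3))
  traj <- simulate_scope(bp, sched,
                         scope_params(r1 = 0.5, r2 = 0.8, r3 = 1.2, M0 = 0.9),
                         t1 = 1)
  s <- traj$samples
  R_expect <- ifelse(s$time <= 0.2, 0.9,
              ifelse(s$time <= 0.5, 0.9 - 0.8 * (s$time - 0.2),
              pmin(0.9, 0.9 - 0.24 + 1.2 * (s$time - 0.5))))
  expect_equal(s$R, R_expect, tolerance = 1e-9)
  expect_true(all(s$M == 0.9))
  expect_equal(time_in_region(traj, "reactive"), 0.3, tolerance = 1e-9)
  expect_equal(time_in_region(traj, "overload"), 0)
})

test_that("M declines by exactly r1 times the overload measure", {
  for (name in c("fig8-ramp", "fig8-box", "fig5-circadian",
                 "fig11-verification")) {
    traj <- simulate_scenario(name)
    dM <- traj$samples$M[1] - traj$samples$M[nrow(traj$samples)]
    expect_equal(dM, traj$scope$r1 * time_in_region(traj, "overload"),
                 tolerance = 1e-12)
  }
})

test_that("exact stepper agrees with an independent fine-step Euler oracle", {
  sc <- load_scenario("fig8-ramp")
  traj <- simulate_scenario(sc)
  orc <- euler_oracle(sc$baseline, sc$schedule, sc$scope, 0, 1,
                      n_steps = 1e6)
  R <- stats::approx(traj$samples$time, traj$samples$R, orc$time)$y
  M <- stats::approx(traj$samples$time, traj$samples$M, orc$time)$y
  expect_lt(max(abs(R - orc$R)), 1e-4)
  expect_lt(max(abs(M - orc$M)), 1e-4)
})

test_that("M is non-increasing and R <= M on randomized runs", {
  set.seed(11)
  for (k in 1:10) {
    n_ev <- sample(1:3, 1)
    events <- lapply(seq_len(n_ev), function(i) {
      stress_event(sample(c("box", "ramp", "gaussian"), 1),
                   s = runif(1, 0.1, 0.8),
                   mu = runif(1, 0.05, 0.7),
                   sigma = runif(1, 0.03, 0.2),
                   alpha = runif(1, 2, 5))
    })
    bp <- baseline_params(a_c = runif(1, 0, 0.15), b_c = 2 * pi,
                          y_c = 0.3, y_act = 0.1)
    traj <- simulate_scope(bp, stress_schedule(events),
                           scope_params(r = runif(1, 0.5, 2),
                                        M0 = runif(1, 0.7, 1.1)),
                           t1 = 1)
    s <- traj$samples
    expect_true(all(diff(s$M) <= 1e-12))
    expect_true(all(s$R <= s$M + 1e-12))
  }
})

test_that("schedules sharing the exceedance window yield identical R", {
  traj_box <- simulate_scenario("fig7-box")
  traj_ramp <- simulate_scenario("fig7-ramp")
  tt <- seq(0, 1, length.out = 2001)
  R1 <- stats::approx(traj_box$samples$time, traj_box$samples$R, tt)$y
  R2 <- stats::approx(traj_ramp$samples$time, traj_ramp$samples$R, tt)$y
  expect_lt(max(abs(R1 - R2)), 1e-8)
  expect_equal(time_in_region(traj_box, "reactive"),
               time_in_region(traj_ramp, "reactive"), tolerance = 1e-8)
  expect_equal(time_in_region(traj_box, "overload"), 0)
})

test_that("equal overload measures produce equal permanent wear", {
  # construct a ramp and a box event whose overload measures agree by
  # closed-form design on a flat baseline
  y_c <- 0.3; y_act <- 0.1; r <- 0.8; M0 <- 0.95
  bp <- baseline_params(y_c = y_c, y_act = y_act)
  ramp <- stress_event("ramp", s = 0.6, mu = 0.2, sigma = 0.2, alpha = 3)
  g_ramp <- flat_episode_oracle(ramp, y_c, y_act, M0, r)
  # box at level 0.8 (< M0): overload begins after R declines to it
  s_box <- 0.5
  tau_box <- (M0 - (y_c + s_box)) / r
  box <- stress_event("box", s = s_box, mu = 0.3,
                      sigma = tau_box + g_ramp$t_over)
  sc <- scope_params(r = r, M0 = M0)
  tr1 <- simulate_scope(bp, stress_schedule(ramp), sc, t1 = 1)
  tr2 <- simulate_scope(bp, stress_schedule(box), sc, t1 = 1)
  ov1 <- time_in_region(tr1, "overload")
  ov2 <- time_in_region(tr2, "overload")
  expect_equal(ov1, g_ramp$t_over, tolerance = 1e-8)
  expect_equal(ov1, ov2, tolerance = 1e-8)
  dM1 <- tr1$samples$M[1] - tr1$samples$M[nrow(tr1$samples)]
  dM2 <- tr2$samples$M[1] - tr2$samples$M[nrow(tr2$samples)]
  expect_equal(dM1, dM2, tolerance = 1e-8)
})

test_that("a mediator down-regulating slower than r2 cannot escape overload", {
  sc <- load_scenario("fig10-inescapable")
  traj <- simulate_scenario(sc)
  ev <- traj$events
  onset <- ev$time[ev$indicator == "y-R" & ev$direction == 1]
  expect_length(onset, 1)
  exits <- ev$time[ev$indicator == "y-R" & ev$direction == -1]
  support_end <- schedule_support(sc$schedule)[2]
  expect_true(all(exits >= support_end - 1e-9))
})

test_that("sigmoid-switched trajectories converge to the heaviside limit", {
  sc <- load_scenario("durant-replication")
  ref <- simulate_scenario(sc)
  tt <- seq(sc$t0, sc$t1, length.out = 2001)
  refR <- stats::approx(ref$samples$time, ref$samples$R, tt)$y
  refM <- stats::approx(ref$samples$time, ref$samples$M, tt)$y
  dist <- vapply(c(5, 20), function(cc) {
    tr <- simulate_scope(sc$baseline, sc$schedule, sc$scope,
                         switching_spec("sigmoid", c = cc),
                         t0 = sc$t0, t1 = sc$t1)
    R <- stats::approx(tr$samples$time, tr$samples$R, tt)$y
    M <- stats::approx(tr$samples$time, tr$samples$M, tt)$y
    max(abs(c(R - refR, M - refM)))
  }, numeric(1))
  expect_lt(dist[2], dist[1])
})

test_that("euler fallback reproduces the exact heaviside solution", {
  sc <- load_scenario("fig4-two-events")
  exact <- simulate_scenario(sc)
  eul <- simulate_scope(sc$baseline, sc$schedule, sc$scope,
                        t0 = 0, t1 = 1, method = "euler")
  tt <- eul$samples$time
  R <- stats::approx(exact$samples$time, exact$samples$R, tt)$y
  expect_lt(max(abs(R - eul$samples$R)), 2e-5)
})

test_that("classification splits samples at P and R with overload on top", {
  expect_equal(classify_region(c(0.3, 0.5, 0.9), P = 0.4, R = 0.8),
               c("predictive", "reactive", "overload"))
  # boundary values belong to the lower range
  expect_equal(classify_region(0.4, 0.4, 0.8), "predictive")
  expect_equal(classify_region(0.8, 0.4, 0.8), "reactive")
})

test_that("simulate rejects invalid configurations", {
  bp <- baseline_params(y_c = 0.3, y_act = 0.1)
  expect_error(simulate_scope(bp, stress_schedule(),
                              scope_params(r = 1, M0 = 0.35), t1 = 1),
               "predictive")
  expect_error(scope_params(r1 = 2, r2 = 1, r3 = 1, M0 = 1), "r1")
  expect_warning(scope_params(r1 = 2, r2 = 1, r3 = 1, M0 = 1,
                              strict = FALSE), "clamp")
  expect_error(scope_params(r = 0, M0 = 1), "positive")
})
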