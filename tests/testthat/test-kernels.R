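test_that("box kernel is the indicator of the open event interval", {
  expect_equal(kernel_box(0.25, mu = 0.2, sigma = 0.1), 1)
  # boundaries are excluded by the strict inequalities (binary-exact
  # endpoints so the comparison is not blurred by decimal rounding)
  expect_equal(kernel_box(0.2, mu = 0.2, sigma = 0.1), 0)
  expect_equal(kernel_box(0.5, mu = 0.25, sigma = 0.25), 0)
  expect_equal(kernel_box(0.6, mu = 0.2, sigma = 0.1), 0)
  expect_error(kernel_box(0.5, mu = 0.2, sigma = 0), "sigma")
  expect_error(kernel_box(0.5, mu = -1, sigma = 0.1), "mu")
})

test_that("ramp kernel rises over sigma, falls over (alpha-1)*sigma, continuously", {
  mu <- 0.15; sigma <- 0.15; alpha <- 3
  expect_equal(kernel_ramp(0.3, mu, sigma, alpha), 1)       # peak at mu+sigma
  expect_equal(kernel_ramp(0.15, mu, sigma, alpha), 0)      # onset
  expect_equal(kernel_ramp(0.45, mu, sigma, alpha), 0.5)    # down-leg midpoint
  expect_equal(kernel_ramp(0.6, mu, sigma, alpha), 0)       # support end
  # continuity at the peak from both sides
  eps <- 1e-9
  expect_equal(kernel_ramp(0.3 - eps, mu, sigma, alpha), 1, tolerance = 1e-7)
  expect_equal(kernel_ramp(0.3 + eps, mu, sigma, alpha), 1, tolerance = 1e-7)
  expect_error(kernel_ramp(0.2, mu, sigma, alpha = 0.5), "alpha")
  expect_error(kernel_ramp(0.2, mu, sigma, alpha = 1), "alpha")
})

test_that("literal (uncorrected) ramp down-leg is discontinuous at the peak", {
  mu <- 0.15; sigma <- 0.15; alpha <- 3
  eps <- 1e-9
  expect_equal(kernel_ramp(0.3 - eps, mu, sigma, alpha, literal = TRUE), 1,
               tolerance = 1e-7)
  # just past the peak the printed formula restarts near 0
  expect_lt(kernel_ramp(0.3 + 1e-6, mu, sigma, alpha, literal = TRUE), 0.01)
})

test_that("gaussian kernel peaks at 1 on its mid-time and is symmetric", {
  expect_equal(kernel_gaussian(0.5, mu = 0.5, sigma = 0.1), 1)
  expect_equal(kernel_gaussian(0.6, mu = 0.5, sigma = 0.1), exp(-1))
  d <- c(0.01, 0.05, 0.2, 1)
  expect_equal(kernel_gaussian(0.5 + d, 0.5, 0.1),
               kernel_gaussian(0.5 - d, 0.5, 0.1))
})

test_that("schedules sum magnitude-weighted kernels; empty schedule is 0", {
  expect_equal(eval_schedule(stress_schedule(), c(-1, 0, 0.5, 10)),
               rep(0, 4))
  sched <- stress_schedule(
    stress_event("box", s = 0.4, mu = 0.2, sigma = 0.1),
    stress_event("box", s = 0.4, mu = 0.6, sigma = 0.1))
  expect_equal(eval_schedule(sched, 0.25), 0.4)
  expect_equal(eval_schedule(sched, 0.65), 0.4)
  expect_equal(eval_schedule(sched, 0.45), 0)
  # overlapping events add
  twice <- stress_schedule(
    stress_event("box", s = 0.4, mu = 0.2, sigma = 0.2),
    stress_event("box", s = 0.3, mu = 0.3, sigma = 0.2))
  expect_equal(eval_schedule(twice, 0.35), 0.7)
})

test_that("kernels stay in [0,1] and schedules are nonnegative", {
  set.seed(42)
  tt <- seq(0, 2, length.out = 4001)
  for (k in 1:20) {
    mu <- runif(1, 0.05, 1); sigma <- runif(1, 0.02, 0.5)
    alpha <- runif(1, 1.1, 6)
    for (kind in c("box", "ramp", "gaussian")) {
      ev <- stress_event(kind, s = runif(1, 0, 2), mu = mu, sigma = sigma,
                         alpha = alpha)
      psi <- eval_event(ev, tt) / max(ev$s, .Machine$double.eps)
      expect_true(all(psi >= 0 & psi <= 1 + 1e-12))
    }
  }
})

test_that("ramp kernel integrates to alpha*sigma/2 over its support", {
  for (alpha in c(1.5, 3, 4)) {
    mu <- 0.2; sigma <- 0.15
    q <- stats::integrate(function(x) kernel_ramp(x, mu, sigma, alpha),
                          mu, mu + alpha * sigma, rel.tol = 1e-10,
                          subdivisions = 500)
    expect_equal(q$value, alpha * sigma / 2, tolerance = 1e-8)
  }
})

test_that("schedule support covers all events, truncating gaussian tails", {
  sched <- stress_schedule(
    stress_event("box", s = 1, mu = 0.2, sigma = 0.1),
    stress_event("ramp", s = 1, mu = 0.5, sigma = 0.1, alpha = 4))
  expect_equal(schedule_support(sched), c(0.2, 0.9))
  g <- stress_schedule(stress_event("gaussian", s = 1, mu = 5, sigma = 0.5))
  sup <- schedule_support(g, tol = 1e-8)
  expect_equal(sup, 5 + c(-1, 1) * 0.5 * sqrt(log(1e8)))
  expect_lt(eval_schedule(g, sup[2]), 1.01e-8)
  expect_true(all(is.na(schedule_support(stress_schedule()))))
})

test_that("event construction rejects invalid parameters", {
  expect_error(stress_event("box", s = -0.1, mu = 0.2, sigma = 0.1),
               "nonnegative")
  expect_error(stress_event("ramp", s = 0.1, mu = 0.2, sigma = 0.1,
                            alpha = 0.5), "alpha")
  # documented override: 0 < alpha < 1 with legs swapped
  ev <- stress_event("ramp", s = 1, mu = 0.2, sigma = 0.4, alpha = 0.5,
                     strict = FALSE)
  expect_equal(eval_event(ev, 0.4), 1)    # peak at mu + alpha*sigma
  expect_equal(eval_event(ev, 0.6), 0)    # support still ends at mu+sigma
})
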