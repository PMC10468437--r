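---
title: "Modelling wear and tear of the reactive scope: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wear and tear of the reactive scope: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactscope)
```

## The model

The reactive scope framework partitions the values of a physiological
mediator — plasma corticosterone in the worked examples, but equally
heart rate or an immune mediator — into stacked ranges: *predictive
homeostasis* (normal circadian/seasonal/activity fluctuation, below
`P(t)`), *reactive homeostasis* (a tolerated buffer between `P(t)` and
`R(t)`), and *homeostatic overload* (pathological, above `R(t)`). The
homeostatic-failure range below predictive homeostasis is acknowledged
by the framework but has no specified dynamics, so this package does
not model it.

The mediator itself is an input signal, not a state variable:

$$y(t) = a_s \sin(b_s t + \varphi_s) + a_c \sin(b_c t + \varphi_c) + s(t) + y_c$$

with seasonal amplitude `a_s`, circadian amplitude `a_c` (mediator
units), angular frequencies `b_s`, `b_c` (radians per time unit), basal
level `y_c`, and the stress schedule `s(t)`. Construction enforces
`y_c - a_s - a_c >= 0`, which (with `s >= 0`) keeps `y` nonnegative.
The phase offsets are an addition of this implementation (default 0,
recovering the zero-phase form): scenario design sometimes needs to
place an event at the circadian peak or trough, and a phase is the
clean way to do it.

The predictive ceiling uses the *full* circadian amplitude rather than
its instantaneous value,

$$P(t) = a_s \sin(b_s t + \varphi_s) + a_c + y_c + y_\mathrm{act},$$

so `P` rides above the daily maximum and, absent stress, `y <= P`
everywhere. One could imagine the `a_c` term was meant to oscillate;
we follow the defining equation as stated, and the stress-free
invariant `y <= P` (property-tested over randomized parameter draws)
is what justifies that choice operationally.

## Stress-event kernels

A stress event contributes `s_i psi(t)` with `psi` one of

* **box** — indicator of the open interval `(mu, mu + sigma)`:
  instantaneous up/down-regulation, useful for analysis because it
  makes episode geometry exactly computable;
* **ramp** — linear rise to 1 over `sigma`, linear fall to 0 over
  `(alpha - 1) sigma`. The down-regulation ratio `alpha > 1` encodes
  that mediator decline takes several times longer than the rise
  (3–4-fold for avian corticosterone). The down-leg as literally
  printed in the source formulation evaluates to 0 at the peak,
  which contradicts continuity with the up-leg; we implement the
  continuity-corrected leg `1 - (t - mu - sigma)/((alpha - 1) sigma)`
  and keep the literal form behind `kernel_ramp(..., literal = TRUE)`
  for comparison;
* **gaussian** — `exp(-((t - mu)/sigma)^2)`, a smooth event centred on
  `mu` (for this kernel `mu` is the event mid-time, not the onset).

Boundary convention: kernels are 0 at their support boundaries (strict
inequalities). `alpha <= 1` is rejected by default; a documented
`strict = FALSE` override accepts `0 < alpha < 1` with the rising and
falling legs swapped consistently (rise over `min(1, alpha) sigma`).

## Threshold dynamics and tie-breaking

With `theta` the Heaviside step (`theta(0) = 0`):

$$\frac{dM}{dt} = -r_1\,\theta(y - R), \qquad
  \frac{dR}{dt} = -r_2\,\theta(y - P) + r_3\,\theta(P - y)\,\theta(M - R),$$

from `M(0) = R(0) = M0`. All rates are positive and `r1 <= r2`;
`r1 = r2 = r3 = r` is the standing working assumption (a single `r`
in `scope_params()` sets all three). The convention `theta(0) = 0` is
followed literally: exact equality `y = P` or `y = R` causes no decay,
and `R = M` receives no recovery push — recovery *halts* rather than
oscillates at the ceiling.

Three consequences that the test suite checks as properties:

* `M` is non-increasing, and `Delta M = r1 x |{t : y > R}|` exactly
  (overload time is the only thing that matters, not the height of the
  excursion);
* `R <= M` always — analytically because `r1 <= r2` during overload
  and recovery stops at `R = M`; numerically reinforced by a clamp
  `R <- min(R, M)` that never moves `R` by more than the event
  tolerance;
* two schedules with the same `{y > P}` occupation time produce
  identical `R` paths (kernel-shape insensitivity), and equal overload
  measures produce equal permanent wear.

`R` has no lower floor: it may decline below `P` and in principle
below 0 (logged as a warning). This is deliberate — when a mediator
down-regulates more slowly than `r2`, the declining `R` stays below
`y` and the overload is inescapable until the stress schedule's
support ends, a qualitative prediction the suite asserts.

## The exact event-driven integrator

Because the right-hand side is piecewise constant, `M` and `R` are
piecewise linear between *switching events* — sign changes of
`y - P`, `y - R`, and `M - R`. The default integrator exploits this:

1. within a regime (fixed indicator signs), advance `M` and `R`
   linearly;
2. bracket the earliest sign change on a scan grid (default
   `n_scan = 10^4` points per horizon, at least 16 per regime) and
   refine it by bisection to an absolute time tolerance of `10^-10`;
3. step to the event, flip the indicator(s) using the old regime's
   formulas evaluated just past the crossing, and continue.

Kernel breakpoints (box edges, ramp corners) and the linear-senescence
ages are *forced* regime boundaries, so discontinuities of `y` cannot
be stepped over; after such a boundary the indicators are re-probed a
hair past it (`10^-9` of the horizon), where frozen-threshold
evaluation is safe because any jump of `y` dominates the thresholds'
motion over the probe. The solution is therefore exact up to event
localisation; the only approximation hazard is an excursion shorter
than the scan spacing, which the spacing (and the forced breakpoints)
is chosen to preclude for physiological event shapes.

Output samples lie on a uniform grid (default 2001 points) augmented
with all event times, and each regime's duration and indicators are
retained, so occupation times (`time_in_region()`) are computed from
the regime partition exactly rather than by quadrature. An
independent fixed-step Euler oracle (step `10^-6` of the horizon, in
the test helpers, deliberately ignorant of events) and a `10^6`-point
indicator quadrature cross-validate the stepper in the suite.

The Euler solver is also the integrator for the sigmoid-switched
variant (`method = "euler"`, default `2 x 10^5` steps), where the
right-hand side is smooth and piecewise linearity is lost. The hard
gate `theta(M - R)` is kept even there, as is the cap `R <= M`.

## Sigmoid switching and the role of scale

`switching_spec("sigmoid", c)` replaces the steps by the logistic
`Theta_c(x) = 1/(1 + e^{-cx})`. As `c -> infinity` this approaches the
Heaviside dynamics. Two numerical facts matter when choosing `c`:

* away from crossings, `Theta_c` leaks `~ e^{-c g}` where `g` is the
  mediator's distance to the threshold, so `M` declines slowly even
  with `y < R` — visible at demonstration values like `c = 10` (the
  `fig13-sigmoid-switch` scenario exaggerates this with `r1 > r2`,
  which requires an explicit `strict = FALSE` since it violates the
  model's standing `r1 <= r2` constraint);
* at a crossing, smoothing a slope kink leaves a residual
  `~ r ln 2 / (c v)` with `v` the crossing speed of the switching
  argument, and *both `c` and `v` carry reciprocal-mediator units*.
  On a dimensionless scenario of scale 1 this residual is `~10^-2`
  even at `c = 50`; on the physically scaled CORT replication
  (mediator scale ~157 ng/ml, crossing speeds of tens of ng/ml per
  day) `c = 50` per ng/ml is effectively razor-sharp and the sigmoid
  and Heaviside trajectories agree to ~`10^-5` of the scale. The
  convergence acceptance test therefore runs on the CORT-scaled
  configuration, where "c > 20 is nearly indistinguishable" is a
  dimensionally meaningful statement.

## Senescence

Lifetime decline enters as a drain `A(t) >= 0` subtracted from
`dM/dt` at all times and gated into `dR/dt` only by `theta(R - M)` —
i.e., `R` feels senescence exclusively through being capped at `M`,
which drags `R` down in stress-free lifetimes (`R = M` throughout).
Two printed conventions disagree in sign (the linear form's `A` is a
positive rate, the logistic form's is `dM/dt` itself, negative); this
package stores `A(t) >= 0` as a decline rate everywhere and
subtracts it.

* **linear**: `A = (p_a1 - p_a2)/(a2 - a1)` on `(a1, a2]`, else 0,
  giving the piecewise-linear stress-free closed form
  `closed_form_M_linear()` with `M0 = p_a1` (the closed form pins the
  initial condition, which is why the function takes no separate `M0`);
* **sigmoid**: `A` is the derivative of the logistic decline from
  `p_i` to `p_f` with midpoint `A_bar` and slope `k`
  (`closed_form_M_sigmoid()`); its maximum is `k (p_i - p_f)/4` at
  `A_bar`. Note the logistic at `t = 0` is slightly below `p_i`
  (by `(p_i - p_f)/(1 + e^{k A_bar})`, about 0.007 for the canonical
  `k = 10`, `A_bar = 0.4`), so the matching scenario starts `M0` *on*
  the curve rather than at `p_i`.

The event stepper integrates the drain in closed form inside each
regime (cumulative-integral bookkeeping), so senescence costs no
accuracy; the suite nevertheless checks the fixed-step Euler route
against the closed forms independently, and asserts the obvious
monotonicity: adding senescence never raises `M` at any time.

## Episodes and wear-rate recovery

`detect_episodes()` walks the regime partition: an episode is a
maximal excursion `y > P`; within it, overload onset is the moment the
declining `R` meets `y` (level `y*`), `tau` the reactive-phase
duration before that, and `t_over` the overload occupation. Brief
dips of `y` below `P` end an episode (gap tolerance 0): the
estimation protocol assumes clean, well-separated episodes, and
bridging ripple-induced dips would silently violate its algebra.
Trajectories read from CSV lack the regime partition, so crossings
are interpolated linearly between samples — documented as approximate
(sample-spacing error, visible as ~1% on the shipped example).

With `r1 = r2 = r3 = r` and full recovery between episodes,

$$r = \frac{y^*_i - y^*_{i+1}}{t_i + \tau_{i+1} - \tau_i},$$

one estimate per consecutive pair (`n` episodes give `n - 1`), and
`M0 = y^*_1 + r \tau_1` (equivalently `y^*_2 + r t_1 + r \tau_2`,
which the tests check as a consistency identity). `estimate_r()`
refuses incomplete recovery (hard error naming the gap) — the
identities are simply false then — and skips near-zero denominators
with a diagnostic. The reported `consistency` is the relative spread
`(max - min)/mean` of the estimates: the experimental protocol's
falsification criterion is precisely that this spread be small. No
uncertainty quantification is attached, because the generating model
is deterministic; with measurement noise the estimator is a ratio of
differences and would need one.

## Scenarios: what is printed and what is assumed

Every configuration used in the model's development ships as a named
scenario (`list_scenarios()`). Scenarios fall in two groups:

* the CORT replication (`durant-replication`), fully printed: basal
  `y_c = 12` ng/ml, `a_c = 6` ng/ml, daily period, `y_act = 1`,
  an 11-day ramp of magnitude 140 ng/ml with `alpha = 4`,
  `M0 = 165` ng/ml, `r = 1.5`, 45 days. Its basal component stays
  under the 30 ng/ml basal ceiling reported for sparrows, and the
  schedule peaks on day 12 — both recomputed by
  `scripts/acceptance.R`;
* conceptual demonstrations on dimensionless axes, whose sources
  print only the schedule (and sometimes rates). Fixture defaults —
  flat baseline `y_c = 0.3`, `y_act = 0.1`, and `M0`/`r` chosen once
  so the printed qualitative outcome (overload or not) occurs — are
  listed in each scenario's `assumed` field, and quantitative claims
  in the tests are made only about derived or printed numbers. One
  derived value worth noting: the kernel-insensitivity pair shares
  its exceedance window `(0.2, 0.5)` exactly, which forces the ramp
  magnitude `s = 0.3`; and the wear-rate verification scenario's
  three box events were designed in closed form so each overloads
  and recovers fully, making `r = 2` recoverable to the event
  tolerance.

These synthetic scenarios emulate the *structure* of stress-response
data — circadian baseline, kernel-shaped excursions, threshold
crossings — but not its noise: real mediator series are sampled
sparsely, with assay error, individual variation in `M0` and rates,
and multiple interacting mediators. Passing tests therefore
demonstrate correctness of the deterministic model and estimators,
not field applicability of the protocol.

## Numerical choices, sizes, limitations

Defaults: scan grid `10^4`/horizon, bisection tolerance `10^-10`,
output grid 2001 + events, Euler `2 x 10^5` steps; test oracles use
`10^6`-step Euler and `10^6`-point quadrature on sub-second horizons.
These sizes keep the full suite under half a minute while leaving
event-localisation error orders below every asserted tolerance.

Known limitations: no homeostatic-failure dynamics (undefined in the
framework); one mediator at a time (multi-mediator coupling is a
research question, not an implemented feature); no stochastic events,
delays, or stiff machinery (the switched system is not stiff — it is
piecewise linear); estimation assumes equal rates and clean episodes;
and the senescence extension is provided with its closed forms but no
empirical calibration, mirroring the state of the underlying theory.
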