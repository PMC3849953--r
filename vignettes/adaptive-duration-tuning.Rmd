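---
title: "Adaptive duration tuning for robot-assisted reaching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive duration tuning for robot-assisted reaching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachadapt)
```

## The problem

Assist-as-needed rehabilitation robots guide a patient's arm along a
reference trajectory, but a fixed movement duration serves nobody well: too
short and the user is dragged, too long and the user idles. `reachadapt`
implements, hardware-free, the adaptive loop used by an upper-limb
rehabilitation system of the HapticMaster family: measure whether the user is
*leading* or *lagging* the robot from end-effector positions alone, then tune
each movement's set duration between repetitions until it settles on the
user's own comfortable pace. The settled ("constant optimum") duration is
itself a clinically interpretable performance measure.

The package provides five interlocking pieces: minimum-jerk reference
trajectories, lead/lag effort metrics, the bounded duration-update rule with
convergence detection, synthetic participants that close the loop in
simulation, and the dummy-coded interaction regression used to analyse how
task conditions shape the settled durations.

## Reference trajectories

Point-to-point movements follow the minimum-jerk trajectory (MJT): a straight
path from source $\mathbf{a}$ to target $\mathbf{b}$ traversed with quintic
time scaling

$$\mathbf{x}(t) = \mathbf{a} + (\mathbf{b}-\mathbf{a})\,\sigma(t/D), \qquad
  \sigma(s) = 10s^3 - 15s^4 + 6s^5,$$

the unique quintic with zero velocity and acceleration at both endpoints, and
the standard smoothness model for human reaching. Useful identities, all
enforced by tests at $10^{-9}$: $\sigma(0)=0$, $\sigma(1)=1$,
$\sigma(1/2)=1/2$, $\sigma(s)+\sigma(1-s)=1$, peak speed $1.875\,L/D$ at
mid-movement for a path of length $L$ and duration $D$, and invariance under
time rescaling $(D,t)\to(kD,kt)$.

`sample_trajectory()` evaluates position and analytic velocity on a regular
grid with interval `dt` (default 0.01 s; the controller recomputed the
reference at the start of every sampling interval, and 100 Hz is a typical
haptic-loop reporting rate). The final sample is forced to land exactly at
$t=D$ even when $D$ is not a multiple of `dt`, so endpoint identities hold
exactly rather than approximately.

### The workspace

The thirteen segments of the study workspace are built by `cube_segments()`
from the packaged segment table: lengths between 0.276 m and 0.415 m, each
labelled by target presentation (embedded real object vs purely virtual),
movement type (reach vs return), gravity direction (against, towards, ground
level) and cross-body magnitude (small, large). Absolute cube coordinates
were never published; endpoints are therefore synthesised to match the
published lengths exactly, with a vertical component for gravity-loaded
segments and a lateral one for large cross-body segments. This is a safe
liberty: every metric in the package depends only on the source, target and
length of a segment, never on absolute placement.

## Lead/lag metrics

At each sample time the **effort projection** is the signed scalar projection
of the displacement from the source onto the unit source-to-target vector:
0 at the source, $L$ at the target, negative behind the source, beyond $L$ on
overshoot. `summarize_efforts()` computes this for the reference
(`effort_mjt`) and the achieved trace (`effort_actual`), their per-sample
difference `delta_effort = effort_mjt - effort_actual`, and the segment
aggregate `sum_delta_effort` $= \Sigma(\Delta\text{Effort})$.

The sign convention is fixed by the adaptation rule: a *positive* aggregate
means the achieved position trailed the reference for the larger part of the
segment (lagging), a *negative* one means it ran ahead (leading). Swapping
the two trajectories negates every difference, and rigid motions of the whole
scene leave the projections unchanged — both are property-tested.

Two auxiliary measures follow the same conventions: `tau()` maps a time
inside the execution window linearly onto $[-1, 1]$ (the linear map is the
minimal choice consistent with the stated purpose of the parameter), and
`normalized_duration()` divides a recorded duration by the segment length
(s/m) so execution pace can be compared across segments.

Achieved trajectories are resampled onto the reference time base by linear
interpolation with clamped extrapolation (`stats::approx`, rule 2), so
logger and controller clocks need not be aligned. The raw-sample aggregate
scales linearly with sampling density; `time_weighted = TRUE` instead weights
each sample by its time step, giving a density-invariant integral
approximation (metre-seconds). Raw summation is the default because the
deployed rule operated on recorded samples; every sign-based decision is
identical under either convention, which is also property-tested.

## The adaptation rule

After each adaptive-mode execution of segment $k$ the set duration is updated
by

$$\delta = \mathrm{clip}(g\,\lvert\Sigma\Delta\text{Effort}\rvert,\;
  \delta_{\min},\,\delta_{\max}), \qquad
  D_{k} \leftarrow \begin{cases}
    D_k + \delta & \Sigma\Delta\text{Effort} > 0 \text{ (lagging)}\\
    D_k - \delta & \text{otherwise (leading)},
  \end{cases}$$

then rounded to a quantum and clamped at a floor. Defaults, with units and
rationale:

| parameter | default | meaning |
|---|---|---|
| `gain` ($g$) | 0.05 s/m | duration change per metre of aggregate effort difference |
| `delta_min`, `delta_max` | 0.0, 1.0 s | bounds on the per-iteration step |
| `duration_floor` | 0.5 s | smallest admissible duration |
| `quantum` | 0.2 s | rounding grid for updated durations (0 disables) |
| `initial_duration` | 4 s | duration of the first repetition |

The step bounds and the 4 s initial duration are the deployed system's
values; the 0.2 s quantum is the granularity visible in every recorded
duration. The floor is a guard the package adds so that an extreme leading
aggregate can never drive the duration non-positive.

The gain is the one genuinely free constant (the deployed value was never
published, only that $\delta$ is proportional to the aggregate and bounded by
1 s). We calibrate it to the recorded sessions' dynamics: at 100 Hz over a
typical 0.4 m segment, $g = 0.05$ s/m saturates the step at $\delta_{\max}$
once the mean lead/lag exceeds about an eighth of the segment, which
reproduces the recorded sessions' step pattern — a user with a 1.6 s
intrinsic pace starting from 4 s descends 4 → 3 → 2 → 1.6 and then holds,
settling within the five repetitions of the standard protocol. A much
smaller gain (e.g. one that saturates only at a *full-segment* mean lag)
cannot cross the 4 s → 1.6 s range in five iterations and would leave almost
every realistic user unconverged; a much larger one overshoots and
oscillates on the quantum grid. Note that with raw-sample aggregates the
physically meaningful constant is `gain * dt`: rescale the gain if you
change the sampling interval, or switch to time-weighted aggregates.

Rounding uses R's `round()` (half-to-even). Ties occur only when the
unrounded update lands exactly halfway between quantum steps, which has
measure zero under noise; determinism is what matters and is guaranteed.

### Convergence: the constant-optimum rule

A duration sequence has reached its constant optimum when it stays constant
for `min_run` (default 2) or more iterations *without further change as the
iterations progress* — i.e. the constant run must be the trailing run.
A mid-sequence plateau that later changes again does not qualify; this
reading is validated against the recorded worked-example session, where a
segment dwelling at 2.8 s mid-session before moving to a final 2.6, 2.6 run
counts as converged at 2.6 s, and exactly nine of thirteen segments qualify.
Equality is exact up to `tol` (default $10^{-6}$ s), appropriate for
already-quantised records; raise `tol` for continuous (quantum-0) studies.

## Synthetic participants

`user_model()` is the package's generative stand-in for a human, designed so
that the adaptive loop's observable has a controlled, sign-correct dependence
on the quantity being tuned. The core assumption is an **intrinsic clock**:
an active user executes the segment as their own MJT with preferred duration
$P$ regardless of the robot's set duration $D$, holding at the target when
they finish early ($P < D$, leading) and trailing when slow ($P > D$,
lagging). A passive user is dragged along the reference delayed by a pure
response lag. Isotropic Gaussian position noise (default 0; 2 mm is a
realistic end-effector scale) is added per sample, seeded and bit-reproducible.

Under this model $\Sigma\Delta\text{Effort}$ is strictly negative whenever
$D > P$ and strictly positive whenever $D < P$, so $P$ is the unique fixed
point of the loop and *parameter recovery* is a meaningful end-to-end test:
the loop must find $P$ to within one quantum. The acceptance suite runs this
recovery noise-free and across 100 noisy replicates.

In full sessions the mode dictates the scenario: passive mode plays the
response-lag model (the lagging scenario), the assisted modes play the
intrinsic clock. Optional `condition_factors` multiply the preferred duration
per condition label (e.g. faster with embedded targets, slower for reaches),
planting known ground-truth effects for the regression module to recover.

What the model does *not* emulate: within-session drift of the preferred
pace (real users pushed themselves harder in later repetitions and sometimes
re-diverged after settling), biomechanics and muscle-group asymmetries, force
interaction, or fatigue. Passing simulation tests therefore demonstrates that
the algorithmic loop is correct and recoverable under its own assumptions,
not that real patients converge at the simulated rates.

## The session protocol

The standard actual-performance session is `protocol()`: passive and first
active-assisted (AA1) passes at the start and again at the end, with five
adaptive active-assisted (AA2) repetitions in between — nine passes over
thirteen segments, 117 executions. Adaptation is enabled *only* during AA2;
non-adaptive passes run at the segment default duration (whether the closing
passive/AA1 passes used adapted durations was never recorded; defaults are
the conservative choice and the setting is configurable). The training phase
that familiarised participants is excluded from analysis and is modelled
only as an optional warm-up count.

Recorded sessions show the first AA2 repetition already below the 4 s
default, so by default the first AA2 duration is seeded by applying one
update using the preceding AA1 pass's aggregate
(`seed_aa2_from_aa1 = FALSE` starts from the raw default instead). Durations
update between iterations, never within a segment execution, matching the
one-duration-per-iteration structure of the recorded tables.

## Condition-effect regression

To analyse how task conditions shape durations, each execution is
dummy-coded against reference categories: Virtual (EV0), Return (RR0),
Against-gravity (G0) and Large cross-body (CB0) are the all-zero profile, so
the intercept $b_0$ is the predicted duration for that profile. Model 1 uses
the main-effect dummies (EV1, RR1, G1, G2, CB1) plus one dummy per
non-reference participant; Model 2 adds the seven products
EV1G1, EV1G2, RR1G1, RR1G2, RR1CB1, G1CB1, G2CB1 as interaction variables.

`fit_duration_model()` estimates both by OLS (`stats::lm` on the explicit
dummy design), reporting unstandardised coefficients with standard errors,
standardised betas ($b_i\,\mathrm{sd}(x_i)/\mathrm{sd}(y)$), $R^2$, adjusted
$R^2$ and the Durbin–Watson statistic on residuals in record order (the
original analysis order was not recorded; we use participant/iteration/segment
log order). Dummies with no variation in the supplied records are dropped;
genuinely aliased designs are rejected with the offending columns named.
`change_statistics()` compares the nested models with the standard increment
test
$$F = \frac{(R^2_{\text{full}} - R^2_{\text{restr}})/\mathrm{df}_1}
         {(1 - R^2_{\text{full}})/\mathrm{df}_2},$$
cross-checked in the tests against the residual-sum-of-squares form
(`anova()`) and, via `f_change()`, against a published model summary's
printed value.

Prediction is plain substitution, $\hat y = b_0 + \sum b_i x_i$
(`predict_duration()`), and `condition_duration_table()` tabulates it over
the 4 × 3 grid of presentation/movement-type by gravity. With the packaged
published coefficients (rounded to 3 d.p.), most grid cells reproduce the
published table exactly; a handful differ by one unit in the third decimal
because the original table was computed from unrounded coefficients. Tests
assert only the exactly-derivable cells and document the rest.

The published cohort-level fitted quantities (the $N = 2432$ record count,
the $R^2$ pair as *fitted* values, the coefficient estimates themselves)
require the raw per-participant logs, which were never released; they are
covered instead by parameter-recovery tests on simulated cohorts with planted
effects (fitted EV1 negative, RR1 positive, matching the directional
findings) and by the substitution checks above.

## Numerical choices, sizes, limitations

* All randomness flows through explicit integer seeds (`withr::with_seed`);
  identical seeds give bit-identical logs. Derived per-iteration seeds are
  small prime multiples of the master seed, kept within 32-bit range.
* Degenerate inputs fail loudly: zero-length segments, times outside the
  execution window, sampling intervals that admit no interior sample,
  non-overlapping time ranges, unknown exclusion ids, non-nested model
  comparisons.
* The test suite runs sessions at `dt` of 0.02–0.05 s and cohorts of 2–4
  participants; the acceptance recovery uses the full 100 Hz grid over 5
  iterations and 100 noisy replicates. These sizes make the suite quick while
  leaving every decision path exercised; all sign-based conclusions are
  sampling-rate invariant by construction.
* Packaged transcriptions of the published tables are checksum-pinned and
  never mutated; `load_fixture()` refuses edited copies.
* Out of scope by design: force/impedance rendering, curved or multi-via
  trajectories, visual feedback, within-segment re-planning, mixed-effects
  modelling of the cohort (the original analysis used fixed participant
  dummies), and any claim about muscle physiology.
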