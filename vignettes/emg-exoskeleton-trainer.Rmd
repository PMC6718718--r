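---
title: "Methods: simulated EMG-driven knee-exoskeleton game training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated EMG-driven knee-exoskeleton game training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgrehab)
```

## What this package simulates

`emgrehab` is a complete, closed-loop simulation of a myoelectric
knee-rehabilitation trainer: a thigh EMG band drives a powered knee
exoskeleton proportionally, and the knee angle in turn flies the bird of a
Flappy-Bird-style training game. Every stage of the real system — the
8-channel EMG stream, the envelope filter, the per-subject calibration, the
servo cascade and joint, the game, and the session protocol — is a tested
software component, and a configurable *virtual subject* closes the loop so
the whole system can be exercised, measured and regression-tested without
hardware or human participants.

The signal chain is:

```
activation a(t) --> 8-ch raw EMG --> Kalman filter --> 8-ch mean envelope
      ^                                                       |
      |                                              proportional map
 virtual subject                                              v
      ^                                      PD position -> PID velocity -> plant
      |                                                       |
      +------ game state <---- bird altitude <---- knee angle θ_a
```

## EMG envelope model and the Kalman filter

The EMG band delivers rectified, low-pass-filtered but still noisy envelope
samples at 200 Hz. The synthetic generator models channel $c$ at time $t$ as

$$Y_{c,t} = \max\bigl(0,\; \mathrm{bias}_c + \mathrm{gain}_c\, a(t) +
\varepsilon_{c,t}\bigr), \qquad \varepsilon_{c,t} \sim N(0, \sigma_c^2),$$

with $a(t) \in [0,1]$ the known ground-truth activation. This is an
*envelope* model: it does not simulate the raw interference EMG waveform or
motor-unit physiology, only the already-rectified stream every downstream
computation consumes. Units are arbitrary; all downstream math is
scale-invariant after calibration. The default preset (`bias = 1`,
`gain = 4`, `noise_sd = 0.5` per channel) gives visibly noisy raw traces
from which calibration is still reliably recoverable. Each channel draws
from its own RNG stream derived from one master seed.

The envelope filter treats the true envelope as locally constant and runs,
per channel, the scalar Kalman recursion

$$X_k^p = X_{k-1},\quad P_k^p = P_{k-1} + Q,\quad
KG_k = \frac{P_k^p}{P_k^p + R},\quad
X_k = X_k^p + KG_k\,(Y_k - X_k^p),\quad P_k = (1 - KG_k)\,P_k^p,$$

with `Q = 0.0001` and `R = 0.59948` for all subjects and channels. The
covariance recursion is measurement-independent and converges to the fixed
point $P^p_* = \tfrac{1}{2}\bigl(Q + \sqrt{Q^2 + 4QR}\bigr)$, so the
steady-state filter is exactly an exponential smoother with gain
$KG_* = P^p_*/(P^p_* + R) \approx 0.012832$ (`steady_state_gain()`); the
test suite asserts the full recursion collapses onto that smoother after
burn-in to $10^{-12}$. The control signal is the arithmetic mean of the
eight filtered extensor channels; because the filter is linear and shares
its gain sequence across channels, filtering before averaging equals
averaging before filtering, which is also asserted.

Numerical choices: the recursion is seeded at $X_0 =$ the first measurement
and $P_0 = R$ (no published initialization exists; starting at the first
sample avoids a transient from zero and is scale-free — in the streaming
session loop the filter starts at the calibrated bias, the known rest
level). The unreachable $0/0$ corner $P^p = R = 0$ is defined as gain 1.
As a single-pole smoother the filter attenuates by about $-8.4$ dB at 1 Hz
and $-21.7$ dB at 5 Hz at 200 Hz sampling (`kalman_response_db()`), i.e. it
suppresses envelope noise above roughly 1 Hz while passing the slow
voluntary envelope.

## Calibration: Bias, MVE and the effort cap

Per leg, the subject relaxes for 5 s and then holds a maximal isometric
knee extension for 5 s. From the 8-channel-mean filtered envelope:

* **Bias** is the mean over the relax window — the mean (rather than a
  maximum) is unbiased, and the downstream clamp absorbs sub-bias noise;
* **MVE** is the highest level *sustained for at least 1 s*,
  operationalized as the maximum over sliding 1 s windows of the
  within-window minimum. A sustained-mean or percentile reading would also
  be defensible; the sustained-minimum has an exact brute-force oracle and
  is isolated behind `estimate_mve()` so the choice is a one-line swap.

Calibration fails with an *insufficient signal range* error when
`mve - bias` is non-positive or smaller than three resting standard
deviations — the safety case of a subject who cannot yet produce a usable
voluntary signal. During training only 60% of the calibrated range is used
(`effort_cap = 0.6`), to avoid fatigue.

## Proportional control, servo cascade and simulated joint

The desired knee angle is proportional to the filtered envelope:
$\theta_d = 90^\circ \cdot \mathrm{clamp}\bigl((E - \mathrm{Bias})/
(\mathrm{MVE} - \mathrm{Bias}),\, 0,\, 0.6\bigr)$, so the commanded range is
exactly $[0^\circ, 54^\circ]$: $0^\circ$ is the seated posture and
$90^\circ$ full extension. Whether an envelope at MVE should saturate at
$54^\circ$ or the map be rescaled is ambiguous in the source description;
saturation (clamp at the cap) is used and isolated in `emg_to_angle()`.

The servo is a cascade: a PD position loop produces a desired angular
velocity from the angle error (derivative on the measured velocity), an
inner PID velocity loop with a clamped integrator produces the motor
command, and the plant tracks velocity with a first-order lag, integrated
by explicit Euler at `dt = 5` ms (200 Hz, matching the EMG rate; the plant
is a benign first-order system, so Euler error at this step is negligible
and the first-order step response is checked against its exact discrete
closed form in the tests). No controller gains were ever published for the
hardware; the defaults (`pos_kp = 8` s⁻¹, `pos_kd = 0.05`,
velocity PID `1 / 5 / 0`, integrator clamp ±200 deg/s, plant time constant
50 ms) are this package's own choice of a stable, well-damped loop whose
desired-to-actual lag is on the order of 100 ms — the regime the hardware
exoskeleton reportedly operates in — and all of them sit in
`controller_gains()` / `plant_config()`.

Safety is three-layered, as data rather than exceptions: software range
and speed limits (`[0°, 54°]` during training, ±120 deg/s) pin the angle
and zero the velocity; simulated overtravel-limit switches at the
mechanical bounds (−10° hyperextension, 110° flexion; hyperextension is
negative in the seated convention) cut motor power if a step ever lands
past them; and an emergency-stop latch freezes the joint until reset.
Only the knee is simulated — hip and ankle are fixed, as in single-joint
training.

## The training game

The game is headless: geometry, scoring, lives and difficulty are exact;
rendering, audio and haptics are emitted as a timestamped event stream
(`point`, `collision`, `life_lost`, `haptic_pulse`, `resume`,
`block_over`), which is the contract a front end would consume. The bird is
a 48 px square at a fixed horizontal station; its altitude is proportional
to the actual knee angle ($0^\circ$ = screen bottom, $54^\circ$ = top). The
question of whether the bird should follow the exoskeleton angle or the raw
EMG envelope is resolved in favor of the measured joint angle, since the
display is described as proportional to the exoskeleton's knee angle.

Pipe pairs appear at uniformly random feasible heights and march left;
clearing a pair scores a point, touching one costs a life (of 4 per block)
and the world pauses (hover) until resume, which also clears a grace
distance ahead of the bird. Difficulty interpolates *linearly* in score
between the printed endpoints — gap 300 px and speed 1× at score 0, gap
190 px and speed 2.5× at score 100, frozen beyond — because only the
endpoints and the cap are documented; the schedule is one pure function
(`difficulty()`) so another shape is a one-line change. Screen size
(480×800), pipe width (80 px), spacing (320 px), base speed (120 px/s) and
tick rate (50 Hz) are undocumented and live in `game_config()` as declared
artifacts. Collision uses axis-aligned bounding boxes: deterministic and
adequate for training dynamics.

## Virtual subject and session protocol

The virtual subject stands in for the human player. Each game tick it
computes the activation that would center the bird in the next gap
(inverting the display and control maps), passes it through a visuomotor
reaction delay (default 150 ms) and a first-order pursuit lag (200 ms), and
multiplies by slowly wandering Ornstein–Uhlenbeck noise (SD 0.15,
correlation time 0.5 s). The *correlated* noise is what makes errors
persist long enough to clip a pipe occasionally, so blocks end the way real
blocks do — by running out of lives. These defaults were chosen so that a
default block exhausts its four lives with scores in the tens, the range
reported for healthy novices on this task; with them, simulated blocks last
70–120 s, mean tracking RMSE is ≈1.5° and the desired-to-actual lag
≈100–120 ms. An optional per-block decay of the noise SD
(`noise_decay`) can emulate learning across blocks; it is off by default
because the package makes no claims about human learning curves.

A session (`run_session()`) is, per leg: calibration from a synthesized
maximal-effort protocol, then 10 blocks of 4 lives with 30 s interblock
rests; then the other leg. The human space-key press after a life loss is
replaced by an automatic resume after a 1 s hover. A guard of 300 s per
block exists only to bound a pathological non-dying subject; default
blocks never reach it. Everything derives from one master seed, and an
identical `(config, subject, seed)` triple reproduces the session log
byte-for-byte.

What the virtual subject does *not* model: fatigue, spasticity, tremor,
electrode shift, attention lapses, or any stroke-specific impairment.
Passing tests therefore demonstrate that the *system* behaves correctly and
measurably — not that any human population would produce these scores.

## Evaluation metrics

* **MAL / mMAL** — per-step muscle activation level
  $\mathrm{clamp}\bigl((E - \mathrm{Bias})/(\mathrm{MVE} -
  \mathrm{Bias}), 0, 1\bigr)$ and its mean over the block's *active* time
  steps. Whether the averaging denominator should include hover time is
  unspecified in the source; active-only is used, consistent with the
  block activation time definition.
* **Block activation time (BAT)** — cumulative flying time per block,
  excluding hovers and rests: the active-therapy dose.
* **Tracking RMSE** between desired and actual joint angle, in degrees.
* **Cross-correlation lag** — the lag maximizing the normalized
  cross-correlation of the mean-removed series (ties broken toward the
  most negative lag by first-maximum; the search is bounded to half the
  window or a caller-supplied bound). Positive = second series lags.
* **Spectral attenuation** — ratio of filtered to raw periodogram power
  above a cutoff, in dB, from plain FFT periodograms (no tapering or
  detrending beyond mean removal, so the quantity is exactly the band-power
  ratio).
* **One-way ANOVA** — the classical equal-variance fixed-effects F test
  (delegated to `stats::oneway.test`), used for block-metric comparisons.

On synthetic burst traces the filter's cross-correlation delay is ≈225 ms
at the default SNR. The delay is an envelope property: it is set by the
smoother's ≈390 ms time constant acting on the burst edges, and is nearly
independent of the noise level (more noise in fact pulls the correlation
peak *slightly* toward zero, since noise passes the filter with its largest
impulse-response weight at lag zero). Hardware-derived delay figures depend
on the recorded envelopes and are not reproducible from synthetic data;
the tests therefore assert the sign, the stability and the order of
magnitude of the delay, not a specific number.

## Problem sizes and test design

The test suite runs entirely from code-generated fixtures: filter
equivalence on $10^5$ random samples at $10^{-12}$; calibration recovery
over 100 seeded 10 s protocol runs (both anchors within 5% in ≥95 runs);
game-logic oracles (a scripted perfect tracker scores exactly one point
per passed pipe; a floor-bound bird loses all four lives scorelessly);
one full default two-leg session (20 blocks); and a 20-seed skill-ordering
comparison using one 30 s-capped block per leg, sizes chosen to keep the
default check run to a couple of minutes while leaving every property
statistically unambiguous.

## Known limitations

* The plant is kinematic (first-order velocity tracking): no torque,
  gravity, inertia or motor-current model, so hardware tracking-error
  magnitudes can only be matched in regime, not derived.
* The envelope noise is Gaussian and per-channel independent; real
  inter-channel crosstalk and impedance drift are not modeled.
* Difficulty interpolation between the documented endpoints, the
  sustained-minimum MVE reading, and all game geometry defaults are
  declared package choices, each isolated behind one function or config
  field.
* The virtual subject is a control-theoretic stand-in, not a model of
  human motor learning; cross-subject score statistics generated here
  carry no clinical meaning.
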