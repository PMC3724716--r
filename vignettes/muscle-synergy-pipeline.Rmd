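---
title: "Modular control analysis of robotic-guided gait: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular control analysis of robotic-guided gait: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergait)
```

## The model

Human walking is well described as low-dimensional, impulsive control: a
small number of *motor modules* — fixed non-negative weightings over the leg
muscles — driven by burst-like *activation signals* tied to phases of the
gait cycle. `synergait` implements this model for seven muscles of the
dominant leg (RF, VL, ST, BF, GM, GL, TA) recorded during treadmill walking
and robotic-guided walking in a gait exoskeleton, where the conditions of
interest are walking speed (1.5, 2.0, 2.5 km/h) and guidance force (GF; 20,
40, 70, 100% of the assistance torque).

The time-normalized, amplitude-normalized envelope matrix
$EMG_0 \in \mathbb{R}_+^{m \times t}$ ($m = 7$ muscles, $t = 101$ samples
spanning 0–100% of the gait cycle) is approximated as $W A$ with
$W \in \mathbb{R}_+^{m\times n}$ and $A \in \mathbb{R}_+^{n\times t}$,
minimizing the squared error $\sum_{ij}(EMG_{0,ij} - (WA)_{ij})^2$.
Reconstruction quality is the variance accounted for,
$\mathrm{VAF} = 1 - \sum (EMG_0 - WA)^2 / \sum EMG_0^2$, with an
*uncentered* denominator: envelopes are non-negative amplitude profiles and
the zero reconstruction should score 0, not the mean-removed baseline.
VAF is evaluated overall, per muscle, and within the seven gait subphases
(initial double support 0–10 %GC, mid stance 10–30, terminal stance 30–50,
pre-swing 50–60, initial swing 60–73, mid swing 73–87, terminal swing
87–100). On the 101-point axis the phase masks are lower-inclusive /
upper-exclusive except the last, which includes 100%, so the seven masks
partition all 101 samples.

## The processing chain and its assumptions

1. **Band-pass filter** — 3rd-order Butterworth, 20–400 Hz, applied forward
   and backward (`signal::filtfilt`). Zero-phase filtering was chosen so
   that filter group delay cannot shift burst onsets, which the timing
   statistics downstream depend on; the cost is that the magnitude response
   is applied twice (a per-pass passband gain of 0.985 at 100 Hz becomes
   0.971). Sampling at 1 kHz keeps the 400 Hz edge below Nyquist.
2. **Rectify + RMS smooth** — absolute value followed by a centered
   50-sample moving RMS (50 ms at 1 kHz). Edge samples use the shrunken
   window that fits inside the signal; this avoids padding artifacts at
   trial boundaries at the cost of slightly noisier estimates in the first
   and last 25 ms, which never fall inside the retained central strides.
3. **Segment + time-normalize** — cycles run heel strike to heel strike
   (half-open), each linearly resampled to 101 points including both 0% and
   100%. Linear interpolation is used because the envelopes are already
   smooth at the 1 ms scale; it preserves affine segments exactly and cannot
   overshoot (no negative values).
4. **Ten central cycles** — of the available cycles, the middle ten by
   stride index are kept; for an odd surplus one more trailing than leading
   cycle is dropped (start-up transients are assumed to have settled by the
   time recording begins; fatigue-related drift accumulates at the end).
5. **Average + amplitude-normalize** — per-condition mean across the ten
   cycles, then each muscle divided by its maximum over *all* of the
   subject's conditions. Normalizing across (not within) conditions
   preserves between-condition amplitude differences, which carry the effect
   of speed and guidance force. Normalization maxima are computed per
   subject; group-average matrices are means of the subjects' normalized
   matrices (`group_average_envelopes()`).

## Factorization: numerical choices

The NNMF uses Lee–Seung multiplicative updates for the squared error, with
denominators floored at $10^{-12}$ so non-negativity is preserved exactly
and the objective is non-increasing at every iteration. A run stops when the
relative objective decrease falls below `tol` (default $10^{-6}$) or at
`max_iter` (default 2000). Because the problem is non-convex, the best of
`restarts` (default 20) seeded uniform-random initializations is kept.

Two ambiguities of NNMF are resolved canonically: scale, by rescaling each
column of $W$ to unit maximum with the inverse scale pushed into $A$
(reconstruction unchanged — a muscle weighting is a shape, the drive lives
in the activation signal); and order, by sorting modules by the %GC of their
activation peak, with ties broken by the muscle index of the largest weight.

Module-count selection fits candidates in increasing order and returns the
smallest $n$ with every per-phase and per-muscle VAF ≥ 0.80 and overall
VAF ≥ 0.90. When fitting $n$, one extra initialization is seeded from the
$(n-1)$-module solution plus one random module, which makes the
best-of-restarts VAF curve non-decreasing in $n$ — a useful diagnostic
property that random restarts alone do not guarantee. If no candidate
qualifies, the largest is returned flagged `qualifies = FALSE`.

The fixed-module re-fit (shared basis across conditions, by convention the
treadmill 2.5 km/h modules) freezes $W$ and solves each time sample as an
independent non-negative least-squares problem with Lawson–Hanson NNLS
(`pracma::lsqnonneg`), which is exact — no iteration tolerance enters. The
test suite cross-checks it against an exhaustive support-enumeration oracle.

Module correspondence across conditions (`match_modules()`) maximizes the
total Pearson correlation between matched weight vectors, exhaustively over
all permutations (cheap for $n \le 5$).

## Timing and biomechanics

Subphase contributions integrate each activation signal over the seven
phases with the trapezoidal rule on the %GC axis (boundary samples are
shared endpoints of adjacent phase integrals), and express them as
percentages of the total, which sum to 100 for any non-zero signal.
Correlations of contribution vectors between conditions use the plain
Pearson product-moment statistic on the integrals; percentages are also
available.

On/off detection needs a rest reference that the gait cycle itself must
supply; the "triple SD" rule is implemented as: baseline = mean of the
lowest-decile samples, threshold = baseline + k·SD of those samples
(k = 3 by default), ON wherever the signal exceeds the threshold. Runs
shorter than 5 %GC are discarded as noise blips, and runs that touch both
100% and 0% are treated as one wrap-around burst (the cycle is periodic)
when the duration filter is applied. The rule is invariant to positive
rescaling of the signal.

Joint summaries are deliberately plain arithmetic: ROM = max − min of the
angle cycle with the %GC of first attainment of each extremum (first
attainment matters because extrema of robotic-guided cycles often sit
adjacent to the 0/100% wrap); ROF = max − min of the machine-interaction
force, overall and per phase, with the closure ROF = max(phase maxima) −
min(phase minima) holding exactly because the phases partition the cycle.
Forces are passed through in machine units exactly as logged by the
exoskeleton; no inverse dynamics is attempted.

## The synthetic-data generator

No public recordings exist for this protocol, so the generator is the test
bed. It emulates:

* **Activation signals** — Gaussian bursts on the periodic 0–100% axis.
  Defaults for four modules: module 1 (RF/VL) midstance (~15 %GC); module 2
  (ST/BF) terminal swing (~93 %GC) with a smaller midstance burst; module 3
  (GM/GL) late stance (~45 %GC); module 4 (TA) midstance plus a broad swing
  burst (~67 %GC). Published work on this protocol describes these roles
  qualitatively but gives no burst centers or widths, so the defaults are
  declared package conventions chosen to match normal gait physiology, with
  widths of 6–12 %GC.
* **Muscle weightings** — dominant weights 0.85–1.0 on each module's muscle
  group, seeded cross-talk weights 0.02–0.20 elsewhere, columns normalized
  to unit maximum.
* **Condition effects** — walking speed scales all amplitudes linearly
  (reference: treadmill at 2.0 km/h, gain 1). Robotic guidance raises
  quadriceps gain, more at low GF where the subject must contribute
  actively (RF/VL gain 1.15 + 0.35·(1 − GF/100)), and attenuates the
  plantarflexors and TA (gain 0.85, the spring foot-lifters assist
  dorsiflexion). These gains reproduce the qualitative trends of the
  protocol; their exact values are free parameters.
* **Raw signals** — the condition's envelope, resampled to the stride
  duration and jittered multiplicatively per stride (SD 5%), amplitude-
  modulates a unit-variance Gaussian carrier band-limited to 20–400 Hz.
  Stride time is 2.4 s at 1.5 km/h, scaling inversely with speed — a
  declared fixture convention, since cadence is not published for this
  protocol.
* **Joint traces** — smooth two-bump cycle shapes mapped affinely so the
  requested extrema are attained exactly at the requested %GC samples.

What the generator does **not** emulate: physiological EMG spectra and their
condition dependence, electromechanical delay, crosstalk between electrode
sites, movement artifacts, pathological (e.g. post-stroke) coordination, and
exoskeleton dynamics. Passing tests therefore demonstrate that the analysis
chain is correct and self-consistent — that it recovers known modular
structure through the full raw-signal path — not that it has been validated
against recorded human data.

## Simulation scale and determinism

The packaged simulations use the protocol's 15-condition grid (3 speeds ×
(treadmill + 4 GF levels)), 7 muscles × 101 samples per envelope, 12 strides
per raw trial at 1 kHz, and envelope noise SD of 5% of the peak — sizes at
which the full test suite and the acceptance simulation complete in well
under a minute each. Every stochastic step (ground-truth weights, noise,
jitter, carrier, NNMF initializations) draws from an explicit integer seed;
per-condition seeds are derived as master seed + condition index, and
re-running any configured pipeline reproduces all CSV artifacts
byte-for-byte.

## Known limitations

* Multiplicative updates converge to local minima; restarts mitigate but do
  not guarantee global optimality. The warm-started selection chain only
  guarantees monotonicity of the reported VAF curve, not optimality at each
  $n$.
* The per-phase VAF of a weakly active phase has a small denominator and is
  therefore noise-sensitive; this mirrors the behavior of the published
  selection rule rather than correcting it.
* The triple-SD rule's reference sample (lowest decile) is a convention; for
  signals whose baseline occupies less than a decile of the cycle the
  threshold is biased upward slightly.
* Amplitude normalization assumes every muscle is genuinely active in at
  least one condition; an identically zero channel is rejected rather than
  silently propagated.
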