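---
title: "An LTI convolution model for tonic electrodermal arousal and the AUC measure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An LTI convolution model for tonic electrodermal arousal and the AUC measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfauc)
```

## The model

Spontaneous fluctuations (SF) in skin conductance are caused by short
bursts of sudomotor nerve firing that open sweat glands. Because the
number of recruited glands scales with burst amplitude, and successive
responses superpose approximately linearly, tonic electrodermal
activity can be modelled as a linear time-invariant (LTI) system: the
measured conductance is the tonic level plus the convolution of a
sudomotor burst train with a stereotyped response function,

$$SC(t) = SCL + SN(t) \otimes RF(t), \qquad
  SN(t) = \sum_{i=1}^{n} a_i\,\delta(t - T_i).$$

Integrating both sides over an epoch gives the identity this package
is built around: with $c = \int RF(t)\,dt$,

$$AUC \;=\; \int SC(t)\,dt - SCL \;=\; c\,n\,\bar a + e,$$

so a single time-integral of the level-corrected signal carries the
same arousal information as the conventional pair (fluctuation count
$n$, mean amplitude $\bar a$) — without peak detection, exclusion
heuristics, or visual scoring. The error $e$ absorbs noise and any
violation of linearity or time-invariance.

`compute_auc()` operationalises $SCL$ as the epoch minimum and
integrates by the trapezoidal rule; no detrending or filtering is
applied first. Two consequences are worth knowing. First, the AUC is
invariant to any constant level shift and linear in the deviations
from the minimum. Second, noise pushes the minimum down, so the AUC
acquires a small positive bias — visible as a positive intercept when
AUC is regressed on $n \bar a$, never as a sign error.

## Frequency-domain view, and why we stay in the time domain

By the convolution theorem, $FT(SC - SCL) = FT(SN)\,FT(RF)$. For a
rectangular burst train of duration $d$ recurring at rate $n$ Hz, the
harmonics are $FT(SN)_i = \sin(i\pi n d)/(i\pi)$ with burst-rate
sensitivity $\partial FT_i/\partial n = d\cos(i\pi n d)$ — largest at
low harmonics while $nd < 1$, which is the classical motivation for
low-frequency spectral-power arousal scores. One could in principle
invert the system spectrally,
$SN = FT^{-1}\{FT(SC - SCL)/FT(RF)\}$, and `naive_deconvolve()`
implements exactly that with a machine-precision floor
(`epsilon = 1e-8`) on the kernel spectrum. The floor is deliberately
*not* a noise regulariser: the estimator is exact for noiseless
circular convolutions and falls apart under measurement noise, and the
package's tests exhibit that failure rather than hide it. That
fragility — the kernel spectrum decays fast, so division amplifies
high-frequency noise — is the argument for the time-domain AUC, whose
computation involves no inversion at all.

`verify_convolution_theorem()` checks the discrete identity by direct
circular summation against the FFT product; `convolve_events()`
exposes both a `"circular"` mode (exact identities) and the default
`"linear"` mode (realistic epochs, truncation at the edges flagged in
the record's metadata).

## Detecting fluctuations

`detect_sf()` stands in for the semi-automatic scoring programs used
in conventional practice. It is a deterministic turning-point scan:
track the running minimum since the last confirmed peak; the candidate
peak is the running maximum since that trough; confirm the peak once
the signal has descended by at least the amplitude threshold below the
candidate. Amplitude is peak minus preceding trough, and events must
clear the threshold (default 0.025 µS, the conventional criterion) and
a minimum trough-to-peak span (`min_rise`, default 3 samples, i.e.
0.3 s at 10 Hz — genuine fluctuations rise over hundreds of
milliseconds, single-sample spikes do not). The hysteresis equals the
threshold, so small oscillations on a rising edge neither split a
fluctuation nor anchor its amplitude to a noise dimple. Deliberately
absent: rise-time/decay-shape exclusion rules — the point of the AUC
measure is that such heuristics are dispensable, so the conventional
arm should not smuggle them in. Plateaus resolve to their first
sample; a terminal rise with no confirmed descent is not counted;
boundary samples are never peaks (a monotone ramp yields zero events).

Two known biases of trough-to-peak scoring matter for interpretation:
overlapping fluctuations merge (undercounting $n$), and a fluctuation
riding on the decay of its predecessor has an elevated trough
(underestimating $a$). Both push $n\bar a$ down relative to the true
summed burst amplitudes at realistic burst rates, which inflates the
AUC-on-$n\bar a$ slope above $c$ — the package's simulations make this
visible because they have ground truth; field data do not.

## FIR deconvolution

To test time-invariance without assuming a kernel shape,
`estimate_rf()` fits the "uninformed" finite impulse response model:
one free coefficient per sampled lag of a window around each event
(120 coefficients for the default peak-anchored $(-4, 8)$ s window at
10 Hz), all epochs fitted jointly with one shared kernel, unit assumed
event amplitudes, and one intercept per epoch to absorb the tonic
level (the minimal way to handle level without filtering). The solver
is plain QR least squares — no regularisation — and rank deficiency
(e.g. coincident events) is a hard error naming the collinear columns.
Variance explained is computed against per-epoch means; with the
per-epoch alternative ambiguous in conventional practice,
`variance_explained()` exposes the centring explicitly so either
convention can be computed.

`estimate_amplitudes()` is the second stage: fix the kernel, give
each event its own shifted-kernel regressor plus an intercept, and
read off per-event amplitudes in µS. In `run_validation()` the
estimated kernel is first normalised to unit peak so that these
amplitudes, and the integral $c$, are commensurate with trough-to-peak
conventional scoring; without a normalisation the fixed-amplitude
first stage absorbs the mean amplitude into the kernel scale.

Windows extending past an epoch edge contribute truncated (zero-
padded) columns and are flagged in the fit metadata; events never
bleed across epoch boundaries.

## The simulator

`simulate_study()` generates the structure the validation statistics
need: 40 subjects × four 60 s epochs at 10 Hz (two baseline, two
anticipation), with known ground truth per epoch. Defaults, fixed
once as the package's reference conditions:

* **Burst rates** 0.09 Hz (baseline) and 0.19 Hz (anticipation) over
  the 52 s placement interval — about 1150 fluctuations per study,
  the order observed in public-speaking anticipation experiments of
  this size. Onsets are homogeneous Poisson; by default a trailing
  kernel-length margin keeps every response inside the epoch so the
  AUC identity is exact (set `allow_edge_events = TRUE` to relax).
* **Amplitudes** log-normal (positive, right-skewed, as SF amplitudes
  are), means 0.25/0.35 µS — ten times the detection threshold, so
  detection is near-ceiling in clean conditions and degradable by
  raising `noise_sd`. The condition acts on both rate and amplitude,
  since both reflect sympathetic arousal.
* **Kernel**: bi-exponential
  $g(t) = A(e^{-t/\tau_d} - e^{-t/\tau_r})$ with $\tau_r = 0.75$ s,
  $\tau_d = 3$ s, unit peak about 1.4 s after onset, integral
  $c \approx 4.30$ s over the standard window — a stereotyped
  single-burst response shape. Empirical kernels are only available
  as FIR estimates, so the canonical simulation kernel is a package
  constant, exchangeable via `read_rf()`/`write_rf()`.
* **Level, drift, noise**: 2 µS tonic level with 0.5 µS between-
  subject SD, 0.002 µS/s linear drift (the simplest stand-in for
  unfiltered level change; zero it for identity tests), white
  Gaussian noise of 0.005 µS per sample.

All draws descend from one master seed through a documented split (a
seeded `sample.int` yields per-epoch seeds; subject intercepts come
from the master stream), the caller's RNG state is restored
afterwards, and a config serialised to YAML/JSON at 17 significant
digits reloads and re-runs bit-identically.

What the simulator does *not* emulate: slow thermoregulatory trends
beyond a line, response-shape variability across subjects (every event
shares one kernel — the LTI assumption is built in, so simulations
validate the machinery, not the physiology), hardware filtering, and
motion artefacts. Passing tests therefore show that the estimators
recover what the model defines, not that real skin behaves linearly —
that question is what the validation statistics are for on real data.

## Validation statistics

`run_validation()` composes the battery: per-epoch AUC; detection and
$n\bar a$; FIR kernel and its integral $c$; per-peak amplitude refit
(overall variance explained); regression of AUC on $n\bar a$ (slope
vs. $c$, intercept vs. 0); a 2 (baseline/anticipation) × 2 (AUC vs.
$c\,n\bar a$) fully within-subject ANOVA on per-subject condition
means (BL and R epochs averaged per subject, the conventional
collapse, giving $(1, n_{subjects}-1)$ df per effect); simple-effect
treatment F within each method; point-biserial classification of
epochs; and an F test on the explained-variance difference,
$F = (r_b^2 - r_w^2) / ((1 - r_b^2)/df)$ with $df = N_{epochs} - 1$
(the residual convention is a documented choice; the better model's
residual is used).

`rm_anova_2x2()` computes each effect as the squared one-sample $t$
of the corresponding per-subject difference score — algebraically the
classical partition with error terms subject×treatment,
subject×method and subject×treatment×method, but numerically exact
when a contrast vanishes (contrasts are formed as differences of
paired differences, so identical methods give F = 0, not 0/0). The
test suite cross-checks it against `stats::aov` error strata and
against a longhand sums-of-squares oracle.

## Numerical choices

* Integration: trapezoidal rule throughout (second-order, standard);
  the kernel's window-truncated integral is the $c$ used everywhere,
  so truncation cancels in identity checks up to endpoint weights
  (≈0.2% for the default kernel).
* Events snap to the nearest sample; sub-sample latency is not
  modelled at 10 Hz.
* DFT convention: forward unscaled, inverse $1/N$; one-sided power
  folds conjugate bins so total power equals the time-domain sum of
  squared deviations.
* OLS by QR decomposition with explicit rank checking; normal
  equations appear only in test oracles.
* Ties/degenerates: plateau peaks resolve to the first sample; empty
  event trains summarise to $(0, 0, 0)$; a flat epoch yields zero AUC,
  zero detections and `NA` variance explained; `r_{better} = 1` makes
  the ΔR² F degenerate-infinite and is flagged.

## Problem sizes

The shipped tests run studies of 2–10 subjects and single 60 s epochs
(seconds in total); the reference acceptance computation uses the full
default study (40 × 4 epochs, ≈ 10 s including the 96 000 × 280 FIR
solve). All fixtures are generated in code.

## Limitations

The detector is a deterministic surrogate for interactive scoring
programs, not a re-implementation of any of them; its merge behaviour
under heavy overlap is simple hysteresis. The FIR model assumes one
kernel for all subjects, underestimating explainable variance when
shapes vary. The AUC cannot separate burst number from burst
amplitude — it estimates their product — and inherits a positive
noise bias from min-subtraction. Wiener-style noise-aware
deconvolution is intentionally out of scope.
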