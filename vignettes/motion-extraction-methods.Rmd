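---
title: "Self-gated cardiac motion extraction: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-gated cardiac motion extraction: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgmotion)
```

## The problem

Free-running cardiac MRI samples k-space continuously, without ECG triggering
or breath-holds, and resolves cardiac and respiratory motion retrospectively.
In a segmented 3D radial spiral-phyllotaxis acquisition, every 22-readout
segment starts with a readout along the superior-inferior (SI) body axis. The
1D Fourier transform of each SI readout is a body-profile snapshot; stacking
the magnitudes of these profiles over time, for every coil element, gives a
2D *self-gating matrix* whose columns are (SI position, coil) time series.
Respiratory and cardiac motion are latent sources mixed into all of these
columns, and the task is to un-mix them well enough to detect cardiac
triggers that rival the ECG.

`sgmotion` implements the full chain — simulation with known ground truth,
self-gating matrix assembly, trajectory-modulation correction, PCA/SOBI/ICA
source separation, spectral component selection, trigger detection,
ECG-referenced evaluation, binning, a desk-scale motion-resolved
reconstruction, and an edge-sharpness metric — so that each stage, and the
headline comparison between separation methods, can be tested quantitatively.

## The synthetic-data model

Because no raw patient data ships with this package, the `simulate_*`
generators define the study conditions. They are first-class, tested code.

**Respiration.** The waveform is $r(t) = \cos^4(\pi f_r t)$ with breathing
frequency $f_r = 0.25$ Hz by default (15 breaths/min). This shape has two
properties real breathing shares: its spectral content is confined to $f_r$
and $2 f_r$ (band-limited below 0.7 Hz), and it dwells at end-expiration
(the flat troughs) while inspiration peaks are brief.

**Cardiac activity and RSA.** Triggers come from an integrate-and-fire
oscillator with instantaneous rate
$HR(t) = HR_{\text{mean}} + g\,\dot r(t) + \eta_n$, where $\dot r$ is the
respiratory flow normalized to unit peak, $g$ is the respiratory sinus
arrhythmia (RSA) gain in bpm, and $\eta_n$ is white per-beat variability
(default SD 2 bpm). Coupling to the *flow* rather than the amplitude is
deliberate: for any time-symmetric waveform, the rising and falling halves
traverse identical amplitudes, so amplitude coupling cannot raise the
inspiratory heart rate above the expiratory one — flow coupling is both the
physiological mechanism (vagal tone follows inspiratory flow) and the only
one-parameter model that reproduces the inspiration/expiration split the
RSA analysis measures. Defaults: 60 bpm, 5-minute records, RSA gain 6 bpm in
the coupled scenarios.

**The SI stack.** Each (position, coil) projection time series is
$B + w_r r(t) + w_c s(t) + m(j(t)) + \epsilon(t)$: a baseline near 10, a
broad respiratory weight bump (amplitude 6 — near the diaphragm the
projection swings between lung and liver intensity, so respiratory excursion
comparable to the baseline is the realistic regime), a narrower overlapping
cardiac bump (amplitude 2), an additive 22-level modulation keyed to the
periodic segment-position index (emulating the angle-dependent signal of the
pseudo-periodic trajectory; its fundamental at $f_s/22 \approx 0.73$ Hz
lands inside the cardiac band, which is exactly why it must be corrected),
and white noise (default SD 0.5). In this regime the first 10 principal
components carry more than 90% of the matrix variance, matching what is
observed on real SI data. The cardiac waveform is
$s(t) = \sin(2\pi\phi(t)) + 0.35\,\sin(4\pi\phi(t))$ of the cardiac phase
$\phi$: its rising zero crossing coincides *exactly* with each trigger, and
the weak second harmonic makes the systolic upstroke steeper than the
diastolic downslope, as in real cardiac self-gating signals.

What the generator does **not** emulate: bulk motion, arrhythmia, coil
drift, through-plane flow enhancement, k-space trajectory errors, or any
sequence physics. Passing tests therefore demonstrate that the algorithms
behave correctly under idealized mixing assumptions plus noise, RSA
coupling and trajectory modulation — not that they are robust to every
failure mode of clinical data.

**Defective ECG.** `simulate_ecg_train()` injects independent trigger
deletions, mid-interval insertions and Gaussian jitter, and returns the
defect bookkeeping so the cleaning stage can be scored against truth.

## Motion extraction

`pca_reduce()` centres (and by default z-scores; set `standardize = FALSE`
for covariance PCA — the variance-explained figures quoted here are from the
covariance spectrum, the conventional reporting scale) the self-gating
matrix and keeps the top 10 components, whitened for the downstream methods.
`correct_angular_dependence()` first removes, per column and per
segment-position group, the group's temporal mean — the minimal operator
that exactly cancels a purely angle-dependent additive term; it is
idempotent and leaves physiological correlations untouched.

Three separation methods share the `source_set` container:

* **PCA** (reference): uncorrelated components ordered by variance.
* **SOBI**: jointly diagonalizes symmetrized time-lagged covariance matrices
  (default lags 1–20 samples, spanning at least one cardiac period at the
  16 Hz self-gating rate) with Jacobi sweeps of Givens rotations. The
  off-diagonal criterion is non-increasing by construction; non-convergence
  returns the best iterate with a flag. SOBI assumes temporally correlated
  sources with *distinct spectra* — precisely the structure of respiration
  (0.1–0.7 Hz) and heartbeat (0.5–2 Hz), even when RSA couples them.
* **FastICA**: symmetric fixed-point iteration maximizing non-Gaussianity
  with the log-cosh contrast. The seed is a *required* argument because the
  iteration starts from a random rotation; identical seeds reproduce
  identical components, and two Gaussian sources are correctly flagged as
  non-identifiable instead of erroring.

All methods fix each source's sign so its skewness is non-negative,
removing the inherent sign ambiguity from downstream code and tests.

## Component selection and triggers

`select_component()` normalizes each component to unit variance (selection
is scale-invariant), estimates its Welch power spectral density, fits a
Gaussian to the tallest in-band local maximum, and picks the component with
the largest fitted amplitude — "most prominent" is defined as fitted
Gaussian amplitude, ties break to the lower index. The respiratory component
is always selected first and removed from the cardiac candidate pool. If no
component shows an in-band peak, the pipeline falls back to the in-band
power argmax and logs the fallback.

The respiratory signal is zero-phase low-pass filtered at 0.7 Hz, linearly
detrended, and oriented so inspiration is high (sign flipped when skewness
is negative — the end-expiratory plateau must sit below the median).

`detect_triggers()` band-passes to 0.5–2 Hz, finds negative-to-positive zero
crossings with sub-sample linear interpolation, and suppresses crossings
closer than 0.4× the running median interval. Polarity (rising vs falling)
is chosen as the set with the steeper mean slope at its crossings; the
interval coefficient of variation is only the tie-break. The slope rule
matters: under beat-to-beat heart-rate variability, the mid-cycle crossing's
intervals are two-beat averages whose coefficient of variation is
systematically lower, so a CV-first rule locks onto the wrong phase of the
cycle and inflates the trigger-timing error several-fold; the steepest
crossing is the systolic upstroke and localizes the trigger most precisely.
Both candidate sets are evaluated identically, so a sign-flipped input
yields the same trigger set.

All zero-phase filtering pads the record by Burg linear-prediction (AR)
extrapolation before forward-backward filtering. Reflection padding flips
the phase of in-band oscillations at the junction; with a 0.5 Hz filter
corner the resulting transient bleeds seconds into the record and moves
end-of-record crossings by tens of milliseconds, while AR padding continues
the oscillation coherently and keeps transients inside the discarded pads.

## Evaluation against the ECG

`clean_ecg()` flags intervals above 1.5× (missing trigger) or below 0.5×
(extrasystolic) the median of the 40 nearest intervals, 20 per side and
truncated at the record edges; flagged intervals are excluded from pairing.
`align_triggers()` absorbs the physiological SG–ECG delay by scanning
offsets in 10 ms steps over ±1 median interval (nearest-trigger matching
gated at half the median interval). `compute_isd()` then forms, over the
$N$ paired consecutive intervals, the absolute interval differences
$d_n = |(S_{n+1}-S_n) - (E_{n+1}-E_n)|$ and reports

$$\mathrm{ISD} = \sqrt{\tfrac{1}{N-1}\sum_{n=1}^{N} (d_n - \mu)^2},$$

with $\mu$ the mean of the $d_n$ (the absolute differences; the sample
standard deviation of the paired list). ISD is zero for perfect interval
agreement and invariant to shifting both trains — it measures precision,
not delay.

Dispersion between methods is compared with a paired Bonett–Seier z-test on
log mean absolute deviations, with the delta-method variance including the
covariance term induced by pairing; it is validated in the test suite
against a permutation oracle. Bland–Altman limits and a paired linear fit
complete the agreement analysis. The pooled pairing across methods goes
through the shared ECG intervals, the same pooling used for the
Bland–Altman analysis of all individual intervals of a cohort.

## Binning and the toy reconstruction

Respiratory binning is amplitude-based: four equally populated bins from
end-expiration up, by rank (equal population to ±1 readout is guaranteed;
ties at thresholds resolve to the lower bin where distinct thresholds
exist). Cardiac binning is trigger-based only: the mean interval divided by
the 50 ms target width, rounded half away from zero (rounding keeps the
realized width closest to 50 ms), gives the bin count — 20 bins at 60 bpm,
and 15–21 across 57–80 bpm; each interval is then split into that many equal
phase fractions of *its own* length, with no amplitude normalization.
Readouts outside the trigger span are rejected rather than wrapped, since
no cycle contains them.

The reconstruction solves
$\hat x = \arg\min_x \|FCx - y\|_2^2 + \lambda_r\|\nabla_r x\|_1 +
\lambda_c\|\nabla_c x\|_1$ at desk scale: images up to 64², at most 4×8
bins and 4 coils, with $F$ an explicit non-uniform DFT matrix per bin and
simulator-provided coil sensitivities. Cardiac differences are cyclic (the
heartbeat is periodic by construction), respiratory differences are not.
ADMM with scaled duals, penalty 1, 10 iterations and a conjugate-gradient
x-update; both $\lambda$ default to 0.001 relative to unit-peak-normalized
data. With both weights zero the solver reduces to conjugate-gradient least
squares and, on a fully sampled Cartesian grid, to the exact inverse
transform. The beating-disk phantom closes the loop: binning with
ground-truth triggers yields strictly lower reconstruction error than
binning with jitter-corrupted triggers, which is the mechanism linking
trigger precision to image quality.

## Edge sharpness

An interpolating cubic curve is drawn through interface points. Tangents
use circular-arc estimation — bisector directions with arc-length-corrected
magnitudes from the local turning angle — which is exact for points on a
circle or a line; plain chord-based Catmull–Rom tangents sag by about 1% of
radius on a coarsely sampled circle, which is material when the curve
serves as the geometric reference for sub-pixel profiles. Evenly arc-spaced
perpendicular lines sample the image bilinearly, and each profile is fitted
with

$$f(x) = a_2 + \frac{a_1 - a_2}{1 + 10^{(a_0 - x)\,s}},$$

where $a_2$/$a_1$ are the minimum/maximum intensity, $a_0$ the half-way
coordinate and $s$ the steepness. The exponent is read multiplicatively,
$(a_0 - x)\cdot s$, so larger $|s|$ means a steeper edge; the reciprocal
reading $(a_0-x)/s$ is a pure reparameterization under which refitting
leaves the rise distance unchanged. The 10%–90% rise distance is

$$\mathrm{RD} = \frac{\mathrm{FOV}}{\mathrm{BR}}\,
  \left|f^{-1}(a_2 + 0.9\,\Delta) - f^{-1}(a_2 + 0.1\,\Delta)\right|
  = \frac{\mathrm{FOV}}{\mathrm{BR}}\cdot\frac{2\log_{10} 9}{|s|},$$

and both the numerical inverse and the closed form are computed and
required to agree. At FOV 220 mm, base resolution 220 and $s = 1$ this is
1.9085 mm. Near-zero steepness is censored at the profile window width
rather than reported as infinite. Per image the median rise distance over
converged lines is the summary (robust to dropped lines). The sigmoid is
fitted by Levenberg–Marquardt on the residuals with an analytic,
overflow-safe Jacobian and a small ladder of perturbed starts; the
formula-interface fitting machinery is avoided because its relative-step
numeric gradient rejects exactly-zero starts and steep, mostly saturated
profiles as "singular".

## Numerical and scale choices

Simulated records are 5 minutes at one SI sample per 22 readouts of
TR = 2.84 ms ($f_s \approx 16$ Hz) in the acceptance runs; most unit tests
use 90–120 s records, and the reconstruction experiments use 16² images
with 160 spokes and 4 cardiac bins — sizes chosen so the whole suite runs
comfortably on a laptop while every property under test is already
expressed at that scale. Determinism is end-to-end: every stochastic
stage takes an explicit seed (FastICA requires one), and identical
configurations reproduce bit-identical reports.

## Known limitations

* The simulator's linear mixing cannot represent amplitude co-modulation of
  the cardiac signal by respiration (bulk heart displacement); SOBI's
  advantage under such model violations is untested here.
* Arrhythmia is absent by construction, and the binning deliberately
  ignores interval-length histograms.
* FastICA's convergence flag is honest: on 10-component real-world-like
  mixtures it frequently stops at the iteration cap with a usable but
  unconverged rotation; results from unconverged runs are flagged, not
  suppressed.
* The reconstruction is a mechanism demonstration, not a clinical-scale
  solver: no NUFFT gridding, no sensitivity estimation, no 3D trajectories.
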