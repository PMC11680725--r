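# sgmotion

Self-gated cardiac and respiratory motion extraction for free-running
cardiac MRI, with a fully synthetic, ground-truth-known test bed.

Free-running acquisitions sample k-space continuously, without ECG leads or
breath-holds. A 3D radial trajectory that repeats a superior–inferior (SI)
readout at the start of every 22-line segment provides, after a 1D Fourier
transform per coil, a time series of body profiles — the *self-gating
matrix* — in which respiration (0.1–0.7 Hz) and heartbeat (0.5–2.0 Hz) are
latent, partially coupled sources. `sgmotion` extracts them and turns the
cardiac one into triggers:

* **Source separation.** PCA reduction to 10 components, then either PCA
  itself (reference), **SOBI** — joint diagonalization of time-lagged
  covariance matrices by Givens-rotation sweeps, exploiting the sources'
  distinct spectra — or **FastICA** (symmetric fixed point, log-cosh
  contrast, seeded).
* **Physiology.** Automated band-limited component selection by fitted
  spectral-peak prominence; respiratory conditioning; cardiac trigger
  detection by interpolated zero crossings with refractory suppression and
  slope-based polarity selection.
* **Evaluation.** ECG cleaning by moving-median interval rules (1.5×/0.5×),
  10 ms-grid alignment, and the interval-SD precision metric
  `ISD = sd(|ΔS_n − ΔE_n|)` over paired consecutive intervals, plus paired
  Bonett–Seier dispersion tests, Bland–Altman limits and regression.
* **Binning & reconstruction.** Four equally populated respiratory
  amplitude bins; cardiac phase bins of ~50 ms (20 bins at 60 bpm); a
  desk-scale k-t sparse SENSE reconstruction (explicit non-uniform DFT,
  ADMM, ℓ1 on cyclic-cardiac/non-cyclic-respiratory finite differences).
* **Sharpness.** Interpolating curve through interface points,
  perpendicular intensity profiles, sigmoid edge fits
  `f(x) = a2 + (a1−a2)/(1+10^((a0−x)s))`, and the 10–90% rise distance
  `RD = (FOV/BR)·2·log10(9)/|s|` in mm.
* **Simulation.** Every input — RSA-coupled physiology, SI stacks with
  trajectory modulation, defective ECG trains, beating-disk cine phantoms,
  sigmoid edge phantoms — is generated with known ground truth and explicit
  seeds.

## Worked example

```r
library(sgmotion)

report <- run_extraction(sg_config(rsa_gain_bpm = 6,
                                   methods = c("PCA", "SOBI"), seed = 11))
report$isd
#> # A tibble: 2 × 5
#>   method     n mu_ms isd_ms offset_ms
#>   <chr>  <int> <dbl>  <dbl>     <dbl>
#> 1 PCA      278  9.23   7.67         0
#> 2 SOBI     278  7.66   6.46         0
```

One simulated 5-minute subject with respiratory sinus arrhythmia (gain
6 bpm): both methods' triggers were aligned to the cleaned simulated ECG,
and over the 278 paired cardiac intervals the mean absolute interval
difference and its SD (the ISD) show the SOBI triggers tracking the ECG
intervals more precisely (ISD 6.5 ms) than the PCA reference
(7.7 ms) — the expected behaviour when RSA mixes the
respiratory and cardiac components and PCA alone cannot fully separate
them. `report$rsa` shows the inspiratory heart rate exceeding the
expiratory one, `report$binning` holds the per-readout respiratory/cardiac
bin assignment (20 cardiac bins at 60 bpm), and `compare_methods()` pools
several such subjects into Bland–Altman, regression and one-sided
Bonett–Seier comparisons.

A thin command-line front end is installed at `inst/cli/sgmotion.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sgmotion.R", package="sgmotion"))')" \
    demo --seed 1 --rsa 6 --out run/
```

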