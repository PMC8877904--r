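---
title: "Acoustic monitoring of broach insertion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic monitoring of broach insertion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bims)
```

## The problem

During total hip arthroplasty the surgeon hammers a broach — a tapered
rasp — into the femoral canal to shape the cavity for the stem. Stopping
too early leaves the implant loose; hammering too far risks a
periprosthetic fracture. The end point is currently judged by feel, sound
and experience. `bims` implements an objective alternative: a contact
microphone on the broach handle records every hammer blow, and the
evolution of the resonant content of those blows tracks insertion depth
and fixation quality.

The physical intuition is a clamped-free (cantilever) beam: the part of
the implant assembly protruding from the bone rings at its natural
frequencies, and as the broach seats deeper the free length shortens, so
the resonances shift up and the blow-to-blow energy response becomes more
repeatable as the fit tightens.

## Pipeline

1. **Segmentation** (`detect_blows`). Blows are separated by near-silent
   gaps, so onsets are detected by thresholding a short (1 ms) moving
   average of the absolute amplitude at `threshold_factor` (default 8)
   times the recording-wide median of that envelope, with a 0.2 s
   refractory period. The envelope, rather than the raw samples, is
   thresholded because a raw single-sample threshold at a handful of
   noise standard deviations still crosses occasionally over minutes of
   audio, while an averaged envelope has far lighter tails; the detected
   crossing is backed off by the envelope length so the transient's
   leading edge stays inside the window. The threshold is floored at a
   tiny fraction (1e-6) of the peak envelope so that digitally silent
   recordings do not degenerate to a zero threshold. Each onset anchors a
   0.2 s analysis window (8820 samples at 44.1 kHz); a final truncated
   window is zero-padded and flagged.

2. **Spectra** (`compute_esd`). Each window is transformed with the
   unnormalized forward DFT and the energy spectral density is its
   squared magnitude, reported one-sided with 5 Hz resolution at the
   defaults. No taper is applied by default (a Hann taper is available):
   the transients decay well inside the window, so leakage is dominated
   by the damping itself. Under this convention the two-sided ESD sums to
   N times the window energy (Parseval) and an on-bin sine of amplitude A
   gives a single-bin peak of (A·N/2)².

3. **Peak tracking** (`find_esd_peaks`, `assign_bands`). Local maxima
   with a minimum height (default 5 times the spectrum's median bin —
   a relative floor, robust to the overall recording level) and a minimum
   separation (default 300 Hz, one band width) are assigned to nominal
   resonant bands: 1400, 2500, 3150 and 4700 Hz, each ±150 Hz, for the
   bench configuration (`nominal_bands(preset = "cadaver")` switches to
   the in-situ peak set). The peak energy is the single-bin ESD height;
   band-integrated energy was considered and rejected as the default
   because the single-bin height is what the tracking statistics
   downstream are defined on. A band with no qualifying peak is recorded
   as missing, never interpolated.

4. **Statistics** (`fit_linear`, `fit_exponential`,
   `compare_fits_ftest`, `calibrate_depth`). Per band: an OLS regression
   of peak frequency on insertion depth with the two-sided zero-slope
   t-test (drift detection), and a nonlinear least-squares fit of
   `y = y0·exp(k·x)` to the peak energies (Levenberg–Marquardt, started
   from the log-linear regression, with the log-linear parameters
   reported if the optimizer fails). The exponential fit's R², computed
   as 1 − SS_res/SS_tot on the original scale and clipped to [0, 1] with
   a flag, is the fixation statistic: higher R² means lower scatter and
   a better-converged seat. Scatter between two fits is compared with a
   two-sided variance-ratio F-test on the fit residuals (n − 2 degrees
   of freedom each). Insertion depth can also be estimated back from a
   band's peak energy through the logarithmic calibration
   `ID = a·ln(PE/b)`, fitted by OLS on `ID ~ ln(PE)`.

## Beam model

`eigen_frequency` evaluates the clamped-free Euler–Bernoulli closed form

  omega_i = ((i − 1/2)·pi)² / L² · sqrt(E·I/mu)

for the implant idealized as a 30 × 8 mm steel bar (E = 210 GPa,
rho = 7850 kg/m³), with free length 350 mm at the start of insertion and
325 mm seated. Bending direction x uses I = w·t³/12 (8 mm dimension
cubed), y uses t·w³/12. Two conventions deserve emphasis, both validated
numerically against the previously published estimates
(`compare_eigen_reference`):

* the published table is reproduced only with E = 210 **GPa** — the
  published text's "210 MPa" is three orders of magnitude below any
  steel and is treated as a typo;
* the published values are **angular** frequencies (rad/s) despite being
  tabulated under a Hz header; the default output unit is rad/s to match,
  with `unit = "hz"` available.

Fifteen of the sixteen published entries agree with the closed form
within 0.5%; the mode-1, end-length, stiff-direction entry (105) is an
order of magnitude below the formula value (~1046) and is flagged as
inconsistent rather than reproduced. `exact_cantilever_frequency` solves
cos(βL)·cosh(βL) = −1 by bracketed root-finding as an oracle for the
half-integer approximation (0.2% low at mode 1, converged by mode 3).
These estimates overshoot the measured bands by roughly an order of
magnitude — the real boundary condition is neither rigidly clamped nor
free — so they are used only as a guide to where the four tracked bands
lie, never as predictions.

## Synthetic experiments

The generator (`simulate_experiment`) replaces the physical bench: it
produces a seeded recording plus depth table with the statistical
structure the analysis assumes, and an exact ground-truth record.

* **Waveform.** Each blow is a sum of exponentially damped sinusoids,
  one per band (decay time 8 ms by default, giving ~40 Hz line widths),
  placed at 1 s spacings on a Gaussian noise floor (sigma 1e-3 full
  scale). This is the minimal model consistent with narrow resonant
  bands; it makes no claim of contact-mechanics realism.
* **Energy calibration.** The configured quantity is the *single-bin ESD
  peak energy* the pipeline should measure. Band amplitudes are solved
  from the closed-form finite geometric sum of the damped-sinusoid DFT,
  with a fixed-point refinement across bands so cross-band leakage is
  accounted for exactly. On a noiseless, scatter-free run the measured
  peak energies match the configured targets within 2% (residual
  off-grid windowing asymmetry) and peak frequencies within one 5 Hz
  bin; blows that would exceed full scale are rescaled and their
  realized targets adjusted, keeping the ground truth exact.
* **Trends.** Band frequency drifts linearly with depth advance; band
  energy follows `y0·exp(k·Δd)` with lognormal per-blow scatter; depth
  advances by `Δ1·exp(−(d − d0)/δ)` per blow from d0 = 65 mm.

The three presets carry the published experiment designs as defaults:
70 blows at 0.24 J (fixated, large broach), 20 blows (loose, undersized
broach), 100 blows (fractured model), with the published per-band
exponential constants and drift slopes as generator truth. Values the
study conditions do not pin down were chosen once, a priori:

* **Depth dynamics** Δ1 = 2.5 mm, δ = 6 mm: ~20 mm total advance in 70
  blows with the 0.1 mm-per-blow-over-5-blows stopping rule firing
  shortly before the end of the run (blow ~60), matching the described
  linear-then-plateau curve. The loose preset uses Δ1 = 8 mm so 20 blows
  reach the same depth.
* **Scatter** sigma_ln = 0.33 for the fixated condition, chosen by
  moment matching so the expected original-scale R² of the band-2
  exponential fit is ≈0.78, the published fixated value; the loose
  preset uses three times that (sigma_ln ≈ 1.0), which makes the
  fixated/loose contrast qualitative (its expected R² ≈ 0.2 is below
  the published 0.51) but preserves the ordering the statistic is meant
  to detect. The fractured preset sits between (0.66).
* **Blow spacing** 1.0 s: well-separated transients as observed on the
  bench.

What the generator does **not** emulate: amplitude coupling between
hammer energy and acoustic output (the per-blow joule figure is
bookkeeping only), inter-specimen variability of the bone model,
non-resonant broadband content of real impacts, and any fracture
physics — the fractured preset is purely a trend/scatter change, in line
with the observation that fracture was not acoustically predictable.
Passing tests on synthetic data therefore demonstrate that the pipeline
recovers what it assumes, not that real recordings satisfy those
assumptions.

## Numerical choices and edge cases

* Peak suppression keeps the higher of two peaks closer than
  `min_distance`; exact ties go to the lower frequency.
* A constant response in `fit_linear` returns slope 0, R² = 0, p = 1 by
  convention (no drift evidence) rather than NaN.
* Non-positive energies are dropped (with a message) before exponential
  or logarithmic fits; fewer than 3 usable pairs is an error.
* R² is clipped to [0, 1] with a flag instead of silently reporting
  negative values for pathological fits.
* Integer-PCM WAV input is rescaled by the type's full-scale value;
  multi-channel input keeps channel 1; any sample rate is accepted and
  propagated.
* All randomness in the generator flows from a single integer seed; a
  seed reproduces the recording bit-for-bit.

## Problem sizes used in the test suite

Deterministic checks run at the study's own scales (70-blow runs). The
repeated-simulation checks use 100 seeds for detection and drift power,
200 paired seeds for the fixated/loose discrimination, and 1000
replicates for the F-test size, with shorter recordings (5–12 blows at
0.4–0.6 s spacing) wherever the property under test does not depend on
run length.

## Known limitations

* The onset detector assumes quiet inter-blow gaps; overlapping blows or
  loud ambient transients are out of scope.
* The fixation statistic is relative: no absolute R² threshold separates
  fixated from loose, and none is asserted.
* The depth calibration is bench-model-specific; its constants transfer
  to other setups only in functional form.
* The beam model ignores the bone/silicone boundary compliance entirely.
```{r, eval = FALSE}
# A complete run, for reference:
sim <- simulate_experiment(simulation_preset("fixated_large", seed = 1))
report <- run_analysis(sim, config = analysis_config(blow_energy_j = 0.24))
print(report)
```
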