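# bims — acoustic monitoring of hammered broach insertion

`bims` analyses contact-microphone recordings of the hammer blows that
seat a femoral broach during total hip arthroplasty (THA). Each blow
excites the implant assembly, which rings like a clamped-free beam; as
the broach seats, the free length shortens, the resonant peaks drift
upward, and the blow-to-blow peak energies converge as the fit tightens.
The package turns a raw WAV recording into per-blow resonant-peak
tracks and fixation-quality statistics, for biomechanics researchers and
surgical-instrumentation developers studying objective end-point
detection.

## What it computes

* **Blow segmentation** — envelope-threshold onset detection with a
  refractory period; fixed 0.2 s analysis windows.
* **Energy spectral density** — per blow, ESD = |FFT(h)|² (one-sided,
  5 Hz bins at 44.1 kHz), peak search with minimum height/distance, and
  assignment to four nominal resonant bands (1400/2500/3150/4700 Hz,
  300 Hz wide).
* **Drift statistic** — per band, OLS of peak frequency on insertion
  depth with the zero-slope t-test: p < 0.05 indicates the upward
  resonance shift that accompanies seating.
* **Fixation statistic** — per band, nonlinear least squares of
  y = y0·exp(k·x) to the peak energies; the fit's R² (original scale)
  quantifies convergence, with higher R² read as better fixation.
  Variance-ratio F-tests compare scatter between fits, and a
  logarithmic calibration ID = a·ln(PE/b) maps peak energy back to
  insertion depth.
* **Beam model** — closed-form cantilever eigenfrequencies
  ω_i = ((i−½)π)²/L²·√(EI/μ) for the implant idealized as a 30 × 8 mm
  steel bar, reproducing the published estimate table and flagging its
  one internally inconsistent entry.
* **Energy bookkeeping** — E = mgh per blow, cumulative energy, J per mm
  of advance, and the insertion-curve plateau stopping rule
  (advance < 0.1 mm over 5 consecutive blows).
* **Synthetic experiments** — a seeded generator of ground-truth
  annotated recordings plus depth tables (fixated / loose / fractured
  presets), so every pipeline stage is testable without bench hardware.

## Worked example

```r
library(bims)

sim <- simulate_experiment(simulation_preset("fixated_large", seed = 1))
report <- run_analysis(sim, config = analysis_config(blow_energy_j = 0.24))
print(report)
#> <bims_report: 70 blows, x axis = depth_mm>
#>   band 1 (1400 Hz): n = 70; drift 0.05199 Hz/unit (p = 0.0636); energy k = -0.08241, R2 = 0.694
#>   band 2 (2500 Hz): n = 70; drift 1.249 Hz/unit (p = 1.69e-41); energy k = -0.1392, R2 = 0.844
#>   band 3 (3150 Hz): n = 70; drift 1.49 Hz/unit (p = 4.47e-45); energy k = -0.1022, R2 = 0.755
#>   band 4 (4700 Hz): n = 70; drift 3.832 Hz/unit (p = 4.14e-72); energy k = -0.05537, R2 = 0.426
#> <energy summary: 70 blows, 0.24 J/blow, cumulative 16.80 J, advance 18.09 mm, 0.93 J/mm>
```

The run simulates the well-fixated bench condition: 70 blows at 0.24 J.
Bands 3 and 4 show the hallmark upward frequency drift (slopes ~1.5 and
~3.8 Hz/mm, p ≪ 0.05 — the generator's truth is 1.519 and 3.812), band 1
does not (p = 0.06), and the exponential energy fits converge well. The
same analysis on the loose (undersized-broach) preset gives a much lower
band-2 R²:

```r
loose <- run_analysis(simulate_experiment(simulation_preset("loose_small", seed = 1)))
fixation_contrast(report$fits$band_2$exponential,
                  loose$fits$band_2$exponential,
                  labels = c("fixated", "loose"))
#> <fixation contrast: 'fixated' better converged (R2 0.8436 vs 0.1113)>
```

The cantilever eigenfrequency table for the default beam (angular
frequency, rad/s — the scale of the published estimates):

```r
eigen_table()
#>   mode    start_x    start_y      end_x     end_y
#> 1    1   240.5902   902.2131   279.0276  1046.354
#> 2    2  2165.3114  8119.9177  2511.2487  9417.183
#> 3    3  6014.7538 22555.3268  6975.6908 26158.841
#> 4    4 11788.9175 44208.4406 13672.3540 51271.328
```

A shell front end covers the same ground:

```sh
./exec/bims simulate --preset fixated_large --seed 7 --out-dir run7
./exec/bims analyze --audio run7/simulation.wav --depth run7/simulation_depth.csv --out-dir run7/analysis
./exec/bims eigentable
```

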