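Package: bims
Title: Acoustic Monitoring of Hammered Broach Insertion in Hip Arthroplasty
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing contact-microphone recordings of the hammer
    blows that seat a femoral broach during total hip arthroplasty. The
    pipeline segments a recording into individual blows, computes per-blow
    energy spectral densities, tracks resonant-peak frequency and energy
    across four nominal bands, and quantifies insertion progress and fixation
    quality through linear frequency-drift regressions, exponential
    peak-energy convergence fits (with R-squared as the fixation statistic),
    and variance-ratio F-tests. Also includes closed-form clamped-free beam
    eigenfrequency estimates for the implant, impact-energy bookkeeping
    (E = mgh per blow, cumulative energy, energy per millimetre advanced),
    and a seeded synthetic-experiment generator producing ground-truth
    annotated audio and depth tables for fixated, loose and fractured
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
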