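test_that("an on-bin unit sine has single-bin ESD (N/2)^2 at its frequency", {
  fs <- 44100
  n <- round(0.2 * fs)               # 8820 samples -> 5 Hz bins
  rec <- tone_recording(1400, fs = fs, amp = 1)  # 1400 Hz = bin 280, on-grid
  spec <- compute_esd(rec$samples, fs)
  expect_equal(spec$resolution, 5)
  peak_bin <- which.max(spec$esd)
  expect_equal(spec$frequency[peak_bin], 1400)
  expect_equal(spec$esd[peak_bin], (n / 2)^2, tolerance = 1e-9)
})

test_that("Parseval: two-sided ESD sums to N times the window energy", {
  set.seed(21)
  for (n in c(64, 441, 8820)) {
    x <- stats::rnorm(n)
    spec <- compute_esd(x, 44100)
    expect_equal(two_sided_esd_sum(spec), n * sum(x^2), tolerance = 1e-6)
  }
})

test_that("a unit impulse at t = 0 has a flat ESD of 1", {
  x <- c(1, rep(0, 255))
  spec <- compute_esd(x, 44100)
  expect_equal(spec$esd, rep(1, 129), tolerance = 1e-12)
})

test_that("an all-zero window gives a valid all-zero spectrum", {
  spec <- compute_esd(rep(0, 100), 44100)
  expect_true(all(spec$esd == 0))
})

test_that("peak frequencies are scale-invariant; energies scale quadratically", {
  set.seed(22)
  x <- tone_recording(1400, amp = 0.3)$samples +
    tone_recording(4700, amp = 0.2)$samples
  s1 <- compute_esd(x, 44100)
  s3 <- compute_esd(3 * x, 44100)
  p1 <- find_esd_peaks(s1, min_height = 1)
  p3 <- find_esd_peaks(s3, min_height = 1)
  expect_equal(p3$frequency, p1$frequency)
  expect_equal(p3$energy, 9 * p1$energy, tolerance = 1e-10)
})

test_that("well-separated tones are both found; close tones are suppressed", {
  x <- tone_recording(1400, amp = 0.5)$samples +
    tone_recording(4700, amp = 0.3)$samples
  peaks <- find_esd_peaks(compute_esd(x, 44100), min_height = 1,
                          min_distance = 300)
  expect_equal(peaks$frequency, c(1400, 4700))

  y <- tone_recording(2000, amp = 0.5)$samples +
    tone_recording(2100, amp = 0.3)$samples
  peaks2 <- find_esd_peaks(compute_esd(y, 44100), min_height = 1,
                           min_distance = 300)
  expect_equal(nrow(peaks2), 1)
  expect_equal(peaks2$frequency, 2000)
})

test_that("peak search is stable under appending zero-energy bins", {
  x <- tone_recording(3150, amp = 0.4)$samples
  spec <- compute_esd(x, 44100)
  padded <- spec
  padded$frequency <- c(spec$frequency,
                        max(spec$frequency) + spec$resolution * (1:50))
  padded$esd <- c(spec$esd, rep(0, 50))
  mh <- 5 * stats::median(spec$esd)
  expect_equal(find_esd_peaks(padded, min_height = mh),
               find_esd_peaks(spec, min_height = mh))
})

test_that("band assignment takes the in-band peak and flags empty bands", {
  bands <- nominal_bands()
  one <- assign_bands(data.frame(frequency = 1450, energy = 10), bands, 3)
  expect_equal(one$blow_index, rep(3L, 4))
  expect_false(one$missing[1])
  expect_equal(one$peak_frequency[1], 1450)
  expect_true(all(one$missing[2:4]))

  # 1600 Hz falls between band 1 (<= 1550) and band 2 (>= 2350)
  none <- assign_bands(data.frame(frequency = 1600, energy = 10), bands, 1)
  expect_true(all(none$missing))

  # highest-energy peak wins within a band
  two <- assign_bands(
    data.frame(frequency = c(2400, 2600), energy = c(5, 9)), bands, 1
  )
  expect_equal(two$peak_frequency[2], 2600)
})

test_that("overlapping configured bands are rejected", {
  expect_error(nominal_bands(centers = c(1400, 1600), half_width = 150),
               "overlap")
  expect_error(nominal_bands(centers = c(2000, 1400)), "increasing")
})

test_that("median/IQR aggregation matches direct quantiles", {
  spec <- compute_esd(tone_recording(2500, amp = 0.3)$samples, 44100)
  agg <- aggregate_esd(rep(list(spec), 5))
  expect_equal(agg$median, spec$esd)
  expect_equal(agg$q75 - agg$q25, rep(0, length(spec$esd)))

  make_flat <- function(v) {
    structure(list(frequency = c(0, 5, 10), esd = rep(v, 3),
                   resolution = 5, n = 4), class = "bims_esd")
  }
  agg3 <- aggregate_esd(lapply(c(1, 2, 9), make_flat))
  expect_equal(agg3$median, rep(2, 3))

  other <- compute_esd(rep(0, 100), 44100)
  expect_error(aggregate_esd(list(spec, other)), "mismatched")
})

test_that("last-blows aggregate puts median peaks within a bin of the truth", {
  nf <- noiseless_fixated()
  specs <- blow_spectra(nf$blows)
  n <- length(specs)
  agg <- aggregate_esd(specs[(n - 19):n])
  truth_last <- nf$sim$truth$observations
  truth_last <- truth_last[truth_last$blow_index > n - 20, ]
  for (b in 1:4) {
    tb <- truth_last[truth_last$band_id == b, ]
    win <- abs(agg$frequency - mean(tb$frequency_hz)) <= 150
    peak_f <- agg$frequency[win][which.max(agg$median[win])]
    expect_lt(abs(peak_f - stats::median(tb$frequency_hz)), 5 + 1e-9)
  }
})
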