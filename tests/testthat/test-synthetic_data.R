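test_that("the same seed reproduces a bit-identical experiment", {
  a <- simulate_experiment(simulation_preset("fixated_large", n_blows = 6,
                                             seed = 77))
  b <- simulate_experiment(simulation_preset("fixated_large", n_blows = 6,
                                             seed = 77))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$depth_table, b$depth_table)
  expect_identical(a$truth$observations, b$truth$observations)
  c <- simulate_experiment(simulation_preset("fixated_large", n_blows = 6,
                                             seed = 78))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("presets carry the published experiment designs", {
  fx <- simulation_preset("fixated_large")
  expect_equal(fx$n_blows, 70L)
  expect_equal(fx$blow_energy_j, 0.24)
  expect_equal(fx$bands[[2]]$energy_y0, 2041)
  expect_equal(fx$bands[[2]]$energy_k, -0.1519)
  expect_equal(fx$bands[[3]]$drift_slope, 1.519)
  expect_equal(fx$bands[[4]]$drift_slope, 3.812)

  ls <- simulation_preset("loose_small")
  expect_equal(ls$n_blows, 20L)
  expect_equal(ls$bands[[2]]$energy_y0, 491.6)
  expect_equal(ls$bands[[2]]$energy_k, -0.1399)
  # high-scatter condition: three times the fixated sigma
  expect_equal(ls$bands[[2]]$scatter_sigma_ln,
               3 * fx$bands[[2]]$scatter_sigma_ln)

  fr <- simulation_preset("fractured")
  expect_equal(fr$n_blows, 100L)
  expect_equal(fr$bands[[1]]$energy_k, 0.001743)
  expect_error(simulation_preset("no_such_preset"))
})

test_that("generator calibration: clean runs hit the configured targets", {
  nf <- noiseless_fixated()
  pk <- nf$peaks
  expect_equal(sum(pk$missing), 0)
  m <- merge(pk[!pk$missing, ], nf$sim$truth$observations,
             by = c("blow_index", "band_id"))
  # peak frequency within one 5 Hz bin; peak energy within the 2%
  # windowing-leakage tolerance
  expect_lte(max(abs(m$peak_frequency - m$frequency_hz)), 5)
  expect_lt(max(abs(m$peak_energy / m$target_energy - 1)), 0.02)
})

test_that("depths advance monotonically and plateau before the run ends", {
  for (name in c("fixated_large", "loose_small", "fractured")) {
    sim <- simulate_experiment(simulation_preset(name, seed = 3))
    cfg <- sim$truth$config
    expect_true(all(diff(sim$depth_table$depth_mm) > 0))
    if (name == "fixated_large") {
      sm <- insertion_curve(sim$depth_table$depth_mm,
                            initial_depth = cfg$initial_depth)
      expect_lt(sm$stopping_blow, cfg$n_blows)
    }
  }
})

test_that("zero drift, scatter and noise give constant recovered frequencies", {
  cfg <- simulation_config(
    bands = lapply(c(1400, 2500, 3150, 4700), function(f) {
      band_params(center_f0 = f, drift_slope = 0, energy_y0 = 500,
                  energy_k = 0, scatter_sigma_ln = 0)
    }),
    n_blows = 5, seed = 1, noise_floor = 0
  )
  sim <- simulate_experiment(cfg)
  pk <- peak_table(detect_blows(sim$recording))
  for (b in 1:4) {
    fb <- pk$peak_frequency[pk$band_id == b]
    expect_equal(length(unique(fb)), 1)
  }
})

test_that("band frequencies beyond Nyquist are rejected", {
  expect_error(
    simulation_config(bands = list(band_params(center_f0 = 23000)),
                      sample_rate = 44100),
    "Nyquist"
  )
  # drift pushing a band over Nyquist is caught at simulation time
  cfg <- simulation_config(
    bands = list(band_params(center_f0 = 22000, drift_slope = 1000)),
    n_blows = 10, seed = 1
  )
  expect_error(simulate_experiment(cfg), "Nyquist")
})

test_that("over-scale blows are rescaled into range and flagged", {
  cfg <- simulation_config(
    bands = list(band_params(center_f0 = 2500, energy_y0 = 5e7)),
    n_blows = 3, seed = 1, noise_floor = 0
  )
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$clipped))
  expect_lte(max(abs(sim$recording$samples)), 1)
  # realized targets are adjusted so the ground truth stays honest
  pk <- peak_table(detect_blows(sim$recording),
                   bands = nominal_bands(centers = 2500))
  m <- merge(pk[!pk$missing, ], sim$truth$observations,
             by = c("blow_index", "band_id"))
  expect_equal(nrow(m), 3)
  expect_lt(max(abs(m$peak_energy / m$target_energy - 1)), 0.02)
})

test_that("band assignment stays nearly complete under preset noise and scatter", {
  miss <- vapply(1:20, function(seed) {
    sim <- simulate_experiment(simulation_preset("fixated_large",
                                                 n_blows = 12, seed = seed))
    pk <- peak_table(detect_blows(sim$recording))
    mean(pk$missing)
  }, numeric(1))
  expect_lt(mean(miss), 0.05)
})

test_that("simulations write and read back through the artifact formats", {
  sim <- simulate_experiment(simulation_preset("loose_small", n_blows = 4,
                                               seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir, "run1")
  expect_true(all(file.exists(paths)))
  rec <- read_wav(paths[["wav"]])
  expect_equal(length(rec$samples), length(sim$recording$samples))
  expect_lt(max(abs(rec$samples - sim$recording$samples)), 2^-22)
  tab <- read_depth_table(paths[["depth"]])
  expect_equal(tab$depth_mm, sim$depth_table$depth_mm, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$config$seed, 12)
})

test_that("band parameter validation enforces the physical ranges", {
  expect_error(band_params(center_f0 = -100), "positive")
  expect_error(band_params(center_f0 = 1000, damping_tau = 0.3), "damping_tau")
  expect_error(band_params(center_f0 = 1000, damping_tau = 0.001), "damping_tau")
  expect_error(band_params(center_f0 = 1000, scatter_sigma_ln = -1), ">= 0")
})
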