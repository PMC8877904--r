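# Shared fixtures. Heavy simulations are cached per test session.

.bims_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .bims_test_cache)) {
    assign(key, force(expr), envir = .bims_test_cache)
  }
  get(key, envir = .bims_test_cache)
}

tone_recording <- function(freq, dur = 0.2, fs = 44100, amp = 0.5) {
  t <- seq_len(round(dur * fs)) - 1
  recording(amp * sin(2 * pi * freq * t / fs), fs)
}

# hand-written 16-bit PCM WAV (independent of write_wav)
write_pcm16_wav <- function(path, values, fs = 44100, channels = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(values)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(as.integer(channels), con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 2L * channels), con, size = 4L, endian = "little")
  writeBin(as.integer(2L * channels), con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  writeBin(as.integer(values), con, size = 2L, endian = "little")
  path
}

# two-sided Parseval sum reconstructed from a one-sided bims_esd
two_sided_esd_sum <- function(spec) {
  e <- spec$esd
  m <- length(e)
  if (spec$n %% 2L == 0L) {
    e[1L] + e[m] + 2 * sum(e[2:(m - 1L)])
  } else {
    e[1L] + 2 * sum(e[2:m])
  }
}

# noiseless, scatter-free fixated run analysed once and reused
noiseless_fixated <- function() {
  cached("noiseless_fixated", {
    sim <- simulate_experiment(simulation_preset(
      "fixated_large", seed = 101, noise_floor = 0, scatter_scale = 0
    ))
    blows <- detect_blows(sim$recording)
    list(sim = sim, blows = blows,
         peaks = peak_table(blows))
  })
}
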