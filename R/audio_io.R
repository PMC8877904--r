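# Audio and tabular I/O for the hammering pipeline.
#
# Recordings are plain RIFF/WAVE files; amplitudes are kept on the WAV
# scale, relative to the maximum measurable intensity (full scale = 1).

#' Construct a recording
#'
#' A recording is the basic container of the pipeline: a mono amplitude
#' series on a relative scale in \[-1, 1\] plus its sample rate.
#'
#' @param samples Numeric vector of amplitudes, all finite, |x| <= 1.
#' @param sample_rate Sampling rate in Hz (positive number; contact-microphone
#'   recordings are nominally 44100 Hz).
#' @return An object of class `bims_recording` with fields `samples` and
#'   `sample_rate`; `duration()` gives length in seconds.
#' @examples
#' rec <- recording(sin(2 * pi * 1400 * seq(0, 0.2, by = 1 / 44100)), 44100)
#' duration(rec)
#' @export
recording <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("empty recording: no samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  if (max(abs(samples)) > 1 + 1e-9) {
    stop("recording samples exceed full scale (|x| > 1)", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar", call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate = sample_rate),
    class = "bims_recording"
  )
}

#' @rdname recording
#' @param rec A `bims_recording`.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "bims_recording"))
  length(rec$samples) / rec$sample_rate
}

#' @export
print.bims_recording <- function(x, ...) {
  cat(sprintf(
    "<bims_recording: %d samples @ %g Hz (%.3f s), peak |x| = %.4g>\n",
    length(x$samples), x$sample_rate, duration(x), max(abs(x$samples))
  ))
  invisible(x)
}

read_chunk_id <- function(con) rawToChar(readBin(con, "raw", 4L))

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file into a [recording()]. IEEE float (32-bit) and
#' integer PCM (16-bit) sample formats are supported; integer samples are
#' rescaled to \[-1, 1\] by the type's full-scale value (32768 for 16-bit).
#' Multi-channel files are reduced to the first channel, since the
#' instrument is a single contact microphone. Any sample rate is accepted;
#' downstream frequency computations always use the rate stored in the file.
#'
#' @param path Path to a WAV file.
#' @return A `bims_recording`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("WAV file not found: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(read_chunk_id(con), "RIFF")) {
    stop(sprintf("not a RIFF/WAVE file: %s", path), call. = FALSE)
  }
  readBin(con, "integer", 1L, size = 4L, endian = "little") # RIFF size, unused
  if (!identical(read_chunk_id(con), "WAVE")) {
    stop(sprintf("not a RIFF/WAVE file: %s", path), call. = FALSE)
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    id <- rawToChar(id)
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(size) != 1L || is.na(size) || size < 0) {
      stop(sprintf("corrupt chunk header in WAV file: %s", path), call. = FALSE)
    }
    if (id == "fmt ") {
      body <- readBin(con, "raw", size)
      if (length(body) < 16L) {
        stop(sprintf("truncated fmt chunk in WAV file: %s", path), call. = FALSE)
      }
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, size = 2L,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1L, size = 2L,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1L, size = 4L,
                              endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, size = 2L,
                       signed = FALSE, endian = "little")
      )
    } else if (id == "data") {
      if (is.null(fmt)) {
        stop(sprintf("WAV data chunk before fmt chunk: %s", path), call. = FALSE)
      }
      if (fmt$audio_format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        samples <- readBin(con, "double", n, size = 4L, endian = "little")
      } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        samples <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                           endian = "little") / 32768
      } else {
        stop(sprintf(
          "unsupported WAV sample format (format code %d, %d bit) in %s",
          fmt$audio_format, fmt$bits, path
        ), call. = FALSE)
      }
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L) # chunk pad byte
    if (!is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples)) {
    stop(sprintf("missing fmt or data chunk in WAV file: %s", path), call. = FALSE)
  }
  if (length(samples) == 0L) {
    stop(sprintf("zero-length audio in WAV file: %s", path), call. = FALSE)
  }
  if (fmt$n_channels > 1L) {
    samples <- samples[seq(1L, length(samples), by = fmt$n_channels)]
  }
  # float WAVs may slightly exceed full scale; clamp rather than refuse
  samples[samples > 1] <- 1
  samples[samples < -1] <- -1
  recording(samples, fmt$sample_rate)
}

#' Write a recording as a 32-bit float mono WAV file
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "bims_recording"))
  if (length(rec$samples) == 0L) {
    stop("refusing to write an empty recording", call. = FALSE)
  }
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  on.exit(close(con))
  data_size <- 4L * length(rec$samples)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(3L, con, size = 2L, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  sr <- as.integer(round(rec$sample_rate))
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(sr * 4L, con, size = 4L, endian = "little") # byte rate
  writeBin(4L, con, size = 2L, endian = "little")   # block align
  writeBin(32L, con, size = 2L, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  writeBin(rec$samples, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a per-blow insertion-depth table
#'
#' The depth table records the caliper measurement taken after each hammer
#' blow: a CSV with header columns `blow_index` (1-based, strictly
#' increasing) and `depth_mm` (non-negative).
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `blow_index` (integer) and `depth_mm`.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("depth table not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("blow_index", "depth_mm")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop(sprintf("depth table %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab <- tab[required]
  tab$blow_index <- as.integer(tab$blow_index)
  if (anyNA(tab$blow_index) || anyNA(tab$depth_mm)) {
    stop(sprintf("depth table %s contains missing values", path), call. = FALSE)
  }
  if (any(diff(tab$blow_index) <= 0L)) {
    stop(sprintf("depth table %s: blow_index must be strictly increasing", path),
         call. = FALSE)
  }
  if (any(tab$depth_mm < 0)) {
    stop(sprintf("depth table %s: depths must be non-negative", path),
         call. = FALSE)
  }
  tab
}

#' Write a per-blow insertion-depth table
#'
#' @param depth_table Data frame with columns `blow_index`, `depth_mm`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depth_table, path) {
  stopifnot(all(c("blow_index", "depth_mm") %in% names(depth_table)))
  utils::write.csv(depth_table[c("blow_index", "depth_mm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
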