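# Blow detection: split a continuous hammering recording into fixed-length
# per-blow analysis windows.

#' Segmentation configuration
#'
#' Controls the onset detector. A blow onset is declared where a short
#' moving average of the absolute amplitude (the envelope) first exceeds
#' `threshold_factor` times the recording's noise scale, at least
#' `refractory` seconds after the previous onset. The noise scale is the
#' median of that envelope over the whole recording — robust because blows
#' occupy a small fraction of the samples and the gaps between them are
#' near-silent. The envelope (rather than raw samples) is thresholded so
#' that single-sample noise excursions cannot fake an onset.
#'
#' @param window_length Analysis window length in seconds (default 0.2, the
#'   per-blow window the spectral stage expects).
#' @param threshold_factor Dimensionless multiple of the noise scale
#'   (default 8).
#' @param refractory Minimum spacing between onsets in seconds (default 0.2);
#'   prevents double-counting one transient.
#' @param smoothing Envelope averaging length in seconds (default 0.001);
#'   also used as the pre-trigger backed off from the threshold crossing so
#'   the window captures the transient's leading edge.
#' @return A list of class `bims_segmentation_config`.
#' @export
segmentation_config <- function(window_length = 0.2, threshold_factor = 8,
                                refractory = 0.2, smoothing = 0.001) {
  if (!is.numeric(threshold_factor) || threshold_factor <= 0) {
    stop("threshold_factor must be > 0", call. = FALSE)
  }
  if (window_length <= 0) stop("window_length must be > 0", call. = FALSE)
  if (refractory <= 0) stop("refractory must be > 0", call. = FALSE)
  if (smoothing <= 0) stop("smoothing must be > 0", call. = FALSE)
  structure(
    list(window_length = window_length, threshold_factor = threshold_factor,
         refractory = refractory, smoothing = smoothing),
    class = "bims_segmentation_config"
  )
}

# causal moving average of |x| over k samples (cumsum trick, O(n));
# the first k-1 entries average the shorter available history
envelope_abs <- function(x, k) {
  if (k <= 1L) return(abs(x))
  cs <- cumsum(abs(x))
  n <- length(x)
  env <- numeric(n)
  head_n <- seq_len(min(k, n))
  env[head_n] <- cs[head_n] / head_n
  if (n > k) {
    idx <- (k + 1L):n
    env[idx] <- (cs[idx] - cs[idx - k]) / k
  }
  env
}

#' Detect hammer blows in a recording
#'
#' Finds blow onsets with the envelope-threshold detector described in
#' [segmentation_config()] and cuts one fixed-length window per onset.
#' Windows that overrun the end of the recording are zero-padded and
#' flagged. An all-zero (or onset-free) recording yields zero windows,
#' which is a valid result, not an error.
#'
#' @param rec A [recording()].
#' @param cfg A [segmentation_config()].
#' @return An object of class `bims_blows`: list with `onsets` (data frame
#'   of `blow_index`, `onset_time` seconds, `padded` flag), `windows`
#'   (matrix, one column per blow, `round(window_length * sample_rate)`
#'   rows), `sample_rate`, `noise_scale`, `threshold`, and the config.
#' @examples
#' sim <- simulate_experiment(simulation_preset("fixated_large",
#'   n_blows = 3, seed = 1))
#' blows <- detect_blows(sim$recording)
#' blows$onsets
#' @export
detect_blows <- function(rec, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "bims_recording"))
  if (!inherits(cfg, "bims_segmentation_config")) {
    stop("cfg must be a segmentation_config()", call. = FALSE)
  }
  fs <- rec$sample_rate
  x <- rec$samples
  smooth_n <- max(1L, as.integer(round(cfg$smoothing * fs)))
  env <- envelope_abs(x, smooth_n)
  env[is.na(env)] <- 0
  noise_scale <- stats::median(env)
  # floor the threshold at a sliver of the peak envelope so that a
  # recording with a silent (all-zero) noise floor does not degenerate to
  # threshold 0, where the transients' own decaying tails would re-trigger
  threshold <- max(cfg$threshold_factor * noise_scale, 1e-6 * max(env))
  win_n <- as.integer(round(cfg$window_length * fs))
  refr_n <- as.integer(round(cfg$refractory * fs))

  above <- which(env > threshold)
  onsets_idx <- integer(0)
  i <- 1L
  while (i <= length(above)) {
    onsets_idx <- c(onsets_idx, above[i])
    nxt <- above[i] + refr_n
    # first candidate at least one refractory later (sorted -> binary search)
    i <- findInterval(nxt - 1L, above) + 1L
  }
  # back off by the envelope length so the leading edge stays in the window
  onsets_idx <- pmax(1L, onsets_idx - smooth_n)

  n_blow <- length(onsets_idx)
  windows <- matrix(0, nrow = win_n, ncol = n_blow)
  padded <- logical(n_blow)
  for (j in seq_len(n_blow)) {
    start <- onsets_idx[j]
    end <- min(length(x), start + win_n - 1L)
    windows[seq_len(end - start + 1L), j] <- x[start:end]
    padded[j] <- (end - start + 1L) < win_n
  }
  structure(
    list(
      onsets = data.frame(
        blow_index = seq_len(n_blow),
        onset_time = (onsets_idx - 1L) / fs,
        padded = padded
      ),
      windows = windows,
      sample_rate = fs,
      noise_scale = noise_scale,
      threshold = threshold,
      config = cfg
    ),
    class = "bims_blows"
  )
}

#' @export
print.bims_blows <- function(x, ...) {
  cat(sprintf(
    "<bims_blows: %d blows, window %d samples @ %g Hz, threshold %.3g>\n",
    nrow(x$onsets), nrow(x$windows), x$sample_rate, x$threshold
  ))
  invisible(x)
}

#' Export detected onsets as CSV
#'
#' @param blows A `bims_blows` object from [detect_blows()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_onsets <- function(blows, path) {
  stopifnot(inherits(blows, "bims_blows"))
  utils::write.csv(blows$onsets[c("blow_index", "onset_time")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
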