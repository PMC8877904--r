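# End-to-end orchestration: recording -> blows -> spectra -> band peak
# tracks -> drift/convergence statistics -> report.

#' Analysis configuration
#'
#' One object holding every tunable of the pipeline, embedded verbatim in
#' the report for provenance.
#'
#' @param window_length,threshold_factor,refractory,smoothing Passed to
#'   [segmentation_config()].
#' @param bands A [nominal_bands()] object.
#' @param min_height Peak-search minimum height (relative ESD units), or
#'   `NULL` for the default 5 x median of each spectrum.
#' @param min_distance Peak-search minimum separation, Hz.
#' @param taper `"none"` or `"hann"`.
#' @param blow_energy_j Nominal hammer energy per blow (J) for the energy
#'   summary, or `NULL` to skip energy bookkeeping.
#' @param x_axis `"auto"` (depth when a depth table is present, else blow
#'   index), `"depth"`, or `"blow"`.
#' @param aggregate_last Number of final blows summarized in the
#'   median/IQR ESD plot data (default 20).
#' @return List of class `bims_analysis_config`.
#' @export
analysis_config <- function(window_length = 0.2, threshold_factor = 8,
                            refractory = 0.2, smoothing = 0.001,
                            bands = nominal_bands(), min_height = NULL,
                            min_distance = 300, taper = c("none", "hann"),
                            blow_energy_j = NULL,
                            x_axis = c("auto", "depth", "blow"),
                            aggregate_last = 20) {
  structure(
    list(
      window_length = window_length, threshold_factor = threshold_factor,
      refractory = refractory, smoothing = smoothing, bands = bands,
      min_height = min_height, min_distance = min_distance,
      taper = match.arg(taper), blow_energy_j = blow_energy_j,
      x_axis = match.arg(x_axis), aggregate_last = aggregate_last
    ),
    class = "bims_analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Recognized top-level keys match the arguments of [analysis_config()];
#' `bands` may be given as `centers` (list of Hz) and `half_width`.
#' Unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), c(known, "centers", "half_width"))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$centers) || !is.null(raw$half_width)) {
    raw$bands <- nominal_bands(
      centers = if (is.null(raw$centers)) NULL else unlist(raw$centers),
      half_width = if (is.null(raw$half_width)) 150 else raw$half_width
    )
    raw$centers <- NULL
    raw$half_width <- NULL
  }
  do.call(analysis_config, raw)
}

#' Run the full analysis pipeline
#'
#' Segments the recording into blows, computes per-blow ESDs, tracks the
#' resonant peaks across the configured bands, and fits per band a linear
#' frequency-drift regression and an exponential peak-energy convergence
#' model (missing peaks dropped pairwise). Pairwise variance-ratio F-tests
#' compare the exponential-fit scatter between bands. When a depth table
#' is supplied the fits use insertion depth as the x-axis, otherwise the
#' blow index (flagged in the report).
#'
#' @param input A [recording()], a WAV file path, or a
#'   [simulate_experiment()] result (whose depth table is used
#'   automatically unless `depth_table` is given).
#' @param depth_table Optional data frame (`blow_index`, `depth_mm`) or
#'   CSV path.
#' @param config An [analysis_config()].
#' @return Object of class `bims_report`: `n_blows`, `x_axis`, `peaks`
#'   (per-(blow, band) table with the fitting x), `fits` (per band:
#'   `linear`, `exponential`), `ftests` (pairwise between bands), `energy`
#'   (summary or `NULL`), `esd_summary` (median/IQR plot data of the last
#'   blows), `onsets`, `provenance`.
#' @examples
#' sim <- simulate_experiment(simulation_preset("fixated_large",
#'   n_blows = 8, seed = 3))
#' rep <- run_analysis(sim)
#' rep$fits$band_3$linear$slope
#' @export
run_analysis <- function(input, depth_table = NULL,
                         config = analysis_config()) {
  stopifnot(inherits(config, "bims_analysis_config"))
  source_label <- "recording"
  if (inherits(input, "bims_simulation")) {
    if (is.null(depth_table)) depth_table <- input$depth_table
    source_label <- sprintf("simulation(%s, seed %d)",
                            input$truth$config$condition,
                            input$truth$config$seed)
    input <- input$recording
  } else if (is.character(input)) {
    source_label <- input
    input <- read_wav(input)
  }
  stopifnot(inherits(input, "bims_recording"))
  if (is.character(depth_table)) depth_table <- read_depth_table(depth_table)

  seg_cfg <- segmentation_config(
    window_length = config$window_length,
    threshold_factor = config$threshold_factor,
    refractory = config$refractory,
    smoothing = config$smoothing
  )
  blows <- detect_blows(input, seg_cfg)
  n_blows <- nrow(blows$onsets)
  if (n_blows == 0L) {
    stop(sprintf(
      paste0("no hammer blows detected (noise scale %.3g, threshold %.3g): ",
             "empty report"),
      blows$noise_scale, blows$threshold
    ), call. = FALSE)
  }

  specs <- blow_spectra(blows, taper = config$taper)
  peaks <- peak_table(blows, bands = config$bands,
                      min_height = config$min_height,
                      min_distance = config$min_distance,
                      specs = specs)

  use_depth <- switch(config$x_axis,
    auto = !is.null(depth_table),
    depth = TRUE,
    blow = FALSE
  )
  if (use_depth && is.null(depth_table)) {
    stop("x_axis = 'depth' requires a depth table", call. = FALSE)
  }
  if (use_depth) {
    peaks$x <- depth_table$depth_mm[match(peaks$blow_index,
                                          depth_table$blow_index)]
  } else {
    peaks$x <- peaks$blow_index
  }

  n_bands <- length(config$bands$centers)
  fits <- lapply(seq_len(n_bands), function(b) {
    rows <- peaks[peaks$band_id == b & !peaks$missing, , drop = FALSE]
    lin <- tryCatch(fit_linear(rows$x, rows$peak_frequency),
                    error = function(e) NULL)
    ex <- tryCatch(suppressMessages(fit_exponential(rows$x, rows$peak_energy)),
                   error = function(e) NULL)
    list(band_id = b, center = config$bands$centers[b],
         n_observed = nrow(rows), linear = lin, exponential = ex)
  })
  names(fits) <- paste0("band_", seq_len(n_bands))

  ftests <- list()
  for (a in seq_len(n_bands)) {
    for (b in seq_len(n_bands)) {
      if (a < b && !is.null(fits[[a]]$exponential) &&
          !is.null(fits[[b]]$exponential)) {
        ftests[[sprintf("band_%d_vs_%d", a, b)]] <-
          compare_fits_ftest(fits[[a]]$exponential, fits[[b]]$exponential)
      }
    }
  }

  energy <- NULL
  if (!is.null(config$blow_energy_j) && !is.null(depth_table)) {
    records <- blow_records(depth_table, config$blow_energy_j)
    energy <- energy_summary(records)
  }

  last <- specs[seq(max(1L, n_blows - config$aggregate_last + 1L), n_blows)]
  esd_summary <- aggregate_esd(last)

  structure(
    list(
      n_blows = n_blows,
      x_axis = if (use_depth) "depth_mm" else "blow_index",
      peaks = peaks,
      fits = fits,
      ftests = ftests,
      energy = energy,
      esd_summary = esd_summary,
      onsets = blows$onsets,
      provenance = list(
        package_version = as.character(utils::packageVersion("bims")),
        source = source_label,
        noise_scale = blows$noise_scale,
        threshold = blows$threshold,
        config = config
      )
    ),
    class = "bims_report"
  )
}

#' @export
print.bims_report <- function(x, ...) {
  cat(sprintf("<bims_report: %d blows, x axis = %s>\n", x$n_blows, x$x_axis))
  for (f in x$fits) {
    lin <- f$linear
    ex <- f$exponential
    cat(sprintf(
      "  band %d (%g Hz): n = %d%s%s\n",
      f$band_id, f$center, f$n_observed,
      if (is.null(lin)) "" else sprintf(
        "; drift %.4g Hz/unit (p = %.3g)", lin$slope, lin$p_value),
      if (is.null(ex)) "" else sprintf(
        "; energy k = %.4g, R2 = %.3f", ex$k, ex$r_squared)
    ))
  }
  if (!is.null(x$energy)) print(x$energy)
  invisible(x)
}

report_serializable <- function(report) {
  strip <- function(f) {
    if (is.null(f)) return(NULL)
    f <- unclass(f)
    f$residuals <- NULL
    f$fitted <- NULL
    f
  }
  list(
    n_blows = report$n_blows,
    x_axis = report$x_axis,
    fits = lapply(report$fits, function(f) {
      list(band_id = f$band_id, center = f$center, n_observed = f$n_observed,
           linear = strip(f$linear), exponential = strip(f$exponential))
    }),
    ftests = lapply(report$ftests, unclass),
    energy = if (is.null(report$energy)) NULL else unclass(report$energy),
    peaks = report$peaks,
    onsets = report$onsets,
    esd_summary = report$esd_summary,
    provenance = local({
      p <- report$provenance
      p$config$bands <- unclass(p$config$bands)
      p$config <- unclass(p$config)
      p
    })
  )
}

#' Serialize an analysis report to JSON
#'
#' Numbers are written at full precision so identical runs produce
#' byte-identical reports.
#'
#' @param report A `bims_report`.
#' @return JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "bims_report"))
  jsonlite::toJSON(report_serializable(report), auto_unbox = TRUE,
                   digits = NA, dataframe = "columns", null = "null",
                   pretty = TRUE)
}

#' Write the report and its plot-data companions
#'
#' Writes `report.json`, the per-blow peak table `peaks.csv`, the
#' median/IQR ESD plot data `esd_summary.csv`, and the onset table
#' `onsets.csv` (plot data is CSV so plotting is optional and external).
#'
#' @param report A `bims_report`.
#' @param dir Output directory (created if needed).
#' @return Named vector of paths, invisibly.
#' @export
write_report_files <- function(report, dir) {
  stopifnot(inherits(report, "bims_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    report = file.path(dir, "report.json"),
    peaks = file.path(dir, "peaks.csv"),
    esd = file.path(dir, "esd_summary.csv"),
    onsets = file.path(dir, "onsets.csv")
  )
  writeLines(report_json(report), paths[["report"]])
  utils::write.csv(report$peaks, paths[["peaks"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$esd_summary, paths[["esd"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$onsets, paths[["onsets"]], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
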