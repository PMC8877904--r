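# Impact-energy and insertion bookkeeping: per-blow potential energy,
# cumulative energy, energy per millimetre advanced, and the
# insertion-curve summary with the plateau stopping rule.

#' Per-blow impact energy of the swing hammer
#'
#' Potential-energy estimate `E = m * g * h` for one hammer blow,
#' neglecting hinge friction and other losses. The bench rig's 1.5 kg
#' hammer dropped from 16 mm gives about 0.24 J; from 132 mm about 1.9 J.
#'
#' @param mass Hammer mass in kg (default 1.5).
#' @param height Drop height in metres (>= 0).
#' @param g Gravitational acceleration, m/s^2 (default 9.81).
#' @return Energy in joules.
#' @examples
#' impact_energy(height = 0.016) # ~0.24 J
#' @export
impact_energy <- function(mass = 1.5, height, g = 9.81) {
  if (mass <= 0 || g <= 0) stop("mass and g must be positive", call. = FALSE)
  if (any(height < 0)) stop("drop height must be non-negative", call. = FALSE)
  mass * g * height
}

#' Cumulative hammering energy
#'
#' Running sum of per-blow impact energies — the total energy added to the
#' system after each blow.
#'
#' @param blow_energies Non-negative per-blow energies in joules.
#' @return List with `cumulative` (running-sum series) and `total` (last
#'   element; 0 for an empty series).
#' @export
cumulative_energy <- function(blow_energies) {
  if (any(blow_energies < 0)) {
    stop("blow energies must be non-negative", call. = FALSE)
  }
  cum <- cumsum(blow_energies)
  list(cumulative = cum,
       total = if (length(cum)) cum[length(cum)] else 0)
}

#' Energy needed per millimetre of broach advance
#'
#' @param total_energy Total hammering energy in joules.
#' @param depth_advance Total advance in mm (> 0).
#' @return Energy per advance in J/mm.
#' @examples
#' energy_per_mm(12, 23) # ~0.52 J/mm
#' @export
energy_per_mm <- function(total_energy, depth_advance) {
  if (depth_advance <= 0) {
    stop("depth advance must be positive: J/mm is undefined otherwise",
         call. = FALSE)
  }
  total_energy / depth_advance
}

#' Summarize an insertion-depth curve
#'
#' The typical insertion curve rises near-linearly for the first several
#' millimetres and then flattens to a plateau as the broach seats. This
#' summary reports: the slope of the initial linear segment (OLS over the
#' prefix of blows that maximizes R^2), the final depth, and the blow at
#' which the bench stopping rule fires — the first blow ending five
#' consecutive blows whose advance is below `advance_tol` mm (default
#' 0.1 mm/blow over 5 blows), or `NA` if it never fires.
#'
#' Per-blow advance is `depth[j] - depth[j-1]`, with the first advance
#' taken relative to `initial_depth` (default: the first recorded depth,
#' i.e. a zero first advance).
#'
#' @param depth_mm Per-blow insertion depths (mm), in blow order (>= 5).
#' @param initial_depth Depth before the first recorded blow, mm.
#' @param advance_tol Advance threshold in mm per blow (default 0.1).
#' @param consecutive Number of consecutive sub-threshold blows (default 5).
#' @return List of class `bims_insertion_summary`: `initial_slope`
#'   (mm/blow), `initial_segment_n`, `end_depth`, `stopping_blow`,
#'   `monotone` (FALSE if any advance is negative; flagged, not fatal).
#' @export
insertion_curve <- function(depth_mm, initial_depth = NULL,
                            advance_tol = 0.1, consecutive = 5L) {
  depth_mm <- as.numeric(depth_mm)
  n <- length(depth_mm)
  if (n < 5L) stop("insertion_curve needs at least 5 records", call. = FALSE)
  if (is.null(initial_depth)) initial_depth <- depth_mm[1L]
  advance <- diff(c(initial_depth, depth_mm))
  monotone <- all(advance >= 0)
  if (!monotone) {
    warning("insertion depths are not monotone non-decreasing", call. = FALSE)
  }

  # initial linear segment: prefix (>= 3 blows) maximizing OLS R^2
  blow <- seq_len(n)
  best <- list(r2 = -Inf, m = NA_integer_, slope = NA_real_)
  for (m in 3:n) {
    xs <- blow[1:m]
    ys <- depth_mm[1:m]
    if (stats::var(ys) == 0) next
    fit <- stats::lm.fit(cbind(1, xs), ys)
    r2 <- 1 - sum(fit$residuals^2) / sum((ys - mean(ys))^2)
    if (r2 > best$r2) best <- list(r2 = r2, m = m, slope = fit$coefficients[2L])
  }

  below <- advance < advance_tol
  run <- 0L
  stopping_blow <- NA_integer_
  for (j in seq_len(n)) {
    run <- if (below[j]) run + 1L else 0L
    if (run >= consecutive) {
      stopping_blow <- j
      break
    }
  }
  structure(
    list(initial_slope = unname(best$slope), initial_segment_n = best$m,
         end_depth = depth_mm[n], stopping_blow = stopping_blow,
         monotone = monotone),
    class = "bims_insertion_summary"
  )
}

#' @export
print.bims_insertion_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<insertion curve: initial slope %.3g mm/blow over %d blows, ",
           "end depth %.2f mm, stopping rule %s>\n"),
    x$initial_slope, x$initial_segment_n, x$end_depth,
    if (is.na(x$stopping_blow)) "never fired"
    else sprintf("fired at blow %d", x$stopping_blow)
  ))
  invisible(x)
}

#' Per-blow energy/depth bookkeeping table
#'
#' Combines a depth table with a constant (or per-blow) impact energy into
#' the standard experiment record: blow index, depth, blow energy,
#' cumulative energy.
#'
#' @param depth_table Data frame with `blow_index`, `depth_mm` (as from
#'   [read_depth_table()]).
#' @param blow_energy Scalar energy per blow (J), or a vector matching the
#'   number of blows.
#' @return Data frame: `blow_index`, `depth_mm`, `blow_energy_j`,
#'   `cumulative_energy_j`.
#' @export
blow_records <- function(depth_table, blow_energy) {
  n <- nrow(depth_table)
  e <- rep_len(blow_energy, n)
  if (any(e < 0)) stop("blow energies must be non-negative", call. = FALSE)
  data.frame(
    blow_index = depth_table$blow_index,
    depth_mm = depth_table$depth_mm,
    blow_energy_j = e,
    cumulative_energy_j = cumsum(e)
  )
}

#' Experiment energy summary
#'
#' The standard comparison row set for an insertion run: blow count, depth
#' advanced, energy per blow, cumulative energy, and energy per millimetre
#' advanced (values rounded to 2 decimals for display, full precision kept
#' in the returned list).
#'
#' @param records Data frame from [blow_records()].
#' @param initial_depth Depth before the first blow, mm (default: first
#'   recorded depth).
#' @return List of class `bims_energy_summary`.
#' @export
energy_summary <- function(records, initial_depth = NULL) {
  n <- nrow(records)
  if (n < 1L) stop("no blow records", call. = FALSE)
  if (is.null(initial_depth)) initial_depth <- records$depth_mm[1L]
  advance <- records$depth_mm[n] - initial_depth
  total <- records$cumulative_energy_j[n]
  structure(
    list(
      n_blows = n,
      depth_advance_mm = advance,
      mean_blow_energy_j = mean(records$blow_energy_j),
      cumulative_energy_j = total,
      energy_per_mm_j = if (advance > 0) energy_per_mm(total, advance)
                        else NA_real_
    ),
    class = "bims_energy_summary"
  )
}

#' @export
print.bims_energy_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<energy summary: %d blows, %.2f J/blow, cumulative %.2f J, ",
           "advance %.2f mm, %s J/mm>\n"),
    x$n_blows, x$mean_blow_energy_j, x$cumulative_energy_j,
    x$depth_advance_mm,
    if (is.na(x$energy_per_mm_j)) "NA" else sprintf("%.2f", x$energy_per_mm_j)
  ))
  invisible(x)
}
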