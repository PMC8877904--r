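# Statistical layer: frequency-drift linear regressions, exponential
# peak-energy convergence fits (R^2 as the fixation statistic), F-test
# comparison of fit scatter, and the logarithmic depth-from-peak-energy
# calibration.

drop_nonfinite_pairs <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], dropped = sum(!ok))
}

# summary.lm warns on noiseless data ("essentially perfect fit"); exact
# recovery is a legitimate use here, so that one warning is muffled
quiet_lm_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Ordinary least-squares line with zero-slope test
#'
#' Simple linear regression of y on x (typically peak frequency in Hz on
#' insertion depth in mm), with the two-sided t-test of the zero-slope
#' null. A p-value below 0.05 indicates a real frequency drift with
#' insertion. Non-finite pairs (missing peaks) are dropped pairwise.
#'
#' For a constant y the slope is 0 and, as a documented boundary
#' convention, R^2 = 0 and p = 1 (no evidence of drift).
#'
#' @param x Predictor (e.g. insertion depth, mm).
#' @param y Response (e.g. peak frequency, Hz).
#' @return Object of class `bims_linear_fit`: `slope`, `intercept`,
#'   `slope_se` (standard error of the slope), `r_squared`, `p_value`,
#'   `n`, `residuals`, `fitted`.
#' @export
fit_linear <- function(x, y) {
  d <- drop_nonfinite_pairs(as.numeric(x), as.numeric(y))
  n <- length(d$x)
  if (n < 3L) stop("fit_linear needs at least 3 finite pairs", call. = FALSE)
  if (stats::var(d$x) == 0) {
    stop("fit_linear: x has zero variance (degenerate input)", call. = FALSE)
  }
  if (stats::var(d$y) == 0) {
    # constant response: slope 0 by convention, no drift evidence
    return(structure(
      list(slope = 0, intercept = d$y[1L], slope_se = 0, r_squared = 0,
           p_value = 1, n = n, residuals = rep(0, n),
           fitted = rep(d$y[1L], n), r_squared_clipped = FALSE),
      class = "bims_linear_fit"
    ))
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = d$x, y = d$y))
  sm <- quiet_lm_summary(fit)
  structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      slope_se = unname(sm$coefficients[2L, 2L]),
      r_squared = sm$r.squared,
      p_value = unname(sm$coefficients[2L, 4L]),
      n = n,
      residuals = unname(stats::residuals(fit)),
      fitted = unname(stats::fitted(fit)),
      r_squared_clipped = FALSE
    ),
    class = "bims_linear_fit"
  )
}

#' @export
print.bims_linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear fit: y = %.4g x + %.4g, R2 = %.4f, p(slope=0) = %.3g, n = %d>\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

# R^2 on the original scale, clipped into [0, 1]; SS_tot == 0 maps to 0
original_scale_r2 <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(list(r2 = 0, clipped = FALSE))
  r2 <- 1 - sum((y - fitted)^2) / ss_tot
  if (r2 < 0) list(r2 = 0, clipped = TRUE) else list(r2 = r2, clipped = FALSE)
}

#' Exponential convergence fit of peak energies
#'
#' Nonlinear least squares of `y = y0 * exp(k * x)` — the model used to
#' quantify how consistently per-blow peak energies settle as the broach
#' seats. The fit's R^2 (computed as 1 - SS_res/SS_tot on the original,
#' untransformed scale) is the fixation statistic: higher R^2 means lower
#' scatter and a better-converged, better-fixated run.
#'
#' The optimizer (Levenberg-Marquardt) is started from the log-linear
#' regression of `ln y` on `x`. If it fails to converge the log-linear
#' fallback parameters are reported with `converged = FALSE`. Non-positive
#' y values cannot enter either fit and are dropped with a message.
#'
#' @param x Predictor (insertion depth mm, or blow index).
#' @param y Peak energies (positive, relative ESD units).
#' @return Object of class `bims_exp_fit`: `y0`, `k`, `r_squared`, `n`,
#'   `converged`, `residuals`, `fitted`, `dropped_nonpositive`.
#' @export
fit_exponential <- function(x, y) {
  d <- drop_nonfinite_pairs(as.numeric(x), as.numeric(y))
  pos <- d$y > 0
  n_dropped <- sum(!pos)
  if (n_dropped > 0L) {
    message(sprintf("fit_exponential: dropped %d non-positive y value(s)",
                    n_dropped))
  }
  x <- d$x[pos]
  y <- d$y[pos]
  n <- length(y)
  if (n < 3L) {
    stop("fit_exponential needs at least 3 positive finite pairs", call. = FALSE)
  }
  # log-linear start values
  lf <- stats::lm(ly ~ x, data = data.frame(x = x, ly = log(y)))
  start <- list(y0 = exp(unname(stats::coef(lf)[1L])),
                k = unname(stats::coef(lf)[2L]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 * exp(k * x),
      data = data.frame(x = x, y = y),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    y0 <- start$y0
    k <- start$k
    fitted_y <- y0 * exp(k * x)
    converged <- FALSE
  } else {
    cf <- stats::coef(fit)
    y0 <- unname(cf["y0"])
    k <- unname(cf["k"])
    fitted_y <- y0 * exp(k * x)
    converged <- TRUE
  }
  r2 <- original_scale_r2(y, fitted_y)
  structure(
    list(y0 = y0, k = k, r_squared = r2$r2, n = n, converged = converged,
         residuals = y - fitted_y, fitted = fitted_y,
         dropped_nonpositive = n_dropped, r_squared_clipped = r2$clipped),
    class = "bims_exp_fit"
  )
}

#' @export
print.bims_exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exponential fit: y = %.4g * exp(%.4g x), R2 = %.4f, n = %d%s>\n",
    x$y0, x$k, x$r_squared, x$n,
    if (x$converged) "" else " (optimizer fallback: log-linear)"
  ))
  invisible(x)
}

#' Compare the convergence of two exponential fits
#'
#' Orders two fits by their R^2 fixation statistic. Higher R^2 is read as
#' lower scatter and hence a higher degree of fixation; no absolute
#' threshold is imposed — the statistic is a relative indicator between
#' conditions.
#'
#' @param fit_a,fit_b `bims_exp_fit` objects.
#' @param labels Length-2 character labels for the two fits.
#' @return List of class `bims_fixation_contrast`: `better` (label or
#'   `"tie"`), `delta_r_squared` (a minus b), per-fit R^2.
#' @export
fixation_contrast <- function(fit_a, fit_b, labels = c("a", "b")) {
  stopifnot(inherits(fit_a, "bims_exp_fit"), inherits(fit_b, "bims_exp_fit"))
  delta <- fit_a$r_squared - fit_b$r_squared
  better <- if (delta > 0) labels[1L] else if (delta < 0) labels[2L] else "tie"
  structure(
    list(better = better, delta_r_squared = delta,
         r_squared = stats::setNames(c(fit_a$r_squared, fit_b$r_squared),
                                     labels)),
    class = "bims_fixation_contrast"
  )
}

#' @export
print.bims_fixation_contrast <- function(x, ...) {
  if (x$better == "tie") {
    cat(sprintf("<fixation contrast: tie at R2 = %.4f>\n", x$r_squared[1L]))
  } else {
    cat(sprintf(
      "<fixation contrast: '%s' better converged (R2 %.4f vs %.4f)>\n",
      x$better, max(x$r_squared), min(x$r_squared)
    ))
  }
  invisible(x)
}

#' Variance-ratio F-test between two regression fits
#'
#' Two-sided F-test comparing the residual variances of two fits (linear
#' or exponential; both use 2 parameters, so residual degrees of freedom
#' are n - 2). The statistic is the larger residual variance over the
#' smaller, with the degrees of freedom ordered accordingly.
#'
#' @param fit_a,fit_b `bims_linear_fit` or `bims_exp_fit` objects.
#' @return List of class `bims_ftest`: `f_statistic`, `p_value`, `df`.
#' @export
compare_fits_ftest <- function(fit_a, fit_b) {
  res_a <- fit_a$residuals
  res_b <- fit_b$residuals
  if (length(res_a) < 3L || length(res_b) < 3L) {
    stop("compare_fits_ftest needs fits with n >= 3", call. = FALSE)
  }
  df_a <- length(res_a) - 2L
  df_b <- length(res_b) - 2L
  s2_a <- sum(res_a^2) / df_a
  s2_b <- sum(res_b^2) / df_b
  if (s2_a >= s2_b) {
    f <- s2_a / s2_b
    df <- c(df_a, df_b)
  } else {
    f <- s2_b / s2_a
    df <- c(df_b, df_a)
  }
  p <- min(1, 2 * stats::pf(f, df[1L], df[2L], lower.tail = FALSE))
  structure(
    list(f_statistic = f, p_value = p, df = df),
    class = "bims_ftest"
  )
}

#' @export
print.bims_ftest <- function(x, ...) {
  cat(sprintf("<F-test: F(%d, %d) = %.4g, two-sided p = %.3g>\n",
              x$df[1L], x$df[2L], x$f_statistic, x$p_value))
  invisible(x)
}

#' Logarithmic depth-from-peak-energy calibration
#'
#' Fits the calibration `ID = a * ln(PE / b)` relating insertion depth
#' (mm) to single-band peak energy, by ordinary least squares on
#' `ID ~ ln(PE)` (the reference energy `b = exp(-intercept / a)` is the
#' peak energy at which the predicted depth is zero). With a decaying
#' energy track, `a` is negative: depth grows as the peak energy falls.
#' Non-positive energies are dropped with a message.
#'
#' @param pe Peak-energy series (positive, relative ESD units).
#' @param id Insertion-depth series (mm), paired with `pe`.
#' @return Object of class `bims_calibration`: `a` (mm per log-unit),
#'   `b` (reference peak energy), `r_squared`, `n`.
#' @seealso [predict_depth()]
#' @export
calibrate_depth <- function(pe, id) {
  d <- drop_nonfinite_pairs(as.numeric(pe), as.numeric(id))
  pos <- d$x > 0
  if (any(!pos)) {
    message(sprintf("calibrate_depth: dropped %d non-positive energy value(s)",
                    sum(!pos)))
  }
  pe <- d$x[pos]
  id <- d$y[pos]
  if (length(pe) < 3L) {
    stop("calibrate_depth needs at least 3 positive pairs", call. = FALSE)
  }
  if (stats::var(log(pe)) == 0) {
    stop("calibrate_depth: ln(PE) has zero variance (degenerate input)",
         call. = FALSE)
  }
  fit <- stats::lm(id ~ lpe, data = data.frame(lpe = log(pe), id = id))
  a <- unname(stats::coef(fit)[2L])
  cc <- unname(stats::coef(fit)[1L])
  if (a == 0) {
    stop("calibrate_depth: fitted slope is exactly zero (degenerate input)",
         call. = FALSE)
  }
  structure(
    list(a = a, b = exp(-cc / a), r_squared = quiet_lm_summary(fit)$r.squared,
         n = length(pe)),
    class = "bims_calibration"
  )
}

#' Predict insertion depth from peak energy
#'
#' @param calib A [calibrate_depth()] fit.
#' @param pe Peak energies (positive).
#' @return Predicted insertion depths in mm, `a * ln(pe / b)`.
#' @export
predict_depth <- function(calib, pe) {
  stopifnot(inherits(calib, "bims_calibration"))
  if (any(pe <= 0)) stop("peak energies must be positive", call. = FALSE)
  calib$a * log(pe / calib$b)
}

#' @export
print.bims_calibration <- function(x, ...) {
  cat(sprintf(
    "<depth calibration: ID = %.4g * ln(PE / %.4g) mm, R2 = %.4f, n = %d>\n",
    x$a, x$b, x$r_squared, x$n
  ))
  invisible(x)
}
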