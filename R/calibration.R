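# SNR(RG) calibration curves: construction, slope fits, linearity
# deviation, interpolation with level-plan discontinuity handling.

#' Convert receiver gain between dB and linear units
#'
#' Benchtop consoles express receiver gain in dB; amplitude gain converts as
#' \eqn{RG_{lin} = 10^{dB/20}}. Curves are always stored with linear RG.
#'
#' @param db,rg Gain in dB (`rg_db_to_linear`) or linear units
#'   (`rg_linear_to_db`).
#' @return The converted gain.
#' @examples
#' rg_db_to_linear(20) # 10
#' rg_linear_to_db(72) # ~37.1 dB
#' @export
rg_db_to_linear <- function(db) 10^(db / 20)

#' @rdname rg_db_to_linear
#' @export
rg_linear_to_db <- function(rg) {
  if (any(rg <= 0)) stop("linear rg must be > 0", call. = FALSE)
  20 * log10(rg)
}

#' One calibration point of an RG sweep
#'
#' @param rg Receiver gain (linear, > 0).
#' @param signal_integral Peak integral, a.u. (>= 0), as measured (summed
#'   over averages).
#' @param noise_rms RMS of a signal-free spectral region, a.u. (> 0).
#' @param fid_max Maximum per-channel FID magnitude, a.u. (>= 0).
#' @param n_averages Number of summed transients (default 1).
#' @return A one-row data frame; rows from several points can be bound with
#'   `rbind()` and passed to [build_calibration()].
#' @export
calibration_point <- function(rg, signal_integral, noise_rms, fid_max = NA,
                              n_averages = 1L) {
  if (!is.numeric(rg) || rg <= 0) stop("rg must be > 0", call. = FALSE)
  if (!is.numeric(noise_rms) || noise_rms <= 0) {
    stop("noise_rms must be > 0", call. = FALSE)
  }
  if (signal_integral < 0) stop("signal_integral must be >= 0", call. = FALSE)
  if (!is.na(fid_max) && fid_max < 0) stop("fid_max must be >= 0", call. = FALSE)
  if (n_averages < 1) stop("n_averages must be >= 1", call. = FALSE)
  data.frame(rg = rg, signal_integral = signal_integral,
             noise_rms = noise_rms, fid_max = as.numeric(fid_max),
             n_averages = as.integer(n_averages))
}

.check_points <- function(points) {
  need <- c("rg", "signal_integral", "noise_rms")
  miss <- setdiff(need, names(points))
  if (length(miss)) {
    stop("calibration points missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(points$fid_max)) points$fid_max <- NA_real_
  if (is.null(points$n_averages)) points$n_averages <- 1L
  if (any(points$rg <= 0)) stop("all rg must be > 0", call. = FALSE)
  if (any(points$noise_rms <= 0)) stop("all noise_rms must be > 0", call. = FALSE)
  if (any(points$signal_integral < 0)) {
    stop("signal_integral must be >= 0", call. = FALSE)
  }
  if (anyDuplicated(points$rg)) {
    stop("duplicate rg values in calibration points", call. = FALSE)
  }
  points[order(points$rg), , drop = FALSE]
}

#' Build an SNR(RG) calibration curve
#'
#' Assembles RG-sweep measurements at fixed reference conditions
#' (flip angle `alpha_ref`, polarization `p_ref`, spin concentration `c_ref`)
#' into a calibration curve. Per-point SNR is the measured
#' `signal_integral / noise_rms`; the stored signal and FID-maximum channels
#' are put on a per-scan scale (divided by `n_averages`) so curves acquired
#' with different averaging are directly comparable, and two through-origin
#' slopes are fitted: `slope_integral` (the hardware coefficient relating
#' spectral signal to RG x concentration at the reference flip angle and
#' polarization) and `slope_fid` (the same for the FID-amplitude channel
#' that saturates the ADC). Segments where SNR drops abruptly between
#' adjacent gains — the level-plan switch — are flagged at the
#' `disc_threshold` relative drop and are never bridged by interpolation.
#'
#' @param points Data frame with columns `rg`, `signal_integral`,
#'   `noise_rms`, and optionally `fid_max`, `n_averages`; see
#'   [calibration_point()]. Gains in dB are accepted with
#'   `rg_units = "dB"` and converted to linear.
#' @param nucleus A [nucleus()] object.
#' @param field Static field in tesla.
#' @param alpha_ref Reference flip angle, degrees in (0, 90].
#' @param p_ref Reference polarization fraction in (0, 1].
#' @param c_ref Reference spin concentration, M (> 0).
#' @param rg_units `"linear"` (default) or `"dB"`.
#' @param disc_threshold Relative SNR drop flagged as a discontinuity
#'   (default 0.1).
#' @return An object of class `"calibration_curve"`.
#' @examples
#' pts <- rbind(
#'   calibration_point(1, 10, 1, 100),
#'   calibration_point(2, 20, 1.2, 200),
#'   calibration_point(4, 40, 1.3, 400)
#' )
#' build_calibration(pts, nucleus("13C"), field = 9.4,
#'                   alpha_ref = 90, p_ref = 8.1e-6, c_ref = 1.308)
#' @export
build_calibration <- function(points, nucleus, field, alpha_ref, p_ref, c_ref,
                              rg_units = c("linear", "dB"),
                              disc_threshold = 0.1) {
  rg_units <- match.arg(rg_units)
  stopifnot(inherits(nucleus, "nucleus"))
  if (!is.numeric(c_ref) || c_ref <= 0) stop("c_ref must be > 0", call. = FALSE)
  if (!is.numeric(p_ref) || p_ref <= 0 || p_ref > 1) {
    stop("p_ref must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha_ref) || alpha_ref <= 0 || alpha_ref > 90) {
    stop("alpha_ref must be in (0, 90] degrees", call. = FALSE)
  }
  if (nrow(points) < 2L) {
    stop("at least 2 calibration points are required", call. = FALSE)
  }
  if (rg_units == "dB") points$rg <- rg_db_to_linear(points$rg)
  points <- .check_points(points)

  # SNR is the measured ratio; signal channels go to per-scan scale.
  points$snr <- points$signal_integral / points$noise_rms
  points$signal_integral <- points$signal_integral / points$n_averages
  points$fid_max <- points$fid_max / points$n_averages

  curve <- structure(
    list(nucleus = nucleus, field = field, alpha_ref = alpha_ref,
         p_ref = p_ref, c_ref = c_ref, points = points,
         rg_units = rg_units, disc_threshold = disc_threshold,
         slope_integral = NULL, slope_fid = NULL, disc_rg = numeric(0)),
    class = "calibration_curve"
  )
  fit_i <- fit_slope(curve, "integral")
  curve$slope_integral <- fit_i$slope
  curve$slope_integral_se <- fit_i$se
  if (!all(is.na(points$fid_max))) {
    fit_f <- fit_slope(curve, "fid_max")
    curve$slope_fid <- fit_f$slope
    curve$slope_fid_se <- fit_f$se
  }
  curve$disc_rg <- detect_discontinuity(curve, disc_threshold)
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve %s @ %.4g T>\n", x$nucleus$name, x$field))
  cat(sprintf("  reference: alpha = %g deg, P = %.4g, C = %.4g M\n",
              x$alpha_ref, x$p_ref, x$c_ref))
  cat(sprintf("  %d points, rg in [%.4g, %.4g]\n", nrow(x$points),
              min(x$points$rg), max(x$points$rg)))
  cat(sprintf("  slope_integral = %.6g a.u./(RG*M)", x$slope_integral))
  if (!is.null(x$slope_fid)) cat(sprintf(", slope_fid = %.6g", x$slope_fid))
  cat("\n")
  if (length(x$disc_rg)) {
    cat("  SNR discontinuity after rg:", paste(signif(x$disc_rg, 4),
                                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Through-origin slope of a calibration channel
#'
#' Least-squares line through the origin of concentration-normalized signal
#' versus RG: `value / c_ref = slope * rg`. The zero intercept reflects zero
#' signal at zero gain.
#'
#' @param curve A [build_calibration()] curve.
#' @param channel `"integral"` (spectral peak integral) or `"fid_max"`
#'   (FID-amplitude channel used for clipping prediction).
#' @return A list with `slope` (a.u. per RG per M), `se` (standard error),
#'   and `residuals`.
#' @export
fit_slope <- function(curve, channel = c("integral", "fid_max")) {
  channel <- match.arg(channel)
  stopifnot(inherits(curve, "calibration_curve"))
  pts <- curve$points
  y <- switch(channel, integral = pts$signal_integral, fid_max = pts$fid_max)
  if (all(is.na(y))) {
    stop("channel '", channel, "' has no data", call. = FALSE)
  }
  ok <- !is.na(y)
  y <- y[ok] / curve$c_ref
  x <- pts$rg[ok]
  if (length(x) < 2L) stop("at least 2 points required for a fit", call. = FALSE)
  if (all(y == 0)) stop("degenerate fit: all signals are zero", call. = FALSE)
  slope <- sum(x * y) / sum(x^2)
  res <- y - slope * x
  df <- length(x) - 1L
  se <- if (df > 0) sqrt(sum(res^2) / df / sum(x^2)) else NA_real_
  list(slope = slope, se = se, residuals = res)
}

#' Relative deviation of signal from RG linearity
#'
#' For each gain, compares signal-per-RG against the same ratio at the
#' largest calibrated gain:
#' \deqn{deviation(RG) = \frac{signal(RG)}{RG} \cdot
#'       \frac{RG_{max}}{signal(RG_{max})} - 1,}
#' which is identically zero for a perfectly linear receiver and is zero at
#' \eqn{RG_{max}} by construction.
#'
#' @param curve A [build_calibration()] curve.
#' @return A data frame with columns `rg` and `deviation`.
#' @export
signal_deviation <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  pts <- curve$points
  n <- nrow(pts)
  s_max <- pts$signal_integral[n]
  rg_max <- pts$rg[n]
  if (s_max == 0) {
    stop("degenerate curve: zero signal at maximum rg", call. = FALSE)
  }
  data.frame(rg = pts$rg,
             deviation = (pts$signal_integral / pts$rg) * (rg_max / s_max) - 1)
}

#' Detect abrupt SNR drops between adjacent gains
#'
#' Flags each gain `rg_i` where the next calibrated point loses more than
#' `rel_drop_threshold` of its SNR, i.e.
#' `snr(rg_[i+1]) < (1 - threshold) * snr(rg_i)`. Such drops arise from the
#' receiver's level-plan switching, a hardware step rather than a smooth
#' feature, so interpolation never bridges a flagged segment.
#'
#' @param curve A [build_calibration()] curve.
#' @param rel_drop_threshold Relative drop in (0, 1); default 0.1.
#' @return Numeric vector of rg values (possibly empty) after which the
#'   drop occurs.
#' @export
detect_discontinuity <- function(curve, rel_drop_threshold = 0.1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (rel_drop_threshold <= 0 || rel_drop_threshold >= 1) {
    stop("rel_drop_threshold must be in (0, 1)", call. = FALSE)
  }
  pts <- curve$points
  n <- nrow(pts)
  if (n < 2L) return(numeric(0))
  s <- pts$snr
  drop <- s[-1] < (1 - rel_drop_threshold) * s[-n]
  pts$rg[-n][drop]
}

# Shared piecewise-linear interpolation with knot snapping inside flagged
# discontinuity segments. `values` is a per-point channel of the curve.
.interp_channel <- function(curve, rg, values, snap_disc = TRUE) {
  pts <- curve$points
  lo <- min(pts$rg); hi <- max(pts$rg)
  if (any(rg < lo) || any(rg > hi)) {
    stop(sprintf("rg out of calibrated range [%g, %g]", lo, hi), call. = FALSE)
  }
  out <- stats::approx(pts$rg, values, xout = rg, method = "linear",
                       ties = "ordered")$y
  if (snap_disc && length(curve$disc_rg)) {
    for (d in curve$disc_rg) {
      i <- match(d, pts$rg)
      if (is.na(i) || i >= nrow(pts)) next
      a <- pts$rg[i]; b <- pts$rg[i + 1L]
      inside <- rg > a & rg < b
      if (any(inside)) {
        nearer <- ifelse(rg[inside] - a <= b - rg[inside], i, i + 1L)
        out[inside] <- values[nearer]
      }
    }
  }
  out
}

#' Interpolate reference SNR at arbitrary gains
#'
#' Piecewise-linear interpolation of the calibrated SNR between measured
#' gains; exact at measured points and never extrapolated. Inside a segment
#' flagged by [detect_discontinuity()] (the level-plan switch) the query
#' snaps to the nearer measured knot instead of bridging the step.
#'
#' @param curve A [build_calibration()] curve.
#' @param rg Receiver gain(s) within the calibrated range.
#' @return SNR at reference conditions, same length as `rg`.
#' @export
interpolate_snr <- function(curve, rg) {
  stopifnot(inherits(curve, "calibration_curve"))
  .interp_channel(curve, rg, curve$points$snr, snap_disc = TRUE)
}

# FID-max reference channel at arbitrary gain: interpolated when measured,
# linear-model fallback (slope_fid * rg * c_ref) when absent. The signal
# channel is smooth in RG, so no discontinuity snapping applies.
.fid_max_ref <- function(curve, rg) {
  pts <- curve$points
  if (all(is.na(pts$fid_max))) {
    if (is.null(curve$slope_fid)) {
      stop("curve has no FID-amplitude channel", call. = FALSE)
    }
    return(curve$slope_fid * rg * curve$c_ref)
  }
  .interp_channel(curve, rg, pts$fid_max, snap_disc = FALSE)
}
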