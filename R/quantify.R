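# FID and spectrum containers plus the measurables the calibration needs:
# peak integrals, noise RMS over a signal-free region, SNR, per-channel
# clipping detection and ADC-ceiling (RRT) estimation.

#' A 1D free induction decay
#'
#' @param samples Complex time-domain samples, a.u.; at least 16 points.
#' @param dwell Dwell time (seconds per point, > 0).
#' @param rg Receiver gain (linear) at acquisition.
#' @param alpha Excitation flip angle, degrees.
#' @param clipped Logical: any quadrature channel touched the ADC ceiling.
#'   Usually set by [detect_clipping()].
#' @param meta Free-form list of acquisition annotations.
#' @return An object of class `"fid_record"`.
#' @export
fid_record <- function(samples, dwell, rg = NA_real_, alpha = NA_real_,
                       clipped = FALSE, meta = list()) {
  samples <- as.complex(samples)
  if (length(samples) < 16L) stop("FID needs >= 16 samples", call. = FALSE)
  if (!is.numeric(dwell) || dwell <= 0) stop("dwell must be > 0", call. = FALSE)
  structure(list(samples = samples, dwell = dwell, rg = rg, alpha = alpha,
                 clipped = isTRUE(clipped), meta = meta),
            class = "fid_record")
}

#' @export
print.fid_record <- function(x, ...) {
  cat(sprintf(
    "<fid_record: %d pts, dwell %.3g s, sw %.4g Hz, rg %.4g, alpha %.4g%s>\n",
    length(x$samples), x$dwell, 1 / x$dwell, x$rg, x$alpha,
    if (x$clipped) ", CLIPPED" else ""))
  invisible(x)
}

#' A 1D spectrum
#'
#' @param freq_axis Strictly increasing frequency axis, Hz offset from the
#'   carrier (rotating frame).
#' @param values Complex (or real) spectral amplitudes, same length.
#' @param phase0,phase1 Zero- and first-order phase already applied, degrees.
#' @return An object of class `"spectrum_record"`.
#' @export
spectrum_record <- function(freq_axis, values, phase0 = 0, phase1 = 0) {
  if (length(freq_axis) != length(values)) {
    stop("freq_axis and values must have the same length", call. = FALSE)
  }
  if (any(diff(freq_axis) <= 0)) {
    stop("freq_axis must be strictly increasing", call. = FALSE)
  }
  structure(list(freq_axis = as.numeric(freq_axis), values = as.complex(values),
                 phase0 = phase0, phase1 = phase1),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record: %d pts, %.4g to %.4g Hz>\n",
              length(x$values), min(x$freq_axis), max(x$freq_axis)))
  invisible(x)
}

#' Fourier transform an FID into a spectrum
#'
#' Plain DFT with optional zero filling and no apodization: windowing
#' changes both signal and noise and is deliberately avoided throughout.
#' Values are scaled by the dwell time so that peak amplitudes and
#' trapezoidal integrals are invariant to the zero-fill factor
#' (continuous-transform normalization); the axis spans
#' \eqn{\pm 1/(2\,dwell)} in the rotating frame.
#'
#' @param fid A [fid_record()].
#' @param zero_fill_factor Integer >= 1; total length is
#'   `zero_fill_factor * length(samples)`.
#' @return A [spectrum_record()].
#' @export
to_spectrum <- function(fid, zero_fill_factor = 1L) {
  stopifnot(inherits(fid, "fid_record"))
  if (zero_fill_factor < 1 || zero_fill_factor != round(zero_fill_factor)) {
    stop("zero_fill_factor must be an integer >= 1", call. = FALSE)
  }
  x <- fid$samples
  n <- length(x) * as.integer(zero_fill_factor)
  padded <- c(x, complex(real = numeric(n - length(x))))
  sp <- stats::fft(padded) * fid$dwell
  # reorder to an ascending axis centered on the carrier
  f <- (seq_len(n) - 1) / (n * fid$dwell)
  f[f >= 1 / (2 * fid$dwell)] <- f[f >= 1 / (2 * fid$dwell)] - 1 / fid$dwell
  ord <- order(f)
  spectrum_record(f[ord], sp[ord])
}

#' Apply zero- and first-order phase correction
#'
#' Multiplies the spectrum by
#' \eqn{\exp(i(\phi_0 + \phi_1 (f - f_{pivot})/sweep))} with the pivot at
#' the center of the axis. The magnitude spectrum is unchanged.
#'
#' @param spectrum A [spectrum_record()].
#' @param phi0 Zero-order phase, degrees.
#' @param phi1 First-order phase, degrees across the full sweep.
#' @return The phased [spectrum_record()].
#' @export
phase_correct <- function(spectrum, phi0 = 0, phi1 = 0) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  f <- spectrum$freq_axis
  sweep <- diff(range(f))
  pivot <- mean(range(f))
  frac <- if (sweep > 0) (f - pivot) / sweep else 0
  phase <- (phi0 + phi1 * frac) * pi / 180
  spectrum$values <- spectrum$values * exp(1i * phase)
  spectrum$phase0 <- spectrum$phase0 + phi0
  spectrum$phase1 <- spectrum$phase1 + phi1
  spectrum
}

.region_idx <- function(spectrum, region) {
  if (length(region) != 2L || region[2] <= region[1]) {
    stop("region must be an increasing frequency interval c(f1, f2)",
         call. = FALSE)
  }
  f <- spectrum$freq_axis
  if (region[1] < min(f) || region[2] > max(f)) {
    stop("region outside the spectral range", call. = FALSE)
  }
  which(f >= region[1] & f <= region[2])
}

#' Integrate a spectral peak
#'
#' Trapezoidal integral of the real (absorption) part over a frequency
#' interval, in a.u. x Hz; by the dwell-time normalization of
#' [to_spectrum()] the result is invariant to zero filling. A zero-order
#' baseline offset, estimated as the median of the real part over the whole
#' spectrum, is subtracted by default.
#'
#' @param spectrum A (phased) [spectrum_record()].
#' @param region `c(f1, f2)` in Hz, within the spectral range.
#' @param baseline `"offset"` (default) or `"none"`.
#' @return Signal integral in a.u.
#' @export
integrate_peak <- function(spectrum, region, baseline = c("offset", "none")) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  baseline <- match.arg(baseline)
  idx <- .region_idx(spectrum, region)
  if (length(idx) < 2L) stop("region contains fewer than 2 points", call. = FALSE)
  y <- Re(spectrum$values)
  if (baseline == "offset") y <- y - stats::median(y)
  f <- spectrum$freq_axis[idx]
  yy <- y[idx]
  sum(diff(f) * (yy[-length(yy)] + yy[-1]) / 2)
}

#' Noise RMS of a signal-free spectral region
#'
#' RMS of the real part after removing a linear baseline within the window.
#' When no region is given, the contiguous window (default 10% of the
#' points) with the smallest standard deviation among windows disjoint from
#' any declared peak regions is selected automatically, emulating an
#' automatic signal-free-region picker.
#'
#' @param spectrum A [spectrum_record()].
#' @param region Optional `c(f1, f2)` in Hz; must avoid `peak_regions`.
#' @param peak_regions List of `c(f1, f2)` intervals that windows must not
#'   overlap in automatic mode.
#' @param window_frac Fraction of spectral points per automatic window
#'   (default 0.1).
#' @return Noise RMS in a.u.
#' @export
estimate_noise <- function(spectrum, region = NULL, peak_regions = list(),
                           window_frac = 0.1) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  y <- Re(spectrum$values)
  n <- length(y)
  rms_detrended <- function(idx) {
    yy <- y[idx]
    t <- seq_along(yy)
    fit <- stats::lm.fit(cbind(1, t), yy)
    sqrt(mean(fit$residuals^2))
  }
  if (!is.null(region)) {
    idx <- .region_idx(spectrum, region)
    for (pr in peak_regions) {
      if (region[1] <= pr[2] && pr[1] <= region[2]) {
        stop("noise region overlaps a declared peak region", call. = FALSE)
      }
    }
    if (length(idx) < 4L) stop("noise region too small", call. = FALSE)
    return(rms_detrended(idx))
  }
  w <- max(4L, floor(window_frac * n))
  if (w > n) stop("window_frac too large for this spectrum", call. = FALSE)
  step <- max(1L, floor(w / 4))
  starts <- seq(1L, n - w + 1L, by = step)
  f <- spectrum$freq_axis
  best <- NULL; best_sd <- Inf
  for (s in starts) {
    idx <- s:(s + w - 1L)
    ok <- TRUE
    for (pr in peak_regions) {
      if (f[idx[length(idx)]] >= pr[1] && f[idx[1]] <= pr[2]) { ok <- FALSE; break }
    }
    if (!ok) next
    sdv <- stats::sd(y[idx])
    if (sdv < best_sd) { best_sd <- sdv; best <- idx }
  }
  if (is.null(best)) {
    stop("no admissible signal-free window found", call. = FALSE)
  }
  rms_detrended(best)
}

#' Signal-to-noise ratio of a spectrum
#'
#' SNR as peak integral divided by noise RMS, the integral convention of the
#' calibration protocol. The peak-amplitude convention (maximum real value
#' in the peak region over noise RMS) is available as an option.
#'
#' @param spectrum A (phased) [spectrum_record()].
#' @param peak_region `c(f1, f2)` of the peak.
#' @param noise_region Optional `c(f1, f2)` signal-free interval; automatic
#'   selection avoiding `peak_region` when `NULL`.
#' @param convention `"integral"` (default) or `"amplitude"`.
#' @return Dimensionless SNR.
#' @export
snr_of <- function(spectrum, peak_region, noise_region = NULL,
                   convention = c("integral", "amplitude")) {
  convention <- match.arg(convention)
  noise <- estimate_noise(spectrum, region = noise_region,
                          peak_regions = list(peak_region))
  if (noise == 0) stop("undefined SNR: noise RMS is zero", call. = FALSE)
  sig <- if (convention == "integral") {
    integrate_peak(spectrum, peak_region)
  } else {
    idx <- .region_idx(spectrum, peak_region)
    max(Re(spectrum$values)[idx])
  }
  sig / noise
}

#' Detect ADC clipping in an FID
#'
#' Each quadrature channel is digitized separately, so a sample is clipped
#' when either `|Re|` or `|Im|` reaches `near_fraction * rrt`. The boundary
#' counts as clipped: the allowed region is signal strictly inside the
#' recorder's range.
#'
#' @param fid A [fid_record()].
#' @param rrt ADC ceiling (receiver range threshold), a.u. (> 0).
#' @param near_fraction Fraction of `rrt` treated as the ceiling
#'   (default 0.999, absorbing rounding of recorded values).
#' @return A list with `clipped` (logical), `indices` of clipped samples,
#'   `fraction` clipped, and the updated `fid`.
#' @export
detect_clipping <- function(fid, rrt, near_fraction = 0.999) {
  stopifnot(inherits(fid, "fid_record"))
  if (!is.numeric(rrt) || rrt <= 0) stop("rrt must be > 0", call. = FALSE)
  lim <- near_fraction * rrt
  hit <- abs(Re(fid$samples)) >= lim | abs(Im(fid$samples)) >= lim
  fid$clipped <- any(hit)
  list(clipped = any(hit), indices = which(hit),
       fraction = mean(hit), fid = fid)
}

#' Estimate the ADC ceiling (RRT) from clipped FIDs
#'
#' A clipped channel shows a flat-topped plateau at the recorder's maximum.
#' For each FID and quadrature channel, runs of at least `min_run`
#' consecutive samples within `tol` (relative) of that channel's maximum
#' magnitude are taken as plateau; the RRT estimate is the median of all
#' plateau magnitudes. FIDs without a plateau (unclipped) are ignored.
#'
#' @param fids A [fid_record()] or list of them.
#' @param min_run Minimum plateau run length (default 4).
#' @param tol Relative tolerance defining the plateau (default 1e-3).
#' @return RRT estimate in a.u.
#' @export
estimate_rrt <- function(fids, min_run = 4L, tol = 1e-3) {
  if (inherits(fids, "fid_record")) fids <- list(fids)
  plateau <- numeric(0)
  for (fid in fids) {
    stopifnot(inherits(fid, "fid_record"))
    for (chan in list(Re(fid$samples), Im(fid$samples))) {
      a <- abs(chan)
      m <- max(a)
      if (m == 0) next
      near <- a >= (1 - tol) * m
      r <- rle(near)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_run
      for (j in which(keep)) plateau <- c(plateau, a[starts[j]:ends[j]])
    }
  }
  if (!length(plateau)) {
    stop("no clipped plateau found: RRT cannot be estimated from unclipped data",
         call. = FALSE)
  }
  stats::median(plateau)
}
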