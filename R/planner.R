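# Acquisition planning: scale a reference SNR(RG) curve to target flip
# angle / polarization / concentration, predict the FID amplitude against
# the ADC ceiling, and maximize SNR over (RG, alpha) on a masked grid.

#' Sample specification for planning
#'
#' @param nucleus A [nucleus()] object.
#' @param concentration Spin concentration in M (> 0): molecular
#'   concentration times `spins_per_molecule`.
#' @param polarization Polarization fraction in (0, 1]. Give the value
#'   directly for hyperpolarized samples, or compute it with
#'   [thermal_polarization()] via `field` and `temperature`.
#' @param field,temperature Used only when `polarization` is `NULL` to
#'   compute the thermal value.
#' @return An object of class `"sample_spec"`.
#' @examples
#' # 90 mM hyperpolarized 13C at 35% polarization
#' sample_spec(nucleus("13C"), concentration = 0.090, polarization = 0.35)
#' # thermally polarized water protons (111.02 M 1H at 9.4 T)
#' sample_spec(nucleus("1H"), concentration = 111.02,
#'             field = 9.4, temperature = 298)
#' @export
sample_spec <- function(nucleus, concentration, polarization = NULL,
                        field = NULL, temperature = 298) {
  stopifnot(inherits(nucleus, "nucleus"))
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be > 0 M", call. = FALSE)
  }
  if (is.null(polarization)) {
    if (is.null(field)) {
      stop("give polarization directly or a field for thermal polarization",
           call. = FALSE)
    }
    polarization <- thermal_polarization(nucleus, field, temperature)
  }
  if (polarization <= 0 || polarization > 1) {
    stop("polarization must be in (0, 1]", call. = FALSE)
  }
  structure(list(nucleus = nucleus, concentration = concentration,
                 polarization = polarization),
            class = "sample_spec")
}

#' Receiver model
#'
#' @param rg_min,rg_max Receiver gain bounds (e.g. 0.25 and 101).
#' @param rrt ADC ceiling (receiver range threshold), a.u. (> 0).
#' @param safety_factor Fraction of RRT used as the overflow limit
#'   \eqn{S_m = safety\_factor \times RRT}; default 1 (the exact overflow
#'   condition), 0.5 for the conservative half-range convention.
#' @param allowed_rg Optional vector of discretely settable gains.
#' @param gain_function Gain function f(RG); identity for a linear receiver.
#' @return An object of class `"receiver_model"`.
#' @export
receiver_model <- function(rg_min = 0.25, rg_max = 101, rrt,
                           safety_factor = 1, allowed_rg = NULL,
                           gain_function = identity) {
  if (rg_min <= 0 || rg_max <= rg_min) {
    stop("need 0 < rg_min < rg_max", call. = FALSE)
  }
  if (!is.numeric(rrt) || rrt <= 0) stop("rrt must be > 0", call. = FALSE)
  if (safety_factor <= 0 || safety_factor > 1) {
    stop("safety_factor must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(allowed_rg)) {
    allowed_rg <- sort(unique(allowed_rg))
    if (any(allowed_rg < rg_min) || any(allowed_rg > rg_max)) {
      stop("allowed_rg outside [rg_min, rg_max]", call. = FALSE)
    }
  }
  structure(list(rg_min = rg_min, rg_max = rg_max, rrt = rrt,
                 safety_factor = safety_factor, allowed_rg = allowed_rg,
                 gain_function = gain_function,
                 s_m = safety_factor * rrt),
            class = "receiver_model")
}

#' Constraints on the acquisition plan
#'
#' @param alpha_max Maximum flip angle in degrees, in (0, 90]. Small values
#'   preserve polarization in hyperpolarized experiments.
#' @param s_m_override Optional overflow limit in a.u., replacing the
#'   receiver's `safety_factor * rrt`.
#' @return An object of class `"constraint_spec"`.
#' @export
constraint_spec <- function(alpha_max = 90, s_m_override = NULL) {
  if (!is.numeric(alpha_max) || alpha_max <= 0 || alpha_max > 90) {
    stop("alpha_max must be in (0, 90] degrees", call. = FALSE)
  }
  if (!is.null(s_m_override) && s_m_override <= 0) {
    stop("s_m_override must be > 0", call. = FALSE)
  }
  structure(list(alpha_max = alpha_max, s_m_override = s_m_override),
            class = "constraint_spec")
}

.sin_deg <- function(deg) sinpi(deg / 180)

# sin(alpha)/sin(alpha_ref) * P/P_ref * C/C_ref
.scale_factor <- function(curve, sample, alpha) {
  .sin_deg(alpha) / .sin_deg(curve$alpha_ref) *
    sample$polarization / curve$p_ref *
    sample$concentration / curve$c_ref
}

#' Scale reference SNR to target conditions
#'
#' The calibrated SNR at reference flip angle, polarization and
#' concentration transfers to any other conditions through the linear
#' signal model:
#' \deqn{SNR(RG) = SNR_{ref}(RG) \cdot \frac{\sin\alpha}{\sin\alpha_{ref}}
#'       \cdot \frac{P}{P_{ref}} \cdot \frac{C}{C_{ref}}.}
#'
#' @param curve A [build_calibration()] curve.
#' @param sample A [sample_spec()].
#' @param alpha Flip angle in degrees, in (0, 90].
#' @param rg Receiver gain(s) within the calibrated range.
#' @return Predicted SNR.
#' @export
scale_snr <- function(curve, sample, alpha, rg) {
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(sample, "sample_spec"))
  if (any(alpha <= 0) || any(alpha > 90)) {
    stop("alpha must be in (0, 90] degrees", call. = FALSE)
  }
  interpolate_snr(curve, rg) * .scale_factor(curve, sample, alpha)
}

#' Predict the maximum FID amplitude
#'
#' Scales the calibrated FID-amplitude channel (the quantity that saturates
#' the ADC) to target conditions with the same
#' \eqn{\sin\alpha \cdot P \cdot C} factors as [scale_snr()]. When the
#' curve carries measured FID maxima they are interpolated in RG; otherwise
#' the linear-receiver form `slope_fid * rg * c_ref` is used.
#'
#' @inheritParams scale_snr
#' @return Predicted maximum FID magnitude, a.u.
#' @export
predict_fid_max <- function(curve, sample, alpha, rg) {
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(sample, "sample_spec"))
  if (any(alpha <= 0) || any(alpha > 90)) {
    stop("alpha must be in (0, 90] degrees", call. = FALSE)
  }
  .fid_max_ref(curve, rg) * .scale_factor(curve, sample, alpha)
}

#' Maximum clipping-free product sin(alpha) x RG
#'
#' For a linear receiver the predicted FID amplitude is proportional to
#' \eqn{\sin\alpha \cdot RG}, so the overflow condition reduces to a single
#' number: the largest product \eqn{k = \sin\alpha \cdot RG} for which the
#' FID stays at or below the limit \eqn{S_m}. It scales inversely with
#' polarization times concentration — dilution or lower polarization
#' relaxes the constraint proportionally.
#'
#' @param curve A [build_calibration()] curve with an FID-amplitude slope.
#' @param sample A [sample_spec()].
#' @param receiver A [receiver_model()] providing \eqn{S_m}.
#' @return The clipping product k (dimensionless).
#' @export
clipping_product <- function(curve, sample, receiver) {
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(sample, "sample_spec"),
            inherits(receiver, "receiver_model"))
  if (is.null(curve$slope_fid)) {
    stop("curve has no FID-amplitude slope; supply fid_max data", call. = FALSE)
  }
  pc <- sample$polarization * sample$concentration
  if (pc <= 0) stop("polarization x concentration must be > 0", call. = FALSE)
  # fid_max = slope_fid * rg * sin(alpha) * P * C / (sin(alpha_ref) * P_ref)
  per_unit <- curve$slope_fid * pc / (.sin_deg(curve$alpha_ref) * curve$p_ref)
  receiver$s_m / per_unit
}

#' Largest clipping-free flip angle at a given gain
#'
#' Inverts the clipping product: \eqn{\alpha_{lim} = \arcsin(\min(1, k/RG))}
#' in degrees, saturating at 90 degrees when the product never binds.
#'
#' @param k Clipping product from [clipping_product()] (> 0).
#' @param rg Receiver gain (> 0).
#' @return Flip-angle limit in degrees.
#' @examples
#' flip_angle_limit(4.14, 18)    # ~13.3 deg
#' flip_angle_limit(107.15, 101) # 90 deg
#' @export
flip_angle_limit <- function(k, rg) {
  if (any(k <= 0)) stop("k must be > 0", call. = FALSE)
  if (any(rg <= 0)) stop("rg must be > 0", call. = FALSE)
  asin(pmin(1, k / rg)) * 180 / pi
}

#' Maximize SNR over receiver gain and flip angle
#'
#' Grid realization of the constrained maximization
#' \deqn{SNR(RG, \alpha) \to \max, \quad signal \le S_m, \quad
#'       0 < \alpha \le \alpha_m \le 90^\circ:}
#' the SNR and FID-amplitude maps are evaluated on the (RG, alpha) grid,
#' cells whose predicted FID amplitude exceeds \eqn{S_m} are masked out,
#' and the argmax of the surviving SNR map is returned. Ties are broken
#' toward lower RG (less clipping risk), then lower alpha.
#'
#' @param curve A [build_calibration()] curve.
#' @param sample A [sample_spec()].
#' @param receiver A [receiver_model()].
#' @param constraints A [constraint_spec()].
#' @param alpha_step Flip-angle grid step in degrees (default 0.1).
#' @param n_rg Number of log-spaced RG grid points when the receiver has no
#'   discrete `allowed_rg` list (default 400).
#' @return An object of class `"plan_result"`: `rg_opt`, `alpha_opt`,
#'   `snr_pred`, `fid_max_pred`, `clip_margin` (fraction of \eqn{S_m}
#'   used), and `maps` (the full grids and overflow mask).
#' @export
optimize_acquisition <- function(curve, sample, receiver,
                                 constraints = constraint_spec(),
                                 alpha_step = 0.1, n_rg = 400L) {
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(sample, "sample_spec"),
            inherits(receiver, "receiver_model"),
            inherits(constraints, "constraint_spec"))
  s_m <- if (!is.null(constraints$s_m_override)) {
    constraints$s_m_override
  } else {
    receiver$s_m
  }
  lo <- max(receiver$rg_min, min(curve$points$rg))
  hi <- min(receiver$rg_max, max(curve$points$rg))
  if (lo >= hi) stop("receiver RG range does not overlap the calibration",
                     call. = FALSE)
  rg_grid <- if (!is.null(receiver$allowed_rg)) {
    r <- receiver$allowed_rg
    r[r >= lo & r <= hi]
  } else {
    g <- exp(seq(log(lo), log(hi), length.out = n_rg))
    g[1] <- lo; g[length(g)] <- hi   # guard against fp overshoot
    # include the measured knots so ties inside a snapped discontinuity
    # segment resolve to the measured gain itself
    k <- curve$points$rg
    sort(unique(c(g, k[k >= lo & k <= hi])))
  }
  if (!length(rg_grid)) stop("no settable RG within the calibrated range",
                             call. = FALSE)
  alpha_grid <- seq(alpha_step, constraints$alpha_max, by = alpha_step)
  if (!length(alpha_grid) ||
      alpha_grid[length(alpha_grid)] < constraints$alpha_max - 1e-12) {
    alpha_grid <- unique(c(alpha_grid, constraints$alpha_max))
  }

  base <- sample$polarization / curve$p_ref *
    sample$concentration / curve$c_ref / .sin_deg(curve$alpha_ref)
  snr_ref <- interpolate_snr(curve, rg_grid)
  fid_ref <- .fid_max_ref(curve, rg_grid)
  sin_a <- .sin_deg(alpha_grid)
  snr_map <- outer(snr_ref, sin_a) * base     # rows: rg, cols: alpha
  fid_map <- outer(fid_ref, sin_a) * base
  mask <- fid_map <= s_m

  if (!any(mask)) {
    i_min <- which.min(fid_map)
    ij <- arrayInd(i_min, dim(fid_map))
    stop(sprintf(
      paste0("infeasible plan: every (RG, alpha) cell clips; smallest ",
             "predicted FID max %.4g a.u. (at rg %.4g, alpha %.4g deg) ",
             "exceeds S_m = %.4g a.u."),
      fid_map[i_min], rg_grid[ij[1]], alpha_grid[ij[2]], s_m), call. = FALSE)
  }

  masked <- ifelse(mask, snr_map, -Inf)
  best <- max(masked)
  # tie-break: lower rg first, then lower alpha
  cand <- which(masked >= best * (1 - 1e-12) & is.finite(masked))
  ij <- arrayInd(cand, dim(masked))
  ord <- order(rg_grid[ij[, 1]], alpha_grid[ij[, 2]])
  pick <- ij[ord[1], ]
  rg_opt <- rg_grid[pick[1]]
  alpha_opt <- alpha_grid[pick[2]]
  fid_pred <- fid_map[pick[1], pick[2]]

  structure(
    list(rg_opt = rg_opt, alpha_opt = alpha_opt,
         snr_pred = snr_map[pick[1], pick[2]],
         fid_max_pred = fid_pred,
         clip_margin = fid_pred / s_m,
         s_m = s_m,
         maps = list(rg = rg_grid, alpha = alpha_grid,
                     snr = snr_map, fid_max = fid_map, allowed = mask)),
    class = "plan_result"
  )
}

#' @export
print.plan_result <- function(x, ...) {
  cat("<plan_result>\n")
  cat(sprintf("  optimal: RG = %.4g, alpha = %.4g deg\n", x$rg_opt, x$alpha_opt))
  cat(sprintf("  predicted SNR = %.6g\n", x$snr_pred))
  cat(sprintf("  predicted FID max = %.4g a.u. (%.1f%% of S_m = %.4g)\n",
              x$fid_max_pred, 100 * x$clip_margin, x$s_m))
  cat(sprintf("  grid: %d RG x %d alpha, %d%% feasible\n",
              length(x$maps$rg), length(x$maps$alpha),
              round(100 * mean(x$maps$allowed))))
  invisible(x)
}

#' Averaging acceleration from an SNR improvement
#'
#' SNR grows with the square root of the number of averaged transients, so
#' an SNR gained for free at acquisition reduces the averages needed for a
#' target SNR by the square of the ratio: a 50% improvement halves the
#' scan time, a 107% improvement cuts it 4.3-fold.
#'
#' @param snr_ratio Ratio of improved to baseline SNR (> 0).
#' @return Fold reduction in the number of averages (`snr_ratio^2`).
#' @export
averaging_acceleration <- function(snr_ratio) {
  if (any(snr_ratio <= 0)) stop("snr_ratio must be > 0", call. = FALSE)
  snr_ratio^2
}
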