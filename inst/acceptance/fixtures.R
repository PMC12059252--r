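# Randomized planning fixtures and an independent brute-force oracle,
# shared by the test suite and the acceptance script. Uses the current RNG
# stream; seed before calling.

# Random planning fixture: arbitrary positive SNR curve, linear FID
# channel, random sample and ceiling drawn so the overflow mask can bite.
random_fixture <- function() {
  n_pts <- sample(4:9, 1)
  rg <- sort(exp(stats::runif(n_pts, log(0.25), log(101))))
  pts <- data.frame(rg = rg,
                    signal_integral = stats::runif(n_pts, 10, 1000),
                    noise_rms = stats::runif(n_pts, 0.5, 5),
                    fid_max = stats::runif(1, 100, 2000) * rg,
                    n_averages = 1L)
  curve <- build_calibration(pts, nucleus("13C"), field = 9.4,
                             alpha_ref = stats::runif(1, 30, 90),
                             p_ref = stats::runif(1, 1e-6, 1e-4),
                             c_ref = stats::runif(1, 0.5, 2))
  sample <- sample_spec(nucleus("13C"),
                        concentration = stats::runif(1, 0.01, 1),
                        polarization = stats::runif(1, 0.05, 0.7))
  fid_lo <- predict_fid_max(curve, sample, 0.5, min(rg))
  fid_hi <- predict_fid_max(curve, sample, 90, max(rg))
  rrt <- exp(stats::runif(1, log(fid_lo * 2), log(fid_hi * 2)))
  receiver <- receiver_model(rg_min = min(rg), rg_max = max(rg), rrt = rrt)
  list(curve = curve, sample = sample, receiver = receiver,
       constraints = constraint_spec(alpha_max = sample(c(5, 10, 45, 90), 1)))
}

# Independent brute-force oracle for the constrained maximization:
# explicit per-cell loops, scalar interpolation with approx(), explicit
# discontinuity snapping and tie-breaking. Deliberately unvectorized.
brute_force_plan <- function(curve, sample, receiver, constraints,
                             alpha_step = 0.5, n_rg = 40L) {
  pts <- curve$points
  lo <- max(receiver$rg_min, min(pts$rg))
  hi <- min(receiver$rg_max, max(pts$rg))
  rg_grid <- exp(seq(log(lo), log(hi), length.out = n_rg))
  rg_grid[1] <- lo; rg_grid[n_rg] <- hi
  rg_grid <- sort(unique(c(rg_grid, pts$rg[pts$rg >= lo & pts$rg <= hi])))
  alpha_grid <- seq(alpha_step, constraints$alpha_max, by = alpha_step)
  if (alpha_grid[length(alpha_grid)] < constraints$alpha_max - 1e-12) {
    alpha_grid <- c(alpha_grid, constraints$alpha_max)
  }
  s_m <- receiver$s_m
  interp1 <- function(x, y, rg, snap) {
    v <- stats::approx(x, y, xout = rg)$y
    if (snap) {
      for (d in curve$disc_rg) {
        i <- match(d, x)
        if (!is.na(i) && i < length(x) && rg > x[i] && rg < x[i + 1]) {
          v <- if (rg - x[i] <= x[i + 1] - rg) y[i] else y[i + 1]
        }
      }
    }
    v
  }
  scale_of <- function(alpha) {
    sin(alpha * pi / 180) / sin(curve$alpha_ref * pi / 180) *
      sample$polarization / curve$p_ref *
      sample$concentration / curve$c_ref
  }
  best <- -Inf; best_rg <- NA; best_alpha <- NA; best_fid <- NA
  for (rg in rg_grid) {
    snr_ref <- interp1(pts$rg, pts$snr, rg, snap = TRUE)
    fid_ref <- interp1(pts$rg, pts$fid_max, rg, snap = FALSE)
    for (alpha in alpha_grid) {
      fid <- fid_ref * scale_of(alpha)
      if (fid > s_m) next
      snr <- snr_ref * scale_of(alpha)
      # ascending rg then alpha loops: the first maximizer found already
      # carries the lowest rg, then the lowest alpha, among ties
      if (snr > best * (1 + 1e-12)) {
        best <- snr; best_rg <- rg; best_alpha <- alpha; best_fid <- fid
      }
    }
  }
  if (!is.finite(best)) stop("oracle: no feasible cell")
  list(rg_opt = best_rg, alpha_opt = best_alpha, snr_pred = best,
       fid_max_pred = best_fid)
}
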