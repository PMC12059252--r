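# Acquisition parameters shared by the spectral tests: a long acquisition
# relative to the linewidth so integral statistics are well conditioned.
acq <- list(n = 4096L, dwell = 1e-4, t2 = 0.05, off = 200)
lw <- 1 / (pi * acq$t2)

test_that("the spectrum of a decaying exponential peaks at its offset", {
  fid <- synth_fid(1, acq$off, acq$t2, acq$n, acq$dwell)
  sp <- to_spectrum(fid)
  expect_equal(sp$freq_axis[which.max(abs(sp$values))], acq$off,
               tolerance = 1 / (acq$n * acq$dwell))  # within one bin
  # axis spans +-1/(2 dwell)
  expect_lt(max(sp$freq_axis), 1 / (2 * acq$dwell))
  expect_gte(min(sp$freq_axis), -1 / (2 * acq$dwell))
})

test_that("an all-zero FID transforms to an all-zero spectrum", {
  fid <- fid_record(complex(real = numeric(32)), dwell = 1e-4)
  sp <- to_spectrum(fid)
  expect_equal(max(abs(sp$values)), 0)
})

test_that("time- and frequency-domain energies agree (Parseval)", {
  set.seed(7)
  x <- complex(real = rnorm(256), imaginary = rnorm(256))
  fid <- fid_record(x, dwell = 2e-4)
  sp <- to_spectrum(fid)
  e_time <- sum(Mod(x)^2) * fid$dwell
  df <- 1 / (256 * fid$dwell)
  e_freq <- sum(Mod(sp$values)^2) * df
  expect_equal(e_freq, e_time, tolerance = 1e-12)
})

test_that("peak integral matches the analytic Lorentzian fraction", {
  # over +-20 FWHM an absorption Lorentzian holds arctan(40)/(pi/2) = 98.4%
  # of its full area a/2 (one-sided decay of initial amplitude a)
  a <- 2
  fid <- synth_fid(a, acq$off, acq$t2, 16384L, acq$dwell)
  sp <- to_spectrum(fid)
  part <- integrate_peak(sp, acq$off + c(-20, 20) * lw)
  frac <- atan(2 * pi * acq$t2 * 20 * lw) / (pi / 2)
  expect_equal(frac, 0.984, tolerance = 1e-3)
  expect_equal(part / (a / 2), frac, tolerance = 0.01)
})

test_that("integration is linear in amplitude and zero off-peak", {
  region <- acq$off + c(-20, 20) * lw
  sp1 <- to_spectrum(synth_fid(1, acq$off, acq$t2, acq$n, acq$dwell))
  sp2 <- to_spectrum(synth_fid(2, acq$off, acq$t2, acq$n, acq$dwell))
  expect_equal(integrate_peak(sp2, region), 2 * integrate_peak(sp1, region),
               tolerance = 1e-9)
  empty <- integrate_peak(sp1, c(-450, -250))
  expect_lt(abs(empty), 1e-3 * integrate_peak(sp1, region))
  expect_error(integrate_peak(sp1, c(100, 50)), "increasing")
  expect_error(integrate_peak(sp1, c(0, 1e6)), "outside")
})

test_that("integrals are invariant to zero filling within 1%", {
  region <- acq$off + c(-20, 20) * lw
  fid <- synth_fid(1, acq$off, acq$t2, acq$n, acq$dwell)
  i1 <- integrate_peak(to_spectrum(fid, 1L), region)
  i2 <- integrate_peak(to_spectrum(fid, 2L), region)
  i4 <- integrate_peak(to_spectrum(fid, 4L), region)
  expect_equal(i2 / i1, 1, tolerance = 0.01)
  expect_equal(i4 / i1, 1, tolerance = 0.01)
  expect_error(to_spectrum(fid, 0L), "zero_fill_factor")
})

test_that("phase correction preserves magnitude and restores absorption", {
  fid <- synth_fid(1, 0, acq$t2, acq$n, acq$dwell)  # on resonance
  sp <- to_spectrum(fid)
  expect_equal(phase_correct(sp, 0, 0)$values, sp$values)
  ph <- phase_correct(sp, 53, -120)
  expect_equal(Mod(ph$values), Mod(sp$values), tolerance = 1e-12)
  # dephase by a known 37 degrees, then undo it at the peak
  twisted <- phase_correct(sp, 37, 0)
  restored <- phase_correct(twisted, -37, 0)
  ipk <- which.max(Mod(restored$values))
  expect_equal(Im(restored$values)[ipk], Im(sp$values)[ipk], tolerance = 1e-9)
  expect_lt(abs(Im(restored$values)[ipk]), 1e-6 * Re(restored$values)[ipk])
})

test_that("noise RMS recovers the generating sigma and removes linear baselines", {
  set.seed(11)
  n <- 8192
  f <- seq(-500, 500, length.out = n)
  sigma <- 3.7
  sp <- spectrum_record(f, complex(real = rnorm(n, 0, sigma)))
  expect_equal(estimate_noise(sp, region = c(-400, 400)), sigma,
               tolerance = 0.05)
  # pure linear ramp has zero residual after detrending
  ramp <- spectrum_record(f, complex(real = 5 + 0.01 * f))
  expect_lt(estimate_noise(ramp, region = c(-400, 400)), 1e-8)
})

test_that("automatic noise window avoids the peak region", {
  fid <- synth_fid(100, acq$off, acq$t2, acq$n, acq$dwell,
                   noise = noise_model(0, 0.01), seed = 5)
  sp <- to_spectrum(fid)
  peak <- acq$off + c(-20, 20) * lw
  auto <- estimate_noise(sp, peak_regions = list(peak))
  ref <- estimate_noise(sp, region = c(-2000, -500))
  expect_equal(auto, ref, tolerance = 0.5)
  expect_lt(auto, 0.05 * max(Re(sp$values)))  # far below the peak height
  expect_error(estimate_noise(sp, region = c(acq$off - 5, acq$off + 5),
                              peak_regions = list(peak)),
               "overlaps")
})

test_that("SNR is scale invariant and rejects zero noise", {
  fid <- synth_fid(50, acq$off, acq$t2, acq$n, acq$dwell,
                   noise = noise_model(0, 0.05), seed = 9)
  sp <- to_spectrum(fid)
  peak <- acq$off + c(-20, 20) * lw
  s1 <- snr_of(sp, peak)
  sp2 <- sp; sp2$values <- sp2$values * 7.3
  expect_equal(snr_of(sp2, peak), s1, tolerance = 1e-9)
  # an exactly noise-free spectrum has zero RMS off the peak: undefined SNR
  v <- numeric(512); v[250:260] <- 100
  clean <- spectrum_record(seq(-500, 500, length.out = 512), complex(real = v))
  expect_error(snr_of(clean, c(-20, 20)), "undefined SNR")
})

test_that("estimated SNR tracks the generator across two decades", {
  # long acquisition, narrow integral: integral statistics support +-10%
  set.seed(21)
  n <- 16384L; dwell <- 1e-3; t2 <- 1; off <- 200
  w <- 1 / (pi * t2)
  pk <- c(off - w, off + w)
  unit <- integrate_peak(to_spectrum(synth_fid(1, off, t2, n, dwell)), pk)
  sig_f <- dwell * sqrt(n)
  ok <- 0; total <- 0
  for (target in c(5, 50, 500)) {
    a <- target * sig_f / unit
    for (r in 1:25) {
      fid <- synth_fid(a, off, t2, n, dwell, noise = noise_model(0, 1))
      est <- snr_of(to_spectrum(fid), pk)
      total <- total + 1
      ok <- ok + (abs(est / target - 1) < 0.1)
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("clipping is judged per quadrature channel with the ceiling inclusive", {
  fid <- synth_fid(0.5, 0, acq$t2, acq$n, acq$dwell)
  expect_false(detect_clipping(fid, rrt = 1)$clipped)
  # driven 1.2x over the ceiling: flagged, first index at the start
  over <- synth_fid(1.2, 0, acq$t2, acq$n, acq$dwell, rrt = 1)
  rep <- detect_clipping(over, rrt = 1, near_fraction = 1)
  expect_true(rep$clipped)
  expect_equal(min(rep$indices), 1L)
  # boundary counts as clipped
  exact <- fid_record(complex(real = c(1, numeric(31))), dwell = 1e-4)
  expect_true(detect_clipping(exact, rrt = 1, near_fraction = 1)$clipped)
  expect_error(detect_clipping(fid, rrt = -1), "rrt")
})

test_that("clipping never fires below 90% of the ceiling", {
  set.seed(31)
  for (r in 1:20) {
    a <- runif(1, 0.1, 0.9)
    fid <- synth_fid(a, runif(1, -500, 500), acq$t2, 256L, acq$dwell)
    expect_false(detect_clipping(fid, rrt = 1)$clipped)
  }
})

test_that("RRT estimation recovers the ADC ceiling exactly from clipped FIDs", {
  ceiling <- 1.24e9
  clipped <- synth_fid(1.5 * ceiling, 0, acq$t2, acq$n, acq$dwell,
                       rrt = ceiling)
  expect_equal(estimate_rrt(clipped), ceiling)
  expect_true(clipped$clipped)
  # unclipped decay: no plateau, no estimate
  free <- synth_fid(0.5 * ceiling, acq$off, acq$t2, acq$n, acq$dwell)
  expect_error(estimate_rrt(free), "no clipped plateau")
  # mixed input: unclipped records are ignored
  expect_equal(estimate_rrt(list(free, clipped)), ceiling)
})
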