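test_that("SNR scaling is the identity at reference conditions and linear in P and C", {
  cv <- dip_curve()
  ref <- sample_spec(nucleus("13C"), concentration = cv$c_ref,
                     polarization = cv$p_ref)
  for (rg in c(0.25, 4, 18, 101)) {
    expect_equal(scale_snr(cv, ref, cv$alpha_ref, rg), interpolate_snr(cv, rg),
                 tolerance = 1e-12)
  }
  dbl_c <- sample_spec(nucleus("13C"), 2 * cv$c_ref, polarization = cv$p_ref)
  half_p <- sample_spec(nucleus("13C"), cv$c_ref,
                        polarization = cv$p_ref / 2)
  expect_equal(scale_snr(cv, dbl_c, 90, 18), 2 * interpolate_snr(cv, 18),
               tolerance = 1e-12)
  expect_equal(scale_snr(cv, half_p, 90, 18), interpolate_snr(cv, 18) / 2,
               tolerance = 1e-12)
})

test_that("scaling arithmetic: double polarization at 30 degrees from a 90-degree reference", {
  # SNR_ref(18) = 60, P = 2 P_ref, alpha 30 vs 90: 60 * 0.5 * 2 = 60
  pts <- data.frame(rg = c(1, 18, 101), signal_integral = c(10, 60, 90),
                    noise_rms = 1, fid_max = c(10, 180, 1010),
                    n_averages = 1L)
  cv <- build_calibration(pts, nucleus("13C"), 9.4, 90, 0.1, 1)
  s <- sample_spec(nucleus("13C"), 1, polarization = 0.2)
  expect_equal(scale_snr(cv, s, 30, 18), 60 * 0.5 * 2, tolerance = 1e-12)
})

test_that("FID-amplitude prediction matches the measured channel and the sine law", {
  cv <- linear_curve(slope_fid = 5000)
  ref <- sample_spec(nucleus("13C"), cv$c_ref, polarization = cv$p_ref)
  expect_equal(predict_fid_max(cv, ref, 90, 18), 5000 * 18 * cv$c_ref,
               tolerance = 1e-9)
  # sin(alpha) factor drives the prediction to zero with the angle
  small <- predict_fid_max(cv, ref, 0.01, 18)
  expect_lt(small, 2e-4 * predict_fid_max(cv, ref, 90, 18))
  # arbitrary conditions against the closed linear form
  s <- sample_spec(nucleus("13C"), 0.4, polarization = 0.35)
  got <- predict_fid_max(cv, s, 25, 40)
  want <- 5000 * 40 * 0.4 * sin(25 * pi / 180) * (0.35 / cv$p_ref)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("clipping product closes with the overflow limit and scales inversely with P*C", {
  # per unit product slope_fid * C * (P/P_ref) / sin(alpha_ref) = 1e8,
  # S_m = 1.24e9: k = 12.4
  cv <- linear_curve(slope_fid = 1e8)
  s <- sample_spec(nucleus("13C"), 1, polarization = cv$p_ref)
  rec <- receiver_model(0.25, 101, rrt = 1.24e9)
  expect_equal(clipping_product(cv, s, rec), 12.4, tolerance = 1e-9)
  s2 <- sample_spec(nucleus("13C"), 1, polarization = 2 * cv$p_ref)
  expect_equal(clipping_product(cv, s2, rec), 6.2, tolerance = 1e-9)
  shalf <- sample_spec(nucleus("13C"), 0.5, polarization = cv$p_ref)
  expect_equal(clipping_product(cv, shalf, rec), 24.8, tolerance = 1e-9)
})

test_that("flip-angle limit inverts the clipping product and saturates at 90", {
  expect_equal(flip_angle_limit(4.14, 18), asin(4.14 / 18) * 180 / pi)
  expect_equal(round(flip_angle_limit(4.14, 18)), 13)
  expect_equal(flip_angle_limit(2.07, 18), 6.6, tolerance = 0.01)
  expect_equal(flip_angle_limit(107.15, 101), 90)
  expect_equal(flip_angle_limit(20, 20), 90)
  expect_equal(flip_angle_limit(21, 20), 90)
  expect_error(flip_angle_limit(-1, 18), "k must")
})

test_that("clipping product, flip-angle limit and FID prediction close exactly", {
  cv <- linear_curve(slope_fid = 1e5)
  s <- sample_spec(nucleus("13C"), 0.09, polarization = 0.35)
  rec <- receiver_model(0.25, 101, rrt = 1.24e9)
  k <- clipping_product(cv, s, rec)
  expect_gt(k, 0.25); expect_lt(k, 101)   # interior of the gain range
  for (rg in c(k * 1.01, 2 * k, 18, 60, 101)) {
    lim <- flip_angle_limit(k, rg)
    if (lim >= 90) next  # only interior limits close
    expect_equal(predict_fid_max(cv, s, lim, rg) / rec$s_m, 1,
                 tolerance = 1e-9)
  }
})

test_that("halving concentration doubles the product and raises the angle limit", {
  cv <- linear_curve(slope_fid = 3.3e7)
  rec <- receiver_model(0.25, 101, rrt = 1.24e9)
  full <- sample_spec(nucleus("13C"), 0.09, polarization = 0.35)
  half <- sample_spec(nucleus("13C"), 0.045, polarization = 0.35)
  k1 <- clipping_product(cv, full, rec)
  k2 <- clipping_product(cv, half, rec)
  expect_equal(k2, 2 * k1, tolerance = 1e-12)
  expect_gt(flip_angle_limit(k2, 18), flip_angle_limit(k1, 18))
  # the sine inverts: sin doubles as long as both limits are interior
  expect_equal(sin(flip_angle_limit(k2, 18) * pi / 180),
               2 * sin(flip_angle_limit(k1, 18) * pi / 180),
               tolerance = 1e-12)
})

test_that("with monotone SNR and no binding constraint the plan sits at the corner", {
  cv <- linear_curve(slope_fid = 1)   # tiny FID channel: never clips
  s <- sample_spec(nucleus("13C"), 1, polarization = cv$p_ref)
  rec <- receiver_model(0.25, 101, rrt = 1e12)
  plan <- optimize_acquisition(cv, s, rec, constraint_spec(alpha_max = 30))
  expect_equal(plan$rg_opt, 101)
  expect_equal(plan$alpha_opt, 30)
  expect_lte(plan$fid_max_pred, rec$s_m)
})

test_that("a fully clipped grid raises an infeasible-plan error naming the best cell", {
  cv <- linear_curve(slope_fid = 1e8)
  s <- sample_spec(nucleus("13C"), 1, polarization = 1)
  rec <- receiver_model(0.25, 101, rrt = 1)
  expect_error(optimize_acquisition(cv, s, rec, constraint_spec(5)),
               "infeasible plan.*smallest predicted FID")
})

test_that("the grid argmax agrees with an exhaustive brute-force scan", {
  set.seed(1234)
  for (rep in 1:8) {
    fx <- random_fixture()
    oracle <- brute_force_plan(fx$curve, fx$sample, fx$receiver,
                               fx$constraints, alpha_step = 0.5, n_rg = 40L)
    plan <- optimize_acquisition(fx$curve, fx$sample, fx$receiver,
                                 fx$constraints, alpha_step = 0.5, n_rg = 40L)
    expect_equal(plan$rg_opt, oracle$rg_opt, tolerance = 1e-12)
    expect_equal(plan$alpha_opt, oracle$alpha_opt, tolerance = 1e-12)
    expect_equal(plan$snr_pred, oracle$snr_pred, tolerance = 1e-9)
  }
})

test_that("no plan ever exceeds the overflow limit", {
  set.seed(555)
  for (rep in 1:50) {
    fx <- random_fixture()
    plan <- tryCatch(
      optimize_acquisition(fx$curve, fx$sample, fx$receiver, fx$constraints,
                           alpha_step = 1, n_rg = 60L),
      error = function(e) NULL)  # infeasible fixtures are legitimate
    if (is.null(plan)) next
    expect_lte(plan$fid_max_pred, fx$receiver$s_m)
    expect_true(plan$rg_opt >= fx$receiver$rg_min - 1e-9)
    expect_true(plan$rg_opt <= fx$receiver$rg_max + 1e-9)
    expect_lte(plan$alpha_opt, fx$constraints$alpha_max)
  }
})

test_that("along an iso-product boundary the plan maximizes flip angle first", {
  # RG-independent noise and linear gain: SNR depends only on sin(a)*RG,
  # so on the clipping boundary the optimizer should spend the product on
  # the angle (lowest RG), not the gain
  cv <- linear_curve(slope_fid = 1e7)
  s <- sample_spec(nucleus("13C"), 1, polarization = cv$p_ref)
  # k = sin(a)*rg <= 10; (rg 10, 90 deg) and (rg 20, 30 deg) both achieve it
  rec <- receiver_model(1, 101, rrt = 1e8, allowed_rg = c(5, 10, 20, 50))
  k <- clipping_product(cv, s, rec)
  expect_equal(k, 10, tolerance = 1e-9)
  plan <- optimize_acquisition(cv, s, rec, constraint_spec(alpha_max = 90),
                               alpha_step = 0.1)
  expect_equal(plan$alpha_opt, 90)
  expect_equal(plan$rg_opt, 10)
})

test_that("SNR improvements translate to quadratic averaging acceleration", {
  expect_equal(averaging_acceleration(1), 1)
  expect_equal(averaging_acceleration(2.07), 4.2849)
  expect_equal(round(averaging_acceleration(2.07), 1), 4.3)
  expect_equal(averaging_acceleration(1.5), 2.25)
  expect_gte(averaging_acceleration(1.5), 2)
  expect_error(averaging_acceleration(0), "snr_ratio")
})
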