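# Fixtures built in code: calibration tables and curves.
# random_fixture() and brute_force_plan() are shared with the acceptance
# script and ship with the installed package.
fixtures_src <- system.file("acceptance", "fixtures.R", package = "rgplan")
if (!nzchar(fixtures_src)) {
  fixtures_src <- testthat::test_path("..", "..", "inst", "acceptance",
                                      "fixtures.R")
}
source(fixtures_src)

# Calibration table for a perfectly linear receiver with RG-independent
# noise: snr is proportional to rg, fid_max = slope_fid * rg * c_ref.
linear_points <- function(rg = c(0.25, 0.5, 1, 2, 4, 8, 18, 36, 72, 101),
                          slope = 1000, slope_fid = 5000, c_ref = 1,
                          noise = 2) {
  data.frame(rg = rg,
             signal_integral = slope * rg * c_ref,
             noise_rms = noise,
             fid_max = slope_fid * rg * c_ref,
             n_averages = 1L)
}

linear_curve <- function(..., c_ref = 1, alpha_ref = 90, p_ref = 1e-5) {
  build_calibration(linear_points(..., c_ref = c_ref), nucleus("13C"),
                    field = 9.4, alpha_ref = alpha_ref, p_ref = p_ref,
                    c_ref = c_ref)
}

# Curve emulating the level-plan dip: SNR saturates by rg ~ 18, drops 40%
# between 18 and 20.2, then recovers slowly.
dip_points <- function(rg = c(0.25, 0.5, 1, 2, 4, 8, 12, 18, 20.2, 25.1,
                              36, 50.8, 72, 101),
                       nm = receiver_preset("dip")$noise,
                       slope = 1000, c_ref = 1) {
  sig <- slope * rg * c_ref
  data.frame(rg = rg, signal_integral = sig,
             noise_rms = noise_sigma(nm, rg) * slope / 1000,
             fid_max = 5 * sig, n_averages = 1L)
}

dip_curve <- function(..., c_ref = 1) {
  build_calibration(dip_points(..., c_ref = c_ref), nucleus("13C"),
                    field = 9.4, alpha_ref = 90, p_ref = 1e-5, c_ref = c_ref)
}

# Gain list used by the simulated dip-preset sweeps.
sweep_rg_list <- c(0.25, 0.5, 1, 2, 4, 8, 12, 18, 20.2, 25.1, 36, 50.8,
                   72, 101)
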