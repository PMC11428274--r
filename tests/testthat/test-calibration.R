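# Calibration estimators against the seeded generators: the two-length
# DNA-ruler focal shift, the Fabry-Perot fringe estimator, the iterative
# calibration loop, and angular-PSD stiffness recovery.

p_short <- wlc_params(6546)
p_long <- wlc_params(11516)

test_that("noise-free two-length ruler inverts the generator exactly", {
  cfg <- synthetic_config(seed = 3, anchor_offset_sd_nm = 0,
                          surface_zero_sd_nm = 0, force_noise_sd_pN = 0)
  ts <- gen_stretch_trace(cfg, 6546)
  tl <- gen_stretch_trace(cfg, 11516)
  est <- dna_ruler_focal_shift(ts, tl, p_short, p_long)
  expect_equal(est$fs, cfg$fs_true, tolerance = 1e-3)
  expect_error(dna_ruler_focal_shift(ts, ts, p_short, p_short), "distinct")
})

test_that("anchor offsets bias the single-length estimate but not the ruler", {
  biases_single <- biases_pair <- numeric(12)
  for (i in seq_along(biases_single)) {
    cfg <- synthetic_config(seed = 100 + i, force_noise_sd_pN = 0)
    ts <- gen_stretch_trace(cfg, 6546)
    tl <- gen_stretch_trace(cfg, 11516)
    biases_single[i] <-
      dna_ruler_focal_shift_single(ts, p_short)$fs - cfg$fs_true
    biases_pair[i] <-
      dna_ruler_focal_shift(ts, tl, p_short, p_long)$fs - cfg$fs_true
  }
  # offsets of the 20-nm class on a ~2.2-um molecule: percent-level bias
  # spread for the single-length variant, canceled by the difference method
  expect_gt(stats::sd(biases_single), 5e-3)
  expect_lt(max(abs(biases_pair)), 1e-3)
  expect_gt(stats::sd(biases_single), 3 * stats::sd(biases_pair))
})

test_that("ruler is invariant to a common zsurf offset and uses only 20-pN crossings", {
  cfg <- synthetic_config(seed = 5)
  ts <- gen_stretch_trace(cfg, 6546)
  tl <- gen_stretch_trace(cfg, 11516)
  est0 <- dna_ruler_focal_shift(ts, tl, p_short, p_long)
  ts$zsurf_nm <- ts$zsurf_nm + 750
  tl$zsurf_nm <- tl$zsurf_nm + 750
  est1 <- dna_ruler_focal_shift(ts, tl, p_short, p_long)
  expect_equal(est1$fs, est0$fs, tolerance = 1e-12)
  # a trace that never reaches the reference force errors out
  tshort <- ts[ts$force_pN < 10, ]
  expect_error(dna_ruler_focal_shift(tshort, tl, p_short, p_long),
               "never reaches")
})

test_that("Fabry-Perot estimator recovers the generator fringe frequency", {
  cfg <- synthetic_config(seed = 8)
  fr <- gen_fringe_trace(cfg)
  est <- fabry_perot_focal_shift(fr)
  expect_equal(est$fs, cfg$fs_true, tolerance = 0.005)
  # at fs = 1 the period is the plane-wave half wavelength in water
  cfg1 <- synthetic_config(seed = 9, fs_true = 1)
  est1 <- fabry_perot_focal_shift(gen_fringe_trace(cfg1))
  expect_equal(est1$period_nm, 1064 / (2 * 1.326), tolerance = 0.005)
  # constant signal: no dominant fringe
  flat <- data.frame(zsurf_nm = seq(0, 3000, 5), signal = 2)
  expect_error(fabry_perot_focal_shift(flat), "dominant|period")
})

test_that("ruler and Fabry-Perot agree on data from one ground truth", {
  cfg <- synthetic_config(seed = 21)
  ts <- gen_stretch_trace(cfg, 6546)
  tl <- gen_stretch_trace(cfg, 11516)
  r <- dna_ruler_focal_shift(ts, tl, p_short, p_long)
  f <- fabry_perot_focal_shift(gen_fringe_trace(cfg))
  expect_lt(abs(r$fs - f$fs), 2 * sqrt(r$se^2 + f$se^2) + 0.02)
})

test_that("iterative calibration converges to the ground truth from fs = 1", {
  cfg <- synthetic_config(seed = 42, force_noise_sd_pN = 0)
  ts <- gen_stretch_trace(cfg, 6546, fs_instrument = 1)
  tl <- gen_stretch_trace(cfg, 11516, fs_instrument = 1)
  it <- iterate_fs_calibration(ts, tl, p_short, p_long, fs_init = 1)
  direct <- dna_ruler_focal_shift(
    gen_stretch_trace(cfg, 6546), gen_stretch_trace(cfg, 11516),
    p_short, p_long)
  # converges to the perfectly-calibrated estimate, and fast
  expect_equal(it$fs, direct$fs, tolerance = 2e-3)
  expect_lte(it$iterations, 6)
  # monotone approach after the first step on noiseless data
  steps <- abs(diff(it$history))
  expect_true(all(diff(steps) <= 1e-12))
  # starting at the truth is a fixed point
  it0 <- iterate_fs_calibration(ts, tl, p_short, p_long,
                                fs_init = direct$fs)
  expect_equal(it0$iterations, 1)
})

test_that("angular PSD calibration recovers the generator stiffness", {
  cfg <- synthetic_config(seed = 13)
  ou <- gen_angular_series(cfg)
  # exact-discretization equipartition
  expect_equal(stats::var(ou$theta_rad), cfg$kT / cfg$kappa_theta_pNnm,
               tolerance = 0.03)
  est <- angular_psd_stiffness(ou, cfg$gamma_theta_pNnms, cfg$kT)
  expect_equal(est$kappa_theta, cfg$kappa_theta_pNnm, tolerance = 0.05)
  expect_equal(est$kappa_equipartition, cfg$kappa_theta_pNnm,
               tolerance = 0.03)
  # doubling the stiffness doubles the fitted corner frequency
  cfg2 <- synthetic_config(seed = 13,
                           kappa_theta_pNnm = 2 * cfg$kappa_theta_pNnm)
  est2 <- angular_psd_stiffness(gen_angular_series(cfg2),
                                cfg$gamma_theta_pNnms, cfg$kT)
  expect_equal(est2$f_corner_Hz / est$f_corner_Hz, 2, tolerance = 0.1)
})

test_that("white noise is rejected by the corner-frequency band check", {
  wn <- data.frame(time_s = (0:49999) / 1e4,
                   theta_rad = aotrap:::with_seed(1, stats::rnorm(50000, 0, 0.05)))
  expect_error(angular_psd_stiffness(wn, gamma_theta = 0.85),
               "corner frequency")
})
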