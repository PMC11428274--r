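# Generator contracts: seeding, noise-free limits, and the statistical
# structure the estimators assume.

test_that("generators are bit-reproducible under the same seed", {
  a <- gen_stretch_trace(synthetic_config(seed = 4), 6546)
  b <- gen_stretch_trace(synthetic_config(seed = 4), 6546)
  expect_identical(a, b)
  expect_false(identical(
    a, gen_stretch_trace(synthetic_config(seed = 5), 6546)))
  o1 <- gen_angular_series(synthetic_config(seed = 4,
                                            angular_duration_s = 2))
  o2 <- gen_angular_series(synthetic_config(seed = 4,
                                            angular_duration_s = 2))
  expect_identical(o1, o2)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); x1 <- stats::rnorm(1)
  set.seed(99)
  invisible(gen_fringe_trace(synthetic_config(seed = 7)))
  x2 <- stats::rnorm(1)
  expect_identical(x1, x2)
})

test_that("noise-free, offset-free trace at fs = 1 is the pure WLC curve", {
  cfg <- synthetic_config(seed = 2, fs_true = 1, anchor_offset_sd_nm = 0,
                          surface_zero_sd_nm = 0, force_noise_sd_pN = 0)
  tr <- gen_stretch_trace(cfg, 6546)
  p <- wlc_params(6546)
  taut <- tr$force_pN > 0.5
  x_model <- wlc_extension(tr$force_pN[taut], p)
  expect_equal(x_model + tr$zcyl_nm[taut], tr$zsurf_nm[taut],
               tolerance = 1e-6)
})

test_that("Ornstein-Uhlenbeck record satisfies equipartition at any step", {
  for (rate in c(2000, 10000)) {
    cfg <- synthetic_config(seed = 31, angular_rate_Hz = rate,
                            angular_duration_s = 40)
    ou <- gen_angular_series(cfg)
    expect_equal(stats::var(ou$theta_rad),
                 cfg$kT / cfg$kappa_theta_pNnm, tolerance = 0.03)
  }
})

test_that("fringe trace at fs = 1 has the half-wavelength period in water", {
  cfg <- synthetic_config(seed = 37, fs_true = 1, fringe_snr = 1e9)
  fr <- gen_fringe_trace(cfg)
  est <- fabry_perot_focal_shift(fr)
  expect_equal(est$period_nm, 401.2, tolerance = 1e-3)
})

test_that("estimator bias is below one standard error across replicates", {
  n_rep <- 30
  p1 <- wlc_params(6546); p2 <- wlc_params(11516)
  fs_hat <- vapply(seq_len(n_rep), function(i) {
    cfg <- synthetic_config(seed = 5000 + i)
    dna_ruler_focal_shift(gen_stretch_trace(cfg, 6546),
                          gen_stretch_trace(cfg, 11516), p1, p2)$fs
  }, numeric(1))
  expect_lt(abs(mean(fs_hat) - 0.829),
            stats::sd(fs_hat) / sqrt(n_rep) * 3)
})
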