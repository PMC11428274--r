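# Constant-force DNA twisting analysis: two-segment recovery, mirror
# symmetry, and the no-buckling path.

test_that("twist analysis recovers the generator parameters", {
  cfg <- synthetic_config(seed = 17)
  tw <- gen_twist_trace(cfg)
  truth <- attr(tw, "truth")
  fit <- twist_analysis(tw)
  expect_true(fit$buckled)
  expect_equal(fit$torque_slope_pNnm_per_turn, truth$torque_slope,
               tolerance = 0.05)
  expect_equal(fit$buckling_turn, truth$buckling_turn, tolerance = 0.05)
  expect_equal(fit$plateau_torque_pNnm, truth$plateau_torque,
               tolerance = 0.05)
  expect_equal(fit$extension_slope_nm_per_turn, truth$extension_slope,
               tolerance = 0.05)
  # extension is flat before buckling
  expect_lt(abs(fit$extension_pre_slope_nm_per_turn),
            0.05 * abs(truth$extension_slope))
})

test_that("noise-free trace is recovered to the breakpoint grid resolution", {
  cfg <- synthetic_config(seed = 19, twist_torque_sd_pNnm = 0,
                          twist_extension_sd_nm = 0)
  tw <- gen_twist_trace(cfg)
  truth <- attr(tw, "truth")
  fit <- twist_analysis(tw, smoothing_s = 0)
  expect_equal(fit$buckling_turn, truth$buckling_turn, tolerance = 0.3)
  expect_equal(fit$plateau_torque_pNnm, truth$plateau_torque,
               tolerance = 1e-2)
})

test_that("plateau estimate is invariant under the mirrored turn convention", {
  cfg <- synthetic_config(seed = 23)
  tw <- gen_twist_trace(cfg)
  fit <- twist_analysis(tw)
  mir <- tw
  mir$turns <- -mir$turns
  mir$torque_pNnm <- -mir$torque_pNnm
  attr(mir, "rate_Hz") <- attr(tw, "rate_Hz")
  fit_m <- twist_analysis(mir)
  expect_equal(abs(fit_m$plateau_torque_pNnm),
               abs(fit$plateau_torque_pNnm), tolerance = 1e-6)
  expect_equal(fit_m$buckling_turn, fit$buckling_turn, tolerance = 1e-6)
  expect_equal(fit_m$orientation, -1)
})

test_that("a torsionally linear trace reports no buckling", {
  cfg <- synthetic_config(seed = 29, buckling_turn = 1000)
  tw <- gen_twist_trace(cfg, n_turns = 40)   # never reaches the transition
  fit <- twist_analysis(tw)
  expect_false(fit$buckled)
  expect_true(is.na(fit$plateau_torque_pNnm))
})
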