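# Worm-like-chain mechanics: contour length, inverse consistency and the
# high-force expansion.

test_that("contour length follows the 0.338 nm/bp rise", {
  expect_equal(wlc_params(6546)$Lc_nm, 6546 * 0.338)
  expect_equal(wlc_params(11516)$Lc_nm, 11516 * 0.338)
  expect_error(wlc_params(-10), "positive")
})

test_that("wlc_force and wlc_extension are mutual inverses to 1e-8", {
  p <- wlc_params(6546)
  F <- c(0.1, 0.3, 1, 3, 10, 20, 40, 60)
  x <- wlc_extension(F, p)
  expect_equal(wlc_force(x, p), F, tolerance = 1e-8)
  # and the other way around
  x2 <- seq(0.3, 0.97, by = 0.1) * p$Lc_nm
  expect_equal(wlc_extension(wlc_force(x2, p), p), x2, tolerance = 1e-8)
})

test_that("high-force expansion is recovered at 20 pN", {
  p <- wlc_params(6546)
  x_rel <- wlc_extension(20, p) / p$Lc_nm
  x_hf <- 1 - 0.5 * sqrt(p$kT / (20 * p$Lp_nm)) + 20 / p$K0_pN
  expect_equal(x_rel, x_hf, tolerance = 3e-3)
  expect_equal(x_rel, 0.98, tolerance = 5e-3)
})

test_that("degenerate inputs behave as documented", {
  p <- wlc_params(1000)
  expect_equal(wlc_extension(0, p), 0)
  expect_equal(wlc_extension(-1, p), 0)
  expect_equal(wlc_force(0, p), 0)
  expect_error(wlc_extension(1500, p), "stretch modulus")
})
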