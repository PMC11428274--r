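# Vector focusing of the apertured Gaussian beam: pupil weights, field
# structure, normalization, the interface identity limit and the focal
# shift of the beam focus.

test_that("pupil apodization follows the aplanatic Gaussian-truncation form", {
  b <- beam_spec(); o <- objective_spec()
  theta_max <- asin(1.3 / 1.518)
  expect_equal(theta_max, 1.0282, tolerance = 1e-4)
  expect_equal(pupil_apodization(0, b, o), 1.0)
  expect_equal(pupil_apodization(theta_max, b, o),
               sqrt(cos(theta_max)) * exp(-1 / 0.98^2), tolerance = 1e-12)
  # zero beyond the aperture, error outside the domain
  expect_equal(pupil_apodization(theta_max + 0.01, b, o), 0)
  expect_error(pupil_apodization(2, b, o), "theta")
})

test_that("on-axis field of an x-polarized beam is purely x-polarized", {
  f <- focal_field_points(cbind(0, 0, seq(-800, 800, by = 200)),
                          beam_spec(), objective_spec())
  expect_equal(max(abs(f$E[, 2])), 0)
  expect_equal(max(abs(f$E[, 3])), 0)
  expect_gt(max(abs(f$E[, 1])), 0)
})

test_that("field scales as sqrt(power) and flux matches the requested power", {
  b1 <- beam_spec(power_mW = 1); b2 <- beam_spec(power_mW = 2)
  o <- objective_spec()
  pts <- cbind(c(0, 150, -300), c(0, 100, 50), c(0, 250, -400))
  f1 <- focal_field_points(pts, b1, o)
  f2 <- focal_field_points(pts, b2, o)
  expect_equal(f2$E, sqrt(2) * f1$E, tolerance = 1e-12)
  # 2-D Poynting quadrature through the focal plane recovers the power
  flux <- poynting_flux_plane(b1, o, NULL, z_nm = 0, r_max_nm = 6000,
                              n_r = 120, n_phi = 48)
  expect_equal(flux, 1, tolerance = 0.01)
})

test_that("energy crossing transverse planes is conserved through focus", {
  b <- beam_spec(power_mW = 1); o <- objective_spec()
  fl_up <- poynting_flux_plane(b, o, NULL, z_nm = -900, r_max_nm = 8000,
                               n_r = 150, n_phi = 48)
  fl_dn <- poynting_flux_plane(b, o, NULL, z_nm = 900, r_max_nm = 8000,
                               n_r = 150, n_phi = 48)
  expect_equal(fl_up, fl_dn, tolerance = 5e-3)
})

test_that("matched-index interface reproduces the free-space field pointwise", {
  b <- beam_spec(); o <- objective_spec()
  iface <- interface_spec(depth_nm = 1000, n_glass = 1.518, n_water = 1.518)
  pts <- cbind(c(0, 120, -250, 60), c(0, -80, 40, 200),
               c(0, 300, -500, 150))
  ff <- focal_field_points(pts, b, o, NULL)
  fi <- focal_field_points(pts, b, o, iface)
  expect_lt(max(abs(ff$E - fi$E)) / max(abs(ff$E)), 1e-3)
  expect_lt(max(abs(ff$H - fi$H)) / max(abs(ff$H)), 1e-3)
})

test_that("aberration phase at normal incidence is k0 d (n1 - n2)", {
  # on-axis (theta = 0) limit: the stratified phase reduces to
  # exp(i k0 d (n2 - n1)) relative to the matched case at z = 0
  b <- beam_spec(); o <- objective_spec(NA_ = 0.05)
  d <- 800
  iface <- interface_spec(d, 1.518, 1.326)
  k0 <- 2 * pi / 1064e-9
  # at tiny NA every component is near axial, so the full field ratio
  # approaches the scalar phase times the Fresnel amplitude
  ff <- focal_field_points(cbind(0, 0, 0), b, o, NULL)
  fi <- focal_field_points(cbind(0, 0, 0), b, o, iface)
  ratio <- fi$E[1] / ff$E[1]
  t_normal <- 2 * 1.518 / (1.518 + 1.326)
  expected <- t_normal * exp(1i * k0 * (d * 1e-9) * (1.326 - 1.518))
  expect_equal(Arg(ratio), Arg(expected), tolerance = 1e-2)
  expect_equal(Mod(ratio), Mod(expected), tolerance = 1e-2)
})

test_that("|E|^2 of an x-polarized beam is symmetric under point inversion", {
  b <- beam_spec(); o <- objective_spec()
  iface <- interface_spec(1000)
  pts <- cbind(c(150, 60, -220), c(80, -120, 40), c(100, -350, 260))
  f1 <- focal_field_points(pts, b, o, iface)
  f2 <- focal_field_points(cbind(-pts[, 1], -pts[, 2], pts[, 3]),
                           b, o, iface)
  expect_equal(rowSums(abs(f1$E)^2), rowSums(abs(f2$E)^2),
               tolerance = 1e-10)
})

test_that("doubling the polar quadrature order leaves the peak unchanged", {
  b <- beam_spec(); o <- objective_spec()
  iface <- interface_spec(1500)
  pk1 <- focal_field_points(cbind(0, 0, -200), b, o, iface, n_theta = 120)
  pk2 <- focal_field_points(cbind(0, 0, -200), b, o, iface, n_theta = 240)
  expect_lt(abs(sqrt(sum(abs(pk2$E)^2)) - sqrt(sum(abs(pk1$E)^2))) /
              sqrt(sum(abs(pk2$E)^2)), 5e-3)
})

test_that("interface pulls the focus toward the coverslip and degrades the peak", {
  b <- beam_spec(); o <- objective_spec()
  prof_ab <- focus_axial_profile(b, o, interface_spec(1000))
  expect_lt(prof_ab$z_peak_nm, 0)          # between interface (-1000) and 0
  expect_gt(prof_ab$z_peak_nm, -1000)
  # aberration grows with depth: the peak degrades as the focus goes deeper
  prof_deep <- focus_axial_profile(b, o, interface_spec(3000))
  expect_lt(max(prof_deep$intensity), max(prof_ab$intensity))
})

test_that("beam focal shift ratio: matched = 1, aberrated ~ 0.75, paraxial ~ n2/n1", {
  b <- beam_spec(); o <- objective_spec()
  fs_matched <- focus_shift_ratio_beam(b, o, n_glass = 1.518,
                                       n_water = 1.518)
  expect_equal(fs_matched$fs, 1.0, tolerance = 1e-9)
  fs_ab <- focus_shift_ratio_beam(b, o)
  expect_equal(fs_ab$fs, 0.75, tolerance = 0.01)
  fs_par <- focus_shift_ratio_beam(b, objective_spec(NA_ = 0.3))
  expect_equal(fs_par$fs, 1.326 / 1.518, tolerance = 0.01)
})

test_that("field grids are well-formed and nearly divergence-free in water", {
  b <- beam_spec(); o <- objective_spec()
  g <- focal_field_free(b, o, x_nm = seq(-200, 200, by = 40),
                        y_nm = seq(-200, 200, by = 40),
                        z_nm = seq(-200, 200, by = 40), n_theta = 96)
  dv <- field_divergence(g)
  expect_lt(stats::median(dv), 0.02)
  expect_error(focal_field_interface(b, o, interface_spec(5000),
                                     z_nm = seq(-1000, 1000, 100)),
               "interface")
})
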