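# Coupled-dipole solver and Maxwell-stress force/torque: permittivity and
# lattice construction, brute-force solver oracles, the Rayleigh-sphere
# radiation-pressure oracle, and the surface-integral properties.

test_that("lab-frame permittivity tensor rotates the crystal axes correctly", {
  cyl <- cylinder_spec()
  e0 <- permittivity_tensor(cyl, alpha = 0)
  expect_equal(diag(e0), c(1.5428^2, 1.5341^2, 1.5341^2))
  expect_equal(e0[1, 1], 2.3802, tolerance = 1e-4)
  expect_equal(e0[2, 2], 2.3535, tolerance = 1e-4)
  e90 <- permittivity_tensor(cyl, alpha = pi / 2)
  expect_equal(e90[1, 1], e0[2, 2], tolerance = 1e-12)
  expect_equal(e90[2, 2], e0[1, 1], tolerance = 1e-12)
  # isotropic override is rotation invariant
  iso <- cylinder_spec(n_ordinary = 1.54, n_extraordinary = 1.54)
  expect_equal(permittivity_tensor(iso, alpha = 0.7),
               diag(rep(1.54^2, 3)), tolerance = 1e-12)
})

test_that("dipole lattice fills the truncated-cone volume", {
  cyl <- cylinder_spec()
  vol <- cylinder_volume(cyl)
  expect_equal(vol, pi * 1016 / 12 * (473^2 + 473 * 589 + 589^2),
               tolerance = 1e-12)
  md <- build_lattice(cyl, 50)
  expect_equal(nrow(md$positions_nm) * 50^3, vol, tolerance = 0.05)
  md2 <- build_lattice(cyl, 25)
  expect_equal(nrow(md2$positions_nm) / nrow(md$positions_nm), 8,
               tolerance = 0.05)
  expect_error(build_lattice(cyl, 80), "too coarse")
  # index-matched particle has zero polarizability
  match <- build_lattice(cylinder_spec(n_ordinary = 1.326 + 1e-15,
                                       n_extraordinary = 1.326 + 1e-15),
                         50, n_medium = 1.326)
  expect_lt(max(abs(match$polarizability)) /
              max(abs(md$polarizability)), 1e-12)
})

test_that("solver reproduces the single- and two-dipole closed forms", {
  pw <- plane_wave()
  md1 <- build_lattice(cylinder_spec(60, 60, 60, 1.57, 1.57), 50,
                       n_medium = 1.326)
  expect_equal(nrow(md1$positions_nm), 1L)
  sol1 <- solve_coupled_dipoles(pw, md1)
  p_expected <- md1$polarizability %*% pw(md1$positions_nm)$E[1, ]
  expect_equal(sol1$P[1, ], as.vector(p_expected), tolerance = 1e-12)
  expect_lt(sol1$residual, 1e-5)

  md2 <- md1
  md2$positions_nm <- rbind(c(0, 0, -40), c(20, 0, 40))
  sol2 <- solve_coupled_dipoles(pw, md2)
  M <- aotrap:::dda_matrix(md2)
  b <- as.vector(t(pw(md2$positions_nm)$E))
  p_direct <- matrix(solve(M, b), 2, 3, byrow = TRUE)
  expect_equal(sol2$P, p_direct, tolerance = 1e-13)
  expect_lt(sol2$residual, 1e-5)
})

test_that("stress tensor has the plane-wave momentum flux and symmetry", {
  n_w <- 1.326; eta0 <- 376.730313668
  E <- cbind(1e5 + 0i, 0i, 0i)
  H <- cbind(0i, n_w * 1e5 / eta0 + 0i, 0i)
  Tarr <- mst_tensor(E, H, epsilon = n_w^2)
  u <- 0.25 * (8.8541878128e-12 * n_w^2 * 1e10 +
                 1.25663706212e-6 * (n_w * 1e5 / eta0)^2)
  # energy-density momentum flux along the propagation direction
  expect_equal(abs((Tarr[, , 1] %*% c(0, 0, 1))[3]), u, tolerance = 1e-12)
  expect_equal(Tarr[, , 1], t(Tarr[, , 1]), tolerance = 1e-12)
  expect_equal(mst_tensor(0 * E, 0 * H)[, , 1], matrix(0, 3, 3))
})

test_that("MST force on a small dielectric sphere matches the Rayleigh oracle", {
  n_w <- 1.326; E0 <- 1e5
  k <- 2 * pi * n_w / 1064e-9
  eps0 <- 8.8541878128e-12
  pw <- plane_wave(E0)
  md <- sphere_model()
  sol <- solve_coupled_dipoles(pw, md)
  surf <- integration_surface(c(0, 0, 0), c(150, 150, 150), 20)
  sc <- scattered_field(sol, surf$points_nm)
  f0 <- pw(surf$points_nm)
  F <- optical_force(f0$E + sc$E, f0$H + sc$H, surf, n_w)
  # Rayleigh scattering-force oracle for the lattice-represented volume
  V <- nrow(md$positions_nm) * (md$spacing_nm * 1e-9)^3
  alpha_s <- 3 * eps0 * n_w^2 * V * (1.57^2 - n_w^2) / (1.57^2 + 2 * n_w^2)
  F_oracle <- k^4 * abs(alpha_s)^2 * E0^2 / (12 * pi * eps0 * n_w^2) * 1e12
  expect_equal(F[3], F_oracle, tolerance = 0.05)
  expect_lt(max(abs(F[1:2])), 0.01 * F[3])

  # dipole-summation force: independent formulation, same answer
  F_sum <- aotrap:::dipole_force_sum(sol, pw)
  expect_equal(F_sum[3], F[3], tolerance = 0.05)

  # no particle: closed-surface integral of the incident wave vanishes
  F_empty <- optical_force(f0$E, f0$H, surf, n_w)
  expect_lt(max(abs(F_empty)), 1e-12 * F[3])

  # growing the integration surface changes nothing
  surf2 <- integration_surface(c(0, 0, 0), c(225, 225, 225), 20)
  sc2 <- scattered_field(sol, surf2$points_nm)
  f02 <- pw(surf2$points_nm)
  F2 <- optical_force(f02$E + sc2$E, f02$H + sc2$H, surf2, n_w)
  expect_equal(F2[3], F[3], tolerance = 0.01)

  # torque on a centered isotropic sphere vanishes
  tau <- optical_torque(f0$E + sc$E, f0$H + sc$H, surf, n_w)
  expect_lt(max(abs(tau)), 1e-6 * F[3] * 150)
})

test_that("lattice refinement is converged: halving the spacing moves F < 3%", {
  # half-scale cylinder so that true spacing halving stays tractable
  cyl <- cylinder_spec(236, 294, 508)
  pw <- plane_wave()
  F_at <- function(sp) {
    md <- build_lattice(cyl, sp, n_medium = 1.326)
    sol <- solve_coupled_dipoles(pw, md)
    surf <- integration_surface(c(0, 0, 0), c(350, 350, 460), 16)
    sc <- scattered_field(sol, surf$points_nm)
    f0 <- pw(surf$points_nm)
    optical_force(f0$E + sc$E, f0$H + sc$H, surf, 1.326)[3]
  }
  F64 <- F_at(64); F32 <- F_at(32)
  expect_equal(F64, F32, tolerance = 0.03)
})
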