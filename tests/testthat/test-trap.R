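# Trap characterization on the coarse-lattice test setup: axial force
# profiles, equilibrium, power linearity, torque curves, and the
# surface-attached force scan. The heavier stiffness maps live in the
# acceptance suite and share this setup's cached solver state.

test_that("axial force profile traps: one stable zero crossing, restoring tail", {
  st <- test_setup()
  prof <- axial_force_profile(st, 1500, seq(-1100, 300, by = 200))
  sgn <- sign(prof$Fz_pN)
  crossings <- which(sgn[-length(sgn)] > 0 & sgn[-1] <= 0)
  expect_equal(length(crossings), 1L)
  # far downstream of focus the force is restoring (negative)
  expect_lt(prof$Fz_pN[nrow(prof)], 0)
})

test_that("equilibrium is found to 1 nm with a small force residual", {
  st <- test_setup()
  eq <- equilibrium_trap_height(st, 1500)
  expect_lt(abs(eq$Fz_residual_pN), 0.01)
  expect_gt(eq$htrap_nm, 0)
  expect_false(eq$multiple_roots)
  # the trap sits downstream of the (shifted) beam focus
  prof <- focus_axial_profile(st$beam, st$objective, interface_spec(1500))
  expect_gt(eq$z_bottom_nm + st$cylinder$height_nm / 2, prof$z_peak_nm)
})

test_that("force and torque scale linearly with beam power", {
  st <- test_setup()
  beam2 <- st$beam; beam2$power_mW <- 2 * st$beam$power_mW
  st2 <- trap_setup(beam = beam2, objective = st$objective,
                    cylinder = st$cylinder, spacing_nm = st$spacing_nm,
                    n_theta = st$n_theta, mst_n_face = st$mst_n_face)
  st2$cache <- st$cache            # same lattice/solver, only power differs
  f1 <- force_torque(st, -500, 1500, alpha = 0.3)
  f2 <- force_torque(st2, -500, 1500, alpha = 0.3)
  expect_equal(f2$force_pN, 2 * f1$force_pN, tolerance = 1e-9)
  expect_equal(f2$torque_pNnm, 2 * f1$torque_pNnm, tolerance = 1e-9)
})

test_that("torque versus alpha is an odd, pi-periodic restoring sinusoid", {
  st <- test_setup()
  tc <- torque_vs_alpha(st, seq(-pi / 2, pi / 2, length.out = 13),
                        zsurf_nm = 1500)
  i0 <- which(abs(tc$alpha) < 1e-12)
  i90 <- which(abs(tc$alpha - pi / 2) < 1e-9)
  amp <- max(abs(tc$tau_z_pNnm))
  # zeros at alpha = 0 and pi/2
  expect_lt(abs(tc$tau_z_pNnm[i0]), 0.02 * amp)
  expect_lt(abs(tc$tau_z_pNnm[i90]), 0.02 * amp)
  # odd in alpha
  expect_equal(tc$tau_z_pNnm, -rev(tc$tau_z_pNnm), tolerance = 0.03 * amp)
  # restoring: negative torque just past alignment, extremum near pi/4
  expect_lt(tc$tau_z_pNnm[which(abs(tc$alpha - pi / 4) < 1e-9)], 0)
  expect_equal(tc$alpha[which.min(tc$tau_z_pNnm)], pi / 4,
               tolerance = 0.2)
  # sinusoid fit quality and positive angular stiffness
  expect_false(tc$shape_warning)
  expect_gt(tc$kappa_theta, 0)
  expect_lt(tc$fit_rms, 0.1 * abs(tc$amplitude))
})

test_that("rotating the crystal equals rotating the polarization (small lattice)", {
  # independent check of the polarization-rotation equivalence used by the
  # cached solver: solve a small cylinder with the crystal axis rotated
  # explicitly and compare torque about z
  cyl_a <- cylinder_spec(236, 294, 508, alpha = 0.4)
  md_a <- build_lattice(cyl_a, 64, n_medium = 1.326)
  beam <- beam_spec(); obj <- objective_spec()
  iface <- interface_spec(1200)
  inc0 <- function(p) focal_field_points(p, beam, obj, iface, n_theta = 96)
  beam_r <- beam; beam_r$polarization_angle <- -0.4
  inc_r <- function(p) focal_field_points(p, beam_r, obj, iface, n_theta = 96)
  cyl_0 <- cyl_a; cyl_0$alpha <- 0
  md_0 <- build_lattice(cyl_0, 64, n_medium = 1.326)
  center <- c(0, 0, -300)
  surf <- integration_surface(center, c(350, 350, 460), 16)
  tau_of <- function(md, inc) {
    sol <- solve_coupled_dipoles(inc, md, center_nm = center)
    sc <- scattered_field(sol, surf$points_nm)
    fi <- inc(surf$points_nm)
    optical_torque(fi$E + sc$E, fi$H + sc$H, surf, 1.326,
                   reference_nm = center)[3]
  }
  tau_crystal <- tau_of(md_a, inc0)     # crystal rotated by +0.4
  tau_pol <- tau_of(md_0, inc_r)        # polarization rotated by -0.4
  expect_equal(tau_crystal, tau_pol, tolerance = 0.02 * abs(tau_crystal))
})

test_that("surface-attached force scan has one dominant extremum and decays", {
  st <- test_setup()
  scan <- surface_attached_force_scan(st, seq(0, 3200, by = 400))
  ipk <- which.max(abs(scan$Fz_pN))
  expect_gt(abs(scan$Fz_pN[ipk]), 3 * abs(scan$Fz_pN[nrow(scan)]))
  # force is small once the cylinder is ~3 um past the focus
  expect_lt(abs(scan$Fz_pN[nrow(scan)]), 0.25 * abs(scan$Fz_pN[ipk]))
})

test_that("equilibria and stiffness move as expected with the surface", {
  st <- test_setup()
  e1 <- equilibrium_trap_height(st, 1500)
  e2 <- equilibrium_trap_height(st, 2000)
  # raising the depth raises the trap height by less than the full step
  dh <- e2$htrap_nm - e1$htrap_nm
  expect_gt(dh, 0.5 * 500)
  expect_lt(dh, 1.0 * 500)
  k <- axial_stiffness(st, 1500, eq = e1)
  expect_gt(k$kappa_pN_per_nm, 0)
})
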