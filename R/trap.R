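# Trap characterization: ties the focused-beam model and the coupled-dipole
# scattering solver together into the measurable trap quantities - axial
# force profiles, equilibrium trap height, the focal shift ratio of the trap,
# and axial/angular stiffness maps.
#
# Geometry (see beam.R): the stage coordinate zsurf equals the interface
# depth d; the coverslip surface is the plane z = -zsurf; the trap height
# htrap is the distance from the cylinder's bottom surface to the coverslip,
# htrap = z_bottom + zsurf. The cylinder axis is +z; poses are parametrized
# by the bottom-surface position z_bottom (nm, lab frame).
#
# The interaction matrix of the dipole lattice depends only on the lattice
# and the medium - not on the cylinder pose, the interface depth, or the
# beam polarization. Its inverse, and the (pose-independent) Green maps from
# dipole moments to the co-moving integration surface, are therefore built
# once per setup and reused for every pose; rotating the cylinder by alpha is
# computed as rotating the beam polarization by -alpha, which is an exact
# equivalence up to lattice-discretization error.

#' Bundle of beam, objective, interface indices, cylinder and numerics
#'
#' Creates the reusable simulation state for all trap-characterization
#' operations. Heavy pose-independent objects (dipole lattice, inverse
#' interaction matrix, surface Green maps) are built lazily on first use and
#' cached inside the returned object.
#'
#' @param beam a [beam_spec()].
#' @param objective an [objective_spec()].
#' @param cylinder a [cylinder_spec()].
#' @param n_glass,n_water interface indices; equal values give the
#'   aberration-free (matched) control.
#' @param spacing_nm dipole lattice spacing.
#' @param n_theta polar quadrature order of the focused-beam integrals.
#' @param mst_n_face Gauss-Legendre order per dimension on each face of the
#'   stress-tensor integration cuboid.
#' @param mst_margin_nm clearance between the cylinder hull and the cuboid.
#' @param max_direct dipole count above which the iterative solver is used.
#' @return object of class `trap_setup`.
#' @export
trap_setup <- function(beam = beam_spec(), objective = objective_spec(),
                       cylinder = cylinder_spec(),
                       n_glass = 1.518, n_water = 1.326,
                       spacing_nm = 50, n_theta = 120,
                       mst_n_face = 20, mst_margin_nm = 200,
                       max_direct = 4000) {
  structure(list(beam = beam, objective = objective, cylinder = cylinder,
                 n_glass = n_glass, n_water = n_water,
                 matched = abs(n_glass - n_water) < 1e-12,
                 spacing_nm = spacing_nm, n_theta = n_theta,
                 mst_n_face = mst_n_face, mst_margin_nm = mst_margin_nm,
                 max_direct = max_direct,
                 cache = new.env(parent = emptyenv())),
            class = "trap_setup")
}

#' @export
print.trap_setup <- function(x, ...) {
  cat(sprintf(
    "trap_setup: NA %.2f, fill %.2f, n %g/%g, cylinder %g/%g x %g nm, spacing %g nm\n",
    x$objective$NA_, x$beam$filling_factor, x$n_glass, x$n_water,
    x$cylinder$bottom_diameter_nm, x$cylinder$top_diameter_nm,
    x$cylinder$height_nm, x$spacing_nm))
  invisible(x)
}

# Rectangular (targets x sources) Green maps from interleaved dipole moments
# to interleaved E and H at fixed body-frame surface points.
surface_green_maps <- function(targets_nm, sources_nm, k, n_medium) {
  tg <- as.matrix(targets_nm) * 1e-9; sc <- as.matrix(sources_nm) * 1e-9
  nt <- nrow(tg); ns <- nrow(sc)
  eps_m <- n_medium^2
  prefE <- 1 / (4 * pi * .const$eps0 * eps_m)
  prefH <- (.const$c0 / n_medium) * k^2 / (4 * pi)
  dx <- outer(tg[, 1], sc[, 1], "-")
  dy <- outer(tg[, 2], sc[, 2], "-")
  dz <- outer(tg[, 3], sc[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  ir <- 1 / r; ir2 <- ir * ir
  e <- exp(1i * k * r)
  C1 <- (prefE * k^2) * e * ir
  C2 <- prefE * e * (ir * ir2 - 1i * k * ir2)
  C3 <- prefH * e * (ir - ir2 / (1i * k))   # acts on unit vectors u below
  u <- list(dx * ir, dy * ir, dz * ir)
  GE <- matrix(0i, 3 * nt, 3 * ns)
  GH <- matrix(0i, 3 * nt, 3 * ns)
  rows <- rep(seq_len(nt), times = ns); cols <- rep(seq_len(ns), each = nt)
  for (a in 1:3) for (b in 1:3) {
    uab <- u[[a]] * u[[b]]
    GE[cbind(3 * (rows - 1) + a, 3 * (cols - 1) + b)] <-
      as.vector(C1 * ((a == b) - uab) + C2 * (3 * uab - (a == b)))
  }
  # H couplings written out explicitly: H = C3 * (u x p)
  blocks <- list(
    list(1, 2, -C3 * u[[3]]), list(1, 3,  C3 * u[[2]]),
    list(2, 1,  C3 * u[[3]]), list(2, 3, -C3 * u[[1]]),
    list(3, 1, -C3 * u[[2]]), list(3, 2,  C3 * u[[1]]))
  for (bl in blocks) {
    GH[cbind(3 * (rows - 1) + bl[[1]], 3 * (cols - 1) + bl[[2]])] <-
      as.vector(bl[[3]])
  }
  list(GE = GE, GH = GH)
}

# Build (or fetch) the cached pose-independent solver state.
trap_solver <- function(setup) {
  cache <- setup$cache
  if (!is.null(cache$Minv)) return(cache)
  cyl0 <- setup$cylinder; cyl0$alpha <- 0
  model <- build_lattice(cyl0, setup$spacing_nm, n_medium = setup$n_water,
                         wavelength_nm = setup$beam$wavelength_nm)
  n <- nrow(model$positions_nm)
  M <- dda_matrix(model)
  if (n <= setup$max_direct) {
    cache$Minv <- solve(M)
    cache$M <- NULL
  } else {
    cache$M <- M    # iterative path keeps the matrix
    cache$Minv <- NULL
  }
  rm(M)
  half <- c(rep(max(cyl0$bottom_diameter_nm, cyl0$top_diameter_nm) / 2 +
                  setup$mst_margin_nm, 2),
            cyl0$height_nm / 2 + setup$mst_margin_nm)
  surf <- integration_surface(c(0, 0, 0), half, setup$mst_n_face)
  g <- surface_green_maps(surf$points_nm, model$positions_nm,
                          model$k_medium, model$n_medium)
  cache$model <- model
  cache$surface <- surf
  cache$half <- half
  cache$GE <- g$GE
  cache$GH <- g$GH
  cache
}

# Incident-field closure for a given interface depth and polarization angle.
trap_incident <- function(setup, zsurf_nm, pol_angle = 0) {
  beam <- setup$beam
  beam$polarization_angle <- pol_angle
  iface <- if (setup$matched) NULL else
    interface_spec(depth_nm = zsurf_nm, n_glass = setup$n_glass,
                   n_water = setup$n_water)
  function(pts_nm) focal_field_points(pts_nm, beam, setup$objective, iface,
                                      n_theta = setup$n_theta)
}

#' Optical force and torque on the cylinder at a pose
#'
#' Solves the coupled-dipole system for the cylinder at the given pose and
#' integrates the Maxwell stress tensor of the total field over the co-moving
#' cuboid surface. If the cuboid would cross the coverslip plane (cylinder
#' close to the surface), the force falls back to the dipole-summation
#' formulation and the torque is not evaluated.
#'
#' @param setup a [trap_setup()].
#' @param z_bottom_nm axial position of the cylinder bottom surface (nm, lab
#'   frame; the nominal focus is at 0).
#' @param zsurf_nm stage coordinate = interface depth (nm); the coverslip is
#'   at z = -zsurf_nm.
#' @param alpha misalignment angle of the extraordinary axis from the beam
#'   polarization (radians); computed by rotating the beam polarization.
#' @return object of class `force_torque_result`: `force_pN`,
#'   `torque_pNnm` (about the cylinder's geometric center), `residual`,
#'   `method`, `htrap_nm`.
#' @export
force_torque <- function(setup, z_bottom_nm, zsurf_nm, alpha = 0) {
  if (!setup$matched && z_bottom_nm <= -zsurf_nm)
    stopf("cylinder bottom (z = %.0f) is below the coverslip (z = %.0f)",
          z_bottom_nm, -zsurf_nm)
  cache <- trap_solver(setup)
  h <- setup$cylinder$height_nm
  center <- c(0, 0, z_bottom_nm + h / 2)
  pol <- setup$beam$polarization_angle - alpha
  inc <- trap_incident(setup, zsurf_nm, pol)

  pos_lab <- sweep(cache$model$positions_nm, 2, center, "+")
  Einc <- inc(pos_lab)$E
  b <- as.vector(t(Einc))
  if (!is.null(cache$Minv)) {
    pvec <- as.vector(cache$Minv %*% b)
  } else {
    pvec <- bicgstab(cache$M, b, tol = 1e-5)
  }
  res <- NA_real_   # filled below only for the direct path when requested
  P <- matrix(pvec, ncol = 3, byrow = TRUE)

  box_bottom <- center[3] - cache$half[3]
  use_mst <- setup$matched || box_bottom > -zsurf_nm + 10
  if (use_mst) {
    spts <- sweep(cache$surface$points_nm, 2, center, "+")
    fs_inc <- inc(spts)
    Esc <- matrix(as.vector(cache$GE %*% pvec), ncol = 3, byrow = TRUE)
    Hsc <- matrix(as.vector(cache$GH %*% pvec), ncol = 3, byrow = TRUE)
    E <- fs_inc$E + Esc; H <- fs_inc$H + Hsc
    surf_lab <- cache$surface
    surf_lab$points_nm <- spts
    F <- optical_force(E, H, surf_lab, setup$n_water)
    tau <- optical_torque(E, H, surf_lab, setup$n_water, reference_nm = center)
    method <- "mst"
  } else {
    sol <- structure(list(P = P, positions_nm = pos_lab, model = cache$model,
                          center_nm = center), class = "dda_solution")
    F <- dipole_force_sum(sol, inc)
    tau <- c(NA_real_, NA_real_, NA_real_)
    method <- "dipole-sum"
  }
  # rotate force/torque back into the physical frame (the solve was done with
  # the polarization rotated by -alpha instead of the crystal by +alpha)
  if (alpha != 0) {
    ca <- cos(alpha); sa <- sin(alpha)
    R <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
    F <- as.vector(R %*% F)
    if (use_mst) tau <- as.vector(R %*% as.vector(tau))
  }
  structure(list(force_pN = unname(F), torque_pNnm = unname(as.vector(tau)),
                 residual = res, method = method,
                 z_bottom_nm = z_bottom_nm, zsurf_nm = zsurf_nm,
                 alpha = alpha, htrap_nm = z_bottom_nm + zsurf_nm,
                 reference_nm = center),
            class = "force_torque_result")
}

#' @export
print.force_torque_result <- function(x, ...) {
  cat(sprintf("F = (%.4g, %.4g, %.4g) pN", x$force_pN[1], x$force_pN[2],
              x$force_pN[3]))
  if (!is.na(x$torque_pNnm[3]))
    cat(sprintf("; tau = (%.4g, %.4g, %.4g) pN nm", x$torque_pNnm[1],
                x$torque_pNnm[2], x$torque_pNnm[3]))
  cat(sprintf("  [%s]\n", x$method))
  invisible(x)
}

#' Axial force profile of the trapped cylinder
#'
#' Fz versus the cylinder bottom position at a fixed surface position, with
#' the extraordinary axis aligned with the beam polarization (alpha = 0, no
#' net torque).
#'
#' @param setup a [trap_setup()].
#' @param zsurf_nm stage coordinate (interface depth, nm).
#' @param z_bottom_nm vector of cylinder bottom positions (nm).
#' @return data.frame with z_bottom_nm, htrap_nm, Fz_pN.
#' @export
axial_force_profile <- function(setup, zsurf_nm,
                                z_bottom_nm = seq(-1200, 200, by = 100)) {
  Fz <- vapply(z_bottom_nm,
               function(zb) force_torque(setup, zb, zsurf_nm)$force_pN[3],
               numeric(1))
  data.frame(z_bottom_nm = z_bottom_nm, htrap_nm = z_bottom_nm + zsurf_nm,
             Fz_pN = Fz)
}

# Locate the stable zero crossing(s) of an Fz profile: sign change + to -.
stable_crossings <- function(z, Fz) {
  i <- which(Fz[-length(Fz)] > 0 & Fz[-1] <= 0)
  i
}

#' Equilibrium trap height
#'
#' Finds the axial position where the net optical force on the cylinder
#' vanishes with negative slope (the stable trapping point) by bracketing and
#' Brent refinement to 1 nm, and reports the trap height htrap (cylinder
#' bottom to coverslip surface).
#'
#' @param setup a [trap_setup()].
#' @param zsurf_nm stage coordinate (interface depth, nm).
#' @param z_guess_nm optional initial guess for the cylinder bottom position;
#'   defaults to the last equilibrium found with this setup (warm start) or
#'   a coarse scan.
#' @param scan_range_nm coarse-scan range for the bracket when no usable
#'   guess exists.
#' @return list with `htrap_nm`, `z_bottom_nm`, `Fz_residual_pN`,
#'   `multiple_roots` flag.
#' @export
equilibrium_trap_height <- function(setup, zsurf_nm, z_guess_nm = NULL,
                                    scan_range_nm = c(-1600, 400)) {
  f <- function(zb) force_torque(setup, zb, zsurf_nm)$force_pN[3]
  cache <- setup$cache
  guess <- z_guess_nm %||% cache$last_root
  bracket <- NULL
  if (!is.null(guess)) {
    lo <- guess - 150; hi <- guess + 150
    if (setup$matched || lo > -zsurf_nm + 20) {
      flo <- f(lo); fhi <- f(hi)
      if (flo > 0 && fhi < 0) bracket <- list(lo = lo, hi = hi,
                                              flo = flo, fhi = fhi)
    }
  }
  multiple <- FALSE
  if (is.null(bracket)) {
    zlo <- if (setup$matched) scan_range_nm[1] else
      max(scan_range_nm[1], -zsurf_nm + 20)
    zs <- seq(zlo, scan_range_nm[2], by = 100)
    Fz <- vapply(zs, f, numeric(1))
    cr <- stable_crossings(zs, Fz)
    if (length(cr) == 0)
      stopf("no stable force zero crossing in [%g, %g] nm at zsurf = %g",
            zlo, scan_range_nm[2], zsurf_nm)
    if (length(cr) > 1) {
      multiple <- TRUE
      warning("multiple stable zero crossings; using the one nearest the focus")
      cr <- cr[which.min(abs(zs[cr]))]
    }
    bracket <- list(lo = zs[cr], hi = zs[cr + 1], flo = Fz[cr],
                    fhi = Fz[cr + 1])
  }
  r <- stats::uniroot(f, c(bracket$lo, bracket$hi),
                      f.lower = bracket$flo, f.upper = bracket$fhi,
                      tol = 0.5)
  cache$last_root <- r$root
  list(htrap_nm = r$root + zsurf_nm, z_bottom_nm = r$root,
       Fz_residual_pN = r$f.root, multiple_roots = multiple)
}

#' Focal shift ratio of the trap
#'
#' Least-squares slope of the equilibrium trap height versus the surface
#' position: fs = d(htrap)/d(zsurf).
#'
#' @param setup a [trap_setup()].
#' @param zsurf_nm >= 4 surface positions spanning >= 1.5 um.
#' @return a `focal_shift_estimate` (method "trap-sim") with the per-surface
#'   equilibria attached.
#' @export
focal_shift_ratio_trap <- function(setup,
                                   zsurf_nm = seq(1000, 3000, by = 500)) {
  if (length(zsurf_nm) < 4 || diff(range(zsurf_nm)) < 1500)
    stopf("need >= 4 surface positions spanning >= 1.5 um")
  zsurf_nm <- sort(zsurf_nm)
  htrap <- numeric(length(zsurf_nm))
  guess <- NULL
  for (i in seq_along(zsurf_nm)) {
    eq <- equilibrium_trap_height(setup, zsurf_nm[i], z_guess_nm = guess)
    htrap[i] <- eq$htrap_nm
    # warm start: the equilibrium moves by about (fs - 1) per unit depth
    guess <- eq$z_bottom_nm +
      if (i < length(zsurf_nm)) -0.2 * (zsurf_nm[i + 1] - zsurf_nm[i]) else 0
  }
  fit <- stats::lm(htrap ~ zsurf_nm)
  structure(list(fs = unname(stats::coef(fit)[2]),
                 se = suppressWarnings(summary(fit))$coefficients[2, 2],
                 method = "trap-sim", zsurf_nm = zsurf_nm, htrap_nm = htrap,
                 fit = fit),
            class = "focal_shift_estimate")
}

#' Axial trap stiffness at equilibrium
#'
#' \eqn{\kappa_z = -dF_z/dz} at the force zero, by a central difference.
#'
#' @param setup a [trap_setup()].
#' @param zsurf_nm stage coordinate (nm).
#' @param step_nm central-difference step.
#' @param eq optional precomputed [equilibrium_trap_height()] result.
#' @return list with `kappa_pN_per_nm`, `htrap_nm`, `z_bottom_nm`.
#' @export
axial_stiffness <- function(setup, zsurf_nm, step_nm = 10, eq = NULL) {
  eq <- eq %||% equilibrium_trap_height(setup, zsurf_nm)
  zp <- eq$z_bottom_nm + step_nm; zm <- eq$z_bottom_nm - step_nm
  Fp <- force_torque(setup, zp, zsurf_nm)$force_pN[3]
  Fm <- force_torque(setup, zm, zsurf_nm)$force_pN[3]
  list(kappa_pN_per_nm = -(Fp - Fm) / (2 * step_nm),
       htrap_nm = eq$htrap_nm, z_bottom_nm = eq$z_bottom_nm)
}

# Map target trap heights to surface positions using the (nearly exact)
# linearity of htrap versus zsurf, calibrated from two equilibria.
zsurf_for_htrap <- function(setup, htrap_nm) {
  z1 <- max(min(htrap_nm) + 300, 800); z2 <- z1 + 1500
  e1 <- equilibrium_trap_height(setup, z1)
  e2 <- equilibrium_trap_height(setup, z2, z_guess_nm = e1$z_bottom_nm -
                                  0.2 * (z2 - z1))
  slope <- (e2$htrap_nm - e1$htrap_nm) / (z2 - z1)
  zs <- z1 + (htrap_nm - e1$htrap_nm) / slope
  # predicted cylinder-bottom position at each target, for warm starts
  attr(zs, "z_bottom_guess") <- htrap_nm - zs
  zs
}

#' Axial stiffness versus trap height
#'
#' Computes the axial stiffness at equilibrium over a set of trap heights and
#' fits the linear trend, expressed as percent decrease per micron relative
#' to the stiffness at 1 um.
#'
#' @param setup a [trap_setup()].
#' @param htrap_nm target trap heights (nm).
#' @return object of class `stiffness_curve` with columns htrap_nm and
#'   kappa (pN/nm), plus `trend_pct_per_um` (positive = decrease) and the fit.
#' @export
axial_stiffness_vs_height <- function(setup,
                                      htrap_nm = seq(500, 3000, by = 500)) {
  zsurf <- zsurf_for_htrap(setup, htrap_nm)
  guess <- attr(zsurf, "z_bottom_guess")
  kap <- hh <- numeric(length(zsurf))
  for (i in seq_along(zsurf)) {
    eq <- equilibrium_trap_height(setup, zsurf[i], z_guess_nm = guess[i])
    st <- axial_stiffness(setup, zsurf[i], eq = eq)
    kap[i] <- st$kappa_pN_per_nm; hh[i] <- st$htrap_nm
  }
  fit <- stats::lm(kap ~ hh)
  k1um <- unname(stats::predict(fit, data.frame(hh = 1000)))
  trend <- -unname(stats::coef(fit)[2]) * 1000 / k1um * 100
  structure(list(htrap_nm = hh, kappa_pN_per_nm = kap,
                 abscissa = "htrap", power_mW = setup$beam$power_mW,
                 trend_pct_per_um = trend, kappa_1um = k1um, fit = fit),
            class = "stiffness_curve")
}

#' @export
print.stiffness_curve <- function(x, ...) {
  print(data.frame(abscissa_nm = x$htrap_nm %||% x$zcyl_nm,
                   stiffness = x$kappa_pN_per_nm %||% x$kappa_pNnm_per_rad))
  if (!is.null(x$trend_pct_per_um))
    cat(sprintf("trend: %.2f %%/um relative to the 1-um value\n",
                x$trend_pct_per_um))
  invisible(x)
}

#' Torque versus misalignment angle
#'
#' \eqn{\tau_z(\alpha)} at a fixed pose, with the angular stiffness from the
#' sinusoid fit \eqn{\tau_z = -(\kappa_\theta/2) \sin 2\alpha}. A shape
#' warning is recorded when the fit RMS exceeds 10\% of the amplitude.
#'
#' @param setup a [trap_setup()].
#' @param alphas misalignment angles (radians), within (-pi/2, pi/2].
#' @param zsurf_nm stage coordinate (nm).
#' @param z_bottom_nm cylinder bottom position; defaults to the equilibrium.
#' @return object of class `torque_curve`: alpha, tau_z (pN nm),
#'   `kappa_theta` (pN nm/rad), fit diagnostics.
#' @export
torque_vs_alpha <- function(setup, alphas = seq(-pi / 2, pi / 2, length.out = 13),
                            zsurf_nm = 1500, z_bottom_nm = NULL) {
  if (any(alphas <= -pi / 2 - 1e-9 | alphas > pi / 2 + 1e-9))
    stopf("alphas must lie within (-pi/2, pi/2]")
  zb <- z_bottom_nm %||%
    equilibrium_trap_height(setup, zsurf_nm)$z_bottom_nm
  tau <- vapply(alphas, function(a)
    force_torque(setup, zb, zsurf_nm, alpha = a)$torque_pNnm[3], numeric(1))
  s2 <- sin(2 * alphas)
  a_hat <- sum(s2 * tau) / sum(s2^2)
  rms <- sqrt(mean((tau - a_hat * s2)^2))
  shape_warning <- is.finite(rms) && abs(a_hat) > 0 && rms > 0.1 * abs(a_hat)
  structure(list(alpha = alphas, tau_z_pNnm = tau,
                 kappa_theta = -2 * a_hat, amplitude = a_hat,
                 fit_rms = rms, shape_warning = shape_warning,
                 zsurf_nm = zsurf_nm, z_bottom_nm = zb),
            class = "torque_curve")
}

#' @export
print.torque_curve <- function(x, ...) {
  cat(sprintf(
    "torque curve: kappa_theta = %.4g pN nm/rad (fit RMS %.2g%% of amplitude)\n",
    x$kappa_theta, 100 * x$fit_rms / abs(x$amplitude)))
  invisible(x)
}

#' Angular stiffness versus trap height
#'
#' @param setup a [trap_setup()].
#' @param htrap_nm target trap heights (nm).
#' @param alphas angles used for each sinusoid fit.
#' @return `stiffness_curve` with kappa_theta (pN nm/rad) per trap height.
#' @export
angular_stiffness_vs_height <- function(setup,
                                        htrap_nm = seq(1000, 3000, by = 500),
                                        alphas = seq(-pi / 3, pi / 3,
                                                     length.out = 9)) {
  zsurf <- zsurf_for_htrap(setup, htrap_nm)
  guess <- attr(zsurf, "z_bottom_guess")
  kap <- hh <- numeric(length(zsurf))
  for (i in seq_along(zsurf)) {
    eq <- equilibrium_trap_height(setup, zsurf[i], z_guess_nm = guess[i])
    tc <- torque_vs_alpha(setup, alphas, zsurf[i], eq$z_bottom_nm)
    kap[i] <- tc$kappa_theta; hh[i] <- eq$htrap_nm
  }
  structure(list(htrap_nm = hh, kappa_pNnm_per_rad = kap, abscissa = "htrap",
                 power_mW = setup$beam$power_mW),
            class = "stiffness_curve")
}

#' Angular stiffness versus axial cylinder displacement
#'
#' The cylinder is displaced by zcyl from the trap center (negative = toward
#' the coverslip, the direction a taut DNA tether pulls) at a fixed trap
#' height, and the angular stiffness is fit at each displacement.
#'
#' @param setup a [trap_setup()].
#' @param zcyl_nm axial displacements from the trap center (nm).
#' @param htrap_nm trap height at zcyl = 0 (nm).
#' @param alphas angles used for each sinusoid fit.
#' @return `stiffness_curve` with kappa_theta per zcyl.
#' @export
angular_stiffness_vs_zcyl <- function(setup,
                                      zcyl_nm = seq(-400, 0, by = 100),
                                      htrap_nm = 1500,
                                      alphas = seq(-pi / 3, pi / 3,
                                                   length.out = 9)) {
  zsurf <- zsurf_for_htrap(setup, htrap_nm)
  eq <- equilibrium_trap_height(setup, zsurf)
  kap <- numeric(length(zcyl_nm))
  for (i in seq_along(zcyl_nm)) {
    tc <- torque_vs_alpha(setup, alphas, zsurf,
                          eq$z_bottom_nm + zcyl_nm[i])
    kap[i] <- tc$kappa_theta
  }
  structure(list(zcyl_nm = zcyl_nm, kappa_pNnm_per_rad = kap,
                 abscissa = "zcyl", htrap_nm = eq$htrap_nm,
                 power_mW = setup$beam$power_mW),
            class = "stiffness_curve")
}

#' Force on a surface-attached cylinder as the stage sweeps through focus
#'
#' The cylinder co-moves with the coverslip, its bottom fixed `gap_nm` above
#' the surface. Because the integration cuboid would cross the coverslip
#' plane, the force is evaluated by the dipole-summation formulation.
#'
#' @param setup a [trap_setup()].
#' @param zsurf_nm stage positions (nm).
#' @param gap_nm clearance between cylinder bottom and surface (nm).
#' @return data.frame with zsurf_nm and Fz_pN.
#' @export
surface_attached_force_scan <- function(setup,
                                        zsurf_nm = seq(-500, 3000, by = 250),
                                        gap_nm = 10) {
  Fz <- vapply(zsurf_nm, function(zs) {
    force_torque(setup, -zs + gap_nm, zs)$force_pN[3]
  }, numeric(1))
  data.frame(zsurf_nm = zsurf_nm, Fz_pN = Fz)
}
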