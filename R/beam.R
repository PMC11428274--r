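# Vector focusing of a high-NA, apertured Gaussian beam (angular-spectrum /
# Debye-Wolf representation), in a homogeneous immersion medium and through a
# planar glass-aqueous interface (stratified medium: Fresnel transmission plus
# the depth-dependent spherical-aberration phase).
#
# Conventions:
#   * +z is the propagation direction; the coordinate origin is the nominal
#     (aberration-free) focus of the objective.
#   * The coverslip interface is the plane z = interface_z_nm; the aqueous
#     medium occupies z > interface_z_nm. "Depth" d = -interface_z_nm, so
#     d > 0 means the nominal focus lies d nanometers beyond the interface,
#     inside the aqueous medium. The stage coordinate zsurf used throughout
#     the trap-characterization module equals d: moving the surface away from
#     the objective (deeper nominal focus) increases zsurf.
#   * Lengths at the interfaces of all functions are nm; fields are SI
#     (E in V/m, H in A/m).

#' Trapping beam specification
#'
#' @param wavelength_nm vacuum wavelength (nm).
#' @param power_mW power at the specimen plane (mW). This is the
#'   post-objective power; see [power_at_specimen()] for the conversion from
#'   pre-objective power via the objective transmission.
#' @param polarization_angle angle of the linear polarization in the
#'   transverse plane, radians from +x.
#' @param filling_factor ratio of the input Gaussian beam waist to the
#'   objective aperture radius, \eqn{f_0 = w_0/(f \sin\theta_{max})};
#'   the pupil amplitude is truncated as
#'   \eqn{\exp[-(\sin\theta/(f_0\sin\theta_{max}))^2]}.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(wavelength_nm = 1064, power_mW = 8.4,
                      polarization_angle = 0, filling_factor = 0.98) {
  if (wavelength_nm <= 0) stopf("wavelength must be positive")
  if (power_mW < 0) stopf("power must be non-negative")
  if (filling_factor <= 0 || filling_factor > 2)
    stopf("filling_factor must be in (0, 2]")
  structure(list(wavelength_nm = wavelength_nm, power_mW = power_mW,
                 polarization_angle = polarization_angle,
                 filling_factor = filling_factor),
            class = "beam_spec")
}

#' Objective specification
#'
#' @param NA_ numerical aperture.
#' @param n_immersion refractive index of the immersion oil / coverslip glass.
#' @param transmission power transmission coefficient of the objective,
#'   used only to convert pre-objective power to specimen-plane power.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(NA_ = 1.3, n_immersion = 1.518,
                           transmission = 0.42) {
  if (NA_ <= 0 || NA_ >= n_immersion)
    stopf("need 0 < NA < n_immersion")
  if (transmission <= 0 || transmission > 1)
    stopf("transmission must be in (0, 1]")
  structure(list(NA_ = NA_, n_immersion = n_immersion,
                 transmission = transmission),
            class = "objective_spec")
}

#' Specimen-plane power from pre-objective power
#'
#' @param power_pre_mW laser power entering the objective (mW).
#' @param objective an [objective_spec()].
#' @return power at the specimen plane (mW).
#' @export
power_at_specimen <- function(power_pre_mW, objective = objective_spec()) {
  power_pre_mW * objective$transmission
}

#' Glass-aqueous interface specification
#'
#' @param depth_nm interface depth: distance from the interface to the
#'   nominal (aberration-free) focus, positive when the focus lies beyond the
#'   interface inside the aqueous medium. The interface plane is
#'   z = -depth_nm; water occupies z > -depth_nm.
#' @param n_glass coverslip / immersion index.
#' @param n_water aqueous-medium index at the trapping wavelength.
#' @return object of class `interface_spec`.
#' @export
interface_spec <- function(depth_nm = 1000, n_glass = 1.518,
                           n_water = 1.326) {
  if (n_glass <= 1 || n_water <= 1) stopf("indices must exceed 1")
  flagged <- n_water >= n_glass
  if (flagged && n_water > n_glass)
    warning("n_water >= n_glass: geometry differs from the oil-immersion trap")
  structure(list(depth_nm = depth_nm, n_glass = n_glass, n_water = n_water,
                 interface_z_nm = -depth_nm),
            class = "interface_spec")
}

#' Pupil apodization weight of the apertured Gaussian beam
#'
#' Aplanatic (Richards-Wolf) apodization \eqn{\sqrt{\cos\theta}} times the
#' Gaussian filling-factor truncation
#' \eqn{\exp[-(\sin\theta/(f_0 \sin\theta_{max}))^2]}; zero beyond the
#' aperture angle \eqn{\theta_{max} = \arcsin(NA/n_{glass})}.
#'
#' @param theta polar angle(s), radians, in \eqn{[0, \pi/2]}.
#' @param beam a [beam_spec()].
#' @param objective an [objective_spec()].
#' @return apodization weight(s), same length as `theta`.
#' @export
pupil_apodization <- function(theta, beam = beam_spec(),
                              objective = objective_spec()) {
  if (any(theta < 0 | theta > pi / 2)) stopf("theta must be in [0, pi/2]")
  theta_max <- asin(objective$NA_ / objective$n_immersion)
  w <- sqrt(cos(theta)) *
    exp(-(sin(theta) / (beam$filling_factor * sin(theta_max)))^2)
  w[theta > theta_max] <- 0
  w
}

# Quadrature-ready ingredients of the focused angular spectrum.
# Returns per-node data for the theta integrals shared by every evaluator.
beam_quadrature <- function(beam, objective, interface = NULL,
                            n_theta = 120) {
  n1 <- objective$n_immersion
  theta_max <- asin(objective$NA_ / n1)
  gl <- gauss_legendre(n_theta, 0, theta_max)
  s1 <- sin(gl$x); c1 <- cos(gl$x)
  fw <- exp(-(s1 / (beam$filling_factor * sin(theta_max)))^2)

  lambda_m <- beam$wavelength_nm * 1e-9
  k0 <- 2 * pi / lambda_m                       # rad/m
  if (is.null(interface)) {
    n2 <- n1
    s2 <- s1; c2 <- as.complex(c1)
    ts <- tp <- rep(1 + 0i, length(s1))
    z_int_m <- -Inf
  } else {
    n2 <- interface$n_water
    s2 <- n1 * s1 / n2
    c2 <- sqrt(as.complex(1 - s2^2))            # principal sqrt: Im >= 0
    ts <- 2 * n1 * c1 / (n1 * c1 + n2 * c2)
    tp <- 2 * n1 * c1 / (n1 * c2 + n2 * c1)
    z_int_m <- interface$interface_z_nm * 1e-9
  }

  # Amplitude normalization: requested power crosses the aperture.
  # P = (C^2 / (2 eta0)) * 2*pi*Qp with C = f*E0,  Qp = int fw^2 c1 s1 dtheta.
  Qp <- sum(gl$w * fw^2 * c1 * s1)
  P_W <- beam$power_mW * 1e-3
  C <- sqrt(.const$eta0 * P_W / (pi * Qp))
  A <- 1i * (k0 * n1) * C / (2 * sqrt(n1))      # field prefactor, V/m

  list(theta = gl$x, w = gl$w, s1 = s1, c1 = c1, s2 = s2, c2 = c2,
       ts = ts, tp = tp, fw = fw, B = fw * sqrt(c1) * s1,
       k0 = k0, n1 = n1, n2 = n2, k1t = k0 * n1 * s1,
       k1z = k0 * n1 * c1, k2z = k0 * n2 * c2,
       z_int_m = z_int_m, A = A, interface = !is.null(interface))
}

#' Focused E and H fields at arbitrary points
#'
#' Evaluates the vector diffraction integrals of the focused beam at an
#' arbitrary set of points, in the homogeneous immersion medium
#' (`interface = NULL`) or in the aqueous region behind the glass-aqueous
#' interface. This is the evaluator behind the grid constructors and the
#' scattering pipeline.
#'
#' @param points_nm N x 3 matrix of coordinates (nm); with an interface all
#'   points must satisfy z > interface_z (aqueous side).
#' @param beam a [beam_spec()].
#' @param objective an [objective_spec()].
#' @param interface an [interface_spec()] or NULL.
#' @param n_theta polar quadrature order.
#' @param quad precomputed quadrature ingredients (internal use).
#' @return list(E, H): N x 3 complex matrices (V/m, A/m).
#' @export
focal_field_points <- function(points_nm, beam = beam_spec(),
                               objective = objective_spec(),
                               interface = NULL, n_theta = 120,
                               quad = NULL) {
  pts <- as.matrix(points_nm)
  if (ncol(pts) != 3) stopf("points must be an N x 3 matrix")
  q <- quad %||% beam_quadrature(beam, objective, interface, n_theta)
  if (q$interface && any(pts[, 3] * 1e-9 <= q$z_int_m))
    stopf("all evaluation points must lie in the aqueous region (z > interface)")

  x <- pts[, 1] * 1e-9; y <- pts[, 2] * 1e-9; z <- pts[, 3] * 1e-9
  rho <- sqrt(x^2 + y^2)
  phir <- atan2(y, x)

  nq <- length(q$theta); np <- nrow(pts)
  arg <- q$k1t %o% rho                          # nq x np
  J0 <- matrix(besselJ(arg, 0), nq, np)
  J1 <- matrix(besselJ(arg, 1), nq, np)
  J2 <- matrix(besselJ(arg, 2), nq, np)
  if (q$interface) {
    ph <- exp(1i * (outer(q$k2z, z - q$z_int_m) + q$k1z * q$z_int_m))
  } else {
    ph <- exp(1i * outer(as.complex(q$k1z), z))
  }
  P0 <- J0 * ph; P1 <- J1 * ph; P2 <- J2 * ph

  int1 <- function(coef, P) drop(rbind(q$w * coef) %*% P)   # length-np complex
  I0  <- int1(q$B * (q$ts + q$tp * q$c2), P0)
  I1  <- int1(q$B * (q$tp * q$s2),        P1)
  I2  <- int1(q$B * (q$ts - q$tp * q$c2), P2)
  Ih0 <- int1(q$B * (q$tp + q$ts * q$c2), P0)
  Ih1 <- int1(q$B * (q$ts * q$s2),        P1)
  Ih2 <- int1(q$B * (q$tp - q$ts * q$c2), P2)

  A <- q$A
  hA <- q$n2 / .const$eta0 * A
  c2f <- cos(2 * phir); s2f <- sin(2 * phir)
  cf <- cos(phir); sf <- sin(phir)

  # x-polarized input
  Ex_x <- A * (I0 + I2 * c2f); Ey_x <- A * I2 * s2f
  Ez_x <- -2i * A * I1 * cf
  Hx_x <- hA * Ih2 * s2f; Hy_x <- hA * (Ih0 - Ih2 * c2f)
  Hz_x <- -2i * hA * Ih1 * sf
  # y-polarized input (rigid 90-degree rotation of the x-polarized solution)
  Ex_y <- A * I2 * s2f; Ey_y <- A * (I0 - I2 * c2f)
  Ez_y <- -2i * A * I1 * sf
  Hx_y <- -hA * (Ih0 + Ih2 * c2f); Hy_y <- -hA * Ih2 * s2f
  Hz_y <- 2i * hA * Ih1 * cf

  psi <- beam$polarization_angle
  cp <- cos(psi); sp <- sin(psi)
  E <- cbind(cp * Ex_x + sp * Ex_y, cp * Ey_x + sp * Ey_y,
             cp * Ez_x + sp * Ez_y)
  H <- cbind(cp * Hx_x + sp * Hx_y, cp * Hy_x + sp * Hy_y,
             cp * Hz_x + sp * Hz_y)
  colnames(E) <- colnames(H) <- c("x", "y", "z")
  list(E = E, H = H)
}

#' Focal field of the focused beam in the homogeneous immersion medium
#'
#' Evaluates the Richards-Wolf diffraction integrals (azimuthal part analytic
#' via Bessel functions, polar part by Gauss-Legendre quadrature) on a
#' Cartesian grid around the focus, with no glass-aqueous interface.
#' The field amplitude is normalized so that the power crossing a transverse
#' plane equals `beam$power_mW`.
#'
#' @param beam a [beam_spec()].
#' @param objective an [objective_spec()].
#' @param x_nm,y_nm,z_nm grid axes (nm), each a monotone numeric vector.
#' @param n_theta polar quadrature order.
#' @param check_convergence if TRUE, re-evaluate the peak field at doubled
#'   quadrature order and error out if it moved by more than `conv_tol`.
#' @param conv_tol relative convergence tolerance on the peak field.
#' @return a [vector_field_grid] object.
#' @export
focal_field_free <- function(beam = beam_spec(), objective = objective_spec(),
                             x_nm = seq(-1000, 1000, by = 25),
                             y_nm = 0,
                             z_nm = seq(-1500, 1500, by = 25),
                             n_theta = 120, check_convergence = FALSE,
                             conv_tol = 5e-3) {
  focal_field_grid(beam, objective, NULL, x_nm, y_nm, z_nm, n_theta,
                   check_convergence, conv_tol)
}

#' Focal field of the focused beam through the glass-aqueous interface
#'
#' Each plane-wave component of the converging angular spectrum acquires its
#' Fresnel transmission (s/p decomposition) and the stratified-medium
#' aberration phase; components beyond the critical angle carry a decaying
#' axial wavenumber. Fields are returned in the aqueous region only; grid
#' nodes on the glass side are filled with NA.
#'
#' @inheritParams focal_field_free
#' @param interface an [interface_spec()].
#' @return a [vector_field_grid] object.
#' @export
focal_field_interface <- function(beam = beam_spec(),
                                  objective = objective_spec(),
                                  interface = interface_spec(),
                                  x_nm = seq(-1000, 1000, by = 25),
                                  y_nm = 0,
                                  z_nm = seq(-1500, 1500, by = 25),
                                  n_theta = 120, check_convergence = FALSE,
                                  conv_tol = 5e-3) {
  if (interface$interface_z_nm > max(z_nm) ||
      interface$interface_z_nm < min(z_nm))
    stopf("interface lies outside the requested grid")
  focal_field_grid(beam, objective, interface, x_nm, y_nm, z_nm, n_theta,
                   check_convergence, conv_tol)
}

focal_field_grid <- function(beam, objective, interface, x_nm, y_nm, z_nm,
                             n_theta, check_convergence, conv_tol) {
  for (ax in list(x_nm, y_nm, z_nm))
    if (length(ax) > 1 && any(diff(ax) <= 0)) stopf("grid axes must be monotone")
  g <- expand.grid(x = x_nm, y = y_nm, z = z_nm)
  pts <- as.matrix(g)
  in_water <- if (is.null(interface)) rep(TRUE, nrow(pts))
              else pts[, 3] > interface$interface_z_nm

  nx <- length(x_nm); ny <- length(y_nm); nz <- length(z_nm)
  E <- H <- array(NA_complex_, c(nx, ny, nz, 3))
  if (any(in_water)) {
    f <- focal_field_points(pts[in_water, , drop = FALSE], beam, objective,
                            interface, n_theta)
    for (k in 1:3) {
      tmp <- array(NA_complex_, nx * ny * nz)
      tmp[in_water] <- f$E[, k]
      E[, , , k] <- tmp
      tmp[in_water] <- f$H[, k]
      H[, , , k] <- tmp
    }
    if (check_convergence) {
      ipk <- which.max(rowSums(abs(f$E)^2))
      f2 <- focal_field_points(pts[in_water, , drop = FALSE][ipk, , drop = FALSE],
                               beam, objective, interface, 2 * n_theta)
      pk1 <- sqrt(sum(abs(f$E[ipk, ])^2)); pk2 <- sqrt(sum(abs(f2$E)^2))
      if (abs(pk2 - pk1) / pk2 > conv_tol)
        stopf("quadrature not converged: peak |E| changed by %.2g on doubling n_theta",
              abs(pk2 - pk1) / pk2)
    }
  }
  n_medium <- if (is.null(interface)) rep(objective$n_immersion, nz) else
    ifelse(z_nm > interface$interface_z_nm, interface$n_water,
           interface$n_glass)
  vector_field_grid(x_nm, y_nm, z_nm, E, H, n_medium, beam$wavelength_nm,
                    interface = interface)
}

#' On-axis intensity profile and axial focus location
#'
#' Evaluates \eqn{|E|^2} along the optical axis and locates its maximum by
#' parabolic refinement around the grid maximum. If a secondary local maximum
#' comes within 1\% of the peak, an ambiguity warning is recorded in the
#' result (attribute `ambiguous`).
#'
#' @inheritParams focal_field_free
#' @param interface an [interface_spec()] or NULL for the matched case.
#' @param z_nm axial sample positions (nm).
#' @return list with `z_nm`, `intensity` (|E|^2, (V/m)^2), `z_peak_nm`,
#'   and logical `ambiguous`.
#' @export
focus_axial_profile <- function(beam = beam_spec(),
                                objective = objective_spec(),
                                interface = NULL,
                                z_nm = NULL, n_theta = 120) {
  if (is.null(z_nm)) {
    z_lo <- if (is.null(interface)) -1500 else interface$interface_z_nm + 20
    z_nm <- seq(z_lo, 1500, by = 20)
  }
  pts <- cbind(0, 0, z_nm)
  f <- focal_field_points(pts, beam, objective, interface, n_theta)
  I <- rowSums(abs(f$E)^2)
  i0 <- which.max(I)
  if (i0 == 1 || i0 == length(I))
    stopf("axial intensity maximum at the edge of the scan range")
  zpk <- parabolic_vertex(z_nm[i0], z_nm[i0 + 1] - z_nm[i0],
                          I[i0 - 1], I[i0], I[i0 + 1])
  # secondary-lobe ambiguity: another local max within 1% of the peak
  loc <- which(diff(sign(diff(I))) == -2) + 1
  loc <- setdiff(loc, i0)
  ambiguous <- length(loc) > 0 && any(I[loc] > 0.99 * I[i0])
  list(z_nm = z_nm, intensity = I, z_peak_nm = zpk, ambiguous = ambiguous)
}

#' Focal shift ratio of the beam focus
#'
#' Computes the displacement of the axial intensity maximum per unit
#' displacement of the coverslip surface. For each interface depth the
#' focus-to-surface distance \eqn{h_{focus} = z_{peak} + d} is measured; the
#' focal shift ratio is the least-squares slope of \eqn{h_{focus}} versus
#' depth (equivalently, versus the stage coordinate zsurf).
#'
#' @inheritParams focal_field_free
#' @param depths_nm interface depths to scan (>= 4 values spanning >= 1 um).
#' @param n_glass,n_water interface indices.
#' @param z_step_nm axial scan step for peak location.
#' @return list of class `focal_shift_estimate` with `fs`, `se`, `method`,
#'   per-depth peak positions, and the fit.
#' @export
focus_shift_ratio_beam <- function(beam = beam_spec(),
                                   objective = objective_spec(),
                                   depths_nm = seq(500, 2500, by = 500),
                                   n_glass = 1.518, n_water = 1.326,
                                   n_theta = 120, z_step_nm = 20) {
  if (length(depths_nm) < 4 || diff(range(depths_nm)) < 1000)
    stopf("need >= 4 depths spanning >= 1 um")
  matched <- abs(n_glass - n_water) < .Machine$double.eps^0.5
  h <- amb <- numeric(length(depths_nm))
  for (i in seq_along(depths_nm)) {
    d <- depths_nm[i]
    iface <- if (matched) NULL else
      interface_spec(depth_nm = d, n_glass = n_glass, n_water = n_water)
    # the aberrated focus lies between the interface and the nominal focus;
    # scan a window wide enough for low-NA (long Rayleigh range) cases too
    zr <- objective$n_immersion * beam$wavelength_nm /
      (pi * objective$NA_^2)
    half <- max(800, min(3 * zr, 0.45 * d + 2000))
    z_lo <- max(if (matched) -Inf else -d + z_step_nm, -half)
    prof <- focus_axial_profile(beam, objective, iface,
                                z_nm = seq(z_lo, half, by = z_step_nm),
                                n_theta = n_theta)
    h[i] <- prof$z_peak_nm + d
    amb[i] <- prof$ambiguous
  }
  fit <- stats::lm(h ~ depths_nm)
  structure(list(fs = unname(stats::coef(fit)[2]),
                 se = suppressWarnings(summary(fit))$coefficients[2, 2],
                 method = "beam-sim",
                 depths_nm = depths_nm, h_focus_nm = h,
                 ambiguous = as.logical(amb), fit = fit),
            class = "focal_shift_estimate")
}

#' @export
print.focal_shift_estimate <- function(x, ...) {
  cat(sprintf("Focal shift estimate (%s): fs = %.4f +/- %.4f\n",
              x$method, x$fs, x$se))
  invisible(x)
}
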