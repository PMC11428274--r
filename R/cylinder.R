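# The trapped particle: a nanofabricated truncated-cone quartz cylinder,
# uniaxial with its extraordinary axis perpendicular to the cylinder axis,
# discretized on a cubic dipole lattice for the coupled-dipole solver.

#' Quartz cylinder specification
#'
#' Dimensions default to the fabricated cylinders (SEM means): 473 nm bottom
#' diameter, 589 nm top diameter, 1016 nm height. The quartz is uniaxial
#' with the extraordinary (optic) axis perpendicular to the cylinder axis;
#' `alpha` is the angle between the extraordinary axis and the x axis (the
#' default beam polarization) in the transverse plane.
#'
#' @param bottom_diameter_nm,top_diameter_nm,height_nm geometry (nm).
#' @param n_ordinary,n_extraordinary principal refractive indices of quartz
#'   at 1064 nm.
#' @param alpha misalignment angle of the extraordinary axis, radians.
#' @return object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(bottom_diameter_nm = 473, top_diameter_nm = 589,
                          height_nm = 1016, n_ordinary = 1.5341,
                          n_extraordinary = 1.5428, alpha = 0) {
  if (min(bottom_diameter_nm, top_diameter_nm, height_nm) <= 0)
    stopf("cylinder dimensions must be positive")
  if (min(n_ordinary, n_extraordinary) <= 1)
    stopf("refractive indices must exceed 1")
  structure(list(bottom_diameter_nm = bottom_diameter_nm,
                 top_diameter_nm = top_diameter_nm,
                 height_nm = height_nm,
                 n_ordinary = n_ordinary,
                 n_extraordinary = n_extraordinary,
                 alpha = alpha),
            class = "cylinder_spec")
}

#' Frustum volume of a cylinder spec
#' @param cylinder a [cylinder_spec()].
#' @return volume in nm^3.
#' @export
cylinder_volume <- function(cylinder) {
  d1 <- cylinder$bottom_diameter_nm; d2 <- cylinder$top_diameter_nm
  pi * cylinder$height_nm / 12 * (d1^2 + d1 * d2 + d2^2)
}

#' Relative permittivity tensor of the uniaxial cylinder in the lab frame
#'
#' diag(ne^2, no^2, no^2) in the crystal frame (extraordinary axis first),
#' rotated by `alpha` about the cylinder (z) axis.
#'
#' @param cylinder a [cylinder_spec()].
#' @param alpha optional override of the misalignment angle (radians).
#' @return 3 x 3 relative permittivity matrix.
#' @export
permittivity_tensor <- function(cylinder = cylinder_spec(),
                                alpha = cylinder$alpha) {
  eps_c <- diag(c(cylinder$n_extraordinary^2, cylinder$n_ordinary^2,
                  cylinder$n_ordinary^2))
  ca <- cos(alpha); sa <- sin(alpha)
  R <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  R %*% eps_c %*% t(R)
}

#' Dipole-lattice discretization of the cylinder
#'
#' Cubic lattice clipped to the truncated-cone hull, centered on the
#' cylinder's geometric center (mid-height, on-axis). Each dipole carries the
#' anisotropic Clausius-Mossotti polarizability relative to the surrounding
#' medium, with the radiative-reaction correction, diagonal along the crystal
#' axes and rotated to the lab frame by `alpha`.
#'
#' @param cylinder a [cylinder_spec()].
#' @param spacing_nm lattice spacing; must satisfy
#'   spacing <= lambda0 / (10 max(n)).
#' @param n_medium refractive index of the surrounding medium.
#' @param wavelength_nm vacuum wavelength (nm).
#' @return object of class `dipole_model`: positions (N x 3, nm, body frame
#'   with origin at the geometric center), spacing, the 3 x 3 complex lab
#'   polarizability tensor (C m^2/V), medium index and wavenumber.
#' @export
build_lattice <- function(cylinder = cylinder_spec(), spacing_nm = 50,
                          n_medium = 1.326, wavelength_nm = 1064) {
  n_max <- max(cylinder$n_ordinary, cylinder$n_extraordinary)
  if (spacing_nm > wavelength_nm / (10 * n_max))
    stopf("lattice spacing %.1f nm too coarse: need <= lambda0/(10 n) = %.1f nm",
          spacing_nm, wavelength_nm / (10 * n_max))
  h <- cylinder$height_nm
  rb <- cylinder$bottom_diameter_nm / 2
  rt <- cylinder$top_diameter_nm / 2
  nz <- max(1L, round(h / spacing_nm))
  nxy <- ceiling(max(rb, rt) / spacing_nm)
  ax_xy <- (seq(-nxy, nxy) ) * spacing_nm
  ax_z <- (seq_len(nz) - (nz + 1) / 2) * spacing_nm     # centered at mid-height
  g <- expand.grid(x = ax_xy, y = ax_xy, z = ax_z)
  tfrac <- (g$z + h / 2) / h                            # 0 at bottom, 1 at top
  rloc <- rb + tfrac * (rt - rb)
  keep <- g$x^2 + g$y^2 <= rloc^2
  pos <- as.matrix(g[keep, , drop = FALSE])

  # per-axis Clausius-Mossotti + radiative reaction, crystal frame
  eps_m <- n_medium^2
  k <- 2 * pi * n_medium / (wavelength_nm * 1e-9)       # rad/m in medium
  Vd <- (spacing_nm * 1e-9)^3
  eps_ax <- c(cylinder$n_extraordinary^2, cylinder$n_ordinary^2,
              cylinder$n_ordinary^2)
  a_cm <- 3 * Vd * .const$eps0 * eps_m * (eps_ax - eps_m) / (eps_ax + 2 * eps_m)
  a_rc <- a_cm / (1 - 1i * k^3 * a_cm / (6 * pi * .const$eps0 * eps_m))
  ca <- cos(cylinder$alpha); sa <- sin(cylinder$alpha)
  R <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  alpha_lab <- R %*% diag(a_rc) %*% t(R)

  structure(list(positions_nm = pos, spacing_nm = spacing_nm,
                 polarizability = alpha_lab, n_medium = n_medium,
                 wavelength_nm = wavelength_nm, k_medium = k,
                 cylinder = cylinder),
            class = "dipole_model")
}

#' @export
print.dipole_model <- function(x, ...) {
  cat(sprintf(
    "dipole_model: %d dipoles, spacing %g nm, medium n = %g\n",
    nrow(x$positions_nm), x$spacing_nm, x$n_medium))
  invisible(x)
}
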