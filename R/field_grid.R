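# Container for vector electromagnetic fields sampled on a Cartesian grid,
# plus the numeric diagnostics (Poynting flux, divergence) used to validate
# the focused-beam computation.

#' Vector field grid
#'
#' Complex E (V/m) and H (A/m) 3-vectors on a Cartesian grid with medium
#' metadata. Constructed by [focal_field_free()] / [focal_field_interface()];
#' the constructor is exported for completeness.
#'
#' @param x_nm,y_nm,z_nm monotone grid axes (nm).
#' @param E,H complex arrays of dimension (nx, ny, nz, 3).
#' @param n_medium refractive index per z-plane (length nz).
#' @param wavelength_nm vacuum wavelength (nm).
#' @param interface optional [interface_spec()] the field was computed with.
#' @return object of class `vector_field_grid`.
#' @export
vector_field_grid <- function(x_nm, y_nm, z_nm, E, H, n_medium,
                              wavelength_nm, interface = NULL) {
  dims <- c(length(x_nm), length(y_nm), length(z_nm), 3)
  if (!all(dim(E) == dims) || !all(dim(H) == dims))
    stopf("E and H must have dimension (nx, ny, nz, 3)")
  for (ax in list(x_nm, y_nm, z_nm))
    if (length(ax) > 1 && any(diff(ax) <= 0)) stopf("grid axes must be monotone")
  if (any(!is.finite(Mod(E[!is.na(E)]))))
    stopf("fields must be finite")
  structure(list(x_nm = x_nm, y_nm = y_nm, z_nm = z_nm, E = E, H = H,
                 n_medium = n_medium, wavelength_nm = wavelength_nm,
                 interface = interface),
            class = "vector_field_grid")
}

#' @export
print.vector_field_grid <- function(x, ...) {
  cat(sprintf(
    "vector_field_grid: %d x %d x %d nodes, lambda0 = %g nm\n",
    length(x$x_nm), length(x$y_nm), length(x$z_nm), x$wavelength_nm))
  pk <- max(sqrt(apply(abs(x$E)^2, 1:3, sum)), na.rm = TRUE)
  cat(sprintf("  peak |E| = %.4g V/m; media: %s\n", pk,
              paste(unique(signif(x$n_medium, 4)), collapse = " / ")))
  invisible(x)
}

#' Poynting flux of the focused beam through a transverse plane
#'
#' Integrates the time-averaged axial Poynting component
#' \eqn{S_z = \frac12 Re(E \times H^*)_z} over a transverse plane by polar
#' Gauss-Legendre x trapezoid quadrature, evaluating the fields directly from
#' the diffraction integrals (no grid interpolation).
#'
#' @inheritParams focal_field_free
#' @param interface an [interface_spec()] or NULL.
#' @param z_nm axial position of the plane (nm).
#' @param r_max_nm radial extent of the quadrature (nm).
#' @param n_r,n_phi radial / azimuthal quadrature orders.
#' @return power crossing the plane, mW.
#' @export
poynting_flux_plane <- function(beam = beam_spec(),
                                objective = objective_spec(),
                                interface = NULL, z_nm = 0,
                                r_max_nm = 3000, n_r = 60, n_phi = 32,
                                n_theta = 120) {
  gl <- gauss_legendre(n_r, 0, r_max_nm)
  phi <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  pts <- cbind(as.vector(outer(gl$x, cos(phi))),
               as.vector(outer(gl$x, sin(phi))), z_nm)
  f <- focal_field_points(pts, beam, objective, interface, n_theta)
  Sz <- 0.5 * Re(f$E[, 1] * Conj(f$H[, 2]) - f$E[, 2] * Conj(f$H[, 1]))
  w2 <- as.vector(outer(gl$w * gl$x, rep(2 * pi / n_phi, n_phi)))
  sum(w2 * Sz) * 1e-18 * 1e3   # nm^2 -> m^2, W -> mW
}

#' Numerical divergence of E on a field grid
#'
#' Central-difference divergence of the complex E field, for checking the
#' source-free Maxwell constraint in homogeneous regions. Returns the
#' divergence normalized by k |E| at each interior node (dimensionless).
#'
#' @param grid a [vector_field_grid].
#' @return array (nx-2, ny-2, nz-2) of |div E| / (k |E|).
#' @export
field_divergence <- function(grid) {
  d <- dim(grid$E)
  if (any(d[1:3] < 3)) stopf("divergence needs >= 3 nodes per axis")
  hx <- diff(grid$x_nm)[1] * 1e-9
  hy <- diff(grid$y_nm)[1] * 1e-9
  hz <- diff(grid$z_nm)[1] * 1e-9
  ii <- 2:(d[1] - 1); jj <- 2:(d[2] - 1); kk <- 2:(d[3] - 1)
  div <- (grid$E[ii + 1, jj, kk, 1] - grid$E[ii - 1, jj, kk, 1]) / (2 * hx) +
         (grid$E[ii, jj + 1, kk, 2] - grid$E[ii, jj - 1, kk, 2]) / (2 * hy) +
         (grid$E[ii, jj, kk + 1, 3] - grid$E[ii, jj, kk - 1, 3]) / (2 * hz)
  k <- 2 * pi / (grid$wavelength_nm * 1e-9) *
    array(rep(grid$n_medium[kk], each = length(ii) * length(jj)),
          c(length(ii), length(jj), length(kk)))
  Emag <- sqrt(Re(grid$E[ii, jj, kk, 1] * Conj(grid$E[ii, jj, kk, 1]) +
                  grid$E[ii, jj, kk, 2] * Conj(grid$E[ii, jj, kk, 2]) +
                  grid$E[ii, jj, kk, 3] * Conj(grid$E[ii, jj, kk, 3])))
  abs(div) / (k * Emag)
}

#' Export a 2-D slice of a field grid to TSV
#'
#' Writes one row per grid node of the selected slice with real/imaginary
#' field components, plus a JSON metadata side file (axes, wavelength,
#' media).
#'
#' @param grid a [vector_field_grid].
#' @param path output TSV path; metadata is written to `<path>.json`.
#' @param y_index index along y of the slice to export.
#' @return `path`, invisibly.
#' @export
write_field_slice <- function(grid, path, y_index = 1) {
  g <- expand.grid(x_nm = grid$x_nm, z_nm = grid$z_nm)
  sl <- function(a, k) as.vector(a[, y_index, , k])
  df <- data.frame(
    x_nm = g$x_nm, y_nm = grid$y_nm[y_index], z_nm = g$z_nm,
    Ex_re = Re(sl(grid$E, 1)), Ex_im = Im(sl(grid$E, 1)),
    Ey_re = Re(sl(grid$E, 2)), Ey_im = Im(sl(grid$E, 2)),
    Ez_re = Re(sl(grid$E, 3)), Ez_im = Im(sl(grid$E, 3)),
    Hx_re = Re(sl(grid$H, 1)), Hx_im = Im(sl(grid$H, 1)),
    Hy_re = Re(sl(grid$H, 2)), Hy_im = Im(sl(grid$H, 2)),
    Hz_re = Re(sl(grid$H, 3)), Hz_im = Im(sl(grid$H, 3)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(wavelength_nm = grid$wavelength_nm,
               x_nm = range(grid$x_nm), z_nm = range(grid$z_nm),
               n_medium = unique(grid$n_medium))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
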