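# Optical force and torque from the time-averaged Maxwell stress tensor,
# integrated over a closed cuboid surface in the aqueous medium enclosing
# the particle. The tensor is the anisotropic-medium form
#   T = D (x) E + B (x) H - (D.E + B.H)/2 I
# evaluated with the half-real-part convention for time-harmonic complex
# fields; on the integration surface the medium is water, so D = eps0 n^2 E.

#' Time-averaged Maxwell stress tensor field
#'
#' Evaluates \eqn{\langle T \rangle = \frac12 Re[D \otimes E^* + B \otimes H^*
#' - \frac12 (D \cdot E^* + B \cdot H^*) I]} at each point. `epsilon` may be
#' a scalar relative permittivity (isotropic medium) or a 3 x 3 relative
#' tensor; `mu` is the scalar relative permeability (1 for water and quartz).
#'
#' @param E,H M x 3 complex field matrices (V/m, A/m).
#' @param epsilon relative permittivity, scalar or 3 x 3 matrix.
#' @param mu relative permeability, scalar.
#' @return 3 x 3 x M array (N/m^2).
#' @export
mst_tensor <- function(E, H, epsilon = 1.326^2, mu = 1) {
  E <- rbind(E); H <- rbind(H)
  m <- nrow(E)
  if (is.matrix(epsilon)) {
    D <- .const$eps0 * E %*% t(epsilon)
  } else {
    D <- .const$eps0 * epsilon * E
  }
  B <- .const$mu0 * mu * H
  Tarr <- array(0, c(3, 3, m))
  uEH <- 0.5 * Re(rowSums(D * Conj(E)) + rowSums(B * Conj(H)))
  for (a in 1:3) for (b in 1:3) {
    Tarr[a, b, ] <- 0.5 * Re(D[, a] * Conj(E[, b]) + B[, a] * Conj(H[, b])) -
      (a == b) * 0.5 * uEH
  }
  Tarr
}

# Cuboid integration surface: tensor-product Gauss-Legendre nodes on each of
# the six faces. half_nm = half-extents (3-vector), center_nm = box center.
# Returns points (M x 3, nm), outward normals (M x 3), weights (M, nm^2).
integration_surface <- function(center_nm = c(0, 0, 0),
                                half_nm = c(500, 500, 700),
                                n_face = 20) {
  gl <- gauss_legendre(n_face, -1, 1)
  pts <- nrm <- NULL
  wts <- NULL
  for (axis in 1:3) for (sgn in c(-1, 1)) {
    oth <- setdiff(1:3, axis)
    u <- gl$x %o% rep(1, n_face); v <- rep(1, n_face) %o% gl$x
    w2 <- (gl$w %o% gl$w) * half_nm[oth[1]] * half_nm[oth[2]]
    p <- matrix(0, n_face^2, 3)
    p[, oth[1]] <- as.vector(u) * half_nm[oth[1]]
    p[, oth[2]] <- as.vector(v) * half_nm[oth[2]]
    p[, axis] <- sgn * half_nm[axis]
    nn <- matrix(0, n_face^2, 3); nn[, axis] <- sgn
    pts <- rbind(pts, sweep(p, 2, center_nm, "+"))
    nrm <- rbind(nrm, nn)
    wts <- c(wts, as.vector(w2))
  }
  list(points_nm = pts, normals = nrm, weights_nm2 = wts)
}

# Traction (T . n) at each surface point, N/m^2 (M x 3 real matrix).
mst_traction <- function(E, H, normals, n_medium) {
  eps <- .const$eps0 * n_medium^2
  mu0 <- .const$mu0
  En <- rowSums(E * normals); Hn <- rowSums(H * normals)
  u <- 0.5 * (eps * rowSums(Mod(E)^2) + mu0 * rowSums(Mod(H)^2))
  0.5 * Re(eps * E * Conj(En) + mu0 * H * Conj(Hn)) - 0.5 * u * normals
}

#' Optical force from a stress-tensor surface integral
#'
#' Integrates the time-averaged Maxwell stress tensor traction of the total
#' (incident + scattered) field over a closed cuboid surface in the aqueous
#' medium enclosing the particle.
#'
#' @param E,H total fields at the surface points (M x 3 complex).
#' @param surface an `integration_surface()` list (points, normals, weights).
#' @param n_medium refractive index of the medium on the surface.
#' @return force 3-vector, pN.
#' @export
optical_force <- function(E, H, surface, n_medium = 1.326) {
  tr <- mst_traction(E, H, surface$normals, n_medium)
  colSums(tr * surface$weights_nm2) * 1e-18 * 1e12    # nm^2 -> m^2, N -> pN
}

#' Optical torque from an angular-momentum-flux surface integral
#'
#' \eqn{\tau = \oint (r - r_0) \times (\langle T \rangle \cdot n) dS} about
#' the reference point `reference_nm` (defaults to the cylinder's geometric
#' center when called through the trap machinery).
#'
#' @inheritParams optical_force
#' @param reference_nm torque reference point (nm, lab frame).
#' @return torque 3-vector, pN nm; the reference point is attached as an
#'   attribute.
#' @export
optical_torque <- function(E, H, surface, n_medium = 1.326,
                           reference_nm = c(0, 0, 0)) {
  tr <- mst_traction(E, H, surface$normals, n_medium)   # N/m^2
  rel <- sweep(surface$points_nm, 2, reference_nm, "-") # nm
  cr <- cbind(rel[, 2] * tr[, 3] - rel[, 3] * tr[, 2],
              rel[, 3] * tr[, 1] - rel[, 1] * tr[, 3],
              rel[, 1] * tr[, 2] - rel[, 2] * tr[, 1])  # nm N/m^2
  tau <- colSums(cr * surface$weights_nm2)              # nm^3 N/m^2
  structure(tau * 1e-27 * 1e21, reference_nm = reference_nm) # -> N m -> pN nm
}
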