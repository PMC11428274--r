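# Coupled-dipole (discrete-dipole) scattering: interaction matrix with the
# free-space dyadic Green's function of the aqueous medium, dense direct
# solve (with a Bi-CGSTAB fallback for large lattices), and evaluation of the
# scattered E and H fields radiated by the solved dipole moments.

# 3x3 Green block layout helpers: dipole i occupies rows/cols 3i-2 .. 3i.

# Build the dense coupled-dipole system matrix M = alpha^{-1} - G (3N x 3N,
# complex, SI units). alpha is the (common) lab-frame polarizability tensor.
dda_matrix <- function(model) {
  pos <- model$positions_nm * 1e-9
  n <- nrow(pos)
  k <- model$k_medium
  eps_m <- model$n_medium^2
  pref <- 1 / (4 * pi * .const$eps0 * eps_m)

  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dz <- outer(pos[, 3], pos[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  diag(r) <- Inf
  ir <- 1 / r
  e <- exp(1i * k * r)
  C1 <- pref * e * k^2 * ir                 # transverse term
  C2 <- pref * e * (ir^3 - 1i * k * ir^2)   # near-field term
  ux <- dx * ir; uy <- dy * ir; uz <- dz * ir

  M <- matrix(0i, 3 * n, 3 * n)
  rows <- rep(seq_len(n), times = n); cols <- rep(seq_len(n), each = n)
  u <- list(ux, uy, uz)
  for (a in 1:3) for (b in 1:3) {
    uab <- u[[a]] * u[[b]]
    gab <- C1 * ((a == b) - uab) + C2 * (3 * uab - (a == b))
    M[cbind(3 * (rows - 1) + a, 3 * (cols - 1) + b)] <- -as.vector(gab)
  }
  ai <- solve(model$polarizability)
  idx <- seq_len(n)
  for (a in 1:3) for (b in 1:3)
    M[cbind(3 * (idx - 1) + a, 3 * (idx - 1) + b)] <- ai[a, b]
  M
}

#' Solve the coupled-dipole system for an incident field
#'
#' Solves \eqn{p_i = \alpha_i (E_{inc}(r_i) + \sum_{j \ne i} G_{ij} p_j)}
#' with the free-space dyadic Green's function of the surrounding medium.
#' Lattices below `max_direct` dipoles use a dense direct solve; larger ones
#' use Bi-CGSTAB on the stored matrix. The achieved relative residual is
#' always computed and reported.
#'
#' @param incident either a function `f(points_nm)` returning
#'   `list(E = N x 3 complex)` (a [vector_field_grid] is also accepted and
#'   interpolated trilinearly), or an N x 3 complex matrix of incident E at
#'   the dipole positions.
#' @param model a [build_lattice()] dipole model.
#' @param center_nm position of the cylinder's geometric center in the lab
#'   frame (nm); dipole positions are `model$positions_nm + center_nm`.
#' @param max_direct dipole count above which the iterative solver is used.
#' @param tol relative residual tolerance for the iterative solver.
#' @return object of class `dda_solution`: `P` (N x 3 complex dipole moments,
#'   C m), `residual`, `positions_nm` (lab frame), and the model.
#' @export
solve_coupled_dipoles <- function(incident, model, center_nm = c(0, 0, 0),
                                  max_direct = 4000, tol = 1e-5) {
  pos_lab <- sweep(model$positions_nm, 2, center_nm, "+")
  Einc <- incident_at(incident, pos_lab)
  n <- nrow(pos_lab)
  M <- dda_matrix(model)
  b <- as.vector(t(Einc))                    # interleaved (x1,y1,z1,x2,...)
  if (n <= max_direct) {
    pvec <- solve(M, b)
  } else {
    pvec <- bicgstab(M, b, tol = tol)
  }
  res <- sqrt(sum(Mod(M %*% pvec - b)^2) / sum(Mod(b)^2))
  if (res > tol)
    stopf("coupled-dipole solve did not reach residual %.1e (got %.1e)",
          tol, res)
  structure(list(P = matrix(pvec, n, 3, byrow = TRUE), residual = res,
                 positions_nm = pos_lab, model = model,
                 center_nm = center_nm),
            class = "dda_solution")
}

# Resolve the incident-field argument to an N x 3 complex matrix.
incident_at <- function(incident, points_nm) {
  if (is.function(incident)) {
    f <- incident(points_nm)
    if (is.list(f)) f$E else f
  } else if (inherits(incident, "vector_field_grid")) {
    interp_field(incident, points_nm)$E
  } else {
    as.matrix(incident)
  }
}

# Trilinear interpolation of a vector_field_grid at arbitrary points.
interp_field <- function(grid, points_nm) {
  pts <- as.matrix(points_nm)
  ax <- list(grid$x_nm, grid$y_nm, grid$z_nm)
  idx <- frac <- matrix(0, nrow(pts), 3)
  for (d in 1:3) {
    a <- ax[[d]]
    if (length(a) == 1) {
      idx[, d] <- 1; frac[, d] <- 0
    } else {
      i <- findInterval(pts[, d], a, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1), length(a) - 1)
      idx[, d] <- i
      frac[, d] <- (pts[, d] - a[i]) / (a[i + 1] - a[i])
    }
  }
  take <- function(arr, k) {
    out <- 0i
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (cx * frac[, 1] + (1 - cx) * (1 - frac[, 1])) *
           (cy * frac[, 2] + (1 - cy) * (1 - frac[, 2])) *
           (cz * frac[, 3] + (1 - cz) * (1 - frac[, 3]))
      ii <- pmin(idx[, 1] + cx, length(ax[[1]]))
      jj <- pmin(idx[, 2] + cy, length(ax[[2]]))
      kk <- pmin(idx[, 3] + cz, length(ax[[3]]))
      out <- out + w * arr[cbind(ii, jj, kk, k)]
    }
    out
  }
  list(E = cbind(take(grid$E, 1), take(grid$E, 2), take(grid$E, 3)),
       H = cbind(take(grid$H, 1), take(grid$H, 2), take(grid$H, 3)))
}

# Plain Bi-CGSTAB for complex dense systems.
bicgstab <- function(A, b, tol = 1e-5, maxit = 400) {
  x <- b * 0; r <- b; r0 <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- b * 0
  nb <- sqrt(sum(Mod(b)^2))
  for (it in seq_len(maxit)) {
    rho1 <- sum(Conj(r0) * r)
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    v <- as.vector(A %*% p)
    alpha <- rho / sum(Conj(r0) * v)
    s <- r - alpha * v
    t <- as.vector(A %*% s)
    omega <- sum(Conj(t) * s) / sum(Conj(t) * t)
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    if (sqrt(sum(Mod(r)^2)) / nb < 0.1 * tol) return(x)
  }
  stopf("Bi-CGSTAB did not converge in %d iterations (residual %.2e)",
        maxit, sqrt(sum(Mod(r)^2)) / nb)
}

# Scattered E and H at target points radiated by dipoles P (C m) at source
# positions (nm). Pairs closer than exclude_radius_nm are skipped (used to
# drop self-terms when targets coincide with or sit next to sources).
green_field_at <- function(targets_nm, sources_nm, P, k_medium, n_medium,
                           exclude_radius_nm = NULL, chunk = 2048) {
  tg <- as.matrix(targets_nm) * 1e-9
  sc <- as.matrix(sources_nm) * 1e-9
  nt <- nrow(tg); ns <- nrow(sc)
  k <- k_medium; eps_m <- n_medium^2
  prefE <- 1 / (4 * pi * .const$eps0 * eps_m)
  prefH <- (.const$c0 / n_medium) * k^2 / (4 * pi)
  excl <- if (is.null(exclude_radius_nm)) 0 else exclude_radius_nm * 1e-9
  E <- H <- matrix(0i, nt, 3)
  P1 <- matrix(P[, 1], nrow = 1); P2 <- matrix(P[, 2], nrow = 1)
  P3 <- matrix(P[, 3], nrow = 1)
  for (i0 in seq(1, nt, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1, nt)
    dx <- outer(tg[ii, 1], sc[, 1], "-")
    dy <- outer(tg[ii, 2], sc[, 2], "-")
    dz <- outer(tg[ii, 3], sc[, 3], "-")
    r <- sqrt(dx^2 + dy^2 + dz^2)
    mask <- r <= excl
    r[mask] <- 1                      # placeholder; contributions zeroed below
    ir <- 1 / r; ir2 <- ir * ir
    e <- exp(1i * k * r)
    e[mask] <- 0i                     # kills C1, C2, C3 for excluded pairs
    C1 <- (prefE * k^2) * e * ir
    C2 <- prefE * e * (ir * ir2 - 1i * k * ir2)
    p1 <- P1[rep(1, length(ii)), ]; p2 <- P2[rep(1, length(ii)), ]
    p3 <- P3[rep(1, length(ii)), ]
    dp <- (dx * p1 + dy * p2 + dz * p3) * ir2       # (rhat.p)/r * r = scaled
    E[ii, 1] <- E[ii, 1] + rowSums(C1 * (p1 - dx * dp) + C2 * (3 * dx * dp - p1))
    E[ii, 2] <- E[ii, 2] + rowSums(C1 * (p2 - dy * dp) + C2 * (3 * dy * dp - p2))
    E[ii, 3] <- E[ii, 3] + rowSums(C1 * (p3 - dz * dp) + C2 * (3 * dz * dp - p3))
    C3 <- prefH * e * (ir - ir2 / (1i * k)) * ir    # includes 1/r of rhat x p
    H[ii, 1] <- H[ii, 1] + rowSums(C3 * (dy * p3 - dz * p2))
    H[ii, 2] <- H[ii, 2] + rowSums(C3 * (dz * p1 - dx * p3))
    H[ii, 3] <- H[ii, 3] + rowSums(C3 * (dx * p2 - dy * p1))
  }
  list(E = E, H = H)
}

#' Scattered field of a coupled-dipole solution
#'
#' @param solution a [solve_coupled_dipoles()] result.
#' @param points_nm M x 3 matrix of lab-frame evaluation points (nm); must
#'   not coincide with dipole positions.
#' @return list(E, H): M x 3 complex matrices (V/m, A/m).
#' @export
scattered_field <- function(solution, points_nm) {
  green_field_at(points_nm, solution$positions_nm, solution$P,
                 solution$model$k_medium, solution$model$n_medium,
                 exclude_radius_nm = solution$model$spacing_nm / 4)
}

# Dipole-summation optical force (independent cross-check of the stress-
# tensor surface integral): F = 1/2 Re sum_i sum_k p*_{ik} grad E_k(r_i),
# with E the incident-plus-scattered field excluding each dipole's own
# radiation, gradients by central differences.
dipole_force_sum <- function(solution, incident, h_nm = 1) {
  pos <- solution$positions_nm
  P <- solution$P
  model <- solution$model
  F <- numeric(3)
  for (d in 1:3) {
    dp <- dm <- pos
    dp[, d] <- dp[, d] + h_nm; dm[, d] <- dm[, d] - h_nm
    excl <- model$spacing_nm / 3
    Ep <- incident_at(incident, dp) +
      green_field_at(dp, pos, P, model$k_medium, model$n_medium, excl)$E
    Em <- incident_at(incident, dm) +
      green_field_at(dm, pos, P, model$k_medium, model$n_medium, excl)$E
    gr <- (Ep - Em) / (2 * h_nm * 1e-9)
    F[d] <- 0.5 * sum(Re(Conj(P) * gr))
  }
  F * 1e12    # N -> pN
}
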