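# Shared fixtures for the test suite. The trap setups use a coarse (but
# still spacing-valid) dipole lattice and reduced quadrature so that the
# whole suite runs in minutes; they are built lazily and cached across test
# files within one session.

.fixtures <- new.env(parent = emptyenv())

# aberrated trap at test resolution (65-nm lattice, 16-point MST faces)
test_setup <- function() {
  if (is.null(.fixtures$setup))
    .fixtures$setup <- trap_setup(spacing_nm = 65, n_theta = 96,
                                  mst_n_face = 16)
  .fixtures$setup
}

# matched-index control: index-matched fluid, no spherical aberration
matched_setup <- function() {
  if (is.null(.fixtures$matched))
    .fixtures$matched <- trap_setup(n_glass = 1.518, n_water = 1.518,
                                    spacing_nm = 68, n_theta = 96,
                                    mst_n_face = 16)
  .fixtures$matched
}

# x-polarized plane wave propagating along +z in water, E0 in V/m
plane_wave <- function(E0 = 1e5, n_medium = 1.326, wavelength_nm = 1064) {
  k <- 2 * pi * n_medium / (wavelength_nm * 1e-9)
  eta0 <- 376.730313668
  function(pts_nm) {
    ph <- exp(1i * k * pts_nm[, 3] * 1e-9)
    list(E = cbind(E0 * ph, 0 * ph, 0 * ph),
         H = cbind(0 * ph, n_medium * E0 / eta0 * ph, 0 * ph))
  }
}

# small isotropic sphere discretized on the dipole lattice
sphere_model <- function(diameter_nm = 50, n_sphere = 1.57, spacing_nm = 8,
                         n_medium = 1.326) {
  md <- build_lattice(cylinder_spec(diameter_nm, diameter_nm, diameter_nm,
                                    n_sphere, n_sphere),
                      spacing_nm, n_medium = n_medium)
  keep <- rowSums(md$positions_nm^2) <= (diameter_nm / 2)^2
  md$positions_nm <- md$positions_nm[keep, , drop = FALSE]
  md
}
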