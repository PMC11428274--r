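# Physical constants (SI) and small numeric helpers shared across modules.

.const <- list(
  c0     = 299792458,        # speed of light, m/s
  eps0   = 8.8541878128e-12, # vacuum permittivity, F/m
  mu0    = 1.25663706212e-6, # vacuum permeability, H/m
  eta0   = 376.730313668,    # vacuum impedance, Ohm
  kB     = 1.380649e-23      # Boltzmann constant, J/K
)

#' Thermal energy at a given temperature
#'
#' @param temperature_C temperature in degrees Celsius (default 23, the
#'   room temperature at which the trap measurements are modeled).
#' @return kT in pN nm.
#' @export
kT_pNnm <- function(temperature_C = 23) {
  .const$kB * (temperature_C + 273.15) * 1e21
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Gauss-Legendre nodes/weights on [a, b].
gauss_legendre <- function(n, a, b) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}

# Parabolic refinement of an extremum from three equally informative points.
# Returns the abscissa of the vertex of the parabola through
# (x0 - h, ym), (x0, y0), (x0 + h, yp).
parabolic_vertex <- function(x0, h, ym, y0, yp) {
  denom <- ym - 2 * y0 + yp
  if (abs(denom) < .Machine$double.eps * max(abs(c(ym, y0, yp, 1)))) return(x0)
  x0 + 0.5 * h * (ym - yp) / denom
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
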