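# Worm-like-chain mechanics of double-stranded DNA: the modified
# Marko-Siggia interpolation with an enthalpic stretch modulus,
#   F = (kT/Lp) [ 1/(4 (1 - x/Lc + F/K0)^2) - 1/4 + x/Lc - F/K0 ],
# used both by the DNA-ruler focal-shift estimator and by the synthetic
# stretch-trace generator.

#' Worm-like-chain parameter set
#'
#' @param n_bp number of base pairs.
#' @param contour_per_bp contour length per base pair (nm/bp); dsDNA rises
#'   0.338 nm/bp.
#' @param persistence_length_nm persistence length Lp (nm).
#' @param stretch_modulus_pN enthalpic stretch modulus K0 (pN).
#' @param kT thermal energy (pN nm); defaults to 23 C.
#' @return object of class `wlc_params` with the derived contour length.
#' @export
wlc_params <- function(n_bp, contour_per_bp = 0.338,
                       persistence_length_nm = 43,
                       stretch_modulus_pN = 1200,
                       kT = kT_pNnm(23)) {
  if (min(n_bp, contour_per_bp, persistence_length_nm, stretch_modulus_pN,
          kT) <= 0)
    stopf("all worm-like-chain parameters must be positive")
  structure(list(n_bp = n_bp, contour_per_bp = contour_per_bp,
                 Lc_nm = n_bp * contour_per_bp,
                 Lp_nm = persistence_length_nm,
                 K0_pN = stretch_modulus_pN, kT = kT),
            class = "wlc_params")
}

#' Extension of dsDNA at a given force (modified Marko-Siggia)
#'
#' Solves the interpolation formula for the fractional extension by Newton
#' iteration (relative tolerance 1e-10). Forces <= 0 give zero extension.
#'
#' @param force_pN force(s), pN; must be below the stretch modulus.
#' @param params a [wlc_params()].
#' @return extension(s), nm.
#' @export
wlc_extension <- function(force_pN, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(force_pN >= params$K0_pN))
    stopf("force must be below the stretch modulus (%g pN)", params$K0_pN)
  out <- numeric(length(force_pN))
  pos <- force_pN > 0
  if (any(pos)) {
    f <- force_pN[pos]
    fl <- f * params$Lp_nm / params$kT
    # u = x/Lc - F/K0; g(u) = 1/(4(1-u)^2) - 1/4 + u - fl is monotone in u
    u <- pmax(0, 1 - 0.5 / sqrt(pmax(fl, 0.3)))      # high-force start
    for (it in 1:100) {
      om <- 1 - u
      g <- 0.25 / om^2 - 0.25 + u - fl
      dg <- 0.5 / om^3 + 1
      du <- g / dg
      u <- pmin(u - du, 1 - 1e-12)
      if (max(abs(du) / pmax(abs(u), 1e-12)) < 1e-12) break
    }
    if (it == 100 && max(abs(du) / pmax(abs(u), 1e-12)) > 1e-10)
      stopf("worm-like-chain inversion did not converge")
    out[pos] <- params$Lc_nm * (u + f / params$K0_pN)
  }
  out
}

#' Force of dsDNA at a given extension (modified Marko-Siggia)
#'
#' Inverse of [wlc_extension()]; evaluated by Newton iteration on the force.
#'
#' @param extension_nm extension(s), nm (non-negative, below the enthalpic
#'   divergence).
#' @param params a [wlc_params()].
#' @return force(s), pN.
#' @export
wlc_force <- function(extension_nm, params) {
  stopifnot(inherits(params, "wlc_params"))
  vapply(extension_nm, function(x) {
    if (x <= 0) return(0)
    g <- function(F) wlc_extension(F, params) - x
    # bracket then refine: extension is strictly increasing in force
    hi <- 1
    while (g(hi) < 0 && hi < params$K0_pN * 0.99) hi <- hi * 2
    stats::uniroot(g, c(0, min(hi, params$K0_pN * 0.99)),
                   tol = 1e-12)$root
  }, numeric(1))
}
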