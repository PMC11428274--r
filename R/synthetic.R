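# Seeded generators for every trace type the calibration estimators consume,
# with known ground truth: worm-like-chain stretching traces with focal-shift
# scaled stage coordinates, Fabry-Perot fringes, Ornstein-Uhlenbeck angular
# fluctuations, and constant-force twisting traces. Each generator draws all
# randomness from one seeded stream and restores the caller's RNG state.

#' Configuration of the synthetic-trace generators
#'
#' Defaults emulate the instrument conditions of the modeled experiments:
#' 400 Hz stretching acquisition, 10 kHz angular records, 2 turn/s twisting
#' at a 3 pN force clamp, two DNA ruler lengths of 6546 and 11516 bp, and a
#' ground-truth focal shift ratio of 0.829.
#'
#' @param seed mandatory integer seed.
#' @param fs_true ground-truth focal shift ratio.
#' @param dna_lengths_bp the two ruler lengths (bp).
#' @param wlc_defaults list(contour_per_bp, persistence_length_nm,
#'   stretch_modulus_pN, kT_pNnm) passed to [wlc_params()].
#' @param anchor_offset_sd_nm SD of the per-trace anchor/extension offset.
#' @param surface_zero_sd_nm SD of the per-trace surface-zero offset.
#' @param force_noise_sd_pN additive Gaussian force noise.
#' @param stage_step_nm stage step between samples.
#' @param kappa_z_pN_per_nm axial trap stiffness used for the zcyl(F)
#'   excursion during the no-feedback phase.
#' @param zcyl_max_nm zcyl at which the constant-zcyl feedback engages.
#' @param rate_Hz stretching acquisition rate.
#' @param fringe_amplitude,fringe_offset,fringe_snr Fabry-Perot fringe
#'   amplitude, baseline and amplitude/noise-SD ratio.
#' @param kappa_theta_pNnm,gamma_theta_pNnms angular stiffness and rotational
#'   drag of the angular-fluctuation generator.
#' @param angular_rate_Hz,angular_duration_s angular record sampling.
#' @param torque_slope_pNnm_per_turn,buckling_turn torsional rise and
#'   buckling point of the twist generator (plateau torque = slope x turn).
#' @param twist_extension_slope_nm_per_turn post-buckling extension slope.
#' @param twist_force_pN force clamp of the twist trace.
#' @param turn_rate_per_s winding speed.
#' @param twist_torque_sd_pNnm,twist_extension_sd_nm raw per-sample noise.
#' @param kT thermal energy (pN nm).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             fs_true = 0.829,
                             dna_lengths_bp = c(6546, 11516),
                             wlc_defaults = list(),
                             anchor_offset_sd_nm = 20,
                             surface_zero_sd_nm = 20,
                             force_noise_sd_pN = 0.3,
                             stage_step_nm = 4,
                             kappa_z_pN_per_nm = 0.3,
                             zcyl_max_nm = 300,
                             rate_Hz = 400,
                             fringe_amplitude = 1,
                             fringe_offset = 2,
                             fringe_snr = 10,
                             kappa_theta_pNnm = 2000,
                             gamma_theta_pNnms = 0.85,
                             angular_rate_Hz = 10000,
                             angular_duration_s = 60,
                             torque_slope_pNnm_per_turn = 0.87,
                             buckling_turn = 30,
                             twist_extension_slope_nm_per_turn = -45,
                             twist_force_pN = 3,
                             turn_rate_per_s = 2,
                             twist_torque_sd_pNnm = 6,
                             twist_extension_sd_nm = 15,
                             kT = kT_pNnm(23)) {
  if (missing(seed) || is.null(seed)) stopf("a seed is mandatory")
  cfg <- as.list(environment())
  sds <- c(cfg$anchor_offset_sd_nm, cfg$surface_zero_sd_nm,
           cfg$force_noise_sd_pN, cfg$twist_torque_sd_pNnm,
           cfg$twist_extension_sd_nm)
  if (any(sds < 0)) stopf("noise SDs must be non-negative")
  structure(cfg, class = "synthetic_config")
}

# wlc_params for one of the configured DNA lengths
config_wlc <- function(config, length_bp) {
  do.call(wlc_params, c(list(n_bp = length_bp), config$wlc_defaults))
}

#' Synthetic dsDNA stretching trace
#'
#' Emulates the two-step stretching protocol: with the stage at zsurf the
#' DNA extension is \eqn{x = f_s (z_{surf} - z_0) - z_{cyl}(F) + offset},
#' where the cylinder excursion follows \eqn{z_{cyl}(F) = min(F/\kappa_z,
#' z_{cyl,max})} (no feedback until the excursion cap, then constant-zcyl
#' feedback), and the force on the trace is the worm-like-chain force at
#' that extension plus Gaussian noise. The per-trace anchor and surface-zero
#' offsets model the experimental uncertainty in locating zero extension.
#'
#' @param config a [synthetic_config()].
#' @param length_bp DNA length (bp).
#' @param fs_instrument focal shift ratio the "instrument" assumed when
#'   calibrating force and zcyl; if it differs from `fs_true` the recorded
#'   force/zcyl axes are mis-scaled accordingly (for the iterative
#'   calibration loop). Default: equal to `fs_true` (perfect calibration).
#' @param force_max_pN trace ends shortly after this force is reached.
#' @return data.frame of class `stretch_trace` with `zsurf_nm`, `force_pN`,
#'   `zcyl_nm`; attributes `n_bp`, `z0_nominal_nm`, `fs_true`,
#'   `fs_instrument`, `rate_Hz`.
#' @export
gen_stretch_trace <- function(config, length_bp,
                              fs_instrument = config$fs_true,
                              force_max_pN = 25) {
  stopifnot(inherits(config, "synthetic_config"))
  params <- config_wlc(config, length_bp)
  # the surface-zero and anchor offsets are systematic for a measurement
  # session: drawn once per config seed, shared by both ruler lengths, so
  # the two-length difference cancels them while any single-length estimate
  # inherits them
  sys_off <- with_seed(config$seed, {
    c(z0 = stats::rnorm(1, 0, config$surface_zero_sd_nm),
      anchor = stats::rnorm(1, 0, config$anchor_offset_sd_nm))
  })
  with_seed(config$seed + length_bp, {
    z0_true <- sys_off[["z0"]]
    anchor <- sys_off[["anchor"]]
    # stage range: from slack to past the force_max crossing
    x_max <- wlc_extension(force_max_pN, params)
    z_end <- (x_max + config$zcyl_max_nm + 60) / config$fs_true +
      z0_true + 100
    zsurf <- seq(-100, z_end, by = config$stage_step_nm)
    zcap <- config$zcyl_max_nm
    kz <- config$kappa_z_pN_per_nm
    pulls <- config$fs_true * (zsurf - z0_true) + anchor
    # invert pull(F) = x_wlc(F) + zcyl(F): monotone interpolation seed
    # followed by vectorized Newton polish
    Fg <- c(seq(1e-4, 2, length.out = 300),
            seq(2.05, 4 * force_max_pN, length.out = 300))
    pg <- wlc_extension(Fg, params) + pmin(Fg / kz, zcap)
    Ftrue <- rep(0, length(pulls))
    pos <- pulls > pg[1]
    Ftrue[pos] <- stats::approx(pg, Fg, xout = pulls[pos], rule = 2)$y
    for (it in 1:4) {
      F <- Ftrue[pos]
      x <- wlc_extension(F, params)
      u <- x / params$Lc_nm - F / params$K0_pN
      dxdF <- params$Lc_nm *
        ((params$Lp_nm / params$kT) / (0.5 / (1 - u)^3 + 1) +
           1 / params$K0_pN)
      dpull <- dxdF + ifelse(F < kz * zcap, 1 / kz, 0)
      g <- x + pmin(F / kz, zcap) - pulls[pos]
      Ftrue[pos] <- pmax(F - g / dpull, 1e-6)
    }
    zcyl <- pmin(Ftrue / kz, zcap)
    scale <- fs_instrument / config$fs_true
    Fobs <- Ftrue * scale + stats::rnorm(length(Ftrue), 0,
                                         config$force_noise_sd_pN)
    keep <- cumsum(Ftrue > force_max_pN) <= 1
    out <- data.frame(zsurf_nm = zsurf[keep], force_pN = Fobs[keep],
                      zcyl_nm = zcyl[keep] * scale)
    attr(out, "n_bp") <- length_bp
    attr(out, "z0_nominal_nm") <- 0      # the instrument's assumed zero
    attr(out, "fs_true") <- config$fs_true
    attr(out, "fs_instrument") <- fs_instrument
    attr(out, "rate_Hz") <- config$rate_Hz
    class(out) <- c("stretch_trace", "data.frame")
    out
  })
}

#' Synthetic Fabry-Perot fringe trace
#'
#' Cosine of the plane-wave round-trip phase across the cylinder-coverslip
#' gap, which grows by `fs_true` per unit stage motion, plus Gaussian noise
#' at the configured signal-to-noise ratio.
#'
#' @param config a [synthetic_config()].
#' @param zsurf_range_nm stage sweep (nm).
#' @param step_nm stage step (nm).
#' @param wavelength_nm,n_water optical constants.
#' @return data.frame of class `fringe_trace` with `zsurf_nm`, `signal`;
#'   attribute `fs_true`.
#' @export
gen_fringe_trace <- function(config, zsurf_range_nm = c(0, 3000),
                             step_nm = 5, wavelength_nm = 1064,
                             n_water = 1.326) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 1L, {
    z <- seq(zsurf_range_nm[1], zsurf_range_nm[2], by = step_nm)
    phi0 <- stats::runif(1, 0, 2 * pi)
    phase <- 4 * pi * n_water * config$fs_true * z / wavelength_nm + phi0
    sig <- config$fringe_amplitude * cos(phase) + config$fringe_offset +
      stats::rnorm(length(z), 0,
                   config$fringe_amplitude / config$fringe_snr)
    out <- data.frame(zsurf_nm = z, signal = sig)
    attr(out, "fs_true") <- config$fs_true
    class(out) <- c("fringe_trace", "data.frame")
    out
  })
}

#' Synthetic angular-fluctuation record (Ornstein-Uhlenbeck)
#'
#' Angular Brownian motion of the trapped cylinder in the harmonic angular
#' potential: an Ornstein-Uhlenbeck process with stiffness kappa_theta and
#' drag gamma_theta, discretized with the exact conditional update so that
#' equipartition holds at any sampling step.
#'
#' @param config a [synthetic_config()].
#' @return data.frame of class `angular_series` with `time_s`, `theta_rad`;
#'   attributes `kappa_theta`, `gamma_theta`, `rate_Hz`.
#' @export
gen_angular_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 2L, {
    dt <- 1 / config$angular_rate_Hz
    n <- round(config$angular_duration_s * config$angular_rate_Hz)
    tau_c <- config$gamma_theta_pNnms / config$kappa_theta_pNnm
    rho <- exp(-dt / tau_c)
    sd_eq <- sqrt(config$kT / config$kappa_theta_pNnm)
    innov <- stats::rnorm(n, 0, sd_eq * sqrt(1 - rho^2))
    innov[1] <- stats::rnorm(1, 0, sd_eq)       # stationary start
    th <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    out <- data.frame(time_s = (seq_len(n) - 1) * dt, theta_rad = th)
    attr(out, "kappa_theta") <- config$kappa_theta_pNnm
    attr(out, "gamma_theta") <- config$gamma_theta_pNnms
    attr(out, "rate_Hz") <- config$angular_rate_Hz
    class(out) <- c("angular_series", "data.frame")
    out
  })
}

#' Synthetic constant-force DNA twisting trace
#'
#' Torque rises linearly with added turns to the buckling point, then
#' plateaus at slope x buckling_turn; the extension is flat before buckling
#' and decreases linearly after, with Gaussian per-sample noise on both
#' channels.
#'
#' @param config a [synthetic_config()].
#' @param n_turns total turns added.
#' @param length_bp DNA length (bp), used for the pre-buckling extension.
#' @return data.frame of class `twist_trace` with `time_s`, `turns`,
#'   `torque_pNnm`, `extension_nm`; attributes `rate_Hz`, `force_pN`, and
#'   the ground-truth fit parameters.
#' @export
gen_twist_trace <- function(config, n_turns = 60,
                            length_bp = config$dna_lengths_bp[1]) {
  stopifnot(inherits(config, "synthetic_config"))
  params <- config_wlc(config, length_bp)
  with_seed(config$seed + 3L, {
    dt <- 1 / config$rate_Hz
    tt <- seq(0, n_turns / config$turn_rate_per_s, by = dt)
    turns <- tt * config$turn_rate_per_s
    nb <- config$buckling_turn
    s1 <- config$torque_slope_pNnm_per_turn
    plateau <- s1 * nb
    tq <- ifelse(turns <= nb, s1 * turns, plateau) +
      stats::rnorm(length(turns), 0, config$twist_torque_sd_pNnm)
    e0 <- wlc_extension(config$twist_force_pN, params)
    s2 <- config$twist_extension_slope_nm_per_turn
    ext <- ifelse(turns <= nb, e0, e0 + s2 * (turns - nb)) +
      stats::rnorm(length(turns), 0, config$twist_extension_sd_nm)
    out <- data.frame(time_s = tt, turns = turns, torque_pNnm = tq,
                      extension_nm = ext)
    attr(out, "rate_Hz") <- config$rate_Hz
    attr(out, "force_pN") <- config$twist_force_pN
    attr(out, "truth") <- list(torque_slope = s1, buckling_turn = nb,
                               plateau_torque = plateau,
                               extension_slope = s2)
    class(out) <- c("twist_trace", "data.frame")
    out
  })
}
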