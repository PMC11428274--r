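# Experimental calibration estimators for the angular optical trap:
# the two-length dsDNA-ruler focal-shift method, the Fabry-Perot fringe
# estimator, the iterative calibration loop, and angular stiffness from the
# power spectral density of the angular fluctuations.

# Stage position at which a monotone force trace crosses force_ref, by local
# linear interpolation over the samples within +/- half_window of the
# crossing. Returns the crossing and its standard error from the local fit.
crossing_zsurf <- function(zsurf, force, force_ref = 20, half_window = 0.5) {
  if (max(force) < force_ref)
    stopf("trace never reaches %g pN", force_ref)
  sel <- abs(force - force_ref) <= half_window
  if (sum(sel) < 3) {
    # sparse sampling: take the 4 samples nearest the crossing
    sel <- rank(abs(force - force_ref), ties.method = "first") <= 4
  }
  fit <- stats::lm(zsurf[sel] ~ force[sel])
  co <- stats::coef(fit)
  z0 <- unname(co[1] + co[2] * force_ref)
  # SE of the predicted crossing position
  X <- cbind(1, force_ref)
  se <- sqrt(drop(X %*% stats::vcov(fit) %*% t(X)))
  list(zsurf = z0, se = se, n = sum(sel))
}

# Linear interpolation of a secondary column (e.g. zcyl) at the force_ref
# crossing of a trace.
crossing_value <- function(force, value, force_ref = 20, half_window = 0.5) {
  sel <- abs(force - force_ref) <= half_window
  if (sum(sel) < 3) sel <- rank(abs(force - force_ref),
                                ties.method = "first") <= 4
  fit <- stats::lm(value[sel] ~ force[sel])
  unname(stats::coef(fit)[1] + stats::coef(fit)[2] * force_ref)
}

#' Focal shift ratio from the two-length dsDNA ruler
#'
#' At ~20 pN dsDNA is stretched to nearly its contour length, so its
#' extension is an accurate distance ruler. Comparing the measured difference
#' of the coverslip positions at 20 pN for two DNA lengths with the expected
#' extension difference from the worm-like-chain model gives
#' \eqn{f_s = \Delta z_{surf,without} / \Delta z_{surf,with}}. Using the
#' difference of two lengths cancels the surface-zero and anchor offsets
#' that bias a single-length estimate.
#'
#' @param trace_short,trace_long stretch traces (data.frames with `zsurf_nm`,
#'   `force_pN`, optional `zcyl_nm`), e.g. from [gen_stretch_trace()].
#' @param params_short,params_long [wlc_params()] for the two DNA lengths.
#' @param force_ref_pN reference force (pN).
#' @return a `focal_shift_estimate` (method "dna-ruler") with first-order
#'   propagated uncertainty from the two crossing fits.
#' @export
dna_ruler_focal_shift <- function(trace_short, trace_long,
                                  params_short, params_long,
                                  force_ref_pN = 20) {
  if (params_short$n_bp == params_long$n_bp)
    stopf("the two traces must come from distinct DNA lengths")
  if (params_short$n_bp > params_long$n_bp)
    stopf("trace_short/params_short must be the shorter molecule")
  cs <- crossing_zsurf(trace_short$zsurf_nm, trace_short$force_pN, force_ref_pN)
  cl <- crossing_zsurf(trace_long$zsurf_nm, trace_long$force_pN, force_ref_pN)
  dz_with <- cl$zsurf - cs$zsurf
  zc_s <- if (!is.null(trace_short$zcyl_nm))
    crossing_value(trace_short$force_pN, trace_short$zcyl_nm, force_ref_pN)
  else 0
  zc_l <- if (!is.null(trace_long$zcyl_nm))
    crossing_value(trace_long$force_pN, trace_long$zcyl_nm, force_ref_pN)
  else 0
  dz_without <- (wlc_extension(force_ref_pN, params_long) -
                 wlc_extension(force_ref_pN, params_short)) + (zc_l - zc_s)
  fs <- dz_without / dz_with
  se <- abs(fs / dz_with) * sqrt(cs$se^2 + cl$se^2)
  structure(list(fs = fs, se = se, method = "dna-ruler",
                 dz_with_nm = dz_with, dz_without_nm = dz_without,
                 force_ref_pN = force_ref_pN),
            class = "focal_shift_estimate")
}

#' Single-length DNA-ruler estimate (offset-sensitive variant)
#'
#' Uses one molecule and the recorded surface-zero position; biased by the
#' surface-zero and anchor offsets that the two-length difference method
#' cancels. Provided for comparison.
#'
#' @param trace a stretch trace carrying attribute `z0_nominal_nm`.
#' @param params the molecule's [wlc_params()].
#' @param force_ref_pN reference force (pN).
#' @return a `focal_shift_estimate` (method "dna-ruler-single").
#' @export
dna_ruler_focal_shift_single <- function(trace, params, force_ref_pN = 20) {
  z0 <- attr(trace, "z0_nominal_nm")
  if (is.null(z0)) stopf("trace carries no nominal surface-zero position")
  cr <- crossing_zsurf(trace$zsurf_nm, trace$force_pN, force_ref_pN)
  zc <- if (!is.null(trace$zcyl_nm))
    crossing_value(trace$force_pN, trace$zcyl_nm, force_ref_pN) else 0
  fs <- (wlc_extension(force_ref_pN, params) + zc) / (cr$zsurf - z0)
  structure(list(fs = fs, se = abs(fs / (cr$zsurf - z0)) * cr$se,
                 method = "dna-ruler-single"),
            class = "focal_shift_estimate")
}

#' Focal shift ratio from Fabry-Perot fringes
#'
#' Interference between reflections off the cylinder bottom and the
#' coverslip modulates the detected intensity as the stage moves; under the
#' plane-wave assumption the round-trip phase advances by
#' \eqn{4\pi n_{water} f_s / \lambda_0} per unit stage motion (the gap grows
#' by \eqn{f_s} per unit zsurf). The fringe spatial frequency therefore
#' yields \eqn{f_s}.
#'
#' @param fringes data.frame with `zsurf_nm` and `signal`.
#' @param n_water aqueous index.
#' @param wavelength_nm vacuum wavelength (nm).
#' @return a `focal_shift_estimate` (method "fabry-perot") with the fitted
#'   fringe period.
#' @export
fabry_perot_focal_shift <- function(fringes, n_water = 1.326,
                                    wavelength_nm = 1064) {
  z <- fringes$zsurf_nm; s <- fringes$signal
  if (length(z) < 16) stopf("fringe trace too short")
  dz <- stats::median(diff(z))
  sd0 <- s - mean(s)
  # dominant spatial frequency from the periodogram
  n <- length(sd0)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  sp <- Mod(stats::fft(sd0 * hann))[2:floor(n / 2)]^2
  pk <- which.max(sp)
  if (sp[pk] < 10 * stats::median(sp))
    stopf("no dominant fringe frequency in the signal")
  nu0 <- pk / (n * dz)                       # cycles per nm
  span <- diff(range(z))
  if (span * nu0 < 3) stopf("need >= 3 fringe periods for estimation")
  fit <- minpack.lm::nlsLM(
    s ~ A * cos(2 * pi * nu * z + phi) + B,
    start = list(A = stats::sd(sd0) * sqrt(2), nu = nu0, phi = 0,
                 B = mean(s)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  nu <- unname(stats::coef(fit)["nu"])
  nu_se <- summary(fit)$coefficients["nu", 2]
  fs <- nu * wavelength_nm / (2 * n_water)
  structure(list(fs = fs, se = nu_se * wavelength_nm / (2 * n_water),
                 method = "fabry-perot",
                 period_nm = 1 / nu, fit = fit),
            class = "focal_shift_estimate")
}

#' Iterative focal-shift calibration
#'
#' Force and displacement calibrations themselves depend on the focal shift
#' ratio, so traces recorded under an assumed ratio must be recalibrated and
#' re-analyzed until the estimate converges. Each iteration rescales the
#' force (and detector-derived zcyl) axes by the ratio of the current
#' estimate to the instrument's assumed value, then re-runs the two-length
#' ruler estimator.
#'
#' @param trace_short,trace_long raw stretch traces carrying attribute
#'   `fs_instrument` (the ratio assumed when the traces were calibrated).
#' @param params_short,params_long [wlc_params()] for the two lengths.
#' @param fs_init initial estimate in (0, 1].
#' @param tol convergence tolerance on `|fs_k - fs_{k-1}|`.
#' @param max_iter iteration cap.
#' @return a `focal_shift_estimate` (method "dna-ruler-iterated") with the
#'   iterate history; if the loop oscillates without converging the last two
#'   iterates are reported in `history` and a warning is raised.
#' @export
iterate_fs_calibration <- function(trace_short, trace_long,
                                   params_short, params_long,
                                   fs_init = 1.0, tol = 1e-3,
                                   max_iter = 20) {
  if (fs_init <= 0 || fs_init > 1) stopf("fs_init must be in (0, 1]")
  fs_inst <- attr(trace_short, "fs_instrument") %||% 1
  history <- fs <- fs_init
  est <- NULL
  for (it in seq_len(max_iter)) {
    scale <- fs / fs_inst
    ts <- trace_short; tl <- trace_long
    ts$force_pN <- ts$force_pN * scale
    tl$force_pN <- tl$force_pN * scale
    if (!is.null(ts$zcyl_nm)) ts$zcyl_nm <- ts$zcyl_nm * scale
    if (!is.null(tl$zcyl_nm)) tl$zcyl_nm <- tl$zcyl_nm * scale
    est <- dna_ruler_focal_shift(ts, tl, params_short, params_long)
    history <- c(history, est$fs)
    if (abs(est$fs - fs) < tol) {
      fs <- est$fs
      break
    }
    fs <- est$fs
  }
  if (abs(utils::tail(history, 1) - utils::tail(history, 2)[1]) >= tol)
    warning(sprintf(
      "calibration loop did not converge; last iterates %.5f, %.5f",
      utils::tail(history, 2)[1], utils::tail(history, 1)))
  structure(list(fs = fs, se = est$se, method = "dna-ruler-iterated",
                 iterations = it, history = history),
            class = "focal_shift_estimate")
}

# Welch-averaged one-sided power spectral density with a Hann window and
# 50% overlap. Returns frequencies (Hz) and PSD (signal^2 / Hz).
welch_psd <- function(x, rate_Hz, n_segment = NULL) {
  n <- length(x)
  nseg <- n_segment %||% 2^max(8, floor(log2(n / 8)))
  nseg <- min(nseg, n)
  step <- floor(nseg / 2)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  wnorm <- sum(win^2)
  starts <- seq(1, n - nseg + 1, by = step)
  acc <- 0
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(stats::fft(seg * win))^2
  }
  psd <- acc / length(starts) / (wnorm * rate_Hz)
  nf <- floor(nseg / 2)
  # one-sided: double everything except DC (and Nyquist, ignored here)
  list(f = (1:nf) * rate_Hz / nseg, psd = 2 * psd[2:(nf + 1)])
}

#' Angular stiffness from the angular power spectral density
#'
#' Welch-averages the PSD of the angular fluctuation record and fits the
#' Lorentzian \eqn{S(f) = D/(\pi^2 (f^2 + f_c^2))}; the angular stiffness is
#' \eqn{\kappa_\theta = 2\pi f_c \gamma_\theta}. The equipartition estimate
#' \eqn{kT/\langle\alpha^2\rangle} is reported as a cross-check.
#'
#' @param series data.frame with `time_s` and `theta_rad` (angular signal),
#'   uniformly sampled; or an object from [gen_angular_series()].
#' @param gamma_theta rotational drag coefficient (pN nm s/rad). See
#'   [cylinder_rotational_drag()] for an approximate helper.
#' @param kT thermal energy (pN nm).
#' @param f_range optional frequency window for the fit (Hz).
#' @return list of class `angular_stiffness_fit`: `kappa_theta`
#'   (pN nm/rad), `f_corner_Hz`, `kappa_equipartition`, fit object.
#' @export
angular_psd_stiffness <- function(series, gamma_theta,
                                  kT = kT_pNnm(23), f_range = NULL) {
  t <- series$time_s; th <- series$theta_rad
  dt <- diff(t[1:2])
  if (max(abs(diff(t) - dt)) > dt * 1e-6) stopf("sampling must be uniform")
  rate <- 1 / dt
  T_total <- t[length(t)] - t[1]
  w <- welch_psd(th, rate)
  kap_eq <- kT / stats::var(th)
  fc0 <- kap_eq / (2 * pi * gamma_theta)
  # fit a band around the corner: the aliased high-frequency tail of the
  # sampled process is not Lorentzian and would bias the corner upward
  sel <- if (is.null(f_range)) w$f < min(3 * fc0, rate / 4) else
    w$f >= f_range[1] & w$f <= f_range[2]
  f <- w$f[sel]; S <- w$psd[sel]
  fit <- minpack.lm::nlsLM(
    S ~ D / (pi^2 * (f^2 + fc^2)),
    start = list(D = kT / gamma_theta, fc = fc0),
    weights = 1 / (S^2),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  fc <- abs(unname(stats::coef(fit)["fc"]))
  if (fc < 2 / T_total || fc > rate / 8)
    stopf("corner frequency %.3g Hz outside the resolvable band (%.3g, %.3g)",
          fc, 2 / T_total, rate / 8)
  structure(list(kappa_theta = 2 * pi * fc * gamma_theta,
                 f_corner_Hz = fc,
                 D_fit = unname(stats::coef(fit)["D"]),
                 kappa_equipartition = kap_eq,
                 record_s = T_total, fit = fit),
            class = "angular_stiffness_fit")
}

#' @export
print.angular_stiffness_fit <- function(x, ...) {
  cat(sprintf(
    "angular stiffness: kappa_theta = %.4g pN nm/rad (fc = %.3g Hz; equipartition %.4g)\n",
    x$kappa_theta, x$f_corner_Hz, x$kappa_equipartition))
  invisible(x)
}

#' Approximate rotational drag of the cylinder about its axis
#'
#' Lateral-surface no-slip estimate \eqn{\gamma_\theta \approx 4\pi\eta h
#' \bar{R}^2} for rotation of a cylinder of mean radius \eqn{\bar{R}} and
#' height h about its own axis. This ignores end effects and the nearby
#' coverslip and is intended only as an order-of-magnitude default; the drag
#' coefficient is an input to [angular_psd_stiffness()], not a calibrated
#' quantity.
#'
#' @param cylinder a [cylinder_spec()].
#' @param viscosity_Pa_s dynamic viscosity of the medium (water at 23 C by
#'   default).
#' @return drag coefficient, pN nm s/rad.
#' @export
cylinder_rotational_drag <- function(cylinder = cylinder_spec(),
                                     viscosity_Pa_s = 0.932e-3) {
  R <- (cylinder$bottom_diameter_nm + cylinder$top_diameter_nm) / 4 * 1e-9
  h <- cylinder$height_nm * 1e-9
  4 * pi * viscosity_Pa_s * h * R^2 * 1e21    # N m s -> pN nm s
}
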