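#' Block-paradigm specification
#'
#' Describes the block design of a mental-arithmetic recording session: an
#' initial baseline rest, then \code{n_trials} repetitions of a task block
#' followed by a recovery rest, sampled at \code{fs_out}. Defaults emulate a
#' seven-subject prefrontal study: 44 s rest / 44 s task / 44 s rest repeated
#' five times, 16 channels, 1.81 Hz.
#'
#' @param rest_pre_s seconds of initial baseline rest.
#' @param task_s seconds of each mental-arithmetic block.
#' @param rest_post_s seconds of rest after each task block.
#' @param n_trials number of task blocks.
#' @param fs_out output sampling rate in Hz.
#' @param n_channels number of measurement channels.
#' @param n_subjects number of subjects in a simulated study.
#' @return An object of class \code{paradigm_spec}.
#' @export
paradigm_spec <- function(rest_pre_s = 44, task_s = 44, rest_post_s = 44,
                          n_trials = 5, fs_out = 1.81, n_channels = 16,
                          n_subjects = 7) {
  p <- structure(list(
    rest_pre_s = rest_pre_s, task_s = task_s, rest_post_s = rest_post_s,
    n_trials = as.integer(n_trials), fs_out = fs_out,
    n_channels = as.integer(n_channels), n_subjects = as.integer(n_subjects)
  ), class = "paradigm_spec")
  validate_paradigm_spec(p)
  p
}

validate_paradigm_spec <- function(p) {
  stopifnot(inherits(p, "paradigm_spec"))
  durs <- c(p$rest_pre_s, p$task_s, p$rest_post_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("paradigm_spec: all block durations must be > 0", call. = FALSE)
  if (!is.finite(p$fs_out) || p$fs_out <= 0)
    stop("paradigm_spec: fs_out must be > 0", call. = FALSE)
  if (p$n_trials < 1L) stop("paradigm_spec: n_trials must be >= 1", call. = FALSE)
  if (p$n_channels < 1L) stop("paradigm_spec: n_channels must be >= 1", call. = FALSE)
  if (p$n_subjects < 1L) stop("paradigm_spec: n_subjects must be >= 1", call. = FALSE)
  invisible(p)
}

#' Task-evoked activation specification
#'
#' Forward hemodynamic model parameters for the simulator: a double-gamma
#' haemodynamic response function (HRF) convolved with the task boxcar gives
#' the oxygenated-hemoglobin (HbO) response; deoxygenated hemoglobin (HbR) is
#' a scaled, slightly delayed negative copy, as is typical of fNIRS
#' recordings. The default shape (time-to-peak 4 s, undershoot 0.35) makes
#' the block response rise quickly, overshoot its plateau by roughly a third
#' and settle — emulating the early peak followed by partial adaptation
#' commonly seen over sustained cognitive blocks, so the epoch peak carries
#' information beyond the epoch mean.
#'
#' @param hbo_amp task-evoked HbO plateau amplitude in micromolar.
#' @param hbr_ratio scale of the HbR response relative to HbO; must be <= 0.
#' @param hbr_delay_s lag of the HbR response behind HbO, seconds.
#' @param hrf_peak_s time-to-peak of the HRF, seconds.
#' @param hrf_undershoot relative amplitude of the post-stimulus undershoot.
#' @param channel_gain optional per-channel multiplicative gains (recycled).
#' @return An object of class \code{activation_spec}.
#' @export
activation_spec <- function(hbo_amp = 1.0, hbr_ratio = -1 / 3, hbr_delay_s = 1,
                            hrf_peak_s = 4, hrf_undershoot = 0.35,
                            channel_gain = 1) {
  a <- structure(list(
    hbo_amp = hbo_amp, hbr_ratio = hbr_ratio, hbr_delay_s = hbr_delay_s,
    hrf_peak_s = hrf_peak_s, hrf_undershoot = hrf_undershoot,
    channel_gain = channel_gain
  ), class = "activation_spec")
  validate_activation_spec(a)
  a
}

validate_activation_spec <- function(a) {
  stopifnot(inherits(a, "activation_spec"))
  if (a$hbo_amp < 0) stop("activation_spec: hbo_amp must be >= 0", call. = FALSE)
  if (a$hbr_ratio > 0) stop("activation_spec: hbr_ratio must be <= 0", call. = FALSE)
  if (a$hrf_peak_s <= 0) stop("activation_spec: hrf_peak_s must be > 0", call. = FALSE)
  if (any(a$channel_gain < 0)) stop("activation_spec: channel_gain must be >= 0", call. = FALSE)
  invisible(a)
}

#' Physiological-noise specification
#'
#' Noise components sit where the preprocessing notch filter expects them:
#' cardiac pulsation near 1-1.2 Hz, respiration near 0.3-0.4 Hz, Mayer waves
#' and low-frequency fluctuations below 0.1 Hz, plus linear drift and white
#' measurement noise. Amplitudes are micromolar in the concentration domain.
#' Each oscillation is a narrowband process: a sinusoid whose phase diffuses
#' as a random walk (\code{phase_diffusion} rad per sqrt-second), as
#' physiological rhythms do; set it to 0 for pure tones. The default
#' Mayer/low-frequency component at 0.025 Hz represents the slow spontaneous
#' fluctuations that overlap the block-design response band and dominate
#' epoch-to-epoch variability in real recordings.
#'
#' @param cardiac_hz,resp_hz,mayer_hz component frequencies in Hz.
#' @param cardiac_amp,resp_amp,mayer_amp component amplitudes, micromolar.
#' @param phase_diffusion random-walk phase-diffusion rate of the
#'   oscillations, rad per sqrt-second.
#' @param drift_slope linear drift in micromolar per second.
#' @param white_sd standard deviation of white measurement noise, micromolar.
#' @param hbr_noise_scale factor applied to all noise on the HbR channel;
#'   deoxygenated hemoglobin swings (signal and noise alike) are smaller than
#'   HbO's in recordings, so its noise scales down with its response.
#' @param seed integer seed for the noise streams.
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(cardiac_hz = 1.1, resp_hz = 0.35, mayer_hz = 0.025,
                       cardiac_amp = 0.25, resp_amp = 0.35, mayer_amp = 3.0,
                       drift_slope = 0.002, white_sd = 0.8,
                       hbr_noise_scale = 0.4, phase_diffusion = 0.15,
                       seed = 1L) {
  n <- structure(list(
    cardiac_hz = cardiac_hz, resp_hz = resp_hz, mayer_hz = mayer_hz,
    cardiac_amp = cardiac_amp, resp_amp = resp_amp, mayer_amp = mayer_amp,
    drift_slope = drift_slope, white_sd = white_sd,
    hbr_noise_scale = hbr_noise_scale, phase_diffusion = phase_diffusion,
    seed = as.integer(seed)
  ), class = "noise_spec")
  validate_noise_spec(n)
  n
}

validate_noise_spec <- function(n) {
  stopifnot(inherits(n, "noise_spec"))
  freqs <- c(n$cardiac_hz, n$resp_hz, n$mayer_hz)
  amps <- c(n$cardiac_amp, n$resp_amp, n$mayer_amp)
  if (any(freqs <= 0)) stop("noise_spec: frequencies must be > 0", call. = FALSE)
  if (any(amps < 0) || n$white_sd < 0 || n$hbr_noise_scale < 0 ||
      n$phase_diffusion < 0)
    stop("noise_spec: amplitudes must be >= 0", call. = FALSE)
  invisible(n)
}

#' Modified Beer-Lambert conversion specification
#'
#' Extinction coefficients, differential path-length factor (DPF) and
#' emitter-detector separation used to convert two-wavelength optical-density
#' changes to chromophore concentration changes. The default coefficient table
#' holds molar extinction values for oxy- and deoxy-hemoglobin at 760 and
#' 830 nm from the widely used Prahl/Gratzer compilation, converted to
#' \eqn{\mu M^{-1} mm^{-1}}. With alpha in \eqn{\mu M^{-1} mm^{-1}} and the
#' separation in mm, inverted concentrations come out in micromolar.
#'
#' @param alpha 2x2 extinction matrix; rows = wavelengths, columns = (HbO, HbR).
#' @param dpf unitless differential path-length factor (adult forehead
#'   convention is around 6).
#' @param distance_mm emitter-detector separation in millimeters.
#' @param wavelengths_nm the two wavelengths, for bookkeeping.
#' @return An object of class \code{extinction_spec}.
#' @export
extinction_spec <- function(alpha = default_extinction_760_830(),
                            dpf = 6.0, distance_mm = 28,
                            wavelengths_nm = c(760, 830)) {
  alpha <- as.matrix(alpha)
  e <- structure(list(
    alpha = alpha, dpf = dpf, distance_mm = distance_mm,
    wavelengths_nm = wavelengths_nm
  ), class = "extinction_spec")
  validate_extinction_spec(e)
  e
}

validate_extinction_spec <- function(e) {
  stopifnot(inherits(e, "extinction_spec"))
  if (!all(dim(e$alpha) == c(2L, 2L)))
    stop("extinction_spec: alpha must be a 2x2 matrix", call. = FALSE)
  if (abs(det(e$alpha)) < .Machine$double.eps * 100)
    stop("extinction_spec: singular extinction matrix", call. = FALSE)
  if (e$dpf <= 0) stop("extinction_spec: dpf must be > 0", call. = FALSE)
  if (e$distance_mm <= 0) stop("extinction_spec: distance_mm must be > 0", call. = FALSE)
  if (length(e$wavelengths_nm) != 2L)
    stop("extinction_spec: exactly two wavelengths required", call. = FALSE)
  invisible(e)
}

#' Default hemoglobin extinction coefficients at 760/830 nm
#'
#' Molar extinction coefficients (base-10) from the Prahl/Gratzer hemoglobin
#' compilation, converted from \eqn{cm^{-1} M^{-1}} to \eqn{\mu M^{-1} mm^{-1}}
#' (multiply by 1e-7). Rows: 760 nm, 830 nm; columns: HbO, HbR.
#'
#' @return A 2x2 numeric matrix with dimnames.
#' @export
default_extinction_760_830 <- function() {
  # 760 nm: HbO2 586, Hb 1548.52; 830 nm: HbO2 974, Hb 693.04 [cm^-1 M^-1]
  matrix(c(586, 1548.52, 974, 693.04) * 1e-7,
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "830"), c("HbO", "HbR")))
}

#' Band-reject / detrend filter specification
#'
#' @param reject_bands list of \code{c(low, high)} Hz pairs to notch out.
#'   Defaults target cardiac (1-1.2 Hz) and respiratory (0.3-0.4 Hz) bands.
#' @param highpass_reject_below_hz frequencies below this (Mayer waves, slow
#'   fluctuations) are removed; set \code{NULL} to disable.
#' @param lf_protect_hz floor of the low-frequency rejection: only
#'   (\code{lf_protect_hz}, \code{highpass_reject_below_hz}) is attenuated, so
#'   that a slow block-locked hemodynamic response (fundamental well below
#'   0.03 Hz for 44-s blocks) survives while the Mayer band is removed;
#'   residual drift below the floor is handled by detrending. Set to 0 for a
#'   literal high-pass (which also removes the block response).
#' @param analysis_band optional \code{c(low, high)} band-pass retained after
#'   notching; \code{NULL} (default) applies no band-pass.
#' @param method \code{"fft_mask"} (zero-phase FFT-domain mask with
#'   raised-cosine edges) or \code{"iir_zero_phase"} (forward-backward
#'   Butterworth band-stop cascade).
#' @param transition_hz width of the raised-cosine band edges, Hz.
#' @param detrend_order polynomial order removed per channel after filtering.
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(reject_bands = list(c(1.0, 1.2), c(0.3, 0.4)),
                        highpass_reject_below_hz = 0.1,
                        lf_protect_hz = 0.03,
                        analysis_band = NULL,
                        method = c("fft_mask", "iir_zero_phase"),
                        transition_hz = 0.02,
                        detrend_order = 1L) {
  method <- match.arg(method)
  f <- structure(list(
    reject_bands = reject_bands,
    highpass_reject_below_hz = highpass_reject_below_hz,
    lf_protect_hz = lf_protect_hz,
    analysis_band = analysis_band, method = method,
    transition_hz = transition_hz, detrend_order = as.integer(detrend_order)
  ), class = "filter_spec")
  validate_filter_spec(f)
  f
}

validate_filter_spec <- function(f) {
  stopifnot(inherits(f, "filter_spec"))
  for (b in f$reject_bands) {
    if (length(b) != 2L || b[1] < 0 || b[1] >= b[2])
      stop("filter_spec: each reject band must satisfy 0 <= low < high", call. = FALSE)
  }
  if (!is.null(f$analysis_band)) {
    b <- f$analysis_band
    if (length(b) != 2L || b[1] < 0 || b[1] >= b[2])
      stop("filter_spec: analysis_band must satisfy 0 <= low < high", call. = FALSE)
  }
  if (!is.null(f$highpass_reject_below_hz) && !is.null(f$lf_protect_hz) &&
      f$lf_protect_hz >= f$highpass_reject_below_hz && f$lf_protect_hz > 0)
    stop("filter_spec: lf_protect_hz must be below highpass_reject_below_hz",
         call. = FALSE)
  if (f$transition_hz <= 0) stop("filter_spec: transition_hz must be > 0", call. = FALSE)
  if (f$detrend_order < 0) stop("filter_spec: detrend_order must be >= 0", call. = FALSE)
  invisible(f)
}

#' Cross-validation specification
#'
#' @param k number of folds (default 10).
#' @param runs number of repetitions with re-randomized fold assignment
#'   (default 10).
#' @param seed integer seed; run r derives its shuffle from \code{seed + r}.
#' @param stratified keep class proportions equal across folds (default TRUE).
#' @param fold_safe_scaling refit min-max scaling inside each training fold
#'   and apply the training parameters to the test fold (leakage-safe mode).
#' @return An object of class \code{cv_spec}.
#' @export
cv_spec <- function(k = 10L, runs = 10L, seed = 1L, stratified = TRUE,
                    fold_safe_scaling = FALSE) {
  s <- structure(list(
    k = as.integer(k), runs = as.integer(runs), seed = as.integer(seed),
    stratified = isTRUE(stratified),
    fold_safe_scaling = isTRUE(fold_safe_scaling)
  ), class = "cv_spec")
  if (s$k < 2L) stop("cv_spec: k must be >= 2", call. = FALSE)
  if (s$runs < 1L) stop("cv_spec: runs must be >= 1", call. = FALSE)
  s
}

#' @export
print.paradigm_spec <- function(x, ...) {
  n <- block_sample_counts(x)
  cat(sprintf(
    "Block paradigm: %g s rest + %d x (%g s task + %g s rest), fs %g Hz\n",
    x$rest_pre_s, x$n_trials, x$task_s, x$rest_post_s, x$fs_out))
  cat(sprintf("  %d channels, %d subjects, %d samples (%.1f s)\n",
              x$n_channels, x$n_subjects, sum(n), sum(n) / x$fs_out))
  invisible(x)
}
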