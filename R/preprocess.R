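#' @keywords internal
fft_gain_mask <- function(n, fs, f) {
  # symmetric real gain over FFT bins -> exactly zero-phase filtering
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq) # fold negative frequencies
  gain <- rep(1, n)
  tw <- f$transition_hz
  nyq <- fs / 2
  skipped <- character(0)

  edge_down <- function(x, lo) { # 1 -> 0 over [lo - tw, lo]
    ifelse(x <= lo - tw, 1,
           ifelse(x >= lo, 0, 0.5 * (1 + cos(pi * (x - (lo - tw)) / tw))))
  }
  edge_up <- function(x, hi) { # 0 -> 1 over [hi, hi + tw]
    ifelse(x <= hi, 0,
           ifelse(x >= hi + tw, 1, 0.5 * (1 - cos(pi * (x - hi) / tw))))
  }

  for (b in f$reject_bands) {
    if (b[1] >= nyq) {
      skipped <- c(skipped, sprintf("%g-%g Hz", b[1], b[2]))
      next
    }
    hi <- min(b[2], nyq)
    g <- pmax(edge_down(freq, b[1]), edge_up(freq, hi))
    if (b[2] >= nyq) g <- edge_down(freq, b[1]) # band runs into Nyquist
    gain <- gain * g
  }
  if (!is.null(f$highpass_reject_below_hz)) {
    c0 <- f$highpass_reject_below_hz
    lo <- if (is.null(f$lf_protect_hz)) 0 else f$lf_protect_hz
    if (lo > 0) { # protected: reject (lo, c0), keep the slower band
      g <- pmax(edge_down(freq, lo), edge_up(freq, c0))
      gain <- gain * g
    } else { # literal high-pass, DC included
      gain <- gain * edge_up(freq, c0)
      gain[freq <= c0] <- 0
    }
  }
  if (!is.null(f$analysis_band)) {
    b <- f$analysis_band
    gain <- gain * edge_up(freq, b[1]) * edge_down(freq, min(b[2], nyq))
  }
  attr(gain, "skipped_bands") <- skipped
  gain
}

#' @keywords internal
band_reject_matrix <- function(x, fs, f) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (f$method == "fft_mask") {
    gain <- fft_gain_mask(n, fs, f)
    out <- apply(x, 2, function(col) {
      Re(stats::fft(stats::fft(col) * gain, inverse = TRUE)) / n
    })
    skipped <- attr(gain, "skipped_bands")
  } else {
    out <- x
    skipped <- character(0)
    nyq <- fs / 2
    for (b in f$reject_bands) {
      if (b[1] >= nyq) { skipped <- c(skipped, sprintf("%g-%g Hz", b[1], b[2])); next }
      w <- c(b[1], min(b[2], nyq * 0.999)) / nyq
      bt <- signal::butter(2, w, type = "stop")
      out <- apply(out, 2, function(col) signal::filtfilt(bt, col))
    }
    if (!is.null(f$highpass_reject_below_hz)) {
      lo <- if (is.null(f$lf_protect_hz)) 0 else f$lf_protect_hz
      bt <- if (lo > 0)
        signal::butter(2, c(lo, f$highpass_reject_below_hz) / nyq, type = "stop")
      else signal::butter(2, f$highpass_reject_below_hz / nyq, type = "high")
      out <- apply(out, 2, function(col) signal::filtfilt(bt, col))
    }
    if (!is.null(f$analysis_band)) {
      bt <- signal::butter(2, pmin(f$analysis_band / nyq, 0.999), type = "pass")
      out <- apply(out, 2, function(col) signal::filtfilt(bt, col))
    }
  }
  if (length(skipped))
    warning("reject band(s) above Nyquist skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  dim(out) <- dim(x)
  attr(out, "skipped_bands") <- skipped
  out
}

#' Zero-phase band-reject (notch) filtering
#'
#' Removes physiological noise bands from concentration series. The default
#' realization multiplies the FFT of each channel by a real, symmetric gain
#' mask with raised-cosine band edges: exactly zero-phase, so block-locked
#' responses are not shifted in time. An alternative forward-backward
#' Butterworth band-stop cascade (\code{method = "iir_zero_phase"} in the
#' \code{\link{filter_spec}}) is available behind the same contract.
#'
#' A reject band lying entirely above the Nyquist frequency cannot be filtered
#' at that sampling rate; it is skipped with a warning (at the default
#' 1.81 Hz output rate this applies to the 1-1.2 Hz cardiac band, whose
#' energy appears aliased below Nyquist instead).
#'
#' @param x a \code{\link{hemo_series}} (both chromophores filtered) or a
#'   numeric matrix/vector.
#' @param f a \code{\link{filter_spec}}.
#' @param fs sampling rate in Hz, required when \code{x} is not a
#'   \code{hemo_series}.
#' @return Same type as \code{x}, filtered.
#' @export
band_reject <- function(x, f = filter_spec(), fs = NULL) {
  validate_filter_spec(f)
  if (inherits(x, "hemo_series")) {
    hbo <- suppressWarnings(band_reject_matrix(x$hbo, x$fs, f))
    hbr <- band_reject_matrix(x$hbr, x$fs, f)
    out <- hemo_series(hbo, hbr, fs = x$fs)
    attr(out, "skipped_bands") <- attr(hbr, "skipped_bands")
    return(out)
  }
  if (is.null(fs)) stop("fs required for plain numeric input", call. = FALSE)
  vec <- is.null(dim(x))
  out <- band_reject_matrix(as.matrix(x), fs, f)
  if (vec) {
    sk <- attr(out, "skipped_bands")
    out <- as.vector(out)
    attr(out, "skipped_bands") <- sk
  }
  out
}

#' Polynomial detrending
#'
#' Removes the least-squares polynomial of the given order from each channel.
#' Order 0 is mean removal; order 1 (the default used by the pipeline) removes
#' linear drift.
#'
#' @param x a \code{\link{hemo_series}}, numeric matrix or vector.
#' @param order polynomial order, >= 0.
#' @return Same type as \code{x}, detrended.
#' @export
detrend_poly <- function(x, order = 1L) {
  order <- as.integer(order)
  if (order < 0L) stop("detrend order must be >= 0", call. = FALSE)
  if (inherits(x, "hemo_series"))
    return(hemo_series(detrend_poly(x$hbo, order), detrend_poly(x$hbr, order),
                       fs = x$fs))
  vec <- is.null(dim(x))
  m <- as.matrix(x)
  if (nrow(m) <= order + 1L)
    stop("series too short for detrend order ", order, call. = FALSE)
  t0 <- seq_len(nrow(m))
  basis <- stats::poly(t0, degree = max(order, 1L), raw = FALSE)
  if (order == 0L) {
    out <- sweep(m, 2, colMeans(m))
  } else {
    out <- apply(m, 2, function(col) stats::lm.fit(cbind(1, basis), col)$residuals)
    dim(out) <- dim(m)
  }
  if (vec) as.vector(out) else out
}

#' Standard preprocessing: notch filter then detrend
#'
#' Applies \code{\link{band_reject}} followed by \code{\link{detrend_poly}}
#' (order taken from the filter specification) to both chromophores.
#'
#' @param hemo a \code{\link{hemo_series}}.
#' @param f a \code{\link{filter_spec}}.
#' @return A preprocessed \code{\link{hemo_series}}.
#' @export
preprocess <- function(hemo, f = filter_spec()) {
  stopifnot(inherits(hemo, "hemo_series"))
  out <- band_reject(hemo, f)
  sk <- attr(out, "skipped_bands")
  out <- detrend_poly(out, f$detrend_order)
  attr(out, "skipped_bands") <- sk
  out
}
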