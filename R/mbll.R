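#' Two-wavelength optical-density container
#'
#' @param values numeric array, time x channels x 2 wavelengths, unitless
#'   absorbance change.
#' @param fs sampling rate, Hz.
#' @param wavelengths_nm the two wavelengths in nanometers.
#' @return An object of class \code{optical_density}.
#' @export
optical_density <- function(values, fs, wavelengths_nm = c(760, 830)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || dim(values)[3] != 2L)
    stop("optical_density: values must be time x channels x 2 wavelengths",
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("optical_density: values must be finite", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("optical_density: fs must be > 0", call. = FALSE)
  if (length(wavelengths_nm) != 2L)
    stop("optical_density: exactly two wavelengths", call. = FALSE)
  structure(list(values = values, fs = fs, wavelengths_nm = wavelengths_nm),
            class = "optical_density")
}

#' Hemoglobin concentration-change container
#'
#' @param hbo,hbr time x channel matrices of concentration changes, micromolar.
#' @param fs sampling rate, Hz.
#' @return An object of class \code{hemo_series}.
#' @export
hemo_series <- function(hbo, hbr, fs) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!identical(dim(hbo), dim(hbr)))
    stop("hemo_series: hbo and hbr must share dimensions", call. = FALSE)
  if (!all(is.finite(hbo)) || !all(is.finite(hbr)))
    stop("hemo_series: values must be finite", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("hemo_series: fs must be > 0", call. = FALSE)
  structure(list(hbo = hbo, hbr = hbr, fs = fs), class = "hemo_series")
}

#' Invert the modified Beer-Lambert law
#'
#' Converts two-wavelength optical-density changes to HbO/HbR concentration
#' changes. For every sample t and channel,
#' \deqn{[\Delta c_{HbO}; \Delta c_{HbR}] = \frac{1}{l d} \alpha^{-1}
#'   [\Delta A(t,\lambda_1); \Delta A(t,\lambda_2)]}
#' with \eqn{\alpha} the 2x2 extinction matrix, \eqn{l} the emitter-detector
#' distance (mm) and \eqn{d} the differential path-length factor. With
#' \eqn{\alpha} in \eqn{\mu M^{-1} mm^{-1}} the output is in micromolar.
#' The map is exactly linear; \code{\link{concentrations_to_od}} is its
#' inverse to machine precision.
#'
#' @param od an \code{\link{optical_density}}.
#' @param e an \code{\link{extinction_spec}}.
#' @return A \code{\link{hemo_series}}.
#' @export
mbll_invert <- function(od, e = extinction_spec()) {
  stopifnot(inherits(od, "optical_density"))
  validate_extinction_spec(e)
  ainv <- solve(e$alpha)
  ld <- e$distance_mm * e$dpf
  a1 <- od$values[, , 1L, drop = TRUE]
  a2 <- od$values[, , 2L, drop = TRUE]
  hbo <- (ainv[1, 1] * a1 + ainv[1, 2] * a2) / ld
  hbr <- (ainv[2, 1] * a1 + ainv[2, 2] * a2) / ld
  hemo_series(hbo, hbr, fs = od$fs)
}

#' Check linearity of the MBLL inversion under scaling
#'
#' Verifies that \code{mbll_invert(k * od) == k * mbll_invert(od)} within a
#' relative tolerance, a property harness used in testing and sanity checks.
#'
#' @param od an \code{\link{optical_density}}.
#' @param e an \code{\link{extinction_spec}}.
#' @param k scalar factor.
#' @param tol relative tolerance.
#' @return TRUE if the identity holds within \code{tol}.
#' @export
scale_linearity_check <- function(od, e = extinction_spec(), k = 2, tol = 1e-12) {
  scaled <- optical_density(od$values * k, fs = od$fs,
                            wavelengths_nm = od$wavelengths_nm)
  h1 <- mbll_invert(scaled, e)
  h0 <- mbll_invert(od, e)
  ref <- max(abs(c(h0$hbo, h0$hbr)), 1)
  max(abs(c(h1$hbo - k * h0$hbo, h1$hbr - k * h0$hbr))) <= tol * abs(k) * ref ||
    (k == 0 && max(abs(c(h1$hbo, h1$hbr))) <= tol)
}

#' Total-hemoglobin convenience sum
#'
#' HbT = HbO + HbR. Provided for reports only; it is the sum of the two
#' chromophores and carries no extra discriminative information, so it is
#' never used as a classification feature.
#'
#' @param hemo a \code{\link{hemo_series}}.
#' @return time x channel matrix of total-hemoglobin changes, micromolar.
#' @export
hbt_total <- function(hemo) {
  stopifnot(inherits(hemo, "hemo_series"))
  hemo$hbo + hemo$hbr
}
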