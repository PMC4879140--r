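#' @keywords internal
block_sample_counts <- function(p) {
  # per-block rounding keeps every 44-s block the same length (80 samples at
  # 1.81 Hz); the total defines the recording length
  n_rest_pre <- round(p$rest_pre_s * p$fs_out)
  n_task <- round(p$task_s * p$fs_out)
  n_rest_post <- round(p$rest_post_s * p$fs_out)
  c(n_rest_pre, rep(c(n_task, n_rest_post), p$n_trials))
}

#' Per-sample task/rest labels for a block paradigm
#'
#' Builds the label vector aligned with a simulated recording: an initial rest
#' block, then \code{n_trials} task blocks each followed by a rest block.
#' Block lengths are \code{round(duration * fs_out)} samples.
#'
#' @param p a \code{\link{paradigm_spec}}.
#' @return Integer vector, 1 for task samples, 0 for rest, with attribute
#'   \code{"block"} giving a per-sample block index (1 = initial rest).
#' @examples
#' labs <- build_block_labels(paradigm_spec())
#' sum(labs == 1)  # 5 blocks x 80 samples
#' @export
build_block_labels <- function(p) {
  validate_paradigm_spec(p)
  counts <- block_sample_counts(p)
  is_task <- c(FALSE, rep(c(TRUE, FALSE), p$n_trials))
  labels <- rep(as.integer(is_task), counts)
  attr(labels, "block") <- rep(seq_along(counts), counts)
  labels
}

#' Canonical double-gamma haemodynamic response function
#'
#' Positive gamma peaking at \code{peak_s} minus a later undershoot gamma,
#' normalized to unit area so that convolution with a long boxcar plateaus at
#' the boxcar amplitude.
#'
#' @param t time points in seconds (>= 0).
#' @param peak_s time-to-peak of the main lobe, seconds.
#' @param undershoot relative undershoot amplitude.
#' @return numeric vector of HRF values at \code{t}.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot = 1 / 6) {
  stopifnot(peak_s > 0)
  # gamma density with rate 1 has mode (shape - 1)
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot * stats::dgamma(t, shape = peak_s + 10 + 1, rate = 1)
  h
}

#' @keywords internal
derive_seed <- function(master, subject = 0L, offset = 0L) {
  (as.integer(master) + 104729L * as.integer(subject) + as.integer(offset)) %%
    2147483647L
}

#' Simulate HbO/HbR concentration changes for one subject
#'
#' Simulates at an oversampled internal rate (\code{oversample * fs_out}, so
#' that cardiac noise above the output Nyquist is representable), then
#' point-samples every \code{oversample}-th value. Point sampling deliberately
#' reproduces the aliasing a real low-rate acquisition would show. The
#' noiseless task response is the boxcar convolved with the double-gamma HRF;
#' HbR is a scaled, delayed negative copy of HbO. Sinusoidal cardiac,
#' respiratory and Mayer-wave components with channel-specific random phases,
#' linear drift and white noise are added per channel.
#'
#' @param p a \code{\link{paradigm_spec}}.
#' @param a an \code{\link{activation_spec}}.
#' @param n a \code{\link{noise_spec}}; its \code{seed} drives all randomness.
#' @param oversample integer internal oversampling factor (default 9, i.e.
#'   about 16.3 Hz at the default 1.81 Hz output rate).
#' @return A list with elements \code{hbo}, \code{hbr} (noisy, time x channel
#'   matrices, micromolar), \code{truth_hbo}, \code{truth_hbr} (noiseless),
#'   \code{labels}, \code{fs}, and \code{fine} (the internal-rate noisy series
#'   and its rate, for spectral diagnostics).
#' @export
simulate_concentrations <- function(p, a, n, oversample = 9L) {
  validate_paradigm_spec(p); validate_activation_spec(a); validate_noise_spec(n)
  oversample <- as.integer(oversample)
  fs_fine <- p$fs_out * oversample
  if (fs_fine < 4 * n$cardiac_hz)
    stop("internal simulation rate must be >= 4 x cardiac_hz; increase oversample",
         call. = FALSE)

  labels <- build_block_labels(p)
  n_out <- length(labels)
  n_fine <- n_out * oversample
  t_fine <- (seq_len(n_fine) - 1L) / fs_fine
  # boxcar on the fine grid: each output sample expands to `oversample` fine samples
  box_fine <- rep(labels, each = oversample)

  # HRF kernel truncated at 32 s, unit area at the fine rate
  t_h <- seq(0, 32, by = 1 / fs_fine)
  h <- hrf_double_gamma(t_h, a$hrf_peak_s, a$hrf_undershoot)
  h <- h / sum(h)
  resp_fine <- stats::convolve(box_fine, rev(h), type = "open")[seq_len(n_fine)]

  delay_samp <- round(a$hbr_delay_s * fs_fine)
  resp_hbr_fine <- c(rep(0, delay_samp), resp_fine)[seq_len(n_fine)]

  gains <- rep_len(a$channel_gain, p$n_channels)
  idx_out <- seq(1L, n_fine, by = oversample)

  hbo <- matrix(0, n_out, p$n_channels)
  hbr <- matrix(0, n_out, p$n_channels)
  truth_hbo <- matrix(0, n_out, p$n_channels)
  truth_hbr <- matrix(0, n_out, p$n_channels)
  fine_hbo <- matrix(0, n_fine, p$n_channels)

  dt <- 1 / fs_fine
  osc_one <- function(freq, amp, jitter) {
    phi0 <- stats::runif(1, 0, 2 * pi)
    drift_phi <- if (jitter > 0)
      cumsum(stats::rnorm(n_fine, 0, jitter * sqrt(dt))) else 0
    amp * sin(2 * pi * freq * t_fine + phi0 + drift_phi)
  }

  for (ch in seq_len(p$n_channels)) {
    set.seed(derive_seed(n$seed, offset = 131L * ch))
    pj <- n$phase_diffusion
    osc <- osc_one(n$cardiac_hz, n$cardiac_amp, pj) +
      osc_one(n$resp_hz, n$resp_amp, pj) +
      osc_one(n$mayer_hz, n$mayer_amp, pj)
    osc_hbr <- osc_one(n$cardiac_hz, n$cardiac_amp, pj) +
      osc_one(n$resp_hz, n$resp_amp, pj) +
      osc_one(n$mayer_hz, n$mayer_amp, pj)
    drift <- n$drift_slope * t_fine
    w_hbo <- stats::rnorm(n_fine, 0, n$white_sd)
    w_hbr <- stats::rnorm(n_fine, 0, n$white_sd)

    clean_hbo <- a$hbo_amp * gains[ch] * resp_fine
    clean_hbr <- a$hbo_amp * gains[ch] * a$hbr_ratio * resp_hbr_fine
    ks <- n$hbr_noise_scale
    noisy_hbo <- clean_hbo + osc + drift + w_hbo
    noisy_hbr <- clean_hbr + ks * (osc_hbr - drift + w_hbr)

    truth_hbo[, ch] <- clean_hbo[idx_out]
    truth_hbr[, ch] <- clean_hbr[idx_out]
    hbo[, ch] <- noisy_hbo[idx_out]
    hbr[, ch] <- noisy_hbr[idx_out]
    fine_hbo[, ch] <- noisy_hbo
  }

  list(hbo = hbo, hbr = hbr, truth_hbo = truth_hbo, truth_hbr = truth_hbr,
       labels = labels, fs = p$fs_out,
       fine = list(hbo = fine_hbo, fs = fs_fine))
}

#' Forward modified Beer-Lambert model: concentrations to optical density
#'
#' Computes \eqn{\Delta A(t, \lambda_j) = l \cdot d \cdot
#' (\alpha_{HbO}(\lambda_j) \Delta c_{HbO} + \alpha_{HbR}(\lambda_j)
#' \Delta c_{HbR})} per sample and channel; the exact linear forward model
#' whose inverse is \code{\link{mbll_invert}}.
#'
#' @param hemo a \code{\link{hemo_series}} (micromolar).
#' @param e an \code{\link{extinction_spec}}.
#' @return An \code{\link{optical_density}} object.
#' @export
concentrations_to_od <- function(hemo, e = extinction_spec()) {
  stopifnot(inherits(hemo, "hemo_series"))
  validate_extinction_spec(e)
  ld <- e$distance_mm * e$dpf
  n_t <- nrow(hemo$hbo); n_ch <- ncol(hemo$hbo)
  values <- array(0, dim = c(n_t, n_ch, 2L))
  values[, , 1L] <- ld * (e$alpha[1, 1] * hemo$hbo + e$alpha[1, 2] * hemo$hbr)
  values[, , 2L] <- ld * (e$alpha[2, 1] * hemo$hbo + e$alpha[2, 2] * hemo$hbr)
  optical_density(values, fs = hemo$fs, wavelengths_nm = e$wavelengths_nm)
}

#' Generate a complete synthetic study
#'
#' One recording per subject. Per-subject noise seeds are derived
#' deterministically from the master seed, so subjects are independent but the
#' whole study is reproducible from a single integer.
#'
#' @param p,a,n,e paradigm, activation, noise and extinction specifications.
#' @param oversample internal oversampling factor, see
#'   \code{\link{simulate_concentrations}}.
#' @return A list of class \code{synthetic_study}: one element per subject,
#'   each with \code{od} (an \code{\link{optical_density}}), \code{truth_hbo},
#'   \code{truth_hbr}, \code{labels} and \code{subject_id}.
#' @export
generate_study <- function(p = paradigm_spec(), a = activation_spec(),
                           n = noise_spec(), e = extinction_spec(),
                           oversample = 9L) {
  validate_paradigm_spec(p)
  subjects <- lapply(seq_len(p$n_subjects), function(s) {
    ns <- n
    ns$seed <- derive_seed(n$seed, subject = s)
    sim <- simulate_concentrations(p, a, ns, oversample = oversample)
    od <- concentrations_to_od(
      hemo_series(sim$hbo, sim$hbr, fs = p$fs_out), e)
    list(subject_id = s, od = od,
         truth_hbo = sim$truth_hbo, truth_hbr = sim$truth_hbr,
         labels = sim$labels)
  })
  structure(subjects, class = "synthetic_study",
            paradigm = p, activation = a, noise = n, extinction = e)
}

#' Write a study's optical-density recordings to long-format CSV
#'
#' Columns: subject, channel, wavelength_nm, time_s, delta_A.
#'
#' @param study a \code{synthetic_study} from \code{\link{generate_study}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_od_csv <- function(study, path) {
  rows <- lapply(study, function(subj) {
    od <- subj$od
    n_t <- dim(od$values)[1]; n_ch <- dim(od$values)[2]
    tt <- (seq_len(n_t) - 1L) / od$fs
    do.call(rbind, lapply(1:2, function(j) {
      data.frame(
        subject = subj$subject_id,
        channel = rep(seq_len(n_ch), each = n_t),
        wavelength_nm = od$wavelengths_nm[j],
        time_s = rep(tt, n_ch),
        delta_A = as.vector(od$values[, , j]))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read long-format optical-density CSV
#'
#' Inverse of \code{\link{write_od_csv}}. The sampling rate is recovered from
#' the time column.
#'
#' @param path CSV path with columns subject, channel, wavelength_nm, time_s,
#'   delta_A (TSV accepted via \code{sep}).
#' @param sep field separator.
#' @return A list per subject with \code{subject_id} and \code{od}.
#' @export
read_od_csv <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("subject", "channel", "wavelength_nm", "time_s", "delta_A")
  if (!all(need %in% names(d)))
    stop("optical-density file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  wls <- sort(unique(d$wavelength_nm))
  if (length(wls) != 2L) stop("exactly two wavelengths required", call. = FALSE)
  lapply(sort(unique(d$subject)), function(s) {
    ds <- d[d$subject == s, ]
    chans <- sort(unique(ds$channel))
    times <- sort(unique(ds$time_s))
    fs <- 1 / stats::median(diff(times))
    values <- array(NA_real_, c(length(times), length(chans), 2L))
    for (j in 1:2) for (ci in seq_along(chans)) {
      sub <- ds[ds$wavelength_nm == wls[j] & ds$channel == chans[ci], ]
      sub <- sub[order(sub$time_s), ]
      values[, ci, j] <- sub$delta_A
    }
    list(subject_id = s,
         od = optical_density(values, fs = fs, wavelengths_nm = wls))
  })
}
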