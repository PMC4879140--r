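test_that("block labels follow the paradigm structure", {
  labs <- build_block_labels(paradigm_spec())
  r <- rle(as.vector(labs))
  task_lens <- r$lengths[r$values == 1L]
  expect_length(task_lens, 5L)                    # 5 task blocks
  expect_true(all(task_lens == round(44 * 1.81))) # 80 samples each
  # label conservation: every sample is task or rest
  expect_equal(sum(labs == 1L) + sum(labs == 0L), length(labs))

  tiny <- build_block_labels(
    paradigm_spec(rest_pre_s = 1, task_s = 1, rest_post_s = 1,
                  n_trials = 1, fs_out = 1))
  expect_equal(as.vector(tiny), c(0L, 1L, 0L))

  expect_error(build_block_labels(paradigm_spec(task_s = 0)))
})

test_that("simulation is silent with no signal sources and deterministic", {
  p <- paradigm_spec(n_subjects = 1, n_channels = 2)
  quiet <- noise_spec(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                      white_sd = 0, drift_slope = 0, seed = 5)
  sim <- simulate_concentrations(p, activation_spec(hbo_amp = 0), quiet)
  expect_true(all(sim$hbo == 0) && all(sim$hbr == 0))

  n <- noise_spec(seed = 42)
  s1 <- simulate_concentrations(p, activation_spec(), n)
  s2 <- simulate_concentrations(p, activation_spec(), n)
  expect_identical(s1$hbo, s2$hbo)
  expect_identical(s1$hbr, s2$hbr)
})

test_that("noiseless response matches a direct boxcar-HRF convolution oracle", {
  p <- paradigm_spec(n_subjects = 1, n_channels = 1)
  quiet <- noise_spec(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                      white_sd = 0, drift_slope = 0, seed = 1)
  a <- activation_spec(hbo_amp = 1)
  sim <- simulate_concentrations(p, a, quiet, oversample = 9L)

  # independent oracle: discrete causal convolution computed lag by lag at
  # the same internal rate
  fs_fine <- p$fs_out * 9
  labs <- build_block_labels(p)
  box <- rep(labs, each = 9)
  t_h <- seq(0, 32, by = 1 / fs_fine)
  h <- hrf_double_gamma(t_h, a$hrf_peak_s, a$hrf_undershoot)
  h <- h / sum(h)
  nf <- length(box)
  conv <- numeric(nf)
  for (k in seq_along(h)) {
    idx <- seq_len(nf) - k + 1L
    ok <- idx >= 1L
    conv[ok] <- conv[ok] + h[k] * box[idx[ok]]
  }
  oracle_out <- conv[seq(1, nf, by = 9)]
  expect_equal(sim$truth_hbo[, 1], as.vector(oracle_out), tolerance = 1e-8)
  # plateau reaches roughly the configured amplitude
  expect_equal(max(sim$truth_hbo), max(oracle_out), tolerance = 1e-8)
  expect_gt(max(sim$truth_hbo), 0.9)
})

test_that("task raises HbO and HbR anticorrelates, monotonically in amplitude", {
  p <- paradigm_spec(n_subjects = 1, n_channels = 1)
  quiet <- noise_spec(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                      white_sd = 0, drift_slope = 0, seed = 1)
  diffs <- sapply(c(0.5, 1, 2), function(amp) {
    sim <- simulate_concentrations(p, activation_spec(hbo_amp = amp), quiet)
    task <- sim$labels == 1L
    expect_lt(cor(sim$truth_hbo[, 1], sim$truth_hbr[, 1]), 0)
    mean(sim$truth_hbo[task, 1]) - mean(sim$truth_hbo[!task, 1])
  })
  expect_gt(diffs[1], 0)
  expect_true(all(diff(diffs) > 0))
})

test_that("noise-only spectrum peaks at the configured frequencies", {
  p <- paradigm_spec(n_subjects = 1, n_channels = 1)
  # pure tones (no phase diffusion) for an exact spectral check
  n <- noise_spec(cardiac_amp = 1, resp_amp = 1, mayer_amp = 1,
                  white_sd = 0, drift_slope = 0, phase_diffusion = 0,
                  seed = 9)
  sim <- simulate_concentrations(p, activation_spec(hbo_amp = 0), n)
  x <- sim$fine$hbo[, 1]
  fs <- sim$fine$fs
  spec <- Mod(stats::fft(x))^2
  nfft <- length(x)
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  half <- freqs <= fs / 2
  spec <- spec[half]; freqs <- freqs[half]
  df <- fs / nfft
  for (f0 in c(n$cardiac_hz, n$resp_hz, n$mayer_hz)) {
    peak_f <- freqs[which.max(ifelse(abs(freqs - f0) <= 5 * df, spec, 0))]
    expect_lt(abs(peak_f - f0), 2 * df)
    # local maximum: stronger than the surrounding region
    region <- abs(freqs - f0) <= 5 * df
    expect_gt(max(spec[region]), 10 * stats::median(spec[!region]))
  }
})

test_that("forward OD model is the exact inverse of MBLL inversion", {
  set.seed(31)
  hemo <- hemo_series(matrix(rnorm(50), 25, 2), matrix(rnorm(50), 25, 2),
                      fs = 1.81)
  e <- extinction_spec()
  od <- concentrations_to_od(hemo, e)
  back <- mbll_invert(od, e)
  expect_lt(max(abs(back$hbo - hemo$hbo)), 1e-9)
  expect_lt(max(abs(back$hbr - hemo$hbr)), 1e-9)

  zero <- hemo_series(matrix(0, 4, 1), matrix(0, 4, 1), fs = 1)
  expect_true(all(concentrations_to_od(zero, e)$values == 0))

  # identity coefficients with unit pathlength: OD equals the concentrations
  ident <- extinction_spec(alpha = diag(2), dpf = 1, distance_mm = 1)
  h <- hemo_series(matrix(c(0.3, 0.1), 2, 1), matrix(c(-0.1, 0.2), 2, 1), fs = 1)
  od2 <- concentrations_to_od(h, ident)
  expect_equal(od2$values[, 1, 1], c(0.3, 0.1))
  expect_equal(od2$values[, 1, 2], c(-0.1, 0.2))
})

test_that("generate_study produces reproducible per-subject recordings", {
  p <- paradigm_spec(n_subjects = 3, n_channels = 4)
  s1 <- generate_study(p, activation_spec(), noise_spec(seed = 7))
  s2 <- generate_study(p, activation_spec(), noise_spec(seed = 7))
  expect_length(s1, 3L)
  expect_equal(dim(s1[[1]]$od$values)[2], 4L)
  expect_identical(s1[[2]]$od$values, s2[[2]]$od$values)
  # different subjects differ
  expect_false(identical(s1[[1]]$od$values, s1[[2]]$od$values))

  single <- generate_study(paradigm_spec(n_subjects = 1),
                           activation_spec(), noise_spec(seed = 7))
  expect_length(single, 1L)
})

test_that("optical-density CSV round-trips", {
  p <- paradigm_spec(n_subjects = 2, n_channels = 2, n_trials = 1)
  study <- generate_study(p, activation_spec(), noise_spec(seed = 3))
  path <- tempfile(fileext = ".csv")
  write_od_csv(study, path)
  back <- read_od_csv(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$od$values, study[[1]]$od$values, tolerance = 1e-12)
  expect_equal(back[[2]]$od$fs, 1.81, tolerance = 1e-6)
})
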