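test_that("epochize cuts one epoch per block, channel and chromophore", {
  p <- paradigm_spec(n_subjects = 1)
  quiet <- noise_spec(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                      white_sd = 0, drift_slope = 0, seed = 1)
  sim <- simulate_concentrations(p, activation_spec(), quiet)
  hemo <- hemo_series(sim$hbo, sim$hbr, fs = p$fs_out)
  ep <- epochize(hemo, sim$labels)
  # 5 task blocks x 16 channels x 2 chromophores
  expect_equal(sum(ep$label == "task"), 160L)
  # 6 rest blocks (initial + 5 post-task)
  expect_equal(sum(ep$label == "rest"), 192L)
  # half-open ranges tile the recording without overlap
  one <- ep[ep$channel == 1 & ep$chromophore == "HbO", ]
  one <- one[order(one$start), ]
  expect_equal(one$start[-1], one$end[-nrow(one)])
  expect_equal(one$end[nrow(one)] - 1L, length(sim$labels))
  expect_true(all(vapply(ep$data, length, 1L) == ep$end - ep$start))

  tiny <- paradigm_spec(rest_pre_s = 2, task_s = 2, rest_post_s = 2,
                        n_trials = 1, fs_out = 1, n_channels = 1,
                        n_subjects = 1)
  sim2 <- simulate_concentrations(tiny, activation_spec(), quiet, oversample = 9)
  h2 <- hemo_series(sim2$hbo, sim2$hbr, fs = 1)
  ep2 <- epochize(h2, sim2$labels)
  ep2_hbo <- ep2[ep2$chromophore == "HbO", ]
  expect_equal(sum(ep2_hbo$label == "task"), 1L)
  expect_equal(sum(ep2_hbo$label == "rest"), 2L)

  expect_error(epochize(h2, integer(0)), "aligned")
  expect_error(epochize(h2, c(0, 1)), "aligned")
})

test_that("feature values match hand arithmetic on small vectors", {
  expect_equal(feat_mean(c(1, 2, 3)), 2)
  expect_equal(feat_mean(rep(7, 5)), 7)
  expect_equal(feat_variance(c(1, 2, 3)), 2 / 3)
  expect_equal(feat_variance(rep(3, 4)), 0)
  expect_equal(feat_skewness(c(-1, 0, 1)), 0)
  expect_equal(feat_kurtosis(c(-1, 1, -1, 1)), 1)
  expect_equal(feat_peak(c(0.1, 0.5, 0.3)), 0.5)
  expect_equal(feat_peak(c(-3, -1, -2)), -1)  # signed maximum, not |max|
  expect_equal(feat_peak(c(-3, -1, -2), absolute = TRUE), -3)
  expect_equal(feat_slope(c(0, 1, 2), t = c(0, 1, 2)), 1.0)
  expect_equal(feat_slope(rep(2, 10), fs = 2), 0)
  # slope is per second: doubling fs halves the slope over the same samples
  x <- c(0, 1, 2, 3)
  expect_equal(feat_slope(x, fs = 2), feat_slope(x, fs = 1) * 2)

  expect_error(feat_mean(numeric(0)), "at least")
  expect_error(feat_skewness(rep(1, 10)), "degenerate")
  expect_error(feat_kurtosis(rep(0, 5)), "degenerate")
  expect_error(feat_slope(3), "at least 2")
})

test_that("features match brute-force oracles on random epochs", {
  set.seed(99)
  for (i in 1:50) {
    x <- rnorm(sample(5:120, 1), sd = runif(1, 0.1, 10))
    t <- (seq_along(x) - 1) / 1.81
    expect_rel_equal(feat_mean(x), oracle_mean(x))
    expect_rel_equal(feat_variance(x), oracle_variance(x))
    expect_rel_equal(feat_skewness(x), oracle_skewness(x), tol = 1e-10)
    expect_rel_equal(feat_kurtosis(x), oracle_kurtosis(x))
    expect_rel_equal(feat_peak(x), oracle_peak(x))
    expect_rel_equal(feat_slope(x, fs = 1.81), oracle_slope(x, t), tol = 1e-10)
  }
  # third-moment oracle on a specific asymmetric vector
  v <- c(0, 0, 0, 1)
  expect_rel_equal(feat_skewness(v), oracle_skewness(v))
  # kurtosis of a large normal sample approaches 3
  set.seed(100)
  expect_equal(feat_kurtosis(rnorm(2e5)), 3, tolerance = 0.05)
})

test_that("noisy line slope is recovered within its standard error", {
  set.seed(7)
  fs <- 1.81
  n <- 80
  t <- (0:(n - 1)) / fs
  x <- 0.05 * t + rnorm(n, sd = 0.1)
  est <- feat_slope(x, fs = fs)
  se <- 0.1 / (sd(t) * sqrt(n))
  expect_lt(abs(est - 0.05), 4 * se)
  expect_rel_equal(est, oracle_slope(x, t), tol = 1e-10)
})

test_that("moment features obey order and affine symmetries", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(60)
    xs <- sample(x)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    # order-invariance of everything except slope
    expect_equal(feat_mean(xs), feat_mean(x))
    expect_equal(feat_variance(xs), feat_variance(x))
    expect_equal(feat_skewness(xs), feat_skewness(x))
    expect_equal(feat_kurtosis(xs), feat_kurtosis(x))
    expect_equal(feat_peak(xs), feat_peak(x))
    # affine response
    y <- a * x + b
    expect_equal(feat_mean(y), a * feat_mean(x) + b)
    expect_equal(feat_peak(y), a * feat_peak(x) + b)
    expect_equal(feat_variance(y), a^2 * feat_variance(x))
    expect_equal(feat_skewness(y), feat_skewness(x))
    expect_equal(feat_kurtosis(y), feat_kurtosis(x))
    # Pearson inequality
    expect_gte(feat_kurtosis(x), feat_skewness(x)^2 + 1)
  }
  # slope is the one order-aware feature
  x <- cumsum(rep(1, 30))
  expect_false(isTRUE(all.equal(feat_slope(rev(x)), feat_slope(x))))
})

test_that("min-max rescaling maps columns onto [0, 1] preserving order", {
  fm <- data.frame(subject = 1, channel = 1, chromophore = "HbO",
                   block = 1:3, label = "task",
                   mean = c(2, 4, 6), slope = c(0, 1, 0.5),
                   variance = c(1, 2, 3), peak = c(5, 1, 3),
                   skewness = c(-1, 0, 1), kurtosis = c(2, 3, 4))
  out <- rescale_minmax(fm)
  expect_equal(out$mean, c(0, 0.5, 1))
  expect_true(all(vapply(feature_names(),
                         function(cn) all(out[[cn]] >= 0 & out[[cn]] <= 1),
                         logical(1))))
  # rank order preserved
  expect_equal(order(out$peak), order(fm$peak))
  # idempotent on an already-[0,1] column
  again <- rescale_minmax(out)
  expect_equal(again$mean, out$mean)
  # scaling record allows reconstruction
  sc <- attr(out, "scaling")
  expect_equal(sc$min[sc$column == "mean"], 2)
  expect_equal(sc$max[sc$column == "mean"], 6)

  fm$variance <- 1
  expect_error(rescale_minmax(fm), "variance")
})

test_that("degenerate epochs error by default and drop on request", {
  p <- paradigm_spec(rest_pre_s = 4, task_s = 4, rest_post_s = 4,
                     n_trials = 1, fs_out = 1, n_channels = 1, n_subjects = 1)
  hemo <- hemo_series(matrix(c(0, 0, 0, 0, 1, 2, 1, 0, 0, 0, 0, 0), 12, 1),
                      matrix(rnorm(12), 12, 1), fs = 1)
  labels <- build_block_labels(p)
  ep <- epochize(hemo, labels)
  expect_error(compute_features(ep), "degenerate")
  expect_warning(fm <- compute_features(ep, degenerate = "drop"), "dropped")
  expect_false(anyNA(fm))
})

test_that("feature matrices round-trip through TSV", {
  study <- tiny_study(seed = 4)
  fm <- suppressWarnings(study_features(study))
  path <- tempfile(fileext = ".tsv")
  write_features_tsv(fm, path)
  back <- read_features_tsv(path)
  expect_equal(nrow(back), nrow(fm))
  expect_equal(back$mean, fm$mean, tolerance = 1e-9)
  expect_equal(attr(back, "scaling")$min, attr(fm, "scaling")$min,
               tolerance = 1e-9)
})

test_that("balanced epoch selection gives 80 samples per class per subject", {
  study <- tiny_study(seed = 5)
  fm <- suppressWarnings(study_features(study))
  hbo <- fm[fm$chromophore == "HbO", ]
  expect_equal(sum(hbo$label == "task"), 80L)
  expect_equal(sum(hbo$label == "rest"), 80L)
  fm_all <- suppressWarnings(study_features(study, rest_blocks = "all"))
  expect_equal(sum(fm_all$chromophore == "HbO" & fm_all$label == "rest"), 96L)
})
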