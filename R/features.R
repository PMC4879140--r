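#' Canonical feature names, in canonical order
#'
#' The fixed ordering used to enumerate combinations and break ties:
#' mean < slope < variance < peak < skewness < kurtosis.
#'
#' @return character vector of the six feature names.
#' @export
feature_names <- function() {
  c("mean", "slope", "variance", "peak", "skewness", "kurtosis")
}

#' Segment a concentration series into task/rest epochs
#'
#' Cuts each channel of each chromophore into one epoch per contiguous task or
#' rest block, using half-open sample ranges. Every sample belongs to exactly
#' one block, so epochs never overlap.
#'
#' @param hemo a \code{\link{hemo_series}}.
#' @param labels per-sample 0/1 indicator aligned with \code{hemo} (task = 1),
#'   as produced by \code{\link{build_block_labels}}.
#' @param subject_id identifier stored with each epoch.
#' @return A data.frame with one row per epoch: \code{subject}, \code{channel}
#'   (1-based), \code{chromophore} ("HbO"/"HbR"), \code{block} (block index in
#'   recording order), \code{label} ("task"/"rest"), \code{start}, \code{end}
#'   (half-open, 1-based start), and a list-column \code{data} holding the
#'   concentration vector.
#' @export
epochize <- function(hemo, labels, subject_id = 1L) {
  stopifnot(inherits(hemo, "hemo_series"))
  n_t <- nrow(hemo$hbo)
  if (length(labels) == 0L || length(labels) != n_t)
    stop("labels must be aligned with the series (", n_t, " samples)", call. = FALSE)
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_ch <- ncol(hemo$hbo)
  blocks <- seq_along(r$lengths)

  grid <- expand.grid(block = blocks, channel = seq_len(n_ch),
                      chromophore = c("HbO", "HbR"),
                      stringsAsFactors = FALSE)
  grid$label <- ifelse(r$values[grid$block] == 1L, "task", "rest")
  grid$start <- starts[grid$block]
  grid$end <- ends[grid$block] + 1L # half-open
  grid$subject <- subject_id
  grid$data <- lapply(seq_len(nrow(grid)), function(i) {
    m <- if (grid$chromophore[i] == "HbO") hemo$hbo else hemo$hbr
    m[grid$start[i]:(grid$end[i] - 1L), grid$channel[i]]
  })
  grid$fs <- hemo$fs
  grid[, c("subject", "channel", "chromophore", "block", "label",
           "start", "end", "fs", "data")]
}

#' @keywords internal
check_epoch <- function(x, min_n = 1L, what = "epoch") {
  if (length(x) < min_n)
    stop(what, " needs at least ", min_n, " samples", call. = FALSE)
  invisible(x)
}

#' Epoch mean
#'
#' Arithmetic mean \eqn{M = \frac{1}{N}\sum_i X_i} of the epoch samples.
#'
#' @param x numeric vector of epoch samples.
#' @return scalar.
#' @export
feat_mean <- function(x) {
  check_epoch(x)
  sum(x) / length(x)
}

#' Epoch variance (population)
#'
#' \eqn{var(X) = \sum (X - \mu)^2 / N}: the population form with divisor
#' \eqn{N}, not the sample form with \eqn{N - 1}.
#'
#' @param x numeric vector of epoch samples.
#' @return scalar, >= 0.
#' @export
feat_variance <- function(x) {
  check_epoch(x)
  mu <- sum(x) / length(x)
  sum((x - mu)^2) / length(x)
}

#' Epoch skewness (population)
#'
#' Third standardized moment \eqn{E[((X - \mu)/\sigma)^3]} with population
#' moments. Degenerate (constant) epochs have no defined skewness.
#'
#' @param x numeric vector of epoch samples.
#' @param na_degenerate return NA instead of erroring on a constant epoch.
#' @return scalar.
#' @export
feat_skewness <- function(x, na_degenerate = FALSE) {
  check_epoch(x)
  mu <- sum(x) / length(x)
  s2 <- sum((x - mu)^2) / length(x)
  if (s2 <= 0) {
    if (na_degenerate) return(NA_real_)
    stop("degenerate epoch: zero standard deviation", call. = FALSE)
  }
  mean(((x - mu) / sqrt(s2))^3)
}

#' Epoch kurtosis (population, non-excess)
#'
#' Fourth standardized moment \eqn{E[((X - \mu)/\sigma)^4]} with population
#' moments and no \eqn{-3} correction (a normal sample gives about 3).
#'
#' @param x numeric vector of epoch samples.
#' @param na_degenerate return NA instead of erroring on a constant epoch.
#' @return scalar, >= 1 for any non-degenerate vector.
#' @export
feat_kurtosis <- function(x, na_degenerate = FALSE) {
  check_epoch(x)
  mu <- sum(x) / length(x)
  s2 <- sum((x - mu)^2) / length(x)
  if (s2 <= 0) {
    if (na_degenerate) return(NA_real_)
    stop("degenerate epoch: zero standard deviation", call. = FALSE)
  }
  mean(((x - mu) / sqrt(s2))^4)
}

#' Epoch peak
#'
#' Signed maximum of the epoch, \code{max(x)} — not the absolute maximum. For
#' HbR epochs, whose task response is negative, the "peak" is therefore the
#' least-negative value; set \code{absolute = TRUE} for the magnitude peak.
#'
#' @param x numeric vector of epoch samples.
#' @param absolute use the largest absolute value (off by default).
#' @return scalar.
#' @export
feat_peak <- function(x, absolute = FALSE) {
  check_epoch(x)
  if (absolute) x[which.max(abs(x))] else max(x)
}

#' Epoch slope
#'
#' Least-squares linear slope of the epoch against time in seconds
#' (micromolar per second when the input is micromolar).
#'
#' @param x numeric vector of epoch samples.
#' @param t time vector in seconds; defaults to \code{(0:(N-1))/fs}.
#' @param fs sampling rate used when \code{t} is missing.
#' @return scalar, micromolar/s.
#' @export
feat_slope <- function(x, t = NULL, fs = 1) {
  check_epoch(x, min_n = 2L)
  if (is.null(t)) t <- (seq_along(x) - 1) / fs
  if (length(t) != length(x)) stop("t must match x in length", call. = FALSE)
  tc <- t - mean(t)
  sum(tc * (x - mean(x))) / sum(tc^2)
}

#' Compute the six features for every epoch
#'
#' @param epochs epoch data.frame from \code{\link{epochize}}.
#' @param degenerate what to do with zero-variance epochs: \code{"error"}
#'   (default) or \code{"drop"} (removed with a warning).
#' @param absolute_peak passed to \code{\link{feat_peak}}.
#' @return A feature matrix: data.frame with provenance columns (subject,
#'   channel, chromophore, block, label) and the six feature columns in
#'   canonical order.
#' @export
compute_features <- function(epochs, degenerate = c("error", "drop"),
                             absolute_peak = FALSE) {
  degenerate <- match.arg(degenerate)
  na_deg <- degenerate == "drop"
  feats <- lapply(seq_len(nrow(epochs)), function(i) {
    x <- epochs$data[[i]]
    fs <- epochs$fs[i]
    c(mean = feat_mean(x),
      slope = feat_slope(x, fs = fs),
      variance = feat_variance(x),
      peak = feat_peak(x, absolute = absolute_peak),
      skewness = feat_skewness(x, na_degenerate = na_deg),
      kurtosis = feat_kurtosis(x, na_degenerate = na_deg))
  })
  fm <- cbind(epochs[, c("subject", "channel", "chromophore", "block", "label")],
              do.call(rbind, feats))
  if (na_deg && anyNA(fm)) {
    bad <- !stats::complete.cases(fm)
    warning(sum(bad), " degenerate epoch(s) dropped", call. = FALSE)
    fm <- fm[!bad, ]
  }
  fm
}

#' Min-max rescaling of feature columns
#'
#' Applies \eqn{x' = (x - \min x) / (\max x - \min x)} to each feature column
#' so every column lies in [0, 1]. The default scope rescales within each
#' (subject, chromophore) group, matching a protocol that scales each
#' subject's features once over all epochs before cross-validation. The
#' scaling parameters are recorded so training-fold parameters can be applied
#' to test folds in leakage-safe mode.
#'
#' @param fm feature matrix from \code{\link{compute_features}}.
#' @param scope \code{"subject_chromophore"} (default) or \code{"global"}.
#' @param columns feature columns to rescale.
#' @return The rescaled feature matrix with a \code{"scaling"} attribute, a
#'   data.frame of per-group, per-column min and max.
#' @export
rescale_minmax <- function(fm, scope = c("subject_chromophore", "global"),
                           columns = feature_names()) {
  scope <- match.arg(scope)
  key <- if (scope == "global") rep("all", nrow(fm)) else
    paste(fm$subject, fm$chromophore, sep = "|")
  rec <- list()
  for (g in unique(key)) {
    idx <- key == g
    for (col in columns) {
      v <- fm[[col]][idx]
      lo <- min(v); hi <- max(v)
      if (hi <= lo)
        stop("constant feature column '", col, "' in group ", g,
             ": min-max scaling undefined", call. = FALSE)
      fm[[col]][idx] <- (v - lo) / (hi - lo)
      rec[[length(rec) + 1L]] <- data.frame(group = g, column = col,
                                            min = lo, max = hi)
    }
  }
  attr(fm, "scaling") <- do.call(rbind, rec)
  fm
}

#' Write a feature matrix to TSV with a scaling sidecar
#'
#' @param fm feature matrix (possibly rescaled).
#' @param path output TSV path; scaling parameters (if present) go to
#'   \code{paste0(path, ".scaling.json")}.
#' @return \code{path}, invisibly.
#' @export
write_features_tsv <- function(fm, path) {
  utils::write.table(fm, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sc <- attr(fm, "scaling")
  if (!is.null(sc))
    jsonlite::write_json(sc, paste0(path, ".scaling.json"), digits = NA)
  invisible(path)
}

#' Read a feature matrix written by \code{\link{write_features_tsv}}
#'
#' @param path TSV path.
#' @return feature matrix data.frame; the scaling sidecar, when present, is
#'   restored as the \code{"scaling"} attribute.
#' @export
read_features_tsv <- function(path) {
  fm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".scaling.json")
  if (file.exists(sidecar))
    attr(fm, "scaling") <- as.data.frame(jsonlite::read_json(sidecar,
                                                             simplifyVector = TRUE))
  fm
}

#' Build per-subject feature matrices for a whole study
#'
#' Runs the standard chain — MBLL inversion, notch filtering, detrending,
#' epoch segmentation, feature computation, min-max rescaling — for every
#' subject of a synthetic (or ingested) study.
#'
#' For classification the rest class is balanced against the task class by
#' default: only the rest block following each task block is used
#' (\code{rest_blocks = "post"}), giving equal task/rest sample counts
#' (5 blocks x 16 channels = 80 per class per subject under the default
#' paradigm). \code{rest_blocks = "all"} keeps the initial baseline rest too.
#'
#' @param study list of subjects, each with \code{od}, \code{labels},
#'   \code{subject_id} (see \code{\link{generate_study}}).
#' @param e an \code{\link{extinction_spec}}.
#' @param f a \code{\link{filter_spec}}.
#' @param rest_blocks \code{"post"} (default, balanced) or \code{"all"}.
#' @param scale rescale features to [0, 1] (default TRUE).
#' @return A feature matrix data.frame covering all subjects.
#' @export
study_features <- function(study, e = extinction_spec(), f = filter_spec(),
                           rest_blocks = c("post", "all"), scale = TRUE) {
  rest_blocks <- match.arg(rest_blocks)
  fms <- lapply(study, function(subj) {
    hemo <- mbll_invert(subj$od, e)
    hemo <- preprocess(hemo, f)
    ep <- epochize(hemo, subj$labels, subject_id = subj$subject_id)
    if (rest_blocks == "post") ep <- ep[ep$block != 1L, ]
    compute_features(ep)
  })
  fm <- do.call(rbind, fms)
  if (scale) fm <- rescale_minmax(fm)
  fm
}
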