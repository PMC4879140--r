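#' Enumerate feature combinations
#'
#' All subsets of the six canonical features of the requested sizes, crossed
#' with the requested chromophores, in deterministic canonical order
#' (lexicographic in the fixed ordering mean < slope < variance < peak <
#' skewness < kurtosis). The full default enumeration yields C(6,2) = 15 plus
#' C(6,3) = 20 subsets per chromophore: 70 combinations in total.
#'
#' @param features feature names to combine (distinct).
#' @param sizes subset sizes, any of 2 and 3.
#' @param chromophores chromophores to cross with.
#' @return data.frame with columns \code{combo} (display name, " and "-joined),
#'   \code{size}, \code{chromophore}, and list-column \code{features}.
#' @export
enumerate_combos <- function(features = feature_names(), sizes = c(2L, 3L),
                             chromophores = c("HbO", "HbR")) {
  if (anyDuplicated(features)) stop("duplicate feature names", call. = FALSE)
  rows <- list()
  for (chr in chromophores) {
    for (s in sort(as.integer(sizes))) {
      sets <- utils::combn(features, s, simplify = FALSE)
      for (fs in sets) {
        rows[[length(rows) + 1L]] <- data.frame(
          combo = paste(fs, collapse = " and "), size = s, chromophore = chr,
          stringsAsFactors = FALSE)
        rows[[length(rows)]]$features <- list(fs)
      }
    }
  }
  do.call(rbind, rows)
}

#' Score every feature combination on every subject
#'
#' For each combination and subject, restricts the feature matrix to that
#' combination's columns and chromophore and runs
#' \code{\link{cross_validate}}. Per-subject CV seeds are derived
#' deterministically from \code{spec$seed} and the subject id, so the whole
#' sweep is reproducible.
#'
#' @param fm feature matrix from \code{\link{study_features}} (all subjects).
#' @param combos combination table from \code{\link{enumerate_combos}}.
#' @param spec a \code{\link{cv_spec}}.
#' @return data.frame with one row per (combo, chromophore): display name,
#'   size, chromophore, one \code{S<i>} column per subject (accuracy, \%), and
#'   \code{mean_accuracy}.
#' @export
score_all <- function(fm, combos, spec = cv_spec()) {
  subjects <- sort(unique(fm$subject))
  res <- combos[, c("combo", "size", "chromophore")]
  acc <- matrix(NA_real_, nrow(combos), length(subjects))
  for (i in seq_len(nrow(combos))) {
    cols <- combos$features[[i]]
    for (si in seq_along(subjects)) {
      rows <- fm$subject == subjects[si] & fm$chromophore == combos$chromophore[i]
      if (!any(rows)) stop("no features for subject ", subjects[si], call. = FALSE)
      sub_spec <- spec
      sub_spec$seed <- derive_seed(spec$seed, subject = subjects[si])
      cv <- cross_validate(as.matrix(fm[rows, cols, drop = FALSE]),
                           fm$label[rows], sub_spec)
      acc[i, si] <- cv$mean_accuracy
    }
  }
  colnames(acc) <- paste0("S", subjects)
  res <- cbind(res, as.data.frame(acc))
  res$mean_accuracy <- rowMeans(acc)
  res
}

#' Exact paired sign-flip permutation test
#'
#' Tests whether combination A's per-subject accuracies exceed combination
#' B's. Under the null that A and B are exchangeable within subject, the sign
#' of each paired difference is arbitrary; the test enumerates all \eqn{2^n}
#' sign assignments and reports the one-sided p-value: the proportion of
#' assignments whose mean difference is >= the observed mean difference. The
#' observed assignment is included in the numerator, so p >= 1/2^n; with 7
#' subjects the 128 assignments make the test exact and its smallest
#' attainable p 1/128 (about 0.0078).
#'
#' @param a,b per-subject accuracies (equal length, paired by subject).
#' @return list of class \code{permutation_result}: \code{observed_diff}
#'   (mean of a - b, percentage points), \code{p_value},
#'   \code{n_permutations}.
#' @export
permutation_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)", call. = FALSE)
  n <- length(a)
  if (n < 1L) stop("need at least one pair", call. = FALSE)
  if (n > 20L) stop("exact enumeration limited to n <= 20", call. = FALSE)
  d <- a - b
  obs <- mean(d)
  # all 2^n sign patterns as a matrix of +-1
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  perm_means <- as.vector(signs %*% d) / n
  p <- mean(perm_means >= obs - 1e-12)
  structure(list(observed_diff = obs, p_value = p, n_permutations = 2L^n),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("paired sign-flip test: observed diff %+.2f pp, p = %.4g (%d permutations)\n",
              x$observed_diff, x$p_value, x$n_permutations))
  invisible(x)
}

#' Cross-subject average accuracy
#'
#' Arithmetic mean of per-subject accuracies, the quantity reported when a
#' combination's performance is summarized across a study's subjects.
#'
#' @param values per-subject accuracies (\%), at least one.
#' @param digits decimals in the returned value (default 1, the convention
#'   used in cross-subject summaries); use \code{Inf} for no rounding.
#' @return scalar, \%.
#' @export
average_across_subjects <- function(values, digits = 1) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("need at least one non-missing accuracy", call. = FALSE)
  m <- mean(values)
  if (is.finite(digits)) round(m, digits) else m
}

#' Rank feature combinations by mean accuracy
#'
#' Descending by cross-subject mean accuracy; ties are broken by canonical
#' combination order (position in the \code{\link{enumerate_combos}} output).
#'
#' @param results data.frame from \code{\link{score_all}} (or a fixture table
#'   in the same layout) with a \code{mean_accuracy} column.
#' @return the same data.frame, ranked, with a \code{rank} column.
#' @export
rank_combos <- function(results) {
  if (nrow(results) < 1L) stop("no results to rank", call. = FALSE)
  ord <- order(-results$mean_accuracy, seq_len(nrow(results)))
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Compare the best combination against all others by permutation test
#'
#' Runs \code{\link{permutation_test}} of the named combination's per-subject
#' accuracies against every other combination of the same chromophore and
#' size, one-sided in the direction "named combination better".
#'
#' @param results a \code{\link{score_all}}-layout data.frame with S-columns.
#' @param combo display name of the reference combination.
#' @param holm also report Holm-adjusted p-values.
#' @return data.frame: opponent combo, observed difference, p (and
#'   \code{p_holm} if requested).
#' @export
compare_against_all <- function(results, combo = "mean and peak", holm = FALSE) {
  scols <- grep("^S[0-9]+$", names(results), value = TRUE)
  ref <- results[results$combo == combo, , drop = FALSE]
  if (nrow(ref) != 1L)
    stop("combination '", combo, "' not found exactly once", call. = FALSE)
  others <- results[results$combo != combo, , drop = FALSE]
  out <- data.frame(combo = others$combo, observed_diff = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(others))) {
    pt <- permutation_test(as.numeric(ref[1, scols]),
                           as.numeric(others[i, scols]))
    out$observed_diff[i] <- pt$observed_diff
    out$p_value[i] <- pt$p_value
  }
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}
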