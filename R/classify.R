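#' Fit a two-class linear discriminant
#'
#' From-scratch Fisher/Gaussian linear discriminant: class means, pooled
#' within-class covariance \eqn{\Sigma = (S_0 + S_1)/(n - 2)}, weight vector
#' \eqn{w = \Sigma^{-1}(\mu_1 - \mu_0)} and bias
#' \eqn{b = -w^\top(\mu_0 + \mu_1)/2 + \log(\pi_1/\pi_0)}. The decision
#' function is affine: class 1 iff \eqn{w^\top x + b > 0}.
#'
#' A small ridge (\code{ridge * trace(\Sigma)/d} on the diagonal) guards
#' against singular pooled covariance; set \code{ridge = 0} for the pure
#' textbook inverse (singular covariance then raises an error).
#'
#' @param X numeric matrix, samples x features.
#' @param y labels coercible to two classes; the second sorted unique value is
#'   "class 1".
#' @param ridge relative diagonal loading (default 1e-8).
#' @param priors class priors; default = training class frequencies.
#' @return An object of class \code{lda_model} with elements \code{w},
#'   \code{b}, \code{means}, \code{pooled_cov}, \code{classes}, \code{priors}.
#' @export
lda_fit <- function(X, y, ridge = 1e-8, priors = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric", call. = FALSE)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L)
    stop("exactly two classes required; got ", length(classes), call. = FALSE)
  n0 <- sum(y == classes[1]); n1 <- sum(y == classes[2])
  if (n0 < 2L || n1 < 2L)
    stop("each class needs at least 2 samples", call. = FALSE)
  if (is.null(priors)) priors <- c(n0, n1) / (n0 + n1)

  X0 <- X[y == classes[1], , drop = FALSE]
  X1 <- X[y == classes[2], , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  S0 <- crossprod(sweep(X0, 2, mu0))
  S1 <- crossprod(sweep(X1, 2, mu1))
  pooled <- (S0 + S1) / (n0 + n1 - 2)

  d <- ncol(X)
  if (ridge > 0) {
    tr <- sum(diag(pooled))
    load <- if (tr > 0) ridge * tr / d else ridge
    pooled_r <- pooled + diag(load, d)
  } else {
    pooled_r <- pooled
  }
  w <- tryCatch(solve(pooled_r, mu1 - mu0), error = function(e)
    stop("singular pooled covariance; increase ridge", call. = FALSE))
  b <- -sum(w * (mu0 + mu1)) / 2 + log(priors[2] / priors[1])

  structure(list(w = w, b = b, means = rbind(mu0, mu1), pooled_cov = pooled,
                 classes = classes, priors = priors, d = d),
            class = "lda_model")
}

#' Predict with a fitted linear discriminant
#'
#' Label = class 1 iff \eqn{w^\top x + b > 0}. Exact boundary ties (score of
#' exactly 0) go to the class with the larger prior; with equal priors, to
#' class 0.
#'
#' @param model an \code{lda_model} from \code{\link{lda_fit}}.
#' @param X samples x features matrix with the training feature count.
#' @return character vector of predicted class labels.
#' @export
lda_predict <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("feature count mismatch: model has ", model$d, ", data has ",
         ncol(X), call. = FALSE)
  score <- as.vector(X %*% model$w) + model$b
  tie_class <- if (model$priors[2] > model$priors[1]) model$classes[2]
               else model$classes[1]
  out <- ifelse(score > 0, model$classes[2], model$classes[1])
  out[score == 0] <- tie_class
  out
}

#' @keywords internal
make_folds <- function(y, k, stratified, seed) {
  set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the linear discriminant
#'
#' Each run re-randomizes the fold assignment with a run-derived seed
#' (\code{spec$seed + run}), partitions into \code{k} folds (stratified by
#' default), trains on k-1 folds and tests on the held-out fold. The headline
#' accuracy is the grand mean of the per-fold accuracies over all runs and
#' folds (identical to the pooled accuracy when folds are equal-sized).
#'
#' When \code{spec$fold_safe_scaling} is on, min-max scaling is refit on each
#' training fold and its parameters applied to the test fold, so no test
#' information enters training.
#'
#' @param X samples x features matrix.
#' @param y two-class label vector.
#' @param spec a \code{\link{cv_spec}}.
#' @param ridge passed to \code{\link{lda_fit}}.
#' @return An object of class \code{cv_result}: \code{fold_acc} (runs x k
#'   matrix, \%), \code{mean_accuracy} (\%), and the spec.
#' @export
cross_validate <- function(X, y, spec = cv_spec(), ridge = 1e-8) {
  X <- as.matrix(X); y <- as.character(y)
  n <- length(y)
  if (nrow(X) != n) stop("X and y lengths differ", call. = FALSE)
  if (spec$k > n) stop("k exceeds number of samples", call. = FALSE)
  if (spec$stratified && any(table(y) < spec$k))
    stop("each class needs >= k samples for stratified folds", call. = FALSE)

  acc <- matrix(NA_real_, spec$runs, spec$k)
  for (r in seq_len(spec$runs)) {
    fold <- make_folds(y, spec$k, spec$stratified,
                       derive_seed(spec$seed, offset = r))
    for (f in seq_len(spec$k)) {
      te <- fold == f
      Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (spec$fold_safe_scaling) {
        lo <- apply(Xtr, 2, min); hi <- apply(Xtr, 2, max)
        rng <- pmax(hi - lo, .Machine$double.eps)
        Xtr <- sweep(sweep(Xtr, 2, lo), 2, rng, "/")
        Xte <- sweep(sweep(Xte, 2, lo), 2, rng, "/")
      }
      m <- lda_fit(Xtr, y[!te], ridge = ridge)
      pred <- lda_predict(m, Xte)
      acc[r, f] <- 100 * mean(pred == y[te])
    }
  }
  structure(list(fold_acc = acc, mean_accuracy = mean(acc), spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d runs: mean accuracy %.2f%%\n",
              x$spec$k, x$spec$runs, x$mean_accuracy))
  invisible(x)
}
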