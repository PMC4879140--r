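# Independent oracles, coded from the textbook definitions with explicit
# loops / explicit matrix inversion, deliberately not sharing code paths with
# the package implementation.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_variance <- function(x) {
  mu <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - mu)^2
  s / length(x)
}

oracle_skewness <- function(x) {
  mu <- oracle_mean(x)
  sig <- sqrt(oracle_variance(x))
  s <- 0
  for (v in x) s <- s + ((v - mu) / sig)^3
  s / length(x)
}

oracle_kurtosis <- function(x) {
  mu <- oracle_mean(x)
  sig <- sqrt(oracle_variance(x))
  s <- 0
  for (v in x) s <- s + ((v - mu) / sig)^4
  s / length(x)
}

oracle_peak <- function(x) {
  best <- x[1]
  for (v in x) if (v > best) best <- v
  best
}

# closed-form normal-equations slope of x against t
oracle_slope <- function(x, t) {
  n <- length(x)
  sxy <- sum(t * x) - sum(t) * sum(x) / n
  sxx <- sum(t^2) - sum(t)^2 / n
  sxy / sxx
}

# textbook two-class Gaussian discriminant with pooled covariance: explicit
# inversion, per-class scores delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2
# + log pi_k
oracle_lda_predict <- function(Xtr, ytr, Xte) {
  classes <- sort(unique(ytr))
  X0 <- Xtr[ytr == classes[1], , drop = FALSE]
  X1 <- Xtr[ytr == classes[2], , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  S <- (crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))) /
    (n0 + n1 - 2)
  Sinv <- solve(S)
  pri <- c(n0, n1) / (n0 + n1)
  d0 <- Xte %*% (Sinv %*% mu0) - drop(t(mu0) %*% Sinv %*% mu0) / 2 + log(pri[1])
  d1 <- Xte %*% (Sinv %*% mu1) - drop(t(mu1) %*% Sinv %*% mu1) / 2 + log(pri[2])
  as.vector(ifelse(d1 > d0, classes[2], classes[1]))
}

# sign-flip p-value by explicit subset enumeration (which indices get flipped)
oracle_signflip_p <- function(d) {
  n <- length(d)
  obs <- mean(d)
  cnt <- 0L
  tot <- 0L
  for (k in 0:n) {
    sets <- utils::combn(n, k, simplify = FALSE)
    for (s in sets) {
      dd <- d
      dd[s] <- -dd[s]
      if (mean(dd) >= obs - 1e-12) cnt <- cnt + 1L
      tot <- tot + 1L
    }
  }
  cnt / tot
}

# small synthetic study used by several tests
tiny_study <- function(seed = 1L, n_subjects = 1L, hbo_amp = 1,
                       noise = noise_spec(seed = seed)) {
  p <- paradigm_spec(n_subjects = n_subjects)
  noise$seed <- as.integer(seed)
  generate_study(p, activation_spec(hbo_amp = hbo_amp), noise)
}

expect_rel_equal <- function(got, want, tol = 1e-12) {
  scale <- max(abs(want), 1e-300)
  expect_lt(abs(got - want) / scale, tol)
}
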