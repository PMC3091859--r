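# Independent oracles and small fixtures used across the suite.

# Exhaustive Otsu search over histogram bin cuts, classic two-class
# formulation sigma_B^2 = w0 * w1 * (mu0 - mu1)^2, computed from a plain
# hist() tabulation with a slow loop.
otsu_oracle <- function(v, bins = 256L) {
  v <- as.numeric(v)
  breaks <- seq(min(v), max(v), length.out = bins + 1L)
  h <- hist(v, breaks = breaks, right = TRUE, include.lowest = TRUE,
            plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  n <- sum(counts)
  best <- -Inf
  best_t <- NA_real_
  for (t in seq_len(bins - 1L)) {
    c0 <- counts[seq_len(t)]; c1 <- counts[-seq_len(t)]
    w0 <- sum(c0) / n; w1 <- sum(c1) / n
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * mids[seq_len(t)]) / sum(c0)
    mu1 <- sum(c1 * mids[-seq_len(t)]) / sum(c1)
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best + 1e-12) {  # strict improvement: ties keep lower cut
      best <- s
      best_t <- breaks[t + 1L]
    }
  }
  best_t
}

# LOOCV by brute force: refit a fresh PLS model per fold and per
# component count through the public API.
loocv_oracle <- function(X, y, a_max) {
  n <- nrow(X)
  rmsecv <- numeric(a_max)
  for (a in seq_len(a_max)) {
    press <- 0
    for (i in seq_len(n)) {
      m <- plsr_fit(X[-i, , drop = FALSE], y[-i], ncomp = a)
      press <- press + (y[i] - predict(m, X[i, , drop = FALSE]))^2
    }
    rmsecv[a] <- sqrt(press / n)
  }
  rmsecv
}

# Ordinary least squares predictions via the normal equations.
ols_predict <- function(X, y, Xnew) {
  Xi <- cbind(1, X)
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  drop(cbind(1, Xnew) %*% beta)
}

# Fisher's two-class discriminant direction w ~ S_W^{-1} (mu1 - mu2),
# normalized to unit length with the package's sign convention.
fisher_direction <- function(X, labels) {
  cls <- unique(labels)
  x1 <- X[labels == cls[1], , drop = FALSE]
  x2 <- X[labels == cls[2], , drop = FALSE]
  sw <- crossprod(sweep(x1, 2, colMeans(x1))) +
    crossprod(sweep(x2, 2, colMeans(x2)))
  w <- solve(sw, colMeans(x1) - colMeans(x2))
  w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  w
}

# Truncated-normal moments by numerical quadrature (independent of the
# package's closed form).
truncnorm_moments_quadrature <- function(mean, sd, lo, hi) {
  z <- stats::integrate(function(x) dnorm(x, mean, sd), lo, hi,
                        rel.tol = 1e-12)$value
  m <- stats::integrate(function(x) x * dnorm(x, mean, sd), lo, hi,
                        rel.tol = 1e-12)$value / z
  v <- stats::integrate(function(x) (x - m)^2 * dnorm(x, mean, sd), lo, hi,
                        rel.tol = 1e-12)$value / z
  c(mean = m, sd = sqrt(v))
}

# Small noiseless phantom used by several files.
tiny_phantom <- function(concentration = 2, noise_sd = 0, seed = 11, ...) {
  render_phantom(phantom_spec(height = 40, width = 50,
                              concentration = concentration,
                              noise_sd = noise_sd, seed = seed, ...))
}

# Random regression instance with a planted linear signal.
random_instance <- function(n, p, noise = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = noise)
  list(X = X, y = y)
}
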