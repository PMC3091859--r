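#' Fit autoscaling (standardization) parameters
#'
#' Column means and sample standard deviations (n - 1 denominator) of a
#' spectra matrix. Applying the fitted parameters to the training matrix
#' gives columns with mean 0 and SD 1.
#'
#' @param X numeric n x p matrix, n >= 2.
#' @return An object of class `autoscale_params` with fields `mean`, `sd`.
#' @export
autoscale_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to autoscale")
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s == 0)) {
    bad <- colnames(X)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("degenerate column (zero variance): ", paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = s), class = "autoscale_params")
}

#' Apply autoscaling parameters
#'
#' Uses the stored (training) means and SDs — they are never recomputed
#' from the new data.
#'
#' @param X numeric matrix with the same column count as the fit.
#' @param params an `autoscale_params` from [autoscale_fit()].
#' @return The scaled matrix.
#' @export
autoscale_apply <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$mean)) {
    stop("shape error: column count does not match autoscaling parameters")
  }
  sweep(sweep(X, 2, params$mean), 2, params$sd, `/`)
}

# NIPALS on pre-scaled X (n x p) and y (n), univariate response.
# Returns weights W, x-loadings P, y-loadings q for components 1..A and
# the regression-vector path B (p x A): b_a = W_a (P_a' W_a)^{-1} q_a.
nipals_pls <- function(Xs, ys, A) {
  p <- ncol(Xs)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  Xd <- Xs
  yd <- ys
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { # residual exhausted; truncate
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      break
    }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    pa <- crossprod(Xd, t_) / tt
    qa <- sum(yd * t_) / tt
    Xd <- Xd - t_ %*% t(pa)
    yd <- yd - t_ * qa
    W[, a] <- w; P[, a] <- pa; q[a] <- qa
  }
  A_eff <- length(q)
  Bpath <- matrix(0, p, A_eff)
  for (a in seq_len(A_eff)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    Bpath[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  list(W = W, P = P, q = q, Bpath = Bpath, ncomp = A_eff)
}

#' Fit a PLS regression model (NIPALS)
#'
#' Autoscales X and standardizes y internally, then runs NIPALS partial
#' least squares with X-deflation for a univariate response. Predictions
#' are reproducible from the stored regression vector alone:
#' `yhat = y_mean + (X_scaled %*% b) * y_sd`.
#'
#' @param X numeric n x p spectra matrix.
#' @param y numeric response (concentrations, ug/g).
#' @param ncomp number of latent components A, `1 <= A <= min(p, n - 1)`.
#' @return An object of class `pls_model` with autoscaling parameters,
#'   weights `W`, x-loadings `P`, y-loadings `q`, regression vector `b`
#'   (and the per-component path `Bpath`), `ncomp`, and training `fitted`
#'   values.
#' @export
plsr_fit <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y sizes differ")
  if (ncomp < 1 || ncomp > min(p, n - 1)) {
    stop(sprintf("domain error: ncomp must be in [1, %d]", min(p, n - 1)))
  }
  if (stats::sd(y) == 0) stop("degenerate response: zero variance in y")
  asc <- autoscale_fit(X)
  Xs <- autoscale_apply(X, asc)
  y_mean <- mean(y); y_sd <- stats::sd(y)
  ys <- (y - y_mean) / y_sd
  fit <- nipals_pls(Xs, ys, ncomp)
  b <- fit$Bpath[, fit$ncomp]
  model <- structure(list(autoscale = asc, y_mean = y_mean, y_sd = y_sd,
                          W = fit$W, P = fit$P, q = fit$q,
                          b = b, Bpath = fit$Bpath, ncomp = fit$ncomp,
                          wavelengths = colnames(X)),
                     class = "pls_model")
  model$fitted <- predict(model, X)
  model
}

#' Predict concentrations from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix (or vector for a single spectrum) with
#'   the model's band count.
#' @param ncomp number of components to use (default: the fitted A).
#' @param ... unused.
#' @return Numeric vector of predicted concentrations.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$autoscale$mean)) {
    stop("shape error: band count does not match model")
  }
  if (ncomp < 1 || ncomp > object$ncomp) stop("ncomp out of fitted range")
  Xs <- autoscale_apply(newdata, object$autoscale)
  drop(object$y_mean + (Xs %*% object$Bpath[, ncomp]) * object$y_sd)
}

#' Leave-one-out cross-validation for PLS component selection
#'
#' For each left-out sample, refits autoscaling and NIPALS on the
#' remaining n - 1 samples (no leakage) and predicts the held-out
#' spectrum with every component count 1..`a_max`. Reports
#' `RMSECV(A) = sqrt(mean((y_i - yhat_{-i,A})^2))` and chooses the A at
#' the minimum (smallest A on ties).
#'
#' @param X numeric n x p training spectra, n >= 3.
#' @param y numeric training concentrations.
#' @param a_max largest component count to evaluate; capped (with a
#'   warning) at `min(p, n - 2)` so every fold can be fitted.
#' @return An object of class `cv_result` with `rmsecv` (named vector over
#'   A = 1..a_max) and `ncomp` (chosen A).
#' @export
loocv_select <- function(X, y, a_max = 10L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 training samples")
  cap <- min(ncol(X), n - 2L)
  if (a_max > cap) {
    warning(sprintf("a_max capped at %d (fold size limit)", cap))
    a_max <- cap
  }
  press <- numeric(a_max)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    asc <- autoscale_fit(Xi)
    Xs <- autoscale_apply(Xi, asc)
    y_mean <- mean(yi); y_sd <- stats::sd(yi)
    fit <- nipals_pls(Xs, (yi - y_mean) / y_sd, a_max)
    xs_new <- autoscale_apply(X[i, , drop = FALSE], asc)
    pred <- y_mean + drop(xs_new %*% fit$Bpath) * y_sd
    if (fit$ncomp < a_max) pred <- c(pred, rep(pred[fit$ncomp],
                                               a_max - fit$ncomp))
    press <- press + (y[i] - pred)^2
  }
  rmsecv <- sqrt(press / n)
  names(rmsecv) <- seq_len(a_max)
  structure(list(rmsecv = rmsecv, ncomp = which.min(rmsecv)),
            class = "cv_result")
}

#' Prediction quality metrics
#'
#' `rmsep` is the root mean squared prediction error, `r2` the coefficient
#' of determination `1 - SS_res / SS_tot`, and `std_error` the standard
#' error of the residuals, `sd(residuals) / sqrt(n)`.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return An object of class `prediction_metrics` with `r2`, `rmsep`,
#'   `std_error` and `residuals`.
#' @export
prediction_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  n <- length(y_true)
  if (length(y_pred) != n || n < 2) stop("need equal lengths >= 2")
  if (stats::var(y_true) == 0) stop("r2 undefined: zero variance in y_true")
  res <- y_true - y_pred
  structure(list(r2 = 1 - sum(res^2) / sum((y_true - mean(y_true))^2),
                 rmsep = sqrt(mean(res^2)),
                 std_error = stats::sd(res) / sqrt(n),
                 residuals = res),
            class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("r2 = %.4f, RMSEP = %.4f, std. error = %.4f (n = %d)\n",
              x$r2, x$rmsep, x$std_error, length(x$residuals)))
  invisible(x)
}

#' Screen spectral outliers with Hotelling's T-squared
#'
#' Autoscales the spectra, projects onto the first `n_pc` principal
#' components, and flags samples whose Hotelling T-squared statistic
#' exceeds the F-distribution quantile at level `alpha`. The score-plot
#' coordinates are returned for manual review.
#'
#' @param X numeric n x p spectra matrix, n >= 5.
#' @param n_pc number of principal components for the statistic.
#' @param alpha quantile level for the flagging threshold.
#' @return A list with `flagged` (row indices), `t2` (statistics),
#'   `threshold`, and `scores` (n x n_pc).
#' @export
screen_outliers <- function(X, n_pc = 2L, alpha = 0.975) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 samples")
  Xs <- autoscale_apply(X, autoscale_fit(X))
  dec <- pca_decomp(Xs, k = n_pc)
  t2 <- rowSums(sweep(dec$scores^2, 2, dec$values, `/`))
  thr <- n_pc * (n - 1) / (n - n_pc) * stats::qf(alpha, n_pc, n - n_pc)
  list(flagged = which(t2 > thr), t2 = t2, threshold = thr,
       scores = dec$scores)
}
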