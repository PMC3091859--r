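#' @name decomposition
#' @title Statistical decompositions of spectra and cubes
#' @description
#' Orthogonal/statistical decompositions used to highlight features for
#' segmentation and exploration: principal component analysis (PCA),
#' the maximum noise fraction transform (MNF; equivalent to maximum
#' autocorrelation factors under shift-difference noise estimation), and
#' canonical discriminant analysis (CDA, Fisher's discriminant).
#' All return a `linear_decomposition` with unit-norm component vectors
#' (largest-magnitude entry positive), per-pixel or per-sample scores,
#' and eigenvalues in the declared sort order.
NULL

new_decomposition <- function(vectors, scores, values, center, kind,
                              explained = NULL, extra = list()) {
  structure(c(list(vectors = vectors, scores = scores, values = values,
                   center = center, kind = kind, explained = explained),
              extra),
            class = "linear_decomposition")
}

#' @export
print.linear_decomposition <- function(x, ...) {
  cat(sprintf("<linear_decomposition:%s> %d components of dimension %d\n",
              x$kind, ncol(x$vectors), nrow(x$vectors)))
  invisible(x)
}

# Fix component signs: largest-magnitude entry of each vector positive.
sign_fix <- function(v) {
  s <- apply(v, 2, function(col) sign(col[which.max(abs(col))]))
  s[s == 0] <- 1
  sweep(v, 2, s, `*`)
}

# Generalized symmetric eigenproblem A v = lambda B v via Cholesky
# whitening of B; returns eigenvalues in decreasing order. A ridge
# eps = 1e-8 * trace(B)/p is added to B when it is near singular.
geigen_sym <- function(A, B) {
  p <- nrow(B)
  ridge <- 1e-8 * sum(diag(B)) / p
  U <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(U)) {
    warning("near-singular covariance; ridge regularization applied")
    U <- chol(B + diag(ridge, p))
  }
  Ui <- backsolve(U, diag(p))
  M <- t(Ui) %*% A %*% Ui
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vectors <- Ui %*% e$vectors
  list(values = e$values, vectors = vectors)
}

#' Principal component analysis of a spectra matrix
#'
#' Thin wrapper around [stats::prcomp()] (centring, no scaling — autoscale
#' upstream with [autoscale_fit()] if desired) returning the package's
#' decomposition container with explained-variance fractions.
#'
#' @param X numeric n x p matrix (rows = samples/pixels).
#' @param k number of components to keep, `<= min(n - 1, p)`.
#' @return A `linear_decomposition` of kind `"pca"` with fields `vectors`
#'   (p x k orthonormal), `scores` (n x k), `values` (variances) and
#'   `explained` (fractions of total variance, all k' = min(n-1, p)
#'   components' variances in `total_values`).
#' @export
pca_decomp <- function(X, k = min(nrow(X) - 1L, ncol(X))) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 rows")
  kmax <- min(n - 1L, p)
  if (k < 1 || k > kmax) {
    stop(sprintf("domain error: k must be in [1, %d]", kmax))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  v <- sign_fix(pc$rotation[, seq_len(k), drop = FALSE])
  scores <- scale(X, center = pc$center, scale = FALSE) %*% v
  new_decomposition(v, scores, vars[seq_len(k)], pc$center, "pca",
                    explained = vars[seq_len(k)] / sum(vars),
                    extra = list(total_values = vars))
}

#' Maximum noise fraction transform of a spectral cube
#'
#' Estimates the noise covariance from half-differences of horizontally
#' adjacent pixels, `Sigma_N = cov(Delta) / 2` (boundary pixels excluded;
#' restricted to `mask` when given), and solves the generalized
#' eigenproblem `Sigma_N v = lambda Sigma v` with `Sigma` the total
#' covariance. Components are ordered by increasing noise fraction
#' `lambda`, i.e. decreasing signal-to-noise, so component 1 is the
#' smoothest image structure — on fillet images the background/fillet
#' contrast.
#'
#' @param cube a [spectral_cube] with H, W >= 2.
#' @param mask optional [cube_mask]/logical matrix restricting covariance
#'   estimation (scores are still computed for every pixel).
#' @param offset pixel shift used for the noise difference (default 1,
#'   horizontal).
#' @param k number of components (default: all bands).
#' @return A `linear_decomposition` of kind `"mnf"`; `values` are noise
#'   fractions (ascending), `snr` the corresponding signal-to-noise ratios
#'   `(1 - lambda) / lambda`, `scores` an (H*W) x k matrix in column-major
#'   pixel order, and `dims` the image size.
#' @export
mnf <- function(cube, mask = NULL, offset = 1L, k = NULL) {
  d <- dim(cube$data)
  if (d[1] < 2 || d[2] < 2) stop("cube must be at least 2 x 2 pixels")
  if (d[2] <= offset) stop("offset too large for image width")
  B <- d[3]
  if (is.null(k)) k <- B
  if (k < 1 || k > B) stop("domain error: k out of range")
  X <- matrix(cube$data, nrow = d[1] * d[2], ncol = B)

  m <- if (is.null(mask)) matrix(TRUE, d[1], d[2]) else mask_data(mask, d[1:2])
  left <- m[, seq_len(d[2] - offset), drop = FALSE] &
    m[, seq_len(d[2] - offset) + offset, drop = FALSE]
  li <- which(left)  # index into the (H x (W-offset)) grid
  rows <- ((li - 1L) %% d[1]) + 1L
  cols <- ((li - 1L) %/% d[1]) + 1L
  i1 <- rows + (cols - 1L) * d[1]
  i2 <- rows + (cols + offset - 1L) * d[1]
  if (length(i1) < 2) stop("too few pixel pairs for noise estimation")
  delta <- X[i1, , drop = FALSE] - X[i2, , drop = FALSE]
  sigma_n <- stats::cov(delta) / 2
  sel <- as.vector(m)
  sigma <- stats::cov(X[sel, , drop = FALSE])

  g <- geigen_sym(sigma_n, sigma)
  ord <- order(g$values)  # ascending noise fraction = descending SNR
  values <- g$values[ord][seq_len(k)]
  vectors <- g$vectors[, ord, drop = FALSE][, seq_len(k), drop = FALSE]
  vectors <- sign_fix(vectors / rep(sqrt(colSums(vectors^2)),
                                    each = nrow(vectors)))
  center <- colMeans(X[sel, , drop = FALSE])
  scores <- sweep(X, 2, center) %*% vectors
  new_decomposition(vectors, scores, values, center, "mnf",
                    extra = list(snr = (1 - values) / pmax(values, 1e-12),
                                 dims = d[1:2]))
}

#' Extract one component's score image from an MNF decomposition
#'
#' @param dec a `linear_decomposition` carrying `dims` (e.g. from [mnf()]).
#' @param i component index.
#' @return An H x W numeric matrix of scores.
#' @export
score_image <- function(dec, i = 1L) {
  if (is.null(dec$dims)) stop("decomposition carries no image dimensions")
  matrix(dec$scores[, i], dec$dims[1], dec$dims[2])
}

#' Canonical discriminant analysis (Fisher's discriminant)
#'
#' Finds directions maximizing between-class over within-class scatter by
#' solving `S_B v = lambda S_W v`. For two classes this yields one
#' canonical variate proportional to `S_W^{-1} (mu_1 - mu_2)`.
#'
#' @param X numeric n x p matrix of (pixel) spectra.
#' @param labels factor/vector of class labels, >= 2 classes with >= 2
#'   observations each.
#' @param k number of canonical variates (default: number of classes - 1).
#' @return A `linear_decomposition` of kind `"cda"`; `values` are the
#'   scatter-ratio eigenvalues (descending), `scores` the canonical
#'   variates of the training rows, `class_means` the per-class mean
#'   scores.
#' @export
cda <- function(X, labels, k = NULL) {
  X <- as.matrix(X)
  labels <- factor(labels)
  cls <- levels(labels)
  if (length(cls) < 2) stop("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2)) stop("each class needs at least 2 observations")
  if (is.null(k)) k <- length(cls) - 1L
  p <- ncol(X)
  center <- colMeans(X)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (cl in cls) {
    xc <- X[labels == cl, , drop = FALSE]
    mu <- colMeans(xc)
    dev <- sweep(xc, 2, mu)
    sw <- sw + crossprod(dev)
    sb <- sb + nrow(xc) * tcrossprod(mu - center)
  }
  g <- geigen_sym(sb, sw)
  vectors <- g$vectors[, seq_len(k), drop = FALSE]
  vectors <- sign_fix(vectors / rep(sqrt(colSums(vectors^2)),
                                    each = nrow(vectors)))
  scores <- sweep(X, 2, center) %*% vectors
  cm <- do.call(rbind, lapply(cls, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE])))
  rownames(cm) <- cls
  new_decomposition(vectors, scores, g$values[seq_len(k)], center, "cda",
                    extra = list(class_means = cm, classes = cls))
}
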