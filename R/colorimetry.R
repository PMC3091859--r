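# piecewise Gaussian with separate left/right widths (CMF lobe shape)
.lobe <- function(x, m, s1, s2) {
  s <- ifelse(x < m, s1, s2)
  exp(-0.5 * ((x - m) / s)^2)
}

# CIE D65 relative spectral power, tabulated at 20 nm and interpolated
# linearly to the working 5 nm grid (fine structure is immaterial for
# smooth reflectances).
.d65_20nm <- function() {
  data.frame(
    wl = seq(380, 780, by = 20),
    S = c(49.98, 82.75, 93.43, 104.86, 117.81, 115.92, 109.35, 104.79,
          104.41, 100.00, 95.79, 90.01, 87.70, 83.70, 80.21, 78.27,
          71.61, 61.60, 75.09, 46.42, 63.38))
}

#' CIE 1931 2-degree observer table
#'
#' Colour-matching functions on the 380--780 nm grid at 5 nm spacing
#' (81 rows), generated from the published multi-lobe Gaussian analytic
#' fit of the CIE 1931 2-degree observer (Wyman, Sloan & Shirley 2013;
#' accurate to about 1%), together with the CIE D65 illuminant
#' relative spectral power interpolated from a 20 nm tabulation.
#'
#' @return A data frame of class `observer_table` with columns `wl`,
#'   `xbar`, `ybar`, `zbar`, `S`.
#' @export
cie_observer <- function() {
  wl <- seq(380, 780, by = 5)
  xbar <- 1.056 * .lobe(wl, 599.8, 37.9, 31.0) +
    0.362 * .lobe(wl, 442.0, 16.0, 26.7) -
    0.065 * .lobe(wl, 501.1, 20.4, 26.2)
  ybar <- 0.821 * .lobe(wl, 568.8, 46.9, 40.5) +
    0.286 * .lobe(wl, 530.9, 16.3, 31.1)
  zbar <- 1.217 * .lobe(wl, 437.0, 11.8, 36.0) +
    0.681 * .lobe(wl, 459.0, 26.0, 13.8)
  d65 <- .d65_20nm()
  S <- stats::approx(d65$wl, d65$S, xout = wl)$y
  out <- data.frame(wl = wl, xbar = pmax(xbar, 0), ybar = pmax(ybar, 0),
                    zbar = pmax(zbar, 0), S = S)
  class(out) <- c("observer_table", "data.frame")
  out
}

# --- vectorized Fritsch-Carlson monotone piecewise-cubic interpolation ---
# Y: n x k matrix of values at knots x (length k). Returns slopes n x k
# using the same algorithm as stats::splinefun(method = "monoH.FC").
.monofc_slopes <- function(x, Y) {
  k <- length(x)
  dx <- diff(x)
  Sx <- sweep(Y[, -1L, drop = FALSE] - Y[, -k, drop = FALSE], 2, dx, `/`)
  M <- cbind(Sx[, 1L],
             (Sx[, -1L, drop = FALSE] + Sx[, -(k - 1L), drop = FALSE]) / 2,
             Sx[, k - 1L])
  for (j in seq_len(k - 1L)) {
    Sk <- Sx[, j]
    zero <- Sk == 0
    M[zero, j] <- 0; M[zero, j + 1L] <- 0
    nz <- which(!zero)
    if (length(nz)) {
      alpha <- M[nz, j] / Sk[nz]
      beta <- M[nz, j + 1L] / Sk[nz]
      a2b3 <- 2 * alpha + beta - 3
      ab23 <- alpha + 2 * beta - 3
      fix <- a2b3 > 0 & ab23 > 0 & alpha * (a2b3 + ab23) < a2b3^2
      if (any(fix)) {
        idx <- nz[fix]
        tau <- 3 * Sk[idx] / sqrt(alpha[fix]^2 + beta[fix]^2)
        M[idx, j] <- tau * alpha[fix]
        M[idx, j + 1L] <- tau * beta[fix]
      }
    }
  }
  M
}

# Evaluate the Hermite interpolant at xout (constant extrapolation outside
# the knot range). Y: n x k, returns n x length(xout).
.monofc_eval <- function(x, Y, M, xout) {
  k <- length(x)
  iv <- findInterval(xout, x)
  out <- matrix(0, nrow(Y), length(xout))
  for (j in seq_along(xout)) {
    i <- iv[j]
    if (i < 1L) { out[, j] <- Y[, 1L]; next }
    if (i >= k) { out[, j] <- Y[, k]; next }
    h <- x[i + 1L] - x[i]
    s <- (xout[j] - x[i]) / h
    h00 <- (1 + 2 * s) * (1 - s)^2
    h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s)
    h11 <- s^2 * (s - 1)
    out[, j] <- h00 * Y[, i] + h * h10 * M[, i] +
      h01 * Y[, i + 1L] + h * h11 * M[, i + 1L]
  }
  out
}

#' Reconstruct dense reflectance spectra from band values
#'
#' Interpolates the visible bands (wavelengths <= 700 nm) onto the
#' 380--780 nm, 5 nm colorimetric grid using monotone piecewise-cubic
#' (Fritsch--Carlson) interpolation, with constant extrapolation beyond
#' the band range and clipping to non-negative reflectance. NIR bands
#' play no role in colour rendering and are excluded.
#'
#' @param bands a [band_set].
#' @param values a B-vector (one spectrum) or n x B matrix of band
#'   reflectances.
#' @return A vector of length 81 (or n x 81 matrix) of reflectances on
#'   the 5 nm grid.
#' @export
reconstruct_spectrum <- function(bands, values) {
  one <- is.null(dim(values))
  V <- if (one) matrix(values, nrow = 1) else as.matrix(values)
  if (ncol(V) != length(bands)) stop("shape error: band count mismatch")
  if (any(V < 0)) stop("reflectance values must be >= 0")
  vis <- bands$wavelengths_nm <= 700
  x <- bands$wavelengths_nm[vis]
  Y <- V[, vis, drop = FALSE]
  grid <- seq(380, 780, by = 5)
  M <- .monofc_slopes(x, Y)
  R <- pmax(.monofc_eval(x, Y, M, grid), 0)
  colnames(R) <- grid
  if (one) drop(R) else R
}

#' Integrate reflectance spectra to CIE XYZ
#'
#' `X = k * sum(R * S * xbar)` (and likewise Y, Z) with the normalization
#' `k = 100 / sum(S * ybar)`, so a perfect diffuser (R == 1) has
#' Y = 100 exactly.
#'
#' @param reflectance length-81 vector or n x 81 matrix on the observer
#'   grid.
#' @param obs an [cie_observer()] table.
#' @return Numeric `c(X, Y, Z)` or an n x 3 matrix.
#' @export
spectrum_to_xyz <- function(reflectance, obs = cie_observer()) {
  one <- is.null(dim(reflectance))
  R <- if (one) matrix(reflectance, nrow = 1) else as.matrix(reflectance)
  if (ncol(R) != nrow(obs)) stop("shape error: spectrum grid mismatch")
  k <- 100 / sum(obs$S * obs$ybar)
  cmf <- cbind(X = obs$S * obs$xbar, Y = obs$S * obs$ybar,
               Z = obs$S * obs$zbar)
  xyz <- k * (R %*% cmf)
  if (one) drop(xyz) else xyz
}

#' Illuminant white point of an observer table
#'
#' XYZ of the perfect diffuser under the table's illuminant (Y = 100).
#'
#' @param obs an [cie_observer()] table.
#' @return Numeric `c(X, Y, Z)`.
#' @export
white_point <- function(obs = cie_observer()) {
  spectrum_to_xyz(rep(1, nrow(obs)), obs)
}

# nominal D65 white used by the sRGB standard (Y = 100 scale)
.d65_nominal <- c(X = 95.047, Y = 100, Z = 108.883)

#' Convert CIE XYZ to 8-bit sRGB
#'
#' Standard sRGB transform (D65-referenced linear matrix, piecewise gamma,
#' clip to \[0, 1\], quantize to 0--255), for XYZ on the Y = 0..100 scale.
#' If `white` is supplied (the XYZ of the working illuminant's white
#' point, e.g. [white_point()]), the input is first rescaled per channel
#' so that `white` maps to the nominal D65 white — anchoring the rendering
#' so a perfect diffuser is exactly sRGB white.
#'
#' @param xyz length-3 vector or n x 3 matrix.
#' @param white optional length-3 white point for anchoring.
#' @return Integer vector `c(R, G, B)` in 0..255, or n x 3 matrix.
#' @export
xyz_to_srgb <- function(xyz, white = NULL) {
  one <- is.null(dim(xyz))
  M <- if (one) matrix(xyz, nrow = 1) else as.matrix(xyz)
  if (ncol(M) != 3) stop("xyz must have 3 columns")
  if (!is.null(white)) {
    M <- sweep(M, 2, .d65_nominal / white, `*`)
  }
  A <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
  lin <- (M / 100) %*% t(A)
  lin <- pmin(pmax(lin, 0), 1)
  gam <- ifelse(lin <= 0.0031308, 12.92 * lin,
                1.055 * lin^(1 / 2.4) - 0.055)
  out <- round(255 * pmin(pmax(gam, 0), 1))
  storage.mode(out) <- "integer"
  if (one) drop(out) else out
}

#' Render a spectral cube as an sRGB image
#'
#' Per-pixel composition of spectral reconstruction, XYZ integration and
#' the white-anchored sRGB transform.
#'
#' @param cube a [spectral_cube].
#' @param obs an [cie_observer()] table.
#' @return An H x W x 3 integer array of 8-bit sRGB values, with the
#'   linear-light RGB (0..1, pre-gamma) attached as attribute
#'   `"linear"`.
#' @export
cube_to_rgb <- function(cube, obs = cie_observer()) {
  d <- dim(cube$data)
  V <- cube_to_matrix(cube)
  R <- reconstruct_spectrum(cube$bands, V)
  xyz <- spectrum_to_xyz(R, obs)
  wp <- white_point(obs)
  anchored <- sweep(xyz, 2, .d65_nominal / wp, `*`)
  A <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
  lin <- pmin(pmax((anchored / 100) %*% t(A), 0), 1)
  srgb <- xyz_to_srgb(xyz, white = wp)
  out <- array(as.integer(srgb), dim = c(d[1], d[2], 3))
  attr(out, "linear") <- array(lin, dim = c(d[1], d[2], 3))
  out
}

#' Mean sRGB features over a region of interest
#'
#' The three-variable feature vector of the colour-baseline model: mean
#' 8-bit R, G, B over the ROI pixels. The mean linear-light values are
#' attached as attribute `"linear"`.
#'
#' @param rgb an image from [cube_to_rgb()] (H x W x 3).
#' @param roi non-empty mask.
#' @return Named numeric vector `c(R, G, B)`.
#' @export
rgb_mean_features <- function(rgb, roi) {
  d <- dim(rgb)
  m <- mask_data(roi, d[1:2])
  if (!any(m)) stop("empty roi")
  sel <- as.vector(m)
  px <- matrix(rgb, d[1] * d[2], 3)[sel, , drop = FALSE]
  out <- colMeans(px)
  names(out) <- c("R", "G", "B")
  lin <- attr(rgb, "linear")
  if (!is.null(lin)) {
    attr(out, "linear") <- colMeans(
      matrix(lin, d[1] * d[2], 3)[sel, , drop = FALSE])
  }
  out
}
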