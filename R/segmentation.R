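#' Otsu's adaptive threshold
#'
#' Builds a `bins`-bin histogram over the value range and returns the cut
#' maximizing the between-class variance (exhaustively over all bin
#' edges). Ties are broken toward the lower threshold. The reported
#' threshold is the canonical bin edge: values `> threshold` fall in the
#' upper class.
#'
#' @param values numeric vector or matrix with at least 2 distinct values.
#' @param bins histogram bin count.
#' @return The threshold (numeric scalar).
#' @export
otsu_threshold <- function(values, bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2 || rng[1] == rng[2]) {
    stop("degenerate input: need at least 2 distinct values")
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  # right-closed bins, lowest bin closed on both sides (hist default)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  left.open = TRUE) + (v == rng[1]),
                     nbins = bins)
  mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[bins]; mtot <- m[bins]
  w0 <- w[-bins]; m0 <- m[-bins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (mtot * w0[valid] / n - m0[valid])^2 /
    (w0[valid] / n * (w1[valid] / n)) / n
  if (!any(is.finite(bcv))) stop("degenerate input: single occupied bin")
  t_idx <- which.max(bcv)  # first maximum = lower threshold on ties
  breaks[t_idx + 1L]
}

#' Segment the fillet from the background
#'
#' Computes the first (highest-SNR) MNF component of the cube, thresholds
#' its score image with [otsu_threshold()], labels the side holding the
#' majority of image-border pixels as background, keeps the largest
#' connected foreground component and fills its holes. An image whose
#' leading MNF component is noise-dominated (noise fraction above 0.5)
#' carries no coherent object and raises a segmentation error.
#'
#' @param cube a [spectral_cube].
#' @return A list of [cube_mask]s: `background` and `fillet`.
#' @export
segment_fillet <- function(cube) {
  dec <- mnf(cube, k = 1L)
  if (dec$values[1] > 0.5) {
    stop("segmentation error: no coherent spatial structure ",
         "(leading MNF component is noise-dominated)")
  }
  img <- score_image(dec, 1L)
  thr <- otsu_threshold(img)
  upper <- img > thr
  border <- c(upper[1, ], upper[nrow(upper), ], upper[, 1], upper[, ncol(upper)])
  fg <- if (mean(border) > 0.5) !upper else upper
  if (!any(fg)) stop("segmentation error: empty foreground")
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  fg <- lab == which.max(sizes)
  fg <- EBImage::fillHull(fg) > 0
  fg <- matrix(as.logical(fg), nrow(img), ncol(img))
  list(background = cube_mask(!fg, "background"),
       fillet = cube_mask(fg, "fillet"))
}

#' Segment fat/collagen within the fillet
#'
#' Trains a two-class canonical discriminant (meat vs fat) on seed-region
#' pixel spectra, projects every fillet pixel onto the canonical variate,
#' thresholds with [otsu_threshold()] inside the fillet, and labels the
#' side whose mean score is closer to the fat seed-class mean as fat.
#'
#' @param cube a [spectral_cube].
#' @param fillet_mask fillet mask from [segment_fillet()].
#' @param seed_labels list with logical matrices `meat` and `fat` marking
#'   training pixels for the two classes (e.g. ground-truth regions on
#'   phantoms, or user-annotated seed regions on real images).
#' @return A [cube_mask] labelled `"fat"`.
#' @export
segment_fat <- function(cube, fillet_mask, seed_labels) {
  d <- dim(cube$data)
  fil <- mask_data(fillet_mask, d[1:2])
  if (!any(fil)) stop("fillet mask is empty")
  meat <- mask_data(seed_labels$meat, d[1:2])
  fat <- mask_data(seed_labels$fat, d[1:2])
  if (sum(meat) < 2 || sum(fat) < 2) {
    stop("label error: each seed class needs at least 2 pixels")
  }
  X <- cube_to_matrix(cube)
  train_idx <- c(which(meat), which(fat))
  labels <- rep(c("meat", "fat"), c(sum(meat), sum(fat)))
  dec <- cda(X[train_idx, , drop = FALSE], labels, k = 1L)
  cv <- as.vector(sweep(X, 2, dec$center) %*% dec$vectors)
  cv_img <- matrix(cv, d[1], d[2])
  thr <- otsu_threshold(cv_img[fil])
  upper <- cv_img > thr
  fat_mean <- dec$class_means["fat", 1]
  meat_mean <- dec$class_means["meat", 1]
  up_mean <- mean(cv_img[fil & upper])
  fat_side_is_upper <-
    abs(up_mean - fat_mean) < abs(up_mean - meat_mean)
  fat_out <- fil & (if (fat_side_is_upper) upper else !upper)
  cube_mask(fat_out, "fat")
}

#' Mean spectrum over a region of interest
#'
#' Arithmetic per-band mean over the ROI pixels — the single spectrum each
#' image contributes to calibration.
#'
#' @param cube a [spectral_cube].
#' @param roi non-empty mask.
#' @return Numeric vector of length B, named by wavelength.
#' @export
extract_mean_spectrum <- function(cube, roi) {
  d <- dim(cube$data)
  m <- mask_data(roi, d[1:2])
  if (!any(m)) stop("empty roi")
  colMeans(cube_to_matrix(cube, m))
}
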