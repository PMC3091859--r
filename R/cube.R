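#' Multispectral reflectance cube
#'
#' A spectral cube is an H x W x B array of reflectance fractions
#' (dimensionless, nominal range \[0, 1.2\] to allow slight specular excess)
#' together with the band set describing the B planes.
#'
#' @param data numeric H x W x B array of reflectance values, all `>= 0`.
#' @param bands a [band_set] with B wavelengths.
#' @param pixel_size_mm optional pixel pitch in mm/pixel.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, bands, pixel_size_mm = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3-d array (H x W x B)")
  }
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L) stop("cube must have H, W >= 1")
  if (!inherits(bands, "band_set")) stop("bands must be a band_set")
  if (d[3] != length(bands)) {
    stop(sprintf("band count mismatch: cube has %d planes, band set has %d",
                 d[3], length(bands)))
  }
  if (anyNA(data) || any(data < 0)) stop("reflectance values must be >= 0")
  structure(list(data = data, bands = bands, pixel_size_mm = pixel_size_mm),
            class = "spectral_cube")
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$bands$wavelengths_nm),
              max(x$bands$wavelengths_nm)))
  invisible(x)
}

#' Flatten a cube to a pixel-by-band matrix
#'
#' @param cube a [spectral_cube].
#' @param mask optional logical H x W matrix (or [cube_mask]); only pixels
#'   where the mask is TRUE are returned.
#' @return A numeric matrix with one row per (selected) pixel and one
#'   column per band, in column-major (R default) pixel order.
#' @export
cube_to_matrix <- function(cube, mask = NULL) {
  d <- dim(cube$data)
  m <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- as.character(cube$bands$wavelengths_nm)
  if (!is.null(mask)) {
    sel <- as.vector(mask_data(mask, d[1:2]))
    m <- m[sel, , drop = FALSE]
  }
  m
}

.sidecar_path <- function(path) {
  paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".bands.json")
}

#' Write a spectral cube to disk
#'
#' Writes a multi-page 16-bit grayscale TIFF (one page per band, stored
#' value = reflectance / scale * 65535) together with a
#' `<stem>.bands.json` sidecar holding the band wavelengths and the scale
#' factor. Reflectances above 1 are preserved via the scale factor.
#'
#' @param cube a [spectral_cube].
#' @param path output TIFF path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path) {
  if (!inherits(cube, "spectral_cube")) stop("cube must be a spectral_cube")
  d <- dim(cube$data)
  scale <- max(1, max(cube$data))
  pages <- lapply(seq_len(d[3]), function(b) cube$data[, , b] / scale)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) stop("could not write TIFF to ", path)
  meta <- list(wavelengths_nm = cube$bands$wavelengths_nm, scale = scale)
  if (!is.null(cube$pixel_size_mm)) meta$pixel_size_mm <- cube$pixel_size_mm
  jsonlite::write_json(meta, .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectral cube from disk
#'
#' Reads a multi-page TIFF written by [write_cube()] plus its
#' `<stem>.bands.json` sidecar. The page count must equal the number of
#' wavelengths declared in the sidecar.
#'
#' @param path TIFF path.
#' @return A [spectral_cube].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- .sidecar_path(path)
  if (!file.exists(side)) {
    stop("metadata error: missing band sidecar ", side)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$wavelengths_nm)) {
    stop("metadata error: sidecar lacks wavelengths_nm")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  wl <- as.numeric(meta$wavelengths_nm)
  if (length(pages) != length(wl)) {
    stop(sprintf("shape error: %d TIFF pages but %d wavelengths in sidecar",
                 length(pages), length(wl)))
  }
  scale <- if (is.null(meta$scale)) 1 else as.numeric(meta$scale)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- pages[[b]] * scale
  arr[arr < 0] <- 0
  spectral_cube(arr, band_set(wl),
                pixel_size_mm = if (!is.null(meta$pixel_size_mm))
                  as.numeric(meta$pixel_size_mm) else NULL)
}
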