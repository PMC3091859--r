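#' Pixel mask for a spectral cube
#'
#' A logical H x W matrix with a semantic label. The `roi` label denotes
#' the analysis region: fillet pixels with fat/collagen areas removed.
#'
#' @param data logical H x W matrix.
#' @param label one of `"background"`, `"fillet"`, `"fat"`, `"roi"`.
#' @return An object of class `cube_mask`.
#' @export
cube_mask <- function(data, label = c("background", "fillet", "fat", "roi")) {
  label <- match.arg(label)
  if (!is.matrix(data)) stop("mask data must be a matrix")
  if (!is.logical(data)) {
    if (is.numeric(data)) data <- data != 0 else stop("mask must be logical")
  }
  if (anyNA(data)) stop("mask must not contain NA")
  structure(list(data = data, label = label), class = "cube_mask")
}

#' @export
print.cube_mask <- function(x, ...) {
  cat(sprintf("<cube_mask:%s> %d x %d, %d pixels set\n", x$label,
              nrow(x$data), ncol(x$data), sum(x$data)))
  invisible(x)
}

# Accept cube_mask or plain logical matrix; check shape against dims if given.
mask_data <- function(mask, dims = NULL) {
  m <- if (inherits(mask, "cube_mask")) mask$data else mask
  if (!is.matrix(m) || !is.logical(m)) stop("mask must be a logical matrix")
  if (!is.null(dims) && !all(dim(m) == dims)) {
    stop(sprintf("mask shape %d x %d does not match image %d x %d",
                 nrow(m), ncol(m), dims[1], dims[2]))
  }
  m
}

#' Region of interest from fillet and fat masks
#'
#' The ROI is the fillet with fat pixels removed: `fillet & !fat`.
#'
#' @param fillet fillet mask (logical matrix or [cube_mask]).
#' @param fat fat mask of the same shape, or NULL for no fat removal.
#' @return A `cube_mask` labelled `"roi"`.
#' @export
roi_mask <- function(fillet, fat = NULL) {
  f <- mask_data(fillet)
  if (is.null(fat)) return(cube_mask(f, "roi"))
  cube_mask(f & !mask_data(fat, dim(f)), "roi")
}

#' Write a mask as a PNG file
#'
#' Pixels inside the mask are written as 255, outside as 0.
#'
#' @param mask a [cube_mask] or logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- mask_data(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Read a mask from a PNG file
#'
#' @param path PNG path (grayscale 0/255 as written by [write_mask()]).
#' @param label semantic label for the mask.
#' @return A [cube_mask].
#' @export
read_mask <- function(path, label = "roi") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  cube_mask(img > 0.5, label)
}
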