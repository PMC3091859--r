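#' Pixel-wise astaxanthin prediction map
#'
#' Autoscales every ROI pixel spectrum with the model's training
#' parameters and projects it through the PLS regression vector. Because
#' the whole pipeline is affine, the ROI mean of the map equals the
#' scalar prediction of the ROI mean spectrum.
#'
#' @param cube a [spectral_cube] with the model's band count.
#' @param roi non-empty mask of pixels to predict.
#' @param model a [plsr_fit()] model.
#' @return An object of class `concentration_map`: list with `values`
#'   (H x W matrix, NA outside the ROI) and `roi` ([cube_mask]).
#' @export
predict_map <- function(cube, roi, model) {
  d <- dim(cube$data)
  if (d[3] != length(model$autoscale$mean)) {
    stop("shape error: cube band count does not match model")
  }
  m <- mask_data(roi, d[1:2])
  if (!any(m)) stop("empty roi")
  px <- cube_to_matrix(cube, m)
  pred <- predict(model, px)
  vals <- matrix(NA_real_, d[1], d[2])
  vals[m] <- pred
  structure(list(values = vals, roi = cube_mask(m, "roi")),
            class = "concentration_map")
}

#' @export
print.concentration_map <- function(x, ...) {
  v <- x$values[x$roi$data]
  cat(sprintf("<concentration_map> %d x %d, %d ROI pixels, mean %.3f ug/g\n",
              nrow(x$values), ncol(x$values), length(v), mean(v)))
  invisible(x)
}

#' Render a concentration map as a colour-coded image
#'
#' Maps concentrations over `[range[1], range[2]]` onto a blue-to-red
#' ramp (low = blue, high = red; values beyond the range saturate at the
#' endpoints). Pixels outside the ROI are rendered neutral grey with zero
#' alpha.
#'
#' @param map a [predict_map()] result.
#' @param range display range in ug/g; default spans the reference
#'   concentration range, `c(0, 4.5)`.
#' @return An H x W x 4 numeric RGBA array in \[0, 1\], suitable for
#'   [png::writePNG()]; the colour ramp and range are attached as
#'   attributes.
#' @export
render_map <- function(map, range = c(0, 4.5)) {
  if (range[2] <= range[1]) stop("domain error: inverted display range")
  v <- map$values
  u <- (v - range[1]) / (range[2] - range[1])
  u <- pmin(pmax(u, 0), 1)
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  d <- dim(v)
  out <- array(0.5, dim = c(d[1], d[2], 4))
  out[, , 4] <- 0
  inside <- which(!is.na(u))
  if (length(inside)) {
    cols <- ramp(u[inside]) / 255
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[inside] <- cols[, ch]
      out[, , ch] <- plane
    }
    alpha <- out[, , 4]
    alpha[inside] <- 1
    out[, , 4] <- alpha
  }
  attr(out, "range") <- range
  attr(out, "ramp") <- c("blue", "cyan", "yellow", "red")
  out
}

#' Write a concentration map to disk
#'
#' Writes a two-page 32-bit float TIFF — page 1 the map values divided by
#' a stored scale factor (0 outside the ROI), page 2 the ROI mask — with
#' a `<stem>.map.json` sidecar holding the scale and units, and,
#' optionally, a rendered RGBA PNG next to it. [read_map()] restores the
#' map with NA outside the ROI.
#'
#' @param map a [predict_map()] result.
#' @param path output TIFF path.
#' @param png_path optional PNG path for the rendered map.
#' @param range display range for the PNG.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, png_path = NULL, range = c(0, 4.5)) {
  v <- map$values
  v[is.na(v)] <- 0
  offset <- min(0, min(v))
  scale <- max(1, max(v - offset))
  pages <- list((v - offset) / scale, map$roi$data * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".map.json")
  jsonlite::write_json(list(scale = scale, offset = offset, units = "ug/g"),
                       side, auto_unbox = TRUE, digits = NA)
  if (!is.null(png_path)) {
    png::writePNG(render_map(map, range), png_path)
  }
  invisible(path)
}

#' Read a concentration map written by [write_map()]
#'
#' @param path TIFF path.
#' @return A `concentration_map` (values NA outside the ROI).
#' @export
read_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L) stop("shape error: expected a 2-page map TIFF")
  side <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".map.json")
  if (!file.exists(side)) stop("metadata error: missing map sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  roi <- pages[[2]] > 0.5
  offset <- if (is.null(meta$offset)) 0 else as.numeric(meta$offset)
  vals <- pages[[1]] * as.numeric(meta$scale) + offset
  vals[!roi] <- NA_real_
  structure(list(values = vals, roi = cube_mask(roi, "roi")),
            class = "concentration_map")
}
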