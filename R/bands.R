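#' Band set for a multispectral instrument
#'
#' A band set records the centre wavelengths (and optional labels) of the
#' narrow-band light sources of a multispectral imaging device. Wavelengths
#' must be strictly increasing and lie within the instrument's feasible range
#' of 350--1100 nm.
#'
#' @param wavelengths_nm numeric vector of band-centre wavelengths in nm,
#'   strictly increasing.
#' @param names optional character vector of band labels.
#' @return An object of class `band_set`.
#' @seealso [videometer_bands()] for the default 19-band instrument layout.
#' @export
band_set <- function(wavelengths_nm, names = NULL) {
  wl <- as.numeric(wavelengths_nm)
  if (length(wl) < 1L || anyNA(wl)) {
    stop("wavelengths_nm must be a non-empty numeric vector without NA")
  }
  if (any(diff(wl) <= 0)) {
    stop("wavelengths_nm must be strictly increasing")
  }
  if (any(wl < 350 | wl > 1100)) {
    stop("wavelengths_nm must lie in [350, 1100] nm")
  }
  if (!is.null(names) && length(names) != length(wl)) {
    stop("names must have one entry per wavelength")
  }
  structure(list(wavelengths_nm = wl, names = names), class = "band_set")
}

#' Default VideometerLab band set
#'
#' The 19 band-centre wavelengths of the VideometerLab multispectral imaging
#' system, covering the visible range and the first part of the near
#' infrared (395--970 nm).
#'
#' @return A `band_set` with 19 bands.
#' @export
videometer_bands <- function() {
  band_set(c(395, 435, 450, 470, 505, 525, 570, 590, 630, 645,
             660, 700, 850, 870, 890, 910, 940, 950, 970))
}

#' @export
print.band_set <- function(x, ...) {
  cat("<band_set> ", length(x$wavelengths_nm), " bands: ",
      paste(x$wavelengths_nm, collapse = ", "), " nm\n", sep = "")
  invisible(x)
}

#' @export
length.band_set <- function(x) length(x$wavelengths_nm)

#' Absorbance spectrum
#'
#' Container for an absorbance spectrum A(lambda), e.g. as recorded by a
#' scanning absorption spectrometer. Absorbance is dimensionless (decadic)
#' and must be non-negative.
#'
#' @param wavelengths_nm numeric vector of wavelengths (nm).
#' @param absorbance numeric vector of absorbance values, same length,
#'   all `>= 0`.
#' @return An object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelengths_nm, absorbance) {
  wl <- as.numeric(wavelengths_nm)
  a <- as.numeric(absorbance)
  if (length(wl) != length(a)) {
    stop("wavelengths_nm and absorbance must have the same length")
  }
  if (anyNA(a) || any(a < 0)) {
    stop("absorbance must be non-negative")
  }
  structure(list(wavelengths_nm = wl, absorbance = a),
            class = "absorbance_spectrum")
}

#' Convert absorbance to reflectance
#'
#' Applies the standard spectrophotometric relation R = 10^(-A)
#' (equivalently A = log10(1/R)) elementwise. Resulting reflectances lie
#' in (0, 1].
#'
#' @param a an `absorbance_spectrum` or a non-negative numeric vector of
#'   absorbance values.
#' @return A numeric vector of reflectance fractions; if `a` is an
#'   `absorbance_spectrum` the result carries the wavelengths as names.
#' @export
absorbance_to_reflectance <- function(a) {
  if (inherits(a, "absorbance_spectrum")) {
    r <- 10^(-a$absorbance)
    names(r) <- a$wavelengths_nm
    return(r)
  }
  a <- as.numeric(a)
  if (anyNA(a) || any(a < 0)) stop("absorbance must be non-negative")
  10^(-a)
}

#' Convert reflectance to absorbance
#'
#' Inverse of [absorbance_to_reflectance()]: A = -log10(R) = log10(1/R).
#'
#' @param r numeric vector of reflectance fractions in (0, 1].
#' @return Numeric vector of absorbance values.
#' @export
reflectance_to_absorbance <- function(r) {
  r <- as.numeric(r)
  if (anyNA(r) || any(r <= 0)) stop("reflectance must be positive")
  -log10(r)
}
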