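#' Construct a spectrum object
#'
#' A spectrum pairs a strictly increasing wavenumber axis (cm^-1) with an
#' intensity vector of the same length.
#'
#' @param wavenumber numeric, strictly increasing, cm^-1.
#' @param intensity numeric, same length as `wavenumber`.
#' @return An object of class `sors_spectrum`.
#' @export
sors_spectrum <- function(wavenumber, intensity) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) == 0L) stop("empty wavenumber axis")
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity lengths differ")
  }
  if (any(diff(wavenumber) <= 0)) stop("wavenumber axis must be strictly increasing")
  structure(list(wavenumber = wavenumber, intensity = intensity),
            class = "sors_spectrum")
}

#' @export
print.sors_spectrum <- function(x, ...) {
  cat(sprintf("<sors_spectrum> %d channels, %.1f-%.1f cm^-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' @export
length.sors_spectrum <- function(x) length(x$intensity)

# Accept either a bare numeric vector or a sors_spectrum.
spectrum_intensity <- function(x) {
  if (inherits(x, "sors_spectrum")) x$intensity else as.numeric(x)
}

#' Synthesize a reference spectrum from Gaussian bands
#'
#' Builds a synthetic pure-material Raman signature as a sum of Gaussian
#' bands on a wavenumber axis. Stands in for a measured pure-material
#' spectrum when simulating bilayer samples.
#'
#' @param peaks a list of length-3 numeric vectors `(center cm^-1,
#'   fwhm cm^-1, amplitude)`, or a 3-column matrix with those columns. An
#'   empty list yields an all-zero spectrum.
#' @param axis strictly increasing wavenumber grid, cm^-1.
#' @return A [sors_spectrum()] whose intensity is the non-negative band sum.
#' @examples
#' ax <- seq(400, 2100, length.out = 904)
#' s <- make_reference_spectrum(list(c(1004, 10, 1)), ax)
#' ax[which.max(s$intensity)]
#' @export
make_reference_spectrum <- function(peaks, axis) {
  axis <- as.numeric(axis)
  if (length(axis) == 0L) stop("empty wavenumber axis")
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  if (is.matrix(peaks)) peaks <- split(peaks, row(peaks))
  intensity <- rep(0, length(axis))
  for (p in peaks) {
    p <- as.numeric(p)
    if (length(p) != 3L) stop("each peak must be (center, fwhm, amplitude)")
    center <- p[1]; fwhm <- p[2]; amp <- p[3]
    if (fwhm <= 0) stop("peak fwhm must be > 0")
    if (center < min(axis) || center > max(axis)) {
      warning(sprintf("peak center %.1f cm^-1 outside axis; only its tail contributes",
                      center))
    }
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    intensity <- intensity + amp * exp(-(axis - center)^2 / (2 * sigma^2))
  }
  sors_spectrum(axis, intensity)
}

#' Bundle two role-assigned reference spectra
#'
#' @param top,bottom [sors_spectrum()] pure signatures of the top and bottom
#'   layer materials, on identical axes.
#' @param names_ optional character(2) material names (top, bottom).
#' @return An object of class `reference_library` with entries keyed by
#'   material name and `roles` naming which entry is top and bottom.
#' @export
reference_library <- function(top, bottom, names_ = c("top", "bottom")) {
  stopifnot(inherits(top, "sors_spectrum"), inherits(bottom, "sors_spectrum"))
  if (!isTRUE(all.equal(top$wavenumber, bottom$wavenumber))) {
    stop("reference spectra must share one wavenumber axis")
  }
  entries <- list(top, bottom)
  names(entries) <- names_
  structure(list(entries = entries,
                 roles = c(top = names_[1], bottom = names_[2]),
                 wavenumber = top$wavenumber),
            class = "reference_library")
}

ref_top <- function(refs) refs$entries[[refs$roles[["top"]]]]
ref_bottom <- function(refs) refs$entries[[refs$roles[["bottom"]]]]

#' Built-in synthetic bilayer signatures
#'
#' Two synthetic Raman signatures with distinct, partially overlapping band
#' sets, loosely patterned on a silicone elastomer (top role) and a
#' polyamide (bottom role). Band positions follow common instrument
#' convention for those materials; amplitudes are scaled so the two raw
#' signatures have equal population standard deviation, which puts the
#' equal-contribution point of a mixture at mixing fraction 1/2.
#'
#' Band widths are scaled up when the axis is sampled more coarsely than
#' the instrument-scale ~1.9 cm^-1 per channel, so the signatures stay
#' resolved by several channels at any spectral sampling.
#'
#' @param axis wavenumber grid, cm^-1.
#' @param fwhm_scale multiplier on the band widths; default `NULL`
#'   computes `max(1, spacing / 1.9)` from the axis.
#' @return A [reference_library()].
#' @export
default_reference_library <- function(axis, fwhm_scale = NULL) {
  if (is.null(fwhm_scale)) {
    fwhm_scale <- max(1, mean(diff(axis)) / 1.9)
  }
  pdms_like <- list(
    c(488, 12, 0.55), c(618, 10, 0.25), c(710, 12, 0.90),
    c(862, 14, 0.45), c(1262, 12, 0.60), c(1410, 16, 0.30),
    c(1450, 30, 0.15)
  )
  nylon_like <- list(
    c(930, 12, 0.35), c(1080, 14, 0.50), c(1128, 12, 0.45),
    c(1296, 12, 0.40), c(1440, 18, 0.90), c(1635, 14, 0.70)
  )
  widen <- function(peaks) lapply(peaks, function(p) c(p[1], p[2] * fwhm_scale, p[3]))
  top <- make_reference_spectrum(widen(pdms_like), axis)
  bottom <- make_reference_spectrum(widen(nylon_like), axis)
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  bottom$intensity <- bottom$intensity * sd_pop(top$intensity) / sd_pop(bottom$intensity)
  reference_library(top, bottom, names_ = c("silicone", "polyamide"))
}
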