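#' Working wavelength grid
#'
#' All spectra are resampled onto a common 1-nm integer grid spanning
#' 300--900 nm, which covers the excitation and emission ranges of visible
#' fluorophores. Every downstream computation (excitation lookup, bandpass
#' integration) operates on this grid.
#'
#' @return Integer vector of wavelengths in nanometres.
#' @export
working_grid <- function() 300:900

.EPS <- 1e-12

#' Create a spectrum
#'
#' A spectrum is a table of relative intensity versus wavelength. Intensities
#' are dimensionless and non-negative; wavelengths must be strictly ascending.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly ascending.
#' @param intensities Numeric vector of relative intensities, all >= 0.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, intensities) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length")
  if (length(wavelengths) == 0L) stop("empty spectrum")
  if (any(!is.finite(wavelengths)) || any(!is.finite(intensities)))
    stop("non-finite values in spectrum")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly ascending")
  if (any(intensities < 0)) stop("negative intensities in spectrum")
  structure(list(wavelengths = wavelengths, intensities = intensities),
            class = "spectrum")
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation between the known sample points; intensity is zero
#' outside the support of the input. A degenerate single-point spectrum is
#' treated as a delta on the nearest grid point.
#'
#' @param s A `spectrum`.
#' @param grid Target wavelength grid (defaults to [working_grid()]).
#' @return A `spectrum` on `grid`.
#' @export
resample_spectrum <- function(s, grid = working_grid()) {
  stopifnot(inherits(s, "spectrum"))
  if (length(s$wavelengths) == 1L) {
    y <- numeric(length(grid))
    y[which.min(abs(grid - s$wavelengths))] <- s$intensities
    return(spectrum(grid, y))
  }
  y <- stats::approx(s$wavelengths, s$intensities, xout = grid,
                     method = "linear", rule = 1)$y
  y[is.na(y)] <- 0
  spectrum(grid, y)
}

#' Peak-normalize a spectrum
#'
#' Divides all intensities by the maximum so the peak equals exactly 1.
#' An all-zero spectrum is rejected.
#'
#' @param s A `spectrum` with at least one positive intensity.
#' @return A `spectrum` with maximum intensity 1.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  m <- max(s$intensities)
  if (m <= .EPS) stop("cannot normalize an all-zero spectrum")
  spectrum(s$wavelengths, s$intensities / m)
}

#' @export
print.spectrum <- function(x, ...) {
  sup <- range(x$wavelengths[x$intensities > 0])
  cat(sprintf("<spectrum> %d points, support %g-%g nm, peak %g\n",
              length(x$wavelengths), sup[1], sup[2], max(x$intensities)))
  invisible(x)
}

#' Create a fluorophore
#'
#' A fluorophore couples an excitation spectrum (relative excitation
#' efficiency versus laser wavelength) with an emission spectrum (relative
#' emitted intensity versus wavelength) and an optional molecular brightness
#' (extinction coefficient x quantum yield, normalized to the brightest
#' member of its library). Both spectra are resampled to the working grid
#' and peak-normalized at construction, so excitation values are efficiencies
#' in [0, 1].
#'
#' @param name Unique identifier within a library.
#' @param excitation,emission `spectrum` objects.
#' @param brightness Optional scalar in (0, 1] after library normalization.
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name, excitation, emission, brightness = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ex <- tryCatch(normalize_spectrum(resample_spectrum(excitation)),
                 error = function(e) stop("fluorophore '", name,
                                          "': excitation spectrum: ",
                                          conditionMessage(e), call. = FALSE))
  em <- tryCatch(normalize_spectrum(resample_spectrum(emission)),
                 error = function(e) stop("fluorophore '", name,
                                          "': emission spectrum: ",
                                          conditionMessage(e), call. = FALSE))
  if (!is.null(brightness)) {
    stopifnot(is.numeric(brightness), length(brightness) == 1L,
              is.finite(brightness), brightness > 0)
  }
  structure(list(name = name, excitation = ex, emission = em,
                 brightness = brightness),
            class = "fluorophore")
}

#' @export
print.fluorophore <- function(x, ...) {
  g <- working_grid()
  cat(sprintf("<fluorophore> %s  ex peak %d nm, em peak %d nm%s\n", x$name,
              g[which.max(x$excitation$intensities)],
              g[which.max(x$emission$intensities)],
              if (is.null(x$brightness)) ""
              else sprintf(", brightness %.3f", x$brightness)))
  invisible(x)
}
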