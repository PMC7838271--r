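# Synthetic fluorophore libraries, instruments, and simulated measurements.
#
# Gaussian excitation/emission curves with a positive Stokes shift emulate
# the shape of published fluorescent-protein spectra well enough to exercise
# every computation in the package without any external data; real spectra
# load through the same readers when available.

#' Specification for a synthetic fluorophore library
#'
#' @param n_fluorophores Library size (default 8, the size of the library
#'   used in the exhaustive-vs-annealing benchmark instance).
#' @param ex_peak_range Excitation peak range in nm.
#' @param stokes_range Stokes shift range in nm (emission peak = excitation
#'   peak + shift; strictly positive).
#' @param sigma_range Gaussian peak width (sigma) range in nm.
#' @param brightness_range Range the per-fluorophore brightness is drawn
#'   from (rescaled so the library maximum is 1).
#' @param noise_sigma Gaussian noise sigma for [simulate_measurements()].
#' @param seed Seed making the library deterministic.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_fluorophores = 8L,
                           ex_peak_range = c(400, 650),
                           stokes_range = c(18, 45),
                           sigma_range = c(12, 28),
                           brightness_range = c(0.3, 1),
                           noise_sigma = 0.02,
                           seed = 1L) {
  g <- range(working_grid())
  stopifnot(n_fluorophores >= 1L,
            ex_peak_range[1] >= g[1], ex_peak_range[2] <= g[2],
            stokes_range[1] > 0,
            ex_peak_range[2] + stokes_range[2] <= g[2],
            sigma_range[1] > 0,
            brightness_range[1] > 0, brightness_range[2] <= 1,
            noise_sigma >= 0)
  structure(list(n_fluorophores = as.integer(n_fluorophores),
                 ex_peak_range = ex_peak_range,
                 stokes_range = stokes_range, sigma_range = sigma_range,
                 brightness_range = brightness_range,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one Gaussian-spectrum fluorophore
#'
#' Excitation and emission are Gaussian curves on the working grid,
#' peak-normalized; the emission peak is strictly red-shifted from the
#' excitation peak.
#'
#' @param name Fluorophore name.
#' @param ex_peak,em_peak Peak wavelengths in nm, `em_peak > ex_peak`.
#' @param ex_sigma,em_sigma Gaussian widths in nm.
#' @param brightness Optional brightness scalar.
#' @return A [fluorophore()].
#' @export
generate_fluorophore <- function(name, ex_peak, em_peak,
                                 ex_sigma = 18, em_sigma = ex_sigma,
                                 brightness = NULL) {
  stopifnot(em_peak > ex_peak)
  g <- working_grid()
  gauss <- function(mu, sigma) exp(-0.5 * ((g - mu) / sigma)^2)
  fluorophore(name,
              spectrum(g, gauss(ex_peak, ex_sigma)),
              spectrum(g, gauss(em_peak, em_sigma)),
              brightness = brightness)
}

#' Generate a synthetic fluorophore library
#'
#' Draws excitation peaks, Stokes shifts, widths, and brightnesses uniformly
#' within the spec's ranges; names are `F001`, `F002`, ... Deterministic
#' given the spec's seed. Brightness values are rescaled so the brightest
#' fluorophore has brightness 1.
#'
#' @param spec A [synthetic_spec()].
#' @return A `fluorophore_library`.
#' @export
generate_library <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    k <- spec$n_fluorophores
    ex <- sort(stats::runif(k, spec$ex_peak_range[1], spec$ex_peak_range[2]))
    shift <- stats::runif(k, spec$stokes_range[1], spec$stokes_range[2])
    ex_sigma <- stats::runif(k, spec$sigma_range[1], spec$sigma_range[2])
    em_sigma <- stats::runif(k, spec$sigma_range[1], spec$sigma_range[2])
    bright <- stats::runif(k, spec$brightness_range[1],
                           spec$brightness_range[2])
    bright <- bright / max(bright)
    fluorophore_library(lapply(seq_len(k), function(i)
      generate_fluorophore(sprintf("F%03d", i), ex[i], ex[i] + shift[i],
                           ex_sigma[i], em_sigma[i], brightness = bright[i])))
  })
}

#' Generate a synthetic cytometer layout
#'
#' For each laser, a run of contiguous non-overlapping bandpass windows
#' red-shifted of the laser line. The defaults emulate a 5-laser,
#' 19-detector configuration of the kind found on large spectral cytometers.
#'
#' @param laser_wavelengths Laser lines in nm.
#' @param detectors_per_laser Number of bandpass windows per laser (recycled
#'   to the number of lasers).
#' @param bandpass_width Window width in nm.
#' @param gap Gap between the laser line and the first window, and between
#'   consecutive windows, in nm.
#' @param name Instrument name.
#' @param autofluorescence Optional named per-detector baseline.
#' @return An [instrument()].
#' @export
generate_instrument <- function(laser_wavelengths = c(355, 405, 488, 561, 638),
                                detectors_per_laser = c(3, 5, 4, 4, 3),
                                bandpass_width = 30, gap = 10,
                                name = "synthetic-cytometer",
                                autofluorescence = NULL) {
  detectors_per_laser <- rep_len(detectors_per_laser,
                                 length(laser_wavelengths))
  g <- range(working_grid())
  lasers <- lapply(seq_along(laser_wavelengths), function(i)
    laser(sprintf("L%d", laser_wavelengths[i]), laser_wavelengths[i]))
  dets <- list()
  for (i in seq_along(lasers)) {
    lo <- laser_wavelengths[i] + gap
    for (k in seq_len(detectors_per_laser[i])) {
      hi <- lo + bandpass_width
      if (hi > g[2]) stop("bandpass window exceeds working grid")
      dets[[length(dets) + 1L]] <-
        detector(sprintf("%s-D%d", lasers[[i]]$name, k), lasers[[i]], lo, hi)
      lo <- hi + gap
    }
  }
  instrument(name, lasers, dets, autofluorescence = autofluorescence)
}

#' Simulate a measured normalized intensity matrix
#'
#' Perturbs the panel's per-detector normalized predictions with additive
#' Gaussian noise truncated at zero, then re-normalizes each detector to 1.
#' With `noise_sigma = 0` this returns the predictions exactly.
#'
#' @param pan A valid [panel()].
#' @param S A `signal_matrix`.
#' @param noise_sigma Noise standard deviation on normalized values.
#' @param seed Seed making the draw reproducible.
#' @return A `panel_matrix` with `source = "measured"`.
#' @export
simulate_measurements <- function(pan, S, noise_sigma = 0, seed = 1L) {
  M <- predicted_panel_matrix(pan, S)
  if (noise_sigma > 0) {
    M <- .with_seed(seed, {
      noisy <- pmax(unclass(M) + stats::rnorm(length(M), 0, noise_sigma), 0)
      noisy / apply(noisy, 1L, max)
    })
  }
  structure(unclass(M), source = "measured",
            class = c("panel_matrix", "matrix"))
}
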