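# Instrument model: lasers and bandpass-filtered detectors.

#' Create a laser
#' @param name Identifier.
#' @param wavelength Laser line in nm (must lie on the working grid).
#' @return A `laser`.
#' @export
laser <- function(name, wavelength) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  wavelength <- as.integer(wavelength)
  if (!(wavelength %in% working_grid()))
    stop("laser '", name, "': wavelength ", wavelength,
         " nm outside working grid")
  structure(list(name = name, wavelength = wavelength), class = "laser")
}

#' Create a detector
#'
#' A detector is owned by one laser and sees emitted light through a bandpass
#' window `[bandpass_lo, bandpass_hi]` nm (both endpoints inclusive).
#'
#' @param name Identifier.
#' @param laser The owning [laser()] object.
#' @param bandpass_lo,bandpass_hi Bandpass window in nm, `lo < hi`.
#' @return A `detector` (with the laser reference resolved).
#' @export
detector <- function(name, laser, bandpass_lo, bandpass_hi) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            inherits(laser, "laser"))
  bandpass_lo <- as.integer(bandpass_lo)
  bandpass_hi <- as.integer(bandpass_hi)
  if (bandpass_lo >= bandpass_hi)
    stop("detector '", name, "': bandpass_lo (", bandpass_lo,
         ") must be < bandpass_hi (", bandpass_hi, ")")
  g <- working_grid()
  if (bandpass_lo < min(g) || bandpass_hi > max(g))
    stop("detector '", name, "': bandpass outside working grid")
  structure(list(name = name, laser = laser$name,
                 laser_wavelength = laser$wavelength,
                 bandpass_lo = bandpass_lo, bandpass_hi = bandpass_hi),
            class = "detector")
}

#' Create an instrument
#'
#' @param name Identifier.
#' @param lasers List of [laser()] objects.
#' @param detectors List of [detector()] objects whose laser references all
#'   resolve among `lasers`.
#' @param autofluorescence Optional named numeric vector of per-detector
#'   baseline intensities (>= 0); names must be detector names. Missing
#'   detectors default to 0.
#' @return An `instrument`.
#' @export
instrument <- function(name, lasers, detectors, autofluorescence = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            length(lasers) >= 1L, length(detectors) >= 1L,
            all(vapply(lasers, inherits, logical(1), "laser")),
            all(vapply(detectors, inherits, logical(1), "detector")))
  lnames <- vapply(lasers, `[[`, character(1), "name")
  if (anyDuplicated(lnames)) stop("duplicate laser names")
  dnames <- vapply(detectors, `[[`, character(1), "name")
  if (anyDuplicated(dnames)) stop("duplicate detector names")
  for (d in detectors) {
    if (!(d$laser %in% lnames))
      stop("detector '", d$name, "' references unknown laser '", d$laser, "'")
  }
  names(lasers) <- lnames
  names(detectors) <- dnames
  af <- stats::setNames(numeric(length(dnames)), dnames)
  if (!is.null(autofluorescence)) {
    bad <- setdiff(names(autofluorescence), dnames)
    if (length(bad))
      stop("autofluorescence for unknown detector(s): ",
           paste(bad, collapse = ", "))
    if (any(autofluorescence < 0)) stop("autofluorescence must be >= 0")
    af[names(autofluorescence)] <- autofluorescence
  }
  structure(list(name = name, lasers = lasers, detectors = detectors,
                 autofluorescence = af),
            class = "instrument")
}

#' Read an instrument configuration
#'
#' Accepts JSON or YAML with the schema
#' `{name, lasers:[{name, wavelength_nm}],
#'   detectors:[{name, laser, bandpass_lo_nm, bandpass_hi_nm}],
#'   autofluorescence:{detector: value}}` (autofluorescence optional).
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @return An [instrument()].
#' @export
read_instrument_config <- function(path) {
  if (!file.exists(path)) stop("instrument config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (fld in c("name", "lasers", "detectors")) {
    if (is.null(cfg[[fld]])) stop("'", path, "': missing field '", fld, "'")
  }
  lasers <- lapply(cfg$lasers, function(l) laser(l$name, l$wavelength_nm))
  names(lasers) <- vapply(lasers, `[[`, character(1), "name")
  dets <- lapply(cfg$detectors, function(d) {
    if (is.null(lasers[[d$laser]]))
      stop("detector '", d$name, "' references unknown laser '", d$laser, "'")
    detector(d$name, lasers[[d$laser]], d$bandpass_lo_nm, d$bandpass_hi_nm)
  })
  af <- NULL
  if (!is.null(cfg$autofluorescence)) af <- unlist(cfg$autofluorescence)
  instrument(cfg$name, lasers, dets, autofluorescence = af)
}

#' Write an instrument configuration as JSON
#' @param inst An [instrument()].
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_instrument_config <- function(inst, path) {
  cfg <- list(
    name = inst$name,
    lasers = unname(lapply(inst$lasers, function(l)
      list(name = l$name, wavelength_nm = l$wavelength))),
    detectors = unname(lapply(inst$detectors, function(d)
      list(name = d$name, laser = d$laser,
           bandpass_lo_nm = d$bandpass_lo, bandpass_hi_nm = d$bandpass_hi)))
  )
  if (any(inst$autofluorescence > 0))
    cfg$autofluorescence <- as.list(
      inst$autofluorescence[inst$autofluorescence > 0])
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf("<instrument> %s: %d lasers (%s nm), %d detectors\n", x$name,
              length(x$lasers),
              paste(vapply(x$lasers, `[[`, integer(1), "wavelength"),
                    collapse = "/"),
              length(x$detectors)))
  invisible(x)
}
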