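# Signal model: predicted detector signal for each fluorophore.
#
# Signal = excitation efficiency at the detector's (monochromatic) laser line
#        x fraction of total emission falling inside the bandpass
#        x (optionally) the fluorophore's normalized brightness.
# Integration is a discrete sum over the 1-nm working grid with inclusive
# bandpass endpoints.

#' Excitation efficiency of a fluorophore under a laser
#'
#' The fluorophore's peak-normalized excitation intensity evaluated at the
#' laser wavelength. Lasers are treated as monochromatic with uniform power.
#'
#' @param fluor A [fluorophore()].
#' @param las A [laser()], or a detector carrying a resolved
#'   `laser_wavelength`.
#' @return A fraction in \[0, 1\].
#' @export
excitation_efficiency <- function(fluor, las) {
  stopifnot(inherits(fluor, "fluorophore"))
  wl <- if (inherits(las, "laser")) las$wavelength else las$laser_wavelength
  g <- working_grid()
  idx <- match(as.integer(wl), g)
  if (is.na(idx)) stop("laser wavelength ", wl, " nm not on working grid")
  fluor$excitation$intensities[idx]
}

#' Fraction of emitted light captured by a detector's bandpass
#'
#' Sum of emission intensities over grid points inside
#' `[bandpass_lo, bandpass_hi]` (both endpoints inclusive) divided by the sum
#' over the full grid.
#'
#' @param fluor A [fluorophore()].
#' @param det A [detector()].
#' @return A fraction in \[0, 1\].
#' @export
emission_fraction <- function(fluor, det) {
  stopifnot(inherits(fluor, "fluorophore"), inherits(det, "detector"))
  g <- working_grid()
  em <- fluor$emission$intensities
  inside <- g >= det$bandpass_lo & g <= det$bandpass_hi
  sum(em[inside]) / sum(em)
}

#' Predicted signal of a fluorophore in a detector
#'
#' Product of [excitation_efficiency()] at the detector's owning laser and
#' [emission_fraction()] in its bandpass, optionally scaled by the
#' fluorophore's normalized brightness.
#'
#' @param fluor A [fluorophore()].
#' @param det A [detector()] (laser reference resolved).
#' @param use_brightness Scale by brightness? Errors if requested but the
#'   fluorophore carries no brightness.
#' @return A signal in \[0, 1\].
#' @export
predict_signal <- function(fluor, det, use_brightness = FALSE) {
  s <- excitation_efficiency(fluor, det) * emission_fraction(fluor, det)
  if (use_brightness) {
    if (is.null(fluor$brightness))
      stop("brightness requested but absent for fluorophore(s): ", fluor$name)
    s <- s * fluor$brightness
  }
  s
}

#' Build the full fluorophore x detector signal matrix
#'
#' @param lib A `fluorophore_library`.
#' @param inst An [instrument()].
#' @param use_brightness Scale each row by the fluorophore's normalized
#'   brightness. Errors listing any fluorophores lacking brightness.
#' @param use_autofluorescence Record the instrument's per-detector baseline
#'   so panel scoring counts it as bleed-through (never as signal).
#' @return A `signal_matrix`: numeric matrix (fluorophores x detectors) with
#'   attributes `brightness_applied`, `autofluorescence_applied`, and
#'   `autofluorescence` (named per-detector baseline, zeros when disabled).
#' @export
build_signal_matrix <- function(lib, inst, use_brightness = FALSE,
                                use_autofluorescence = FALSE) {
  stopifnot(length(lib) >= 1L, inherits(inst, "instrument"))
  g <- working_grid()
  if (use_brightness) {
    missing <- names(lib)[vapply(lib, function(f) is.null(f$brightness),
                                 logical(1))]
    if (length(missing))
      stop("brightness requested but absent for fluorophore(s): ",
           paste(missing, collapse = ", "))
  }
  # excitation efficiency of every fluorophore at every laser line
  ex <- do.call(rbind, lapply(lib, function(f) f$excitation$intensities))
  em <- do.call(rbind, lapply(lib, function(f) f$emission$intensities))
  em_tot <- rowSums(em)
  S <- matrix(0, nrow = length(lib), ncol = length(inst$detectors),
              dimnames = list(names(lib), names(inst$detectors)))
  for (j in seq_along(inst$detectors)) {
    d <- inst$detectors[[j]]
    inside <- g >= d$bandpass_lo & g <= d$bandpass_hi
    frac <- rowSums(em[, inside, drop = FALSE]) / em_tot
    eff <- ex[, match(d$laser_wavelength, g)]
    S[, j] <- eff * frac
  }
  if (use_brightness) {
    S <- S * vapply(lib, `[[`, numeric(1), "brightness")
  }
  af <- stats::setNames(numeric(ncol(S)), colnames(S))
  if (use_autofluorescence) af[] <- inst$autofluorescence[colnames(S)]
  structure(S,
            brightness_applied = use_brightness,
            autofluorescence_applied = use_autofluorescence,
            autofluorescence = af,
            class = c("signal_matrix", class(S)))
}

.matrix_autofl <- function(S) {
  af <- attr(S, "autofluorescence")
  if (is.null(af)) af <- stats::setNames(numeric(ncol(S)), colnames(S))
  af
}

#' Normalize values to 1 within each detector
#'
#' Within each detector (column), every value is divided by that detector's
#' maximum, so the per-detector maximum is exactly 1. This is the
#' normalization applied to both predictions and measurements before the two
#' are compared.
#'
#' @param values Numeric matrix, fluorophores x detectors.
#' @return Matrix of the same shape with per-column maximum 1.
#' @export
normalize_per_detector <- function(values) {
  values <- as.matrix(values)
  mx <- apply(values, 2, max)
  zero <- mx <= .EPS
  if (any(zero))
    stop("detector(s) with all-zero values: ",
         paste(colnames(values)[zero] %||% which(zero), collapse = ", "))
  sweep(values, 2, mx, "/")
}

#' Export a signal matrix as CSV
#' @param S A `signal_matrix` (or plain matrix), fluorophore rows x detector
#'   columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(S, path) {
  df <- data.frame(fluorophore = rownames(S),
                   as.data.frame(unclass(S)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
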