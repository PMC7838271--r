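# Comparing predictions against measured normalized intensities.
#
# Both predictions and measurements are normalized to 1 per detector (by the
# highest value in that detector) before comparison. Two agreement metrics:
# argmax match (the fluorophore at 1 is the same in both) and entrywise
# tolerance (|prediction - measurement| <= tol for every entry).

.TIE_EPS <- 1e-9

#' Per-detector normalized prediction matrix for a panel
#'
#' Restricts the signal matrix to the panel's fluorophores and detectors and
#' normalizes within each detector so the largest value is 1.
#'
#' @param pan A [panel()].
#' @param S A `signal_matrix`.
#' @return A `panel_matrix`: numeric matrix, detectors (rows) x panel
#'   fluorophores (columns), each row max 1; attribute `source =
#'   "predicted"`.
#' @export
predicted_panel_matrix <- function(pan, S) {
  ix <- .panel_indices(pan, S)
  M <- t(unclass(S)[ix$fl, ix$dt, drop = FALSE])
  mx <- apply(M, 1L, max)
  zero <- mx <= .EPS
  if (any(zero))
    stop("detector(s) with all-zero predictions: ",
         paste(rownames(M)[zero], collapse = ", "))
  structure(M / mx, source = "predicted", class = c("panel_matrix", "matrix"))
}

.check_aligned <- function(predicted, measured) {
  if (!identical(dim(predicted), dim(measured)) ||
      !identical(dimnames(predicted), dimnames(measured)))
    stop("predicted and measured matrices are not aligned ",
         "(detector/fluorophore sets differ)")
}

.argmax_fluor <- function(M, what) {
  vapply(rownames(M), function(d) {
    v <- M[d, ]
    ones <- which(v >= max(v) - .TIE_EPS)
    if (length(ones) != 1L)
      stop("detector '", d, "' has tied maxima in the ", what,
           " matrix (", paste(colnames(M)[ones], collapse = ", "),
           "); resolve manually")
    colnames(M)[ones]
  }, character(1))
}

#' Do predicted and measured argmax fluorophores match?
#'
#' For every detector, the unique fluorophore with normalized value 1 must
#' be the same in the predicted and the measured matrix. A detector with two
#' entries at the maximum is an error (reported for manual resolution), not
#' a silent pass.
#'
#' @param predicted,measured Aligned `panel_matrix` objects (detectors x
#'   fluorophores, per-detector max 1).
#' @return Logical.
#' @export
signals_match <- function(predicted, measured) {
  .check_aligned(predicted, measured)
  all(.argmax_fluor(predicted, "predicted") ==
      .argmax_fluor(measured, "measured"))
}

#' Are all prediction-measurement differences within a tolerance?
#'
#' True when `|predicted - measured| <= tol` (inclusive) for every
#' (detector, fluorophore) entry, signal and bleed-through entries alike.
#'
#' @inheritParams signals_match
#' @param tol Positive tolerance on normalized values (e.g. 0.05, 0.10,
#'   0.20).
#' @return Logical.
#' @export
within_tolerance <- function(predicted, measured, tol) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0)
  .check_aligned(predicted, measured)
  all(abs(predicted - measured) <= tol + .EPS)
}

#' Agreement summary over a set of panels
#'
#' For each tolerance, the percentage of panels whose predictions and
#' measurements agree entrywise within it; plus the percentage whose argmax
#' fluorophores match on every detector.
#'
#' @param predicted_set,measured_set Lists of aligned `panel_matrix`
#'   objects, one pair per panel.
#' @param tols Tolerances to tabulate.
#' @return A data.frame with columns `metric` and `percent`.
#' @export
agreement_summary <- function(predicted_set, measured_set,
                              tols = c(0.05, 0.10, 0.20)) {
  stopifnot(length(predicted_set) == length(measured_set))
  if (!length(predicted_set)) stop("empty panel collection")
  k <- length(predicted_set)
  match_pct <- 100 * mean(vapply(seq_len(k), function(i)
    signals_match(predicted_set[[i]], measured_set[[i]]), logical(1)))
  tol_pct <- vapply(tols, function(tol)
    100 * mean(vapply(seq_len(k), function(i)
      within_tolerance(predicted_set[[i]], measured_set[[i]], tol),
      logical(1))), numeric(1))
  data.frame(metric = c("signals_match", sprintf("within_%.2f", tols)),
             percent = c(match_pct, tol_pct))
}

#' Per-detector signal and bleed-through report
#'
#' For each detector of a panel: its signal, the total bleed-through from
#' the other panel fluorophores (plus autofluorescence when enabled), the
#' bleed/signal ratio, and whether the detector is within eta. The count of
#' within-eta detectors is stored as attribute `n_within_eta`.
#'
#' @param pan A valid [panel()].
#' @param S A `signal_matrix`.
#' @param eta Bleed-through threshold.
#' @return A data.frame with one row per detector.
#' @export
bleedthrough_report <- function(pan, S, eta = 0.1) {
  ix <- .panel_indices(pan, S)
  sc <- .score_idx(S, .matrix_autofl(S), ix$fl, ix$dt, eta)
  df <- data.frame(detector = pan$detectors, fluorophore = pan$fluorophores,
                   signal = sc$sig, bleedthrough = sc$bleed,
                   bleed_ratio = ifelse(sc$sig > .EPS, sc$bleed / sc$sig,
                                        Inf),
                   within_eta = sc$bleed <= eta * sc$sig)
  rownames(df) <- NULL
  attr(df, "n_within_eta") <- sum(df$within_eta)
  attr(df, "eta") <- eta
  df
}

#' Read a measured normalized intensity matrix
#'
#' Long-format CSV with columns `detector,fluorophore,value`, one row per
#' (detector, fluorophore) pair, values already normalized per detector.
#'
#' @param path CSV path.
#' @return A `panel_matrix` with `source = "measured"`.
#' @export
read_measured_matrix <- function(path) {
  if (!file.exists(path)) stop("measured matrix not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("detector", "fluorophore", "value")
  if (!all(need %in% names(df)))
    stop("'", path, "': needs columns detector,fluorophore,value")
  dets <- unique(df$detector)
  fls <- unique(df$fluorophore)
  M <- matrix(NA_real_, length(dets), length(fls),
              dimnames = list(dets, fls))
  M[cbind(df$detector, df$fluorophore)] <- df$value
  if (anyNA(M)) stop("'", path, "': incomplete detector x fluorophore grid")
  if (any(M < 0) || any(M > 1 + .TIE_EPS))
    stop("'", path, "': normalized values must lie in [0, 1]")
  structure(M, source = "measured", class = c("panel_matrix", "matrix"))
}

#' Write a normalized intensity matrix
#' @param M A `panel_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measured_matrix <- function(M, path) {
  df <- expand.grid(detector = rownames(M), fluorophore = colnames(M),
                    stringsAsFactors = FALSE)
  df$value <- M[cbind(df$detector, df$fluorophore)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
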