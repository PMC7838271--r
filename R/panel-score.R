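# Panels, validity, the three-tier score, and the comparator.
#
# A panel is ranked by three properties in strict order:
#   1. number of detectors whose total bleed-through is within eta of their
#      signal (more is better);
#   2. geometric mean of the signals (larger is better);
#   3. arithmetic mean of the per-detector total bleed-through (smaller is
#      better).
# Ties on all three make two panels equivalent.

#' Create an n-color panel
#'
#' An assignment of n distinct fluorophores to n distinct detectors; the
#' i-th fluorophore is the one detector i is intended to measure.
#'
#' @param fluorophores Character vector of fluorophore names, pairwise
#'   distinct.
#' @param detectors Character vector of detector names, same length,
#'   pairwise distinct.
#' @return A `panel`.
#' @export
panel <- function(fluorophores, detectors) {
  stopifnot(is.character(fluorophores), is.character(detectors),
            length(fluorophores) == length(detectors),
            length(fluorophores) >= 1L)
  if (anyDuplicated(fluorophores)) stop("duplicate fluorophores in panel")
  if (anyDuplicated(detectors)) stop("duplicate detectors in panel")
  ord <- order(fluorophores)        # canonical assignment order
  fluorophores <- fluorophores[ord]
  detectors <- detectors[ord]
  structure(list(fluorophores = fluorophores, detectors = detectors,
                 n = length(fluorophores)),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel> n=%d\n", x$n))
  for (i in seq_len(x$n))
    cat(sprintf("  %s -> %s\n", x$fluorophores[i], x$detectors[i]))
  invisible(x)
}

.panel_indices <- function(pan, S) {
  fi <- match(pan$fluorophores, rownames(S))
  di <- match(pan$detectors, colnames(S))
  if (anyNA(fi)) stop("panel fluorophore(s) not in signal matrix: ",
                      paste(pan$fluorophores[is.na(fi)], collapse = ", "))
  if (anyNA(di)) stop("panel detector(s) not in signal matrix: ",
                      paste(pan$detectors[is.na(di)], collapse = ", "))
  list(fl = fi, dt = di)
}

#' Signal of the fluorophore a detector is intended to measure
#' @param pan A [panel()].
#' @param S A `signal_matrix`.
#' @param det Detector name (must be assigned in the panel).
#' @return The predicted signal.
#' @export
detector_signal <- function(pan, S, det) {
  i <- match(det, pan$detectors)
  if (is.na(i)) stop("detector '", det, "' is not assigned in the panel")
  S[pan$fluorophores[i], det]
}

#' Total bleed-through in a detector from the rest of the panel
#'
#' Sum of the signals of all other panel fluorophores in this detector, plus
#' the detector's autofluorescence baseline when the matrix carries one
#' (autofluorescence always counts as bleed-through, never as signal).
#'
#' @inheritParams detector_signal
#' @return The total bleed-through.
#' @export
detector_bleedthrough <- function(pan, S, det) {
  i <- match(det, pan$detectors)
  if (is.na(i)) stop("detector '", det, "' is not assigned in the panel")
  others <- pan$fluorophores[-i]
  sum(S[others, det]) + .matrix_autofl(S)[[det]]
}

#' Is a panel valid?
#'
#' A panel is valid when every assigned detector measures strictly positive
#' signal for its intended fluorophore (values below 1e-12 count as zero).
#'
#' @param pan A [panel()].
#' @param S A `signal_matrix`.
#' @return Logical.
#' @export
is_valid_panel <- function(pan, S) {
  ix <- .panel_indices(pan, S)
  all(S[cbind(ix$fl, ix$dt)] > .EPS)
}

# core scoring on index vectors; used by score_panel, exhaustive search
# and the annealer so all paths agree bit-for-bit.
.score_idx <- function(S, af, fl, dt, eta) {
  n <- length(fl)
  sig <- S[cbind(fl, dt)]
  tot <- .colSums(S[fl, dt, drop = FALSE], n, n)
  bleed <- tot - sig + af[dt]
  w <- sum(bleed <= eta * sig)
  g <- if (any(sig <= .EPS)) 0 else exp(sum(log(sig)) / n)
  list(within_eta_count = w, geomean_signal = g,
       mean_bleedthrough = sum(bleed) / n, sig = sig, bleed = bleed)
}

#' Score a panel
#'
#' Computes the three ranking properties: the number of detectors whose
#' total bleed-through is within `eta` of their signal (inclusive), the
#' geometric mean of the signals (zero if any signal is zero), and the
#' arithmetic mean of the per-detector total bleed-through.
#'
#' @param pan A [panel()].
#' @param S A `signal_matrix`.
#' @param eta Tolerated bleed-through as a fraction of a detector's signal
#'   (default 0.10).
#' @return A `panel_score` with fields `within_eta_count`, `geomean_signal`,
#'   `mean_bleedthrough`, `eta`, `n`, and `valid`.
#' @export
score_panel <- function(pan, S, eta = 0.1) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta >= 0)
  ix <- .panel_indices(pan, S)
  sc <- .score_idx(S, .matrix_autofl(S), ix$fl, ix$dt, eta)
  panel_score(sc$within_eta_count, sc$geomean_signal, sc$mean_bleedthrough,
              eta = eta, n = pan$n, valid = all(sc$sig > .EPS))
}

#' Construct a panel score
#' @param within_eta_count Integer in \[0, n\].
#' @param geomean_signal Geometric mean of signals, >= 0.
#' @param mean_bleedthrough Arithmetic mean of per-detector bleed-through.
#' @param eta The threshold the score was computed with.
#' @param n Panel size.
#' @param valid Was the panel valid?
#' @return A `panel_score`.
#' @export
panel_score <- function(within_eta_count, geomean_signal, mean_bleedthrough,
                        eta = 0.1, n = NA_integer_, valid = NA) {
  stopifnot(is.finite(within_eta_count), is.finite(geomean_signal),
            is.finite(mean_bleedthrough), geomean_signal >= 0)
  structure(list(within_eta_count = as.integer(within_eta_count),
                 geomean_signal = geomean_signal,
                 mean_bleedthrough = mean_bleedthrough,
                 eta = eta, n = as.integer(n), valid = valid),
            class = "panel_score")
}

#' @export
print.panel_score <- function(x, ...) {
  cat(sprintf(
    "<panel_score> within-eta %d/%s  geomean signal %.4f  mean bleed %.4f (eta=%g)\n",
    x$within_eta_count, ifelse(is.na(x$n), "?", x$n),
    x$geomean_signal, x$mean_bleedthrough, x$eta))
  invisible(x)
}

# -1/0/+1 comparison of score triples; +1 means the first is better
.cmp3 <- function(w1, g1, b1, w2, g2, b2) {
  if (w1 != w2) return(if (w1 > w2) 1L else -1L)
  if (g1 != g2) return(if (g1 > g2) 1L else -1L)
  if (b1 != b2) return(if (b1 < b2) 1L else -1L)
  0L
}

#' Compare two panel scores
#'
#' Lexicographic comparison over the three tiers: more within-eta detectors
#' wins; then larger geometric-mean signal; then smaller mean bleed-through;
#' equal on all three means the panels are equivalent.
#'
#' @param a,b `panel_score` objects computed with the same `eta`.
#' @return One of `"A_better"`, `"B_better"`, `"equivalent"`.
#' @export
compare_panels <- function(a, b) {
  stopifnot(inherits(a, "panel_score"), inherits(b, "panel_score"))
  if (a$eta != b$eta)
    stop("scores computed with different eta (", a$eta, " vs ", b$eta, ")")
  r <- .cmp3(a$within_eta_count, a$geomean_signal, a$mean_bleedthrough,
             b$within_eta_count, b$geomean_signal, b$mean_bleedthrough)
  c("B_better", "equivalent", "A_better")[r + 2L]
}
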