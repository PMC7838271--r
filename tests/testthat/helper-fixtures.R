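# Hand-built fixtures with exactly computable signals, and an independent
# comparator-driven merge sort used as the ranking oracle.

# flat ("box") spectrum: 1 on [lo, hi], 0 elsewhere
box_spectrum <- function(lo, hi) {
  g <- working_grid()
  spectrum(g, as.numeric(g >= lo & g <= hi))
}

# two fluorophores with box spectra; signals are ratios of grid-point counts
make_box_library <- function() {
  fluorophore_library(list(
    fluorophore("BoxA", box_spectrum(480, 500), box_spectrum(500, 600)),
    fluorophore("BoxB", box_spectrum(540, 570), box_spectrum(580, 660))
  ))
}

make_box_instrument <- function(autofluorescence = NULL) {
  l488 <- laser("L488", 488)
  l561 <- laser("L561", 561)
  instrument("box-cytometer", list(l488, l561),
             list(detector("D1", l488, 500, 549),
                  detector("D2", l561, 580, 660),
                  detector("D3", l561, 700, 760)),
             autofluorescence = autofluorescence)
}

# build a signal matrix by hand from chosen entries (fluor x detector)
manual_matrix <- function(values, fluors, dets, autofl = NULL) {
  S <- matrix(values, nrow = length(fluors), ncol = length(dets),
              byrow = TRUE, dimnames = list(fluors, dets))
  af <- stats::setNames(numeric(length(dets)), dets)
  if (!is.null(autofl)) af[names(autofl)] <- autofl
  structure(S, brightness_applied = FALSE,
            autofluorescence_applied = !is.null(autofl),
            autofluorescence = af, class = c("signal_matrix", "matrix"))
}

# independent oracle: rank panels by repeated pairwise comparison only
# (merge sort over compare_panels), no numeric sort keys
oracle_sort_scores <- function(scores) {
  merge2 <- function(a, b) {
    out <- vector("list", length(a) + length(b))
    i <- j <- 1L; k <- 0L
    while (i <= length(a) && j <= length(b)) {
      k <- k + 1L
      if (compare_panels(b[[j]]$score, a[[i]]$score) == "A_better") {
        out[[k]] <- b[[j]]; j <- j + 1L
      } else {
        out[[k]] <- a[[i]]; i <- i + 1L
      }
    }
    while (i <= length(a)) { k <- k + 1L; out[[k]] <- a[[i]]; i <- i + 1L }
    while (j <= length(b)) { k <- k + 1L; out[[k]] <- b[[j]]; j <- j + 1L }
    out
  }
  msort <- function(x) {
    if (length(x) <= 1L) return(x)
    mid <- length(x) %/% 2L
    merge2(msort(x[seq_len(mid)]), msort(x[(mid + 1L):length(x)]))
  }
  msort(scores)
}

random_score <- function() {
  panel_score(sample(0:4, 1),
              sample(c(0, round(runif(1), 2)), 1, prob = c(0.2, 0.8)),
              round(runif(1, 0, 0.5), 2), eta = 0.1, n = 4L)
}
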