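# Exhaustive enumeration and ranking of n-color panels.

# all n-permutations of 1..m, rows in lexicographic order
.permutations <- function(m, n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  if (n == 1L) return(matrix(seq_len(m), ncol = 1L))
  out <- vector("list", m)
  vals <- seq_len(m)
  for (i in vals) {
    sub <- .permutations(m - 1L, n - 1L)
    rest <- vals[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }
  do.call(rbind, out)
}

#' Enumerate every distinct n-color panel
#'
#' Yields each panel exactly once, in a deterministic order: lexicographic by
#' fluorophore subset (library order), then by detector arrangement. The
#' total equals [count_panels()].
#'
#' @param lib A `fluorophore_library` (or a character vector of names).
#' @param inst An [instrument()] (or a character vector of detector names).
#' @param n Panel size.
#' @param budget Refuse to materialize more than this many panels.
#' @return A list of [panel()] objects.
#' @export
enumerate_panels <- function(lib, inst, n, budget = 1e5) {
  fl <- if (is.character(lib)) lib else names(lib)
  dt <- if (is.character(inst)) inst else names(inst$detectors)
  n <- as.integer(n)
  total <- count_panels(length(fl), length(dt), n)
  if (total$approx > budget)
    stop("enumeration of ", format(total), " panels exceeds the budget")
  subsets <- utils::combn(length(fl), n)
  arr <- .permutations(length(dt), n)
  out <- vector("list", total$approx)
  k <- 0L
  for (s in seq_len(ncol(subsets))) {
    fsub <- fl[subsets[, s]]
    for (r in seq_len(nrow(arr))) {
      k <- k + 1L
      out[[k]] <- panel(fsub, dt[arr[r, ]])
    }
  }
  out
}

# score every detector arrangement of one fluorophore subset, vectorized.
# Returns within / geomean / meanbleed / valid vectors over arrangements.
.score_subset <- function(S, af, fl, arr, eta) {
  n <- length(fl)
  m <- nrow(arr)
  colsum_f <- .colSums(S[fl, , drop = FALSE], n, ncol(S))
  sig <- matrix(0, m, n)
  bleed <- matrix(0, m, n)
  for (j in seq_len(n)) {
    dj <- arr[, j]
    sig[, j] <- S[fl[j], dj]
    bleed[, j] <- colsum_f[dj] - sig[, j] + af[dj]
  }
  valid <- .rowSums(sig <= .EPS, m, n) == 0L
  within <- .rowSums(bleed <= eta * sig, m, n)
  g <- numeric(m)
  g[valid] <- exp(.rowSums(log(sig[valid, , drop = FALSE]), sum(valid), n) / n)
  list(within = within, geomean = g,
       meanbleed = .rowSums(bleed, m, n) / n, valid = valid)
}

#' Exhaustively rank all valid n-color panels
#'
#' Scores every panel in the solution space, drops invalid ones, and ranks
#' the rest best-to-worst under the three-tier comparator. Equivalent panels
#' share the lowest rank; among equivalents the enumeration order is kept
#' (stable), so results are deterministic.
#'
#' @param lib A `fluorophore_library`.
#' @param inst An [instrument()].
#' @param n Panel size.
#' @param eta Bleed-through threshold (default 0.10).
#' @param top_k Keep only the best `top_k` rows (default all).
#' @param use_brightness,use_autofluorescence Passed to
#'   [build_signal_matrix()] (ignored when `S` is given).
#' @param S Optional precomputed `signal_matrix`.
#' @param budget Refuse above this many panels unless `force = TRUE`
#'   (exhaustive ranking of very large spaces can take days).
#' @param force Override the budget guard.
#' @return A `panel_search`: list with `table` (data.frame with columns
#'   rank, fluorophores, detectors, within_eta_count, geomean_signal,
#'   mean_bleedthrough; assignments are "/"-joined in detector order),
#'   `n_panels`, `n_valid`, `eta`, `n`.
#' @export
exhaustive_search <- function(lib, inst, n, eta = 0.1, top_k = Inf,
                              use_brightness = FALSE,
                              use_autofluorescence = FALSE,
                              S = NULL, budget = 1e8, force = FALSE) {
  if (is.null(S))
    S <- build_signal_matrix(lib, inst, use_brightness, use_autofluorescence)
  af <- .matrix_autofl(S)
  F <- nrow(S); D <- ncol(S); n <- as.integer(n)
  total <- count_panels(F, D, n)
  if (total$approx > budget && !force)
    stop("solution space of ", format(total),
         " panels exceeds the budget; pass force = TRUE to proceed")
  subsets <- utils::combn(F, n)
  arr <- .permutations(D, n)
  acc <- vector("list", ncol(subsets))
  n_valid <- 0
  for (s in seq_len(ncol(subsets))) {
    # canonical name-sorted order, so scores accumulate in the same order
    # as score_panel() on a canonical panel (bit-identical results)
    fl <- subsets[, s][order(rownames(S)[subsets[, s]])]
    sc <- .score_subset(S, af, fl, arr, eta)
    keep <- which(sc$valid)
    n_valid <- n_valid + length(keep)
    if (!length(keep)) next
    arrk <- arr[keep, , drop = FALSE]
    acc[[s]] <- data.frame(
      fluorophores = paste(rownames(S)[fl], collapse = "/"),
      detectors = apply(arrk, 1L, function(r)
        paste(colnames(S)[r], collapse = "/")),
      within_eta_count = sc$within[keep],
      geomean_signal = sc$geomean[keep],
      mean_bleedthrough = sc$meanbleed[keep],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- data.frame(rank = integer(0), fluorophores = character(0),
                      detectors = character(0), within_eta_count = integer(0),
                      geomean_signal = numeric(0),
                      mean_bleedthrough = numeric(0))
  } else {
    ord <- order(-tab$within_eta_count, -tab$geomean_signal,
                 tab$mean_bleedthrough)
    tab <- tab[ord, , drop = FALSE]
    same <- c(FALSE,
              diff(tab$within_eta_count) == 0 &
              diff(tab$geomean_signal) == 0 &
              diff(tab$mean_bleedthrough) == 0)
    rk <- seq_len(nrow(tab))
    for (i in which(same)) rk[i] <- rk[i - 1L]   # ties share the lowest rank
    tab <- cbind(rank = rk, tab)
    rownames(tab) <- NULL
    if (is.finite(top_k)) tab <- utils::head(tab, top_k)
  }
  structure(list(table = tab, n_panels = total$approx,
                 n_valid = n_valid, eta = eta, n = n),
            class = "panel_search")
}

#' @export
print.panel_search <- function(x, ...) {
  cat(sprintf("<panel_search> n=%d: %s panels, %d valid (%.3g%%), eta=%g\n",
              x$n, format(x$n_panels, big.mark = ","), x$n_valid,
              100 * x$n_valid / x$n_panels, x$eta))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' Extract the rank-1 panel of a search result
#' @param res A `panel_search`.
#' @return A list with `panel` and `score`, or `NULL` when no panel is valid.
#' @export
best_panel <- function(res) {
  stopifnot(inherits(res, "panel_search"))
  if (nrow(res$table) == 0L) return(NULL)
  row <- res$table[1L, ]
  list(panel = panel(strsplit(row$fluorophores, "/", fixed = TRUE)[[1]],
                     strsplit(row$detectors, "/", fixed = TRUE)[[1]]),
       score = panel_score(row$within_eta_count, row$geomean_signal,
                           row$mean_bleedthrough, eta = res$eta, n = res$n,
                           valid = TRUE))
}
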