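# Exact counting of the panel solution space.
#
# C(F, n) * P(D, n) overflows double precision already for the 10-color /
# 188-fluorophore design problem (~4e27), so counts are carried as exact
# arbitrary-precision integers: little-endian digit vectors in base 1e4 with
# multiply-by-small and exact divide-by-small. Dividing the running product
# of numerators by 2, 3, ..., n in order keeps every intermediate integral
# (k! always divides a product of k consecutive integers).

.big_one <- function() 1L

.big_mul <- function(b, m) {
  stopifnot(m >= 0, m < 2^20)
  x <- as.numeric(b) * m
  carry <- 0
  for (i in seq_along(x)) {
    x[i] <- x[i] + carry
    carry <- x[i] %/% 1e4
    x[i] <- x[i] %% 1e4
  }
  while (carry > 0) {
    x <- c(x, carry %% 1e4)
    carry <- carry %/% 1e4
  }
  as.integer(x)
}

.big_div <- function(b, d) {
  x <- as.numeric(b)
  rem <- 0
  for (i in rev(seq_along(x))) {
    cur <- rem * 1e4 + x[i]
    x[i] <- cur %/% d
    rem <- cur %% d
  }
  if (rem != 0) stop("inexact big-integer division")  # cannot happen here
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  as.integer(x)
}

.big_str <- function(b) {
  n <- length(b)
  paste0(b[n], paste(sprintf("%04d", rev(b[-n])), collapse = ""))
}

#' Count the n-color panel solution space exactly
#'
#' The number of distinct n-color panels from a library of `F` fluorophores
#' on an instrument with `D` detectors is `C(F, n) * P(D, n)`: choose the n
#' fluorophores, then assign each to a distinct detector. Computed in exact
#' integer arithmetic (the count exceeds double precision already for
#' moderate libraries).
#'
#' @param F Library size.
#' @param D Detector count.
#' @param n Panel size, `1 <= n <= min(F, D)`.
#' @return A `panel_count`: list with `count` (exact decimal string) and
#'   `approx` (double). `as.numeric()` returns the approximation.
#' @export
count_panels <- function(F, D, n) {
  F <- as.integer(F); D <- as.integer(D); n <- as.integer(n)
  if (n < 1L) stop("panel size n must be >= 1")
  if (n > F || n > D)
    stop("panel size n = ", n, " exceeds the library (", F,
         ") or detector (", D, ") count")
  b <- .big_one()
  for (i in seq.int(F - n + 1L, F)) b <- .big_mul(b, i)
  for (i in seq.int(D - n + 1L, D)) b <- .big_mul(b, i)
  if (n >= 2L) for (i in 2:n) b <- .big_div(b, i)
  s <- .big_str(b)
  structure(list(count = s, approx = as.numeric(s), F = F, D = D, n = n),
            class = "panel_count")
}

#' @export
as.numeric.panel_count <- function(x, ...) x$approx

#' @export
format.panel_count <- function(x, ...) {
  grouped <- prettyNum(x$count, big.mark = ",", preserve.width = "none")
  sprintf("%s (%.3g)", grouped, x$approx)
}

#' @export
print.panel_count <- function(x, ...) {
  cat(sprintf("<panel_count> F=%d D=%d n=%d: %s panels\n",
              x$F, x$D, x$n, format(x)))
  invisible(x)
}

#' Count valid panels exactly
#'
#' A panel is valid when every assigned detector has strictly positive
#' predicted signal for its fluorophore. The count is computed from the
#' boolean `signal > 0` matrix: for each n-subset of fluorophores, the
#' number of injective fluorophore-to-detector assignments with all-positive
#' signals is a permanent-style dynamic program over detectors and
#' fluorophore subsets (O(D * 2^n) per subset).
#'
#' @param S A `signal_matrix` (or any numeric matrix, fluorophores x
#'   detectors).
#' @param n Panel size.
#' @param budget Refuse when `C(F, n)` exceeds this many subsets.
#' @return The exact number of valid n-color panels (double; exact while
#'   below 2^53, which covers any instance this can enumerate).
#' @export
count_valid_panels <- function(S, n, budget = 1e6) {
  B <- unclass(S) > .EPS
  F <- nrow(B); D <- ncol(B)
  n <- as.integer(n)
  if (n > F || n > D) stop("panel size exceeds library or detector count")
  if (choose(F, n) > budget)
    stop("C(F, n) exceeds the subset budget (", budget, ")")
  subsets <- utils::combn(F, n)
  nmask <- 2L^n
  full <- nmask - 1L
  # per fluorophore-in-subset bit, the masks not containing it
  bits <- 2L^(seq_len(n) - 1L)
  without <- lapply(seq_len(n), function(f)
    which(bitwAnd(seq_len(nmask) - 1L, bits[f]) == 0L))
  total <- 0
  for (s in seq_len(ncol(subsets))) {
    rows <- subsets[, s]
    g <- numeric(nmask)
    g[1L] <- 1
    for (d in seq_len(D)) {
      add <- numeric(nmask)
      for (f in seq_len(n)) {
        if (B[rows[f], d]) {
          idx <- without[[f]]
          add[idx + bits[f]] <- add[idx + bits[f]] + g[idx]
        }
      }
      g <- g + add
    }
    total <- total + g[full + 1L]
  }
  total
}
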