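#' Number of unordered ROI pairs
#'
#' A "connection" is an unordered pair of distinct ROIs. For `R` regions there
#' are `R*(R-1)/2` connections; the whole-brain lattice of 7266 regions yields
#' 26,393,745 of them.
#'
#' @param n_roi Number of regions of interest (>= 2).
#' @return Connection count as a double (counts exceed .Machine$integer.max
#'   for whole-brain lattices).
#' @export
n_connections <- function(n_roi) {
  stopifnot(length(n_roi) == 1L, n_roi >= 2)
  n_roi * (n_roi - 1) / 2
}

#' Canonical connection enumeration
#'
#' Enumerates unordered ROI pairs (i, j), i < j, 0-based, in lexicographic
#' order. This single ordering is used everywhere a per-connection vector is
#' stored, so column `k` of a connection matrix always refers to the same pair.
#'
#' @param n_roi Number of ROIs.
#' @return List with integer vectors `i` and `j` (0-based) of length
#'   `n_connections(n_roi)`.
#' @export
connection_pairs <- function(n_roi) {
  stopifnot(n_roi >= 2)
  R <- as.integer(n_roi)
  i <- rep.int(0:(R - 2L), (R - 1L):1L)
  j <- sequence((R - 1L):1L, from = 2:R) - 1L
  list(i = i, j = j)
}

#' Connection index of an ROI pair
#'
#' Maps a 0-based unordered pair (i, j), i < j, to its 1-based position in the
#' canonical lexicographic enumeration.
#'
#' @param i,j 0-based ROI indices with `i < j` (vectorized).
#' @param n_roi Number of ROIs.
#' @return 1-based connection index (double).
#' @export
connection_index <- function(i, j, n_roi) {
  stopifnot(all(i < j), all(j < n_roi), all(i >= 0))
  i * (2 * n_roi - i - 1) / 2 + (j - i)
}

#' Human-readable connection count
#'
#' Formats the connection count of an ROI set to three significant figures in
#' millions, e.g. "26.4 million" for 7266 ROIs.
#'
#' @param n_roi Number of ROIs.
#' @return Character scalar.
#' @export
format_connection_count <- function(n_roi) {
  nc <- n_connections(n_roi)
  if (nc < 1e6) return(format(nc, big.mark = ",", scientific = FALSE))
  m <- signif(nc / 1e6, 3)
  paste(format(m, trim = TRUE), "million")
}
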