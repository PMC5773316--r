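# "1100"-type phylogenetically informative (PI) sites: alignment columns
# in which one nucleotide is shared by exactly two taxa and a different
# nucleotide by the remaining two, so the column votes for one of the
# three unrooted quartet topologies.  Any gap or ambiguity symbol voids
# the column.

# integer classification of all columns: 0 = none, 1..3 = AB, AC, BC
.classify_columns <- function(seqs) {
  enc <- lapply(seqs, .encode_seq)
  a <- enc[[1]]; b <- enc[[2]]; cc <- enc[[3]]; o <- enc[[4]]
  valid <- a > 0L & b > 0L & cc > 0L & o > 0L
  cls <- integer(length(a))
  cls[valid & a == b & cc == o & a != cc] <- 1L
  cls[valid & a == cc & b == o & a != b] <- 2L
  cls[valid & b == cc & a == o & a != b] <- 3L
  cls
}

#' Classify one alignment column as a "1100"-type PI site
#'
#' @param bases Character vector of 4 bases in role order A, B, C, O.
#' @return `"AB"`, `"AC"`, `"BC"` or `"none"`.  `AB` means
#'   `A == B != C == O`, and so on; 3-1 splits, constant columns and any
#'   column containing a non-ACGT symbol are `"none"`.
#' @examples
#' classify_column(c("A", "A", "C", "C"))   # "AB"
#' classify_column(c("A", "A", "A", "C"))   # "none"
#' @export
classify_column <- function(bases) {
  if (length(bases) != 4L) .stopf("a column has exactly 4 bases")
  cls <- .classify_columns(as.list(bases))
  c("none", .TOPOLOGIES)[cls + 1L]
}

#' Scan a locus for PI sites
#'
#' @param locus A `locus_alignment` (or any object with 4 sequences in
#'   role order A, B, C, O).
#' @return Data frame (`locus_id`, `position` 0-based, `topology`) with
#'   records in ascending position; empty if the locus has no PI site.
#' @examples
#' loc <- generate_locus(species_tree_model(), 200, linkage_params(200),
#'                       seed = 1)
#' head(scan_alignment(loc))
#' @export
scan_alignment <- function(locus) {
  seqs <- .as_seqs(locus)
  id <- if (is.list(locus) && !is.null(locus$locus_id)) locus$locus_id
        else "locus"
  cls <- .classify_columns(seqs)
  pos <- which(cls > 0L)
  data.frame(locus_id = rep(id, length(pos)), position = pos - 1L,
             topology = .TOPOLOGIES[cls[pos]], stringsAsFactors = FALSE)
}

#' Distances between adjacent PI sites supporting the same topology
#'
#' For each topology class, collects the distances (in bp, difference of
#' positions) between consecutive same-class PI sites within each locus;
#' pairs never span locus boundaries.
#'
#' @param records PI-site records as returned by [scan_alignment()]
#'   (rows from several loci may be concatenated).
#' @return Named list (`AB`, `AC`, `BC`) of integer distance vectors.
#' @export
adjacent_same_topology_distances <- function(records) {
  out <- setNames(vector("list", 3L), .TOPOLOGIES)
  for (topo in .TOPOLOGIES) {
    r <- records[records$topology == topo, , drop = FALSE]
    d <- unlist(lapply(split(r$position, r$locus_id), function(p)
      if (length(p) > 1L) diff(sort(p)) else integer(0)), use.names = FALSE)
    out[[topo]] <- as.integer(if (is.null(d)) integer(0) else d)
  }
  out
}

#' Topology frequencies of adjacent PI-site pairs by distance bin
#'
#' Bins the adjacent same-topology distances of
#' [adjacent_same_topology_distances()] into half-open intervals
#' `[edge_i, edge_{i+1})` and, within each bin, reports the relative
#' frequency of pairs supporting each topology (rows sum to 1; empty bins
#' are kept with `NA` frequencies and flagged).
#'
#' @inheritParams adjacent_same_topology_distances
#' @param bin_edges Increasing distance bin edges; the default is
#'   `c(0, 100, 250, 500, 1000, 1500, 2000, Inf)`.
#' @return Data frame with `bin` label, `lower`, `upper`, per-topology
#'   frequencies `freq_AB`, `freq_AC`, `freq_BC`, total pair count `n`,
#'   and logical `empty`.
#' @export
distance_binned_topology_freq <- function(records,
                                          bin_edges = c(0, 100, 250, 500,
                                                        1000, 1500, 2000,
                                                        Inf)) {
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE))
    .stopf("bin_edges must be strictly increasing with at least 2 values")
  dists <- adjacent_same_topology_distances(records)
  if (sum(lengths(dists)) == 0L) .stopf("no adjacent same-topology PI pair")
  nb <- length(bin_edges) - 1L
  counts <- matrix(0L, nb, 3L, dimnames = list(NULL, .TOPOLOGIES))
  for (topo in .TOPOLOGIES) {
    bins <- findInterval(dists[[topo]], bin_edges,
                         rightmost.closed = FALSE)
    bins <- bins[bins >= 1L & bins <= nb]
    counts[, topo] <- tabulate(bins, nb)
  }
  n <- rowSums(counts)
  freq <- counts / ifelse(n == 0L, NA_real_, n)
  data.frame(
    bin = sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1L]),
    lower = bin_edges[-length(bin_edges)], upper = bin_edges[-1L],
    freq_AB = freq[, "AB"], freq_AC = freq[, "AC"], freq_BC = freq[, "BC"],
    n = n, empty = n == 0L, stringsAsFactors = FALSE
  )
}
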