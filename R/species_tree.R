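# Quartet species-tree estimation.  For four taxa the MSC-consistent
# summary estimator is the plurality quartet topology over gene trees;
# its support is assessed by a multinomial parametric bootstrap at the
# observed topology frequencies.  Concatenation inference pools all
# fragments of a length class into one alignment and runs the quartet ML
# engine on it.

#' Quartet species tree from gene-tree topology counts
#'
#' Calls the plurality topology over resolved gene-tree counts and
#' attaches a parametric-bootstrap support: the fraction of multinomial
#' resamples (at the observed frequencies and total count) in which the
#' observed plurality topology remains the strict plurality.  An exact
#' tie in the observed counts yields `"unresolved"` with `NA` support.
#'
#' @param counts Named counts for topologies `AB`, `AC`, `BC` (e.g. from
#'   [simulate_topology_distribution()] or tabulated from
#'   [infer_gene_trees()]).
#' @param n_boot Number of bootstrap resamples (default 1e4).
#' @param seed Optional seed for the bootstrap.
#' @return List with `topology`, `support`, `counts`.
#' @examples
#' quartet_species_tree(c(AB = 470, AC = 290, BC = 240), seed = 1)
#' @export
quartet_species_tree <- function(counts, n_boot = 1e4, seed = NULL) {
  if (is.null(names(counts))) names(counts) <- .TOPOLOGIES
  counts <- counts[.TOPOLOGIES]
  if (any(is.na(counts)) || any(counts < 0))
    .stopf("counts must be non-negative for AB, AC, BC")
  n <- sum(counts)
  if (n == 0) .stopf("all-zero topology counts")
  top <- which(counts == max(counts))
  if (length(top) > 1L)
    return(list(topology = "unresolved", support = NA_real_,
                counts = counts))
  support <- .with_seed(seed, {
    res <- rmultinom(n_boot, n, prob = counts / n)
    mean(res[top, ] > apply(res[-top, , drop = FALSE], 2L, max))
  })
  list(topology = .TOPOLOGIES[top], support = support, counts = counts)
}

#' Concatenation inference for one fragment-length class
#'
#' Concatenates all fragments of a class (role-wise) into a single
#' four-taxon alignment and infers its quartet topology with
#' [infer_topology_ml()].
#'
#' @param fragments List of fragments (one class of [sample_fragments()])
#'   or loci; each must carry 4 sequences in role order A, B, C, O.
#' @param ... Passed to [infer_topology_ml()].
#' @return An `inferred_gene_tree` for the concatenated alignment.
#' @export
concat_infer <- function(fragments, ...) {
  if (length(fragments) == 0L) .stopf("empty fragment class")
  seqs <- lapply(fragments, .as_seqs)
  concat <- vapply(1:4, function(i)
    paste(vapply(seqs, `[[`, character(1), i), collapse = ""), character(1))
  names(concat) <- c("A", "B", "C", "O")
  infer_topology_ml(concat, ...)
}
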