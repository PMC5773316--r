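# Native quartet gene-tree inference.  The likelihood engine (JC69,
# Felsenstein pruning specialised to four taxa, cyclic Brent optimisation
# of the five branch lengths of each unrooted topology) lives in
# src/quartet_ml.cpp; this file provides the user-facing wrappers, the
# parsimony cross-check, and the JC distance.

# ASCII code -> state map (A=1, C=2, G=3, T=4; 0 = non-comparable).
.DNA_LOOKUP <- local({
  m <- integer(256)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("T")] <- 4L
  m[utf8ToInt("a")] <- 1L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("g")] <- 3L; m[utf8ToInt("t")] <- 4L
  m
})

.encode_seq <- function(s) .DNA_LOOKUP[utf8ToInt(s)]

# 4 sequences -> counts over the 256 ungapped site patterns
# (index = sA + 4 sB + 16 sC + 64 sO, states 0..3).
.pattern_counts <- function(seqs) {
  if (length(seqs) != 4L) .stopf("need 4 sequences in role order A,B,C,O")
  enc <- lapply(seqs, .encode_seq)
  L <- unique(lengths(enc))
  if (length(L) != 1L) .stopf("sequences must have equal length")
  ok <- enc[[1]] > 0L & enc[[2]] > 0L & enc[[3]] > 0L & enc[[4]] > 0L
  idx <- (enc[[1]][ok] - 1L) + 4L * (enc[[2]][ok] - 1L) +
    16L * (enc[[3]][ok] - 1L) + 64L * (enc[[4]][ok] - 1L)
  tabulate(idx + 1L, 256L)
}

.as_seqs <- function(x) {
  if (inherits(x, "locus_alignment")) return(x$seqs)
  if (is.list(x) && !is.null(x$seqs)) return(x$seqs)
  if (is.character(x) && length(x) == 4L) return(x)
  .stopf("expected a fragment/locus with 4 sequences in role order A,B,C,O")
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' `d = -(3/4) log(1 - (4/3) p)` from the proportion `p` of differing
#' sites among comparable (ungapped, unambiguous A/C/G/T) columns.
#'
#' @param seq_i,seq_j Aligned sequences of equal length.
#' @return Distance in expected substitutions/site.
#' @examples
#' jc_distance("ACGTACGTAC", "ACGTACGTAT")
#' @export
jc_distance <- function(seq_i, seq_j) {
  a <- .encode_seq(seq_i); b <- .encode_seq(seq_j)
  if (length(a) != length(b)) .stopf("sequences must have equal length")
  ok <- a > 0L & b > 0L
  n <- sum(ok)
  if (n == 0L) .stopf("no comparable sites")
  p <- sum(a[ok] != b[ok]) / n
  if (p >= 0.75)
    .stopf("saturated distance: proportion of differences %.3f >= 0.75", p)
  -0.75 * log(1 - 4 * p / 3)
}

#' Maximum-likelihood quartet gene-tree inference
#'
#' Evaluates all three unrooted quartet topologies under JC69, numerically
#' optimising the five branch lengths of each (coordinate-wise Brent
#' search on `[0, 10]`, tolerance `1e-8`), and returns the
#' maximum-likelihood topology with a likelihood-weight support
#' `exp(lnL_t) / sum_t exp(lnL_t)` computed stably on the log scale.
#' When the two best log-likelihoods are tied within `tol_tie` the call is
#' `"unresolved"` (an alignment with no variable comparable sites is
#' always unresolved with support 1/3).  `cherry_depth` is half the
#' patristic distance between the two ingroup-cherry taxa of the best
#' topology, a proxy for their coalescence time in substitutions/site.
#'
#' @param x A fragment or `locus_alignment`, or a character vector of 4
#'   sequences in role order A, B, C, O.
#' @param subst_model Substitution model; only `"JC69"` is implemented.
#' @param tol_tie Log-likelihood tie tolerance for declaring the topology
#'   unresolved.
#' @return A list of class `inferred_gene_tree`: `topology` (`"AB"`,
#'   `"AC"`, `"BC"` or `"unresolved"`), `lnl` (named, all three
#'   topologies), `support`, `branch_lengths` (named A, B, C, O, internal;
#'   best topology), `cherry_depth`, `n_sites`.
#' @examples
#' tr <- simulate_gene_tree(model_with_internode(species_tree_model(), 1),
#'                          seed = 5)
#' aln <- evolve_sequences(tr, 2000, seed = 6)
#' infer_topology_ml(aln)$topology
#' @export
infer_topology_ml <- function(x, subst_model = "JC69", tol_tie = 1e-6) {
  if (!identical(subst_model, "JC69"))
    .stopf("unknown substitution model '%s' (only JC69 is implemented)",
           subst_model)
  counts <- .pattern_counts(.as_seqs(x))
  if (sum(counts) == 0L) .stopf("no comparable sites")
  fit <- .quartet_ml_fit_cpp(as.numeric(counts))
  lnl <- setNames(fit$lnl, .TOPOLOGIES)
  ord <- order(lnl, decreasing = TRUE)
  tied <- (lnl[ord[1L]] - lnl[ord[2L]]) <= tol_tie
  best <- ord[1L]
  w <- exp(lnl - max(lnl))
  support <- unname(w[best] / sum(w))
  bl <- setNames(fit$branch[best, ], c("A", "B", "C", "O", "internal"))
  cherry <- list(c("A", "B"), c("A", "C"), c("B", "C"))[[best]]
  structure(
    list(topology = if (tied) "unresolved" else .TOPOLOGIES[best],
         lnl = lnl,
         support = if (tied) 1 / 3 else support,
         branch_lengths = bl,
         cherry_depth = unname(sum(bl[cherry]) / 2),
         n_sites = sum(counts)),
    class = "inferred_gene_tree"
  )
}

#' @export
print.inferred_gene_tree <- function(x, ...) {
  cat(sprintf("Quartet ML gene tree: %s (support %.3f, %d sites)\n",
              x$topology, x$support, x$n_sites))
  cat("  lnL:", paste(sprintf("%s=%.3f", names(x$lnl), x$lnl),
                      collapse = " "), "\n")
  invisible(x)
}

#' Batch ML inference over fragments
#'
#' Runs [infer_topology_ml()] on a list of fragments (one length class of
#' [sample_fragments()], or a `locus_set`) and collects the results in a
#' data frame.
#'
#' @param fragments List of fragments or loci.
#' @param ... Passed to [infer_topology_ml()].
#' @return Data frame with columns `id`, `topology`, `support`,
#'   `cherry_depth`, `lnl_AB`, `lnl_AC`, `lnl_BC`.
#' @export
infer_gene_trees <- function(fragments, ...) {
  res <- lapply(fragments, function(f) {
    fit <- infer_topology_ml(f, ...)
    id <- if (is.list(f) && !is.null(f$locus_id)) f$locus_id else NA_character_
    data.frame(id = id, topology = fit$topology, support = fit$support,
               cherry_depth = fit$cherry_depth, lnl_AB = fit$lnl[["AB"]],
               lnl_AC = fit$lnl[["AC"]], lnl_BC = fit$lnl[["BC"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Parsimony quartet topology from informative-site votes
#'
#' Counts the "1100"-type phylogenetically informative sites supporting
#' each quartet topology (see [classify_column()]) and calls the plurality
#' topology; ties (including zero informative sites) are `"unresolved"`.
#' A fast, model-free cross-check of the likelihood engine.
#'
#' @inheritParams infer_topology_ml
#' @return List with `topology` and `votes` (named counts).
#' @export
infer_topology_parsimony <- function(x) {
  seqs <- .as_seqs(x)
  cls <- .classify_columns(seqs)
  votes <- setNames(tabulate(cls, 3L), .TOPOLOGIES)
  top <- which(votes == max(votes))
  list(topology = if (max(votes) == 0L || length(top) > 1L) "unresolved"
       else .TOPOLOGIES[top],
       votes = votes)
}
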