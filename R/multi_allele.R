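# Multi-allele coalescent simulation: k alleles sampled per species, full
# structured coalescent through tip and ancestral populations, and a
# species-level topology call defined as the plurality quartet topology
# over all k^4 one-allele-per-species quartets read from the genealogy.

# Coalesce the lineages of one population between t0 and t_end.
# `state` is an environment holding:
#   M          : 4k x 4k pairwise coalescence-time matrix (filled on merge)
#   node_time  : times of all created nodes
#   edges      : list collecting (parent, child) pairs
#   next_node  : next internal node id
# Returns the surviving lineages (list of list(node =, tips =)).
.coalesce_pop <- function(lineages, N, t0, t_end, state) {
  k <- length(lineages)
  t <- t0
  while (k >= 2L) {
    t <- t + rexp(1L) * (2 * N) / (k * (k - 1) / 2)
    if (t >= t_end) break
    pair <- sample.int(k, 2L)
    l1 <- lineages[[pair[1L]]]; l2 <- lineages[[pair[2L]]]
    state$M[l1$tips, l2$tips] <- t
    state$M[l2$tips, l1$tips] <- t
    id <- state$next_node
    state$next_node <- id + 1L
    state$node_time[id] <- t
    state$edges[[length(state$edges) + 1L]] <- c(id, l1$node)
    state$edges[[length(state$edges) + 1L]] <- c(id, l2$node)
    lineages[[pair[1L]]] <- list(node = id, tips = c(l1$tips, l2$tips))
    lineages[[pair[2L]]] <- NULL
    k <- k - 1L
  }
  lineages
}

.simulate_multi_allele_raw <- function(model, k) {
  ntips <- 4L * k
  state <- new.env(parent = emptyenv())
  state$M <- matrix(NA_real_, ntips, ntips)
  state$node_time <- c(rep(0, ntips), rep(NA_real_, ntips - 1L))
  state$edges <- list()
  state$next_node <- ntips + 1L

  tip_ids <- split(seq_len(ntips), rep(c("A", "B", "C", "O"), each = k))
  pops <- lapply(c("A", "B", "C", "O"), function(sp)
    lapply(tip_ids[[sp]], function(i) list(node = i, tips = i)))
  names(pops) <- c("A", "B", "C", "O")

  # tip branches: [0, tau_AB) for A and B, [0, tau_ABC) for C, [0, tau_root) for O
  pops$A <- .coalesce_pop(pops$A, model$N[["A"]], 0, model$tau_AB, state)
  pops$B <- .coalesce_pop(pops$B, model$N[["B"]], 0, model$tau_AB, state)
  pops$C <- .coalesce_pop(pops$C, model$N[["C"]], 0, model$tau_ABC, state)
  pops$O <- .coalesce_pop(pops$O, model$N[["O"]], 0, model$tau_root, state)
  # ancestral populations
  ab <- .coalesce_pop(c(pops$A, pops$B), model$N[["AB"]], model$tau_AB,
                      model$tau_ABC, state)
  abc <- .coalesce_pop(c(ab, pops$C), model$N[["ABC"]], model$tau_ABC,
                       model$tau_root, state)
  root <- .coalesce_pop(c(abc, pops$O), model$N[["root"]], model$tau_root,
                        Inf, state)
  stopifnot(length(root) == 1L)
  state
}

# Precomputed linear indices into the 4k x 4k time matrix for the six
# species-pair comparisons of every one-allele-per-species quartet, plus
# the topology class implied when that pair is the first to coalesce.
.quartet_index <- function(k) {
  ntips <- 4L * k
  g <- expand.grid(i = seq_len(k), j = seq_len(k), l = seq_len(k),
                   m = seq_len(k))
  a <- g$i; b <- k + g$j; cc <- 2L * k + g$l; o <- 3L * k + g$m
  lin <- function(r, c) (c - 1L) * ntips + r
  idx <- cbind(ab = lin(a, b), ac = lin(a, cc), ao = lin(a, o),
               bc = lin(b, cc), bo = lin(b, o), co = lin(cc, o))
  list(idx = idx, class = c(1L, 2L, 3L, 3L, 2L, 1L))  # AB, AC, BC
}

.species_call_from_M <- function(M, qidx) {
  tm <- matrix(M[qidx$idx], ncol = 6L)
  first <- max.col(-tm, ties.method = "first")
  counts <- tabulate(qidx$class[first], 3L)
  names(counts) <- .TOPOLOGIES
  top <- which(counts == max(counts))
  call <- if (length(top) > 1L) "unresolved" else .TOPOLOGIES[top]
  list(call = call, quartet_counts = counts)
}

#' Simulate a multi-allele genealogy and its species-level topology call
#'
#' Samples `k` alleles per species and runs the structured coalescent
#' through all tip and ancestral populations of the four-species model.
#' The species-level quartet topology is called as the plurality topology
#' over all `k^4` one-allele-per-species quartets read from the genealogy
#' (for an ultrametric genealogy, a quartet's topology is decided by its
#' first-coalescing species pair); an exact tie in the plurality count
#' yields `"unresolved"`.
#'
#' @param model A [species_tree_model()].
#' @param k Alleles sampled per species (`>= 1`); `k = 1` reduces to
#'   [simulate_gene_tree()] in distribution.
#' @param seed Optional integer seed.
#' @return A list of class `multi_allele_genealogy`: `call` (plurality
#'   topology or `"unresolved"`), `quartet_counts` (counts of the three
#'   topologies over the `k^4` quartets), `pair_times` (4k x 4k matrix of
#'   pairwise coalescence times in generations), and `tree` (the full
#'   genealogy as a `phylo`-compatible list, branch lengths in
#'   substitutions/site).
#' @examples
#' g <- simulate_multi_allele(species_tree_model(), k = 2, seed = 1)
#' g$call
#' @export
simulate_multi_allele <- function(model, k, seed = NULL) {
  stopifnot(inherits(model, "species_tree_model"))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    .stopf("k must be a count >= 1")
  k <- as.integer(k)
  .with_seed(seed, {
    state <- .simulate_multi_allele_raw(model, k)
    qidx <- .quartet_index(k)
    call <- .species_call_from_M(state$M, qidx)
    tree <- .multi_allele_phylo(state, k, model$mu)
    structure(
      list(call = call$call, quartet_counts = call$quartet_counts,
           pair_times = state$M, tree = tree, k = k),
      class = "multi_allele_genealogy"
    )
  })
}

# Assemble an ape-compatible "phylo" from the recorded merges.  ape
# requires tips 1..ntips and root = ntips + 1; internal nodes were created
# in time order, so the root (created last) maps to ntips + 1 by
# reversing the internal numbering.
.multi_allele_phylo <- function(state, k, mu) {
  ntips <- 4L * k
  nint <- ntips - 1L
  renum <- function(v) ifelse(v <= ntips, v, ntips + (2L * ntips - v))
  em <- do.call(rbind, state$edges)
  edge <- cbind(renum(em[, 1L]), renum(em[, 2L]))
  storage.mode(edge) <- "integer"
  edge_len <- (state$node_time[em[, 1L]] - state$node_time[em[, 2L]]) * mu
  tip.label <- paste0(rep(c("A", "B", "C", "O"), each = k), "_",
                      rep(seq_len(k), 4L))
  structure(list(edge = edge, edge.length = edge_len, Nnode = nint,
                 tip.label = tip.label), class = "phylo", order = NULL)
}

#' Species-level topology calls over replicate multi-allele simulations
#'
#' Batch driver for the demography experiment: repeats the multi-allele
#' simulation and tabulates the species-level topology calls (plurality
#' ties are counted as `unresolved` and excluded from the three topology
#' frequencies).
#'
#' @inheritParams simulate_multi_allele
#' @param n Number of replicate genealogies.
#' @return Named integer vector of counts (`AB`, `AC`, `BC`,
#'   `unresolved`) summing to `n`.
#' @examples
#' m <- unequal_ne_model(x = 1e6)
#' simulate_species_calls(m, k = 2, n = 50, seed = 1)
#' @export
simulate_species_calls <- function(model, k, n, seed = NULL) {
  stopifnot(inherits(model, "species_tree_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    .stopf("n must be a count >= 1")
  k <- as.integer(k)
  .with_seed(seed, {
    qidx <- .quartet_index(k)
    calls <- character(n)
    for (i in seq_len(n)) {
      state <- .simulate_multi_allele_raw(model, k)
      calls[i] <- .species_call_from_M(state$M, qidx)$call
    }
    counts <- table(factor(calls, levels = c(.TOPOLOGIES, "unresolved")))
    setNames(as.integer(counts), c(.TOPOLOGIES, "unresolved"))
  })
}

#' @export
print.multi_allele_genealogy <- function(x, ...) {
  cat(sprintf("Multi-allele MSC genealogy (%d alleles/species, %d tips)\n",
              x$k, 4L * x$k))
  cat(sprintf("  species-level call: %s (quartet counts AB=%d AC=%d BC=%d)\n",
              x$call, x$quartet_counts[1], x$quartet_counts[2],
              x$quartet_counts[3]))
  invisible(x)
}
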