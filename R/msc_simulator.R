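# Gene-genealogy simulation under the four-species multispecies coalescent.
#
# One allele is sampled per species, so no coalescence can happen before
# tau_AB.  Backwards in time the lineages pass through the (A,B) ancestral
# population (size N_AB), then the ((A,B),C) population (N_ABC), then the
# root population (N_root) where the outgroup lineage joins.  Within a
# population holding k lineages the waiting time to the next coalescence
# is exponential with rate k(k-1)/2 per 2N generations (continuous-time
# Wright-Fisher approximation), and the coalescing pair is uniform.
#
# The quartet topology is fully determined by the first coalescence: the
# first pair to merge forms a cherry of the quartet, and the induced
# 2|2 split labels the tree (ab or co -> AB, ac or bo -> AC, bc or ao -> BC).

# Vectorised core: returns one row per replicate with the topology, the
# three coalescence times (generations, ascending), and two merge codes
# sufficient to reconstruct the full labelled genealogy:
#   first_pair: 1..6 = ab, ac, bc, ao, bo, co
#   second_code: 1..3 indexing the pair among the 3 post-merge lineages in
#   canonical order (merged node first, then remaining tips ascending).
.sim_gene_tree_rows <- function(model, n) {
  tau1 <- model$tau_AB; tau2 <- model$tau_ABC; tau3 <- model$tau_root
  twoN_AB <- 2 * model$N[["AB"]]
  twoN_ABC <- 2 * model$N[["ABC"]]
  twoN_root <- 2 * model$N[["root"]]

  t1 <- t2 <- t3 <- numeric(n)
  p1 <- p2 <- integer(n)

  # phase 1: a and b alone in the (A,B) ancestor
  w1 <- rexp(n) * twoN_AB
  cAB <- w1 < (tau2 - tau1)

  i1 <- which(cAB)
  if (length(i1)) {
    t1[i1] <- tau1 + w1[i1]
    p1[i1] <- 1L
    w2 <- rexp(length(i1)) * twoN_ABC
    in2 <- w2 < (tau3 - tau2)
    i1a <- i1[in2]; i1b <- i1[!in2]
    if (length(i1a)) {                       # (ab, c) coalesce before the root
      t2[i1a] <- tau2 + w2[in2]
      p2[i1a] <- 1L
      t3[i1a] <- tau3 + rexp(length(i1a)) * twoN_root
    }
    if (length(i1b)) {                       # (ab, c, o) enter the root pop
      t2[i1b] <- tau3 + rexp(length(i1b)) * twoN_root / 3
      p2[i1b] <- sample.int(3L, length(i1b), replace = TRUE)
      t3[i1b] <- t2[i1b] + rexp(length(i1b)) * twoN_root
    }
  }

  i2 <- which(!cAB)
  if (length(i2)) {
    # a, b, c free in the ((A,B),C) ancestor
    f1 <- rexp(length(i2)) * twoN_ABC / 3
    inA <- f1 < (tau3 - tau2)
    i2a <- i2[inA]; i2b <- i2[!inA]
    if (length(i2a)) {
      t1[i2a] <- tau2 + f1[inA]
      p1[i2a] <- sample.int(3L, length(i2a), replace = TRUE)
      f2 <- rexp(length(i2a)) * twoN_ABC
      t2c <- t1[i2a] + f2
      ok <- t2c < tau3
      i2ai <- i2a[ok]; i2aii <- i2a[!ok]
      if (length(i2ai)) {
        t2[i2ai] <- t2c[ok]
        p2[i2ai] <- 1L
        t3[i2ai] <- tau3 + rexp(length(i2ai)) * twoN_root
      }
      if (length(i2aii)) {                   # (pair, tip, o) at the root
        t2[i2aii] <- tau3 + rexp(length(i2aii)) * twoN_root / 3
        p2[i2aii] <- sample.int(3L, length(i2aii), replace = TRUE)
        t3[i2aii] <- t2[i2aii] + rexp(length(i2aii)) * twoN_root
      }
    }
    if (length(i2b)) {                       # a, b, c, o all at the root
      t1[i2b] <- tau3 + rexp(length(i2b)) * twoN_root / 6
      p1[i2b] <- sample.int(6L, length(i2b), replace = TRUE)
      t2[i2b] <- t1[i2b] + rexp(length(i2b)) * twoN_root / 3
      p2[i2b] <- sample.int(3L, length(i2b), replace = TRUE)
      t3[i2b] <- t2[i2b] + rexp(length(i2b)) * twoN_root
    }
  }

  data.frame(topology = .PAIR_TOPOLOGY[p1], t_first = t1, t_second = t2,
             t_third = t3, first_pair = p1, second_code = p2,
             stringsAsFactors = FALSE)
}

#' Simulate gene genealogies under the four-species MSC
#'
#' `simulate_gene_trees()` returns a data frame with one row per
#' genealogy: the quartet `topology` (`"AB"`, `"AC"`, `"BC"`), the three
#' coalescence times in generations (`t_first <= t_second <= t_third`),
#' and merge codes identifying the labelled tree shape.
#' `simulate_gene_tree()` returns a single genealogy as a `gene_tree`
#' object with an explicit edge table (branch lengths both in generations
#' and in expected substitutions/site, i.e. time times `mu`).
#'
#' @param model A [species_tree_model()].
#' @param n Number of genealogies (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame (`simulate_gene_trees`) or a `gene_tree` object.
#' @examples
#' m <- species_tree_model()
#' g <- simulate_gene_trees(m, 1000, seed = 1)
#' table(g$topology) / 1000          # near match_probability(internode_units(m))
#' simulate_gene_tree(m, seed = 1)
#' @export
simulate_gene_trees <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "species_tree_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    .stopf("n must be a count >= 1")
  .with_seed(seed, .sim_gene_tree_rows(model, as.integer(n)))
}

#' @rdname simulate_gene_trees
#' @export
simulate_gene_tree <- function(model, seed = NULL) {
  row <- simulate_gene_trees(model, 1L, seed = seed)
  gene_tree_from_row(row[1L, ], model)
}

# Pairs of tip node ids (a=1 b=2 c=3 o=4) for first_pair codes 1..6.
.PAIRS6 <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(1L, 4L), c(2L, 4L),
                c(3L, 4L))

#' Reconstruct a gene tree from a simulated genealogy row
#'
#' Expands one row of [simulate_gene_trees()] into a `gene_tree`: a rooted
#' four-tip genealogy with node times and an edge table.  Nodes are
#' numbered 1..4 for tips A, B, C, O and 5..7 for the internal nodes in
#' coalescence order (7 = root).
#'
#' @param row One-row data frame from [simulate_gene_trees()].
#' @param model The generating [species_tree_model()] (supplies `mu` and
#'   taxon labels).
#' @return An object of class `gene_tree`: list with `topology`,
#'   `coal_times` (generations), `edges` (data frame `parent`, `child`,
#'   `time_length`, `length` in substitutions/site), `taxa`, `mu`.
#' @export
gene_tree_from_row <- function(row, model) {
  stopifnot(inherits(model, "species_tree_model"))
  m1 <- .PAIRS6[[row$first_pair]]
  lin2 <- c(5L, setdiff(1:4, m1))            # canonical post-merge lineages
  pairs3 <- list(lin2[c(1L, 2L)], lin2[c(1L, 3L)], lin2[c(2L, 3L)])
  m2 <- pairs3[[row$second_code]]
  m3 <- c(6L, setdiff(lin2, m2))             # lineages joined at the root
  node_time <- c(0, 0, 0, 0, row$t_first, row$t_second, row$t_third)
  parent <- c(5L, 5L, 6L, 6L, 7L, 7L)
  child <- c(m1[1L], m1[2L], m2[1L], m2[2L], m3[1L], m3[2L])
  tl <- node_time[parent] - node_time[child]
  structure(
    list(topology = row$topology,
         coal_times = c(first = row$t_first, second = row$t_second,
                        third = row$t_third),
         edges = data.frame(parent = parent, child = child,
                            time_length = tl, length = tl * model$mu),
         taxa = model$taxon_labels, mu = model$mu),
    class = "gene_tree"
  )
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("Quartet gene tree: topology %s; coalescences at %.0f, %.0f, %.0f generations\n",
              x$topology, x$coal_times[1], x$coal_times[2], x$coal_times[3]))
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

#' Distribution of quartet topologies over simulated genealogies
#'
#' Batch driver around the MSC simulator: draws `n` independent gene
#' genealogies and tabulates their quartet topologies.
#'
#' @inheritParams simulate_gene_trees
#' @return Named integer vector with counts for `AB`, `AC`, `BC`
#'   (summing to `n`).
#' @examples
#' m <- model_with_internode(species_tree_model(), 0.1924)
#' simulate_topology_distribution(m, 1e4, seed = 7) / 1e4   # AB ~ 0.45
#' @export
simulate_topology_distribution <- function(model, n, seed = NULL) {
  rows <- simulate_gene_trees(model, n, seed = seed)
  counts <- table(factor(rows$topology, levels = .TOPOLOGIES))
  setNames(as.integer(counts), .TOPOLOGIES)
}
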