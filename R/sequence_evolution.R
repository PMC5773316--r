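# Nucleotide evolution along a fixed genealogy.  Sites are i.i.d. given
# the tree; branch lengths are expected substitutions/site.  JC69 is the
# default (and the model assumed by the inference engine); HKY85 is
# available for the generator side.

.BASES <- c("A", "C", "G", "T")

# 4x4 transition-probability matrix for branch length d (subs/site).
.pij_matrix <- function(d, subst_model = c("JC69", "HKY85"), kappa = 2,
                        base_freqs = rep(0.25, 4)) {
  subst_model <- match.arg(subst_model)
  if (subst_model == "JC69") {
    x <- exp(-4 * d / 3)
    p_same <- 0.25 + 0.75 * x
    p_diff <- 0.25 - 0.25 * x
    P <- matrix(p_diff, 4, 4)
    diag(P) <- p_same
    return(P)
  }
  # HKY85 via spectral decomposition of the reversible rate matrix,
  # scaled so that d is the expected number of substitutions per site.
  if (length(base_freqs) != 4L || any(base_freqs <= 0))
    .stopf("base_freqs must be 4 positive frequencies")
  pi <- base_freqs / sum(base_freqs)
  if (kappa <= 0) .stopf("kappa must be > 0")
  transition <- matrix(c(FALSE, FALSE, TRUE, FALSE,
                         FALSE, FALSE, FALSE, TRUE,
                         TRUE, FALSE, FALSE, FALSE,
                         FALSE, TRUE, FALSE, FALSE), 4, 4)  # A<->G, C<->T
  Q <- matrix(rep(pi, each = 4), 4, 4)
  Q[transition] <- Q[transition] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)       # symmetric similar matrix
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / sq) %*% es$vectors %*% diag(exp(es$values * d)) %*%
    t(es$vectors) %*% diag(sq)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Sample child states (integer 1..4) from parent states through P.
.transition_sample <- function(parent_states, P) {
  cp <- t(apply(P, 1L, cumsum))
  u <- runif(length(parent_states))
  1L + (u > cp[parent_states, 1L]) + (u > cp[parent_states, 2L]) +
    (u > cp[parent_states, 3L])
}

# Core: evolve L sites along an edge table (columns parent, child, length
# in subs/site; nodes 1..4 are the tips A,B,C,O).  Returns 4 x L integer
# matrix of states.
.evolve_states <- function(edges, L, subst_model = "JC69", kappa = 2,
                           base_freqs = rep(0.25, 4)) {
  root <- setdiff(edges$parent, edges$child)[1L]
  nnode <- max(edges$parent)
  states <- vector("list", nnode)
  root_freqs <- if (subst_model == "JC69") rep(0.25, 4) else
    base_freqs / sum(base_freqs)
  states[[root]] <- sample.int(4L, L, replace = TRUE, prob = root_freqs)
  ord <- order(-edges$parent)                # parents before children
  for (i in ord) {
    P <- .pij_matrix(edges$length[i], subst_model, kappa, base_freqs)
    states[[edges$child[i]]] <-
      .transition_sample(states[[edges$parent[i]]], P)
  }
  rbind(states[[1L]], states[[2L]], states[[3L]], states[[4L]])
}

.states_to_strings <- function(m) {
  apply(m, 1L, function(r) paste(.BASES[r], collapse = ""))
}

#' Evolve nucleotide sequences along a gene genealogy
#'
#' Simulates four aligned sequences of length `L` along a [gene
#' tree][simulate_gene_tree()], with sites independent and identically
#' distributed given the tree.  Branch lengths are taken from the tree's
#' edge table (expected substitutions/site).
#'
#' @param tree A `gene_tree` (see [simulate_gene_tree()]).
#' @param L Number of sites (`>= 1`).
#' @param subst_model `"JC69"` (default) or `"HKY85"`.
#' @param kappa Transition/transversion rate ratio (HKY85 only; `kappa =
#'   1` with equal base frequencies reduces HKY85 to JC69).
#' @param base_freqs Stationary base frequencies in order A, C, G, T
#'   (HKY85 only).
#' @param seed Optional integer seed.
#' @return Named character vector of 4 sequences (roles `A`, `B`, `C`,
#'   `O`) over `{A,C,G,T}`.
#' @examples
#' tr <- simulate_gene_tree(species_tree_model(), seed = 2)
#' evolve_sequences(tr, 60, seed = 3)
#' @export
evolve_sequences <- function(tree, L, subst_model = c("JC69", "HKY85"),
                             kappa = 2, base_freqs = rep(0.25, 4),
                             seed = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  subst_model <- match.arg(subst_model)
  if (!is.numeric(L) || length(L) != 1L || L < 1)
    .stopf("L must be a count >= 1")
  .with_seed(seed, {
    m <- .evolve_states(tree$edges, as.integer(L), subst_model, kappa,
                        base_freqs)
    setNames(.states_to_strings(m), c("A", "B", "C", "O"))
  })
}
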