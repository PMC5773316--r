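# Synthetic multi-segment loci.  A locus of length L is partitioned into
# geometric segments; each segment carries its own gene genealogy drawn
# from the MSC (optionally with a biased topology mixture, times drawn
# conditional on topology by rejection sampling), and with probability
# `persistence_rho` an adjacent segment reuses the previous genealogy.
# This segmental mechanism is a deliberately simple surrogate for the
# linkage heterogeneity produced by long-term chromosomal shuffling; it
# is not a mechanistic recombination model.

#' Linkage parameters for the segmental locus generator
#'
#' @param mean_segment_length Mean segment length in bp (`>= 1`).  Segment
#'   lengths are geometric on `{1, 2, ...}` with this mean, truncated at
#'   the locus boundary.
#' @param topology_mixture Either `"msc"` (segment genealogies follow the
#'   natural MSC topology frequencies of the model) or a vector of three
#'   probabilities for topologies `AB`, `AC`, `BC` summing to 1 (segment
#'   topologies resampled from this mixture, coalescence times drawn
#'   conditional on topology).  The mixture `c(0.47, 0.29, 0.24)` emulates
#'   the imbalanced regime observed in lineages with extensive karyotype
#'   shuffling.
#' @param persistence_rho Probability in `[0, 1]` that an adjacent segment
#'   reuses the previous segment's genealogy (`1` = classic single-history
#'   locus when combined with long segments).
#' @return A list of class `linkage_params`.
#' @export
linkage_params <- function(mean_segment_length = 350,
                           topology_mixture = "msc",
                           persistence_rho = 0) {
  if (!is.numeric(mean_segment_length) || mean_segment_length < 1)
    .stopf("mean_segment_length must be >= 1")
  if (is.character(topology_mixture)) {
    if (!identical(topology_mixture, "msc"))
      .stopf("topology_mixture must be \"msc\" or 3 probabilities")
  } else {
    if (length(topology_mixture) != 3L || any(topology_mixture < 0) ||
        abs(sum(topology_mixture) - 1) > 1e-8)
      .stopf("topology_mixture must be 3 probabilities summing to 1")
    topology_mixture <- setNames(as.numeric(topology_mixture), .TOPOLOGIES)
  }
  if (!is.numeric(persistence_rho) || persistence_rho < 0 ||
      persistence_rho > 1)
    .stopf("persistence_rho must be in [0, 1]")
  structure(list(mean_segment_length = mean_segment_length,
                 topology_mixture = topology_mixture,
                 persistence_rho = persistence_rho),
            class = "linkage_params")
}

# Buffered gene-tree supplier: draws MSC genealogies in vectorised batches
# and serves them either unconditionally or conditional on topology
# (rejection from the same batches, hence exactly MSC-distributed).
.gene_tree_pool <- function(model, batch = 4096L) {
  buf <- .sim_gene_tree_rows(model, batch)
  queues <- split(seq_len(nrow(buf)), buf$topology)
  cursor_any <- 0L
  refill <- function() {
    buf <<- .sim_gene_tree_rows(model, batch)
    queues <<- split(seq_len(nrow(buf)), buf$topology)
    cursor_any <<- 0L
  }
  draw_any <- function() {
    if (cursor_any >= nrow(buf)) refill()
    cursor_any <<- cursor_any + 1L
    buf[cursor_any, ]
  }
  draw_topology <- function(topo) {
    while (length(queues[[topo]]) == 0L) refill()
    i <- queues[[topo]][1L]
    queues[[topo]] <<- queues[[topo]][-1L]
    buf[i, ]
  }
  list(draw_any = draw_any, draw_topology = draw_topology)
}

.draw_segment_lengths <- function(L, mean_len) {
  if (mean_len >= L) return(L)
  p <- 1 / mean_len
  lens <- integer(0)
  tot <- 0L
  while (tot < L) {
    k <- max(8L, ceiling((L - tot) / mean_len * 2))
    new <- rgeom(k, p) + 1L
    lens <- c(lens, new)
    tot <- tot + sum(new)
  }
  cum <- cumsum(lens)
  keep <- which(cum < L)
  lens <- c(lens[keep], L - if (length(keep)) cum[max(keep)] else 0L)
  lens
}

.generate_locus_impl <- function(model, L, linkage, subst_model, locus_id,
                                 pool) {
  lens <- .draw_segment_lengths(L, linkage$mean_segment_length)
  nseg <- length(lens)
  reuse <- runif(nseg) < linkage$persistence_rho
  reuse[1L] <- FALSE
  mixture <- linkage$topology_mixture
  rows <- vector("list", nseg)
  for (s in seq_len(nseg)) {
    if (reuse[s]) {
      rows[[s]] <- rows[[s - 1L]]
    } else if (identical(mixture, "msc")) {
      rows[[s]] <- pool$draw_any()
    } else {
      topo <- sample(.TOPOLOGIES, 1L, prob = mixture)
      rows[[s]] <- pool$draw_topology(topo)
    }
  }
  segs <- vector("list", nseg)
  for (s in seq_len(nseg)) {
    tree <- gene_tree_from_row(rows[[s]], model)
    segs[[s]] <- .evolve_states(tree$edges, lens[s], subst_model)
  }
  m <- do.call(cbind, segs)
  ends <- cumsum(lens)
  seg_rows <- do.call(rbind, rows)
  segment_map <- data.frame(
    start = ends - lens, end = ends,
    topology = seg_rows$topology,
    t_first = seg_rows$t_first, t_second = seg_rows$t_second,
    t_third = seg_rows$t_third,
    first_pair = seg_rows$first_pair, second_code = seg_rows$second_code,
    stringsAsFactors = FALSE
  )
  structure(
    list(locus_id = locus_id,
         seqs = setNames(.states_to_strings(m), c("A", "B", "C", "O")),
         L = L, taxa = model$taxon_labels, segment_map = segment_map),
    class = "locus_alignment"
  )
}

#' Generate synthetic multi-segment loci under the MSC
#'
#' `generate_locus()` builds one four-taxon locus alignment whose internal
#' segments may follow different gene genealogies; `generate_locus_set()`
#' builds `n_loci` independent loci.  With `persistence_rho = 1` and
#' `mean_segment_length >= L` each locus has a single history (the
#' chromosomally stable regime); with short segments and a biased
#' `topology_mixture` the loci emulate genomes reshaped by extensive
#' chromosomal shuffling.
#'
#' @param model A [species_tree_model()].
#' @param L Locus length in bp.
#' @param linkage A [linkage_params()] object.
#' @param subst_model `"JC69"` (default) or `"HKY85"`.
#' @param locus_id Identifier stored with the locus.
#' @param seed Optional integer seed (for `generate_locus_set`, a single
#'   seed makes the whole set reproducible).
#' @return A `locus_alignment` (fields `locus_id`, `seqs`, `L`,
#'   `segment_map` with 0-based half-open intervals), or a list of them of
#'   class `locus_set`.
#' @examples
#' loci <- generate_locus_set(species_tree_model(), n_loci = 3, L = 500,
#'                            linkage_params(250), seed = 1)
#' loci[[1]]$segment_map
#' @export
generate_locus <- function(model, L, linkage = linkage_params(),
                           subst_model = c("JC69", "HKY85"),
                           locus_id = "locus1", seed = NULL) {
  stopifnot(inherits(model, "species_tree_model"),
            inherits(linkage, "linkage_params"))
  subst_model <- match.arg(subst_model)
  if (!is.numeric(L) || L < 1) .stopf("L must be >= 1")
  .with_seed(seed, {
    pool <- .gene_tree_pool(model)
    .generate_locus_impl(model, as.integer(L), linkage, subst_model,
                         locus_id, pool)
  })
}

#' @rdname generate_locus
#' @param n_loci Number of loci (`>= 1`).
#' @export
generate_locus_set <- function(model, n_loci = 2000, L = 3500,
                               linkage = linkage_params(),
                               subst_model = c("JC69", "HKY85"),
                               seed = NULL) {
  stopifnot(inherits(model, "species_tree_model"),
            inherits(linkage, "linkage_params"))
  subst_model <- match.arg(subst_model)
  if (!is.numeric(n_loci) || n_loci < 1) .stopf("n_loci must be >= 1")
  ids <- sprintf("locus%05d", seq_len(n_loci))
  .with_seed(seed, {
    pool <- .gene_tree_pool(model)
    structure(lapply(seq_len(n_loci), function(i)
      .generate_locus_impl(model, as.integer(L), linkage, subst_model,
                           ids[i], pool)),
      class = "locus_set")
  })
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("Locus %s: 4 x %d bp, %d segment(s) [%s]\n", x$locus_id, x$L,
              nrow(x$segment_map),
              paste(x$segment_map$topology, collapse = ",")))
  invisible(x)
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Set of %d four-taxon loci (%d bp each)\n", length(x),
              x[[1L]]$L))
  invisible(x)
}
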