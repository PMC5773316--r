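# Fragment-length-class sampling design: for each length class, one
# uniformly placed fragment per locus (loci shorter than the class are
# skipped and counted); sampling is independent across classes.

#' Sample fragments of increasing length classes from loci
#'
#' For every length class, draws one fragment per locus with a start
#' position uniform on the valid range (0-based, half-open coordinates).
#' Each locus contributes at most one fragment per class; loci shorter
#' than a class are skipped and counted in the `skipped` attribute.
#'
#' @param loci A `locus_set` (or list of `locus_alignment` objects).
#' @param length_classes Fragment lengths in bp (default the seven classes
#'   50, 100, 200, 500, 1000, 1500, 2000).
#' @param seed Optional integer seed.
#' @return A named list (one element per class, names = class sizes) of
#'   fragment lists; each fragment has `locus_id`, `start`,
#'   `length_class`, and `seqs` (4 subsequences in role order A,B,C,O).
#'   Attribute `skipped` gives per-class counts of loci too short to
#'   sample.
#' @examples
#' loci <- generate_locus_set(species_tree_model(), 5, L = 300,
#'                            linkage_params(300), seed = 1)
#' fr <- sample_fragments(loci, c(50, 200), seed = 2)
#' fr[["200"]][[1]]$start
#' @export
sample_fragments <- function(loci,
                             length_classes = c(50, 100, 200, 500, 1000,
                                                1500, 2000),
                             seed = NULL) {
  if (length(loci) == 0L) .stopf("empty locus set")
  if (any(length_classes < 1)) .stopf("length classes must be >= 1")
  .with_seed(seed, {
    out <- vector("list", length(length_classes))
    names(out) <- as.character(length_classes)
    skipped <- setNames(integer(length(length_classes)),
                        as.character(length_classes))
    lens <- vapply(loci, function(l) l$L, numeric(1))
    for (ci in seq_along(length_classes)) {
      cl <- length_classes[ci]
      eligible <- which(lens >= cl)
      skipped[ci] <- length(loci) - length(eligible)
      starts <- floor(runif(length(eligible)) * (lens[eligible] - cl + 1))
      out[[ci]] <- lapply(seq_along(eligible), function(j) {
        loc <- loci[[eligible[j]]]
        s <- as.integer(starts[j])
        list(locus_id = loc$locus_id, start = s, length_class = cl,
             seqs = vapply(loc$seqs, substr, character(1), s + 1L, s + cl))
      })
    }
    attr(out, "skipped") <- skipped
    out
  })
}

#' Fragment manifest table
#'
#' Flattens the output of [sample_fragments()] into a data frame
#' (`locus_id`, `length_class`, `start`) mirroring the sampling design.
#'
#' @param fragments Output of [sample_fragments()].
#' @return A data frame with one row per sampled fragment.
#' @export
fragment_manifest <- function(fragments) {
  do.call(rbind, lapply(fragments, function(cls)
    do.call(rbind, lapply(cls, function(f)
      data.frame(locus_id = f$locus_id, length_class = f$length_class,
                 start = f$start, stringsAsFactors = FALSE)))))
}
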