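# File formats: multi-locus FASTA with `locusID|role|taxonName` headers
# (role order A,B,C,O preserved within each locus), BED-like segment maps
# (0-based, half-open), Newick gene trees with branch lengths in
# substitutions/site.

#' Read and write four-taxon locus sets as FASTA
#'
#' Loci are stored in a single multi-locus FASTA with headers
#' `locusID|role|taxonName`; within each locus the four roles A, B, C, O
#' must all be present with equal sequence lengths.  Lowercase input is
#' normalised to uppercase (with a message).
#'
#' @param loci A `locus_set` (or list of `locus_alignment` objects).
#' @param path File path.
#' @return `read_fasta`: a `locus_set`; `write_fasta`: `path`, invisibly.
#' @examples
#' loci <- generate_locus_set(species_tree_model(), 2, L = 100,
#'                            linkage_params(100), seed = 1)
#' f <- tempfile(fileext = ".fasta")
#' write_fasta(loci, f)
#' loci2 <- read_fasta(f)
#' identical(loci2[[1]]$seqs, loci[[1]]$seqs)
#' @export
write_fasta <- function(loci, path) {
  seqs <- unlist(lapply(loci, function(l) {
    stopifnot(length(l$seqs) == 4L)
    setNames(unname(l$seqs),
             paste(l$locus_id, c("A", "B", "C", "O"),
                   l$taxa[c("A", "B", "C", "O")], sep = "|"))
  }))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  raw <- readLines(path)
  if (any(grepl("[acgt]", raw[!startsWith(raw, ">")])))
    message("lowercase bases normalised to uppercase")
  x <- Biostrings::readDNAStringSet(path)   # normalises case on parse
  headers <- names(x)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    .stopf("malformed FASTA header (expected locusID|role|taxonName): %s",
           headers[bad][1L])
  meta <- do.call(rbind, parts)
  seqs <- as.character(x)
  ids <- unique(meta[, 1L])
  loci <- lapply(ids, function(id) {
    sel <- meta[, 1L] == id
    roles <- meta[sel, 2L]
    missing_roles <- setdiff(c("A", "B", "C", "O"), roles)
    if (length(missing_roles))
      .stopf("locus %s is missing role(s) %s", id,
             paste(missing_roles, collapse = ", "))
    s <- setNames(seqs[sel], roles)[c("A", "B", "C", "O")]
    if (length(unique(nchar(s))) != 1L)
      .stopf("locus %s has unequal sequence lengths", id)
    structure(
      list(locus_id = id, seqs = s, L = nchar(s[[1L]]),
           taxa = setNames(meta[sel, 3L][match(c("A", "B", "C", "O"),
                                               roles)],
                           c("A", "B", "C", "O")),
           segment_map = NULL),
      class = "locus_alignment"
    )
  })
  structure(loci, class = "locus_set")
}

#' Newick string for a quartet gene tree
#'
#' Serialises a `gene_tree` (or an unresolved topology) as rooted Newick
#' with branch lengths in expected substitutions/site, printed to 10
#' significant digits.  An `"unresolved"` topology yields the star tree
#' `(A,B,C,O);`.
#'
#' @param tree A `gene_tree` from [simulate_gene_tree()], or the string
#'   `"unresolved"`.
#' @param labels Optional tip labels for roles A, B, C, O (defaults to
#'   the tree's taxa).
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, labels = NULL, file = NULL) {
  if (identical(tree, "unresolved")) {
    s <- "(A,B,C,O);"
  } else {
    stopifnot(inherits(tree, "gene_tree"))
    if (is.null(labels)) labels <- unname(tree$taxa)
    fmt <- function(x) formatC(x, digits = 10L, format = "g")
    build <- function(node) {
      kids <- tree$edges$child[tree$edges$parent == node]
      if (length(kids) == 0L) return(labels[node])
      inner <- vapply(kids, function(k) {
        len <- tree$edges$length[tree$edges$parent == node &
                                   tree$edges$child == k]
        paste0(build(k), ":", fmt(len))
      }, character(1))
      paste0("(", paste(inner, collapse = ","), ")")
    }
    root <- setdiff(tree$edges$parent, tree$edges$child)[1L]
    s <- paste0(build(root), ";")
  }
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Write a BED-like segment map
#'
#' One row per locus segment with 0-based half-open coordinates and the
#' generating genealogy's topology and coalescence times.
#'
#' @param loci A `locus_set` whose loci carry `segment_map`s.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segment_map <- function(loci, path) {
  tab <- do.call(rbind, lapply(loci, function(l) {
    if (is.null(l$segment_map)) return(NULL)
    cbind(locus_id = l$locus_id, l$segment_map)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
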