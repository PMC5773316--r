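test_that("JC distance matches its closed form and rejects saturation", {
  expect_equal(jc_distance("ACGTACGTAC", "ACGTACGTAC"), 0)
  # exactly 10% differing sites
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-12)
  b75 <- paste(c(rep("C", 75), rep("A", 25)), collapse = "")
  expect_error(jc_distance(a, b75), "saturated")
  expect_error(jc_distance("NNN", "NNN"), "comparable")
  expect_error(jc_distance("ACGT", "ACG"), "equal length")
})

test_that("the pruning likelihood equals brute-force enumeration over internal states", {
  tr <- manual_gene_tree("AB", tips = c(0.1, 0.2, 0.15, 0.25),
                         internal = 0.05, outer = 0)
  seqs <- evolve_sequences(tr, 50, seed = 51)
  counts <- quartetcoal:::.pattern_counts(seqs)
  for (topo in 1:3) {
    bl <- c(0.1, 0.2, 0.15, 0.3, 0.05)
    expect_equal(
      quartetcoal:::.quartet_lnl_cpp(as.numeric(counts), topo, bl),
      brute_force_lnl(seqs, c("AB", "AC", "BC")[topo], bl),
      tolerance = 1e-8
    )
  }
})

test_that("the likelihood agrees with an independent phylogenetic implementation", {
  tr <- manual_gene_tree("AB", tips = c(0.1, 0.2, 0.15, 0.25),
                         internal = 0.05, outer = 0)
  seqs <- evolve_sequences(tr, 200, seed = 52)
  counts <- quartetcoal:::.pattern_counts(seqs)
  bl <- c(0.07, 0.21, 0.13, 0.29, 0.04)
  ours <- quartetcoal:::.quartet_lnl_cpp(as.numeric(counts), 1L, bl)
  ph_tree <- ape::read.tree(text = sprintf(
    "((A:%g,B:%g):%g,C:%g,O:%g);", bl[1], bl[2], bl[5], bl[3], bl[4]))
  mat <- do.call(rbind, strsplit(unlist(seqs), ""))
  rownames(mat) <- c("A", "B", "C", "O")
  dat <- phangorn::phyDat(mat)
  fit <- phangorn::pml(ph_tree, dat)
  expect_equal(ours, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("ML recovers a clear single-history topology from 2000-bp alignments", {
  tr <- manual_gene_tree("AB", tips = rep(0.02, 4), internal = 0.01,
                         outer = 0.005)
  hits <- 0L
  set.seed(53)
  for (i in 1:200) {
    seqs <- evolve_sequences(tr, 2000)
    if (infer_topology_ml(seqs)$topology == "AB") hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * 200)
})

test_that("degenerate alignments are unresolved with uniform support", {
  seqs <- setNames(rep(paste(rep("A", 100), collapse = ""), 4),
                   c("A", "B", "C", "O"))
  fit <- infer_topology_ml(seqs)
  expect_equal(fit$topology, "unresolved")
  expect_equal(max(fit$lnl) - min(fit$lnl), 0, tolerance = 1e-9)
  expect_equal(fit$support, 1 / 3)
  expect_error(infer_topology_ml(setNames(rep("NNNN", 4),
                                          c("A", "B", "C", "O"))),
               "comparable")
  expect_error(infer_topology_ml(seqs, subst_model = "GTR"), "unknown")
})

test_that("every optimised topology dominates the star tree", {
  set.seed(54)
  m <- model_T(0.3)
  for (i in 1:10) {
    seqs <- evolve_sequences(simulate_gene_tree(m), 300)
    counts <- as.numeric(quartetcoal:::.pattern_counts(seqs))
    star <- quartetcoal:::.quartet_star_lnl_cpp(counts)
    fit <- infer_topology_ml(seqs)
    expect_true(all(fit$lnl >= star - 1e-6))
  }
})

test_that("permuting taxon roles permutes the topology call", {
  tr <- manual_gene_tree("AB", tips = rep(0.02, 4), internal = 0.05)
  seqs <- evolve_sequences(tr, 2000, seed = 55)
  expect_equal(infer_topology_ml(seqs)$topology, "AB")
  swapped <- seqs[c("A", "C", "B", "O")]   # roles B and C exchanged
  names(swapped) <- c("A", "B", "C", "O")
  expect_equal(infer_topology_ml(swapped)$topology, "AC")
})

test_that("parsimony votes follow PI-site pluralities", {
  col <- function(p, n) paste(rep(p, n), collapse = "")
  seqs <- c(A = paste0(col("A", 10), col("A", 2), col("G", 1), col("T", 5)),
            B = paste0(col("A", 10), col("C", 2), col("A", 1), col("T", 5)),
            C = paste0(col("C", 10), col("A", 2), col("A", 1), col("T", 5)),
            O = paste0(col("C", 10), col("C", 2), col("G", 1), col("T", 5)))
  fit <- infer_topology_parsimony(seqs)
  expect_equal(fit$topology, "AB")
  expect_equal(unname(fit$votes), c(10L, 2L, 1L))
  # one AB column and one AC column: exact tie
  votes_tie <- infer_topology_parsimony(
    c(A = "AC", B = "AG", C = "CC", O = "CG"))
  expect_equal(votes_tie$topology, "unresolved")
})

test_that("parsimony and ML calls agree on most resolved single-history fragments", {
  m <- model_T(0.3)
  loci <- generate_locus_set(m, 500, L = 500,
                             linkage = linkage_params(500, "msc", 1),
                             seed = 56)
  ml <- vapply(loci, function(l) infer_topology_ml(l)$topology, character(1))
  pars <- vapply(loci, function(l) infer_topology_parsimony(l)$topology,
                 character(1))
  both <- ml != "unresolved" & pars != "unresolved"
  expect_gt(sum(both), 100)
  expect_gte(mean(ml[both] == pars[both]), 0.90)
})

test_that("topology support grows with fragment length", {
  m <- model_T(0.3)
  mean_support <- vapply(c(100, 500, 2000), function(L) {
    loci <- generate_locus_set(m, 80, L = L,
                               linkage = linkage_params(L, "msc", 1),
                               seed = 57)
    mean(vapply(loci, function(l) infer_topology_ml(l)$support, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_support) > 0))
})
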