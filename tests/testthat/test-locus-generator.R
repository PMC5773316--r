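test_that("zero branch lengths leave all four sequences identical", {
  tr <- manual_gene_tree(tips = rep(0, 4), internal = 0, outer = 0)
  seqs <- evolve_sequences(tr, 300, seed = 21)
  expect_equal(length(unique(seqs)), 1L)
})

test_that("pairwise divergence follows the JC expectation", {
  # A-B path length d = 0.1; all other branches zero
  tr <- manual_gene_tree(tips = c(0.05, 0.05, 0, 0), internal = 0,
                         outer = 0)
  seqs <- evolve_sequences(tr, 1e5, seed = 22)
  p_expected <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(pdist(seqs[["A"]], seqs[["B"]]) - p_expected),
            4 * binom_se(p_expected, 1e5))
})

test_that("HKY85 with kappa = 1 and equal frequencies reduces to JC69", {
  tr <- manual_gene_tree(tips = c(0.08, 0.08, 0, 0), internal = 0,
                         outer = 0)
  s_jc <- evolve_sequences(tr, 4e4, subst_model = "JC69", seed = 23)
  s_hky <- evolve_sequences(tr, 4e4, subst_model = "HKY85", kappa = 1,
                            seed = 24)
  p_jc <- pdist(s_jc[["A"]], s_jc[["B"]])
  p_hky <- pdist(s_hky[["A"]], s_hky[["B"]])
  se <- sqrt(p_jc * (1 - p_jc) / 4e4 + p_hky * (1 - p_hky) / 4e4)
  expect_lt(abs(p_jc - p_hky), 4 * se)
})

transition_share <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  d <- x != y
  ts <- (x %in% c("A", "G") & y %in% c("A", "G")) |
    (x %in% c("C", "T") & y %in% c("C", "T"))
  sum(d & ts) / sum(d)
}

test_that("the HKY85 kappa parameter biases differences towards transitions", {
  tr <- manual_gene_tree(tips = c(0.08, 0.08, 0, 0), internal = 0,
                         outer = 0)
  s_hky <- evolve_sequences(tr, 4e4, subst_model = "HKY85", kappa = 8,
                            seed = 25)
  s_jc <- evolve_sequences(tr, 4e4, subst_model = "JC69", seed = 26)
  expect_gt(transition_share(s_hky[["A"]], s_hky[["B"]]),
            transition_share(s_jc[["A"]], s_jc[["B"]]) + 0.1)
})

test_that("segment counts match the memoryless segmentation expectation", {
  m <- model_T(0.3)
  loci <- generate_locus_set(m, 400, L = 3500,
                             linkage = linkage_params(350), seed = 27)
  counts <- vapply(loci, function(l) nrow(l$segment_map), numeric(1))
  # geometric cuts: 1 + Binomial(L - 1, 1/mean) interior boundaries
  expected <- 1 + (3500 - 1) / 350
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("segment maps partition the locus", {
  loci <- generate_locus_set(model_T(0.3), 20, L = 1000,
                             linkage = linkage_params(150), seed = 28)
  for (l in loci) {
    sm <- l$segment_map
    expect_equal(sm$start[1], 0)
    expect_equal(sm$end[nrow(sm)], l$L)
    expect_equal(sm$start[-1], sm$end[-nrow(sm)])
    expect_true(all(sm$end > sm$start))
    expect_equal(sum(nchar(l$seqs) == l$L), 4L)
  }
})

test_that("a biased topology mixture controls the per-topology base-pair share", {
  mix <- c(0.47, 0.29, 0.24)
  loci <- generate_locus_set(model_T(0.3), 300, L = 3500,
                             linkage = linkage_params(350, mix, 0),
                             seed = 29)
  share <- sapply(loci, function(l) {
    bp <- tapply(l$segment_map$end - l$segment_map$start,
                 factor(l$segment_map$topology, levels = c("AB", "AC", "BC")),
                 sum, default = 0)
    bp / sum(bp)
  })
  for (i in 1:3) {
    se <- sd(share[i, ]) / sqrt(ncol(share))
    expect_lt(abs(mean(share[i, ]) - mix[i]), 4 * se)
  }
})

test_that("full persistence with long segments gives single-history loci", {
  loc <- generate_locus(model_T(0.3), 800,
                        linkage_params(mean_segment_length = 800,
                                       persistence_rho = 1), seed = 30)
  expect_equal(nrow(loc$segment_map), 1L)
  # short segments but rho = 1: all segments share one genealogy
  loc2 <- generate_locus(model_T(0.3), 800,
                         linkage_params(mean_segment_length = 100,
                                        persistence_rho = 1), seed = 31)
  expect_equal(length(unique(loc2$segment_map$t_first)), 1L)
  expect_equal(length(unique(loc2$segment_map$topology)), 1L)
})

test_that("locus generation is reproducible under a fixed seed", {
  a <- generate_locus_set(model_T(0.3), 5, L = 400,
                          linkage = linkage_params(100), seed = 32)
  b <- generate_locus_set(model_T(0.3), 5, L = 400,
                          linkage = linkage_params(100), seed = 32)
  expect_identical(lapply(a, `[[`, "seqs"), lapply(b, `[[`, "seqs"))
  expect_identical(lapply(a, `[[`, "segment_map"),
                   lapply(b, `[[`, "segment_map"))
})
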