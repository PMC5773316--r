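test_that("simulated genealogies respect the species-tree constraints", {
  m <- model_T(0.3)
  rows <- simulate_gene_trees(m, 2000, seed = 11)
  expect_true(all(rows$t_first <= rows$t_second))
  expect_true(all(rows$t_second <= rows$t_third))
  expect_true(all(rows$t_first >= m$tau_AB))
  # mismatch topologies require the internode to be crossed
  mis <- rows$topology != "AB"
  expect_true(all(rows$t_first[mis] >= m$tau_ABC))
  # coalescences involving the outgroup happen above the root
  expect_true(all(rows$t_first[rows$first_pair >= 4L] >= m$tau_root))
  # reproducibility
  expect_identical(rows, simulate_gene_trees(m, 2000, seed = 11))
  expect_error(simulate_gene_trees(m, 0), "count")
})

test_that("gene tree reconstruction yields a valid four-tip genealogy", {
  m <- model_T(0.3)
  rows <- simulate_gene_trees(m, 50, seed = 12)
  for (i in seq_len(10)) {
    tr <- gene_tree_from_row(rows[i, ], m)
    expect_equal(nrow(tr$edges), 6)
    expect_true(all(tr$edges$time_length >= 0))
    expect_setequal(tr$edges$child, 1:6)
    expect_equal(setdiff(tr$edges$parent, tr$edges$child), 7)
    expect_equal(tr$edges$length, tr$edges$time_length * m$mu)
  }
})

test_that("instant coalescence in the (A,B) ancestor forces the AB topology", {
  m <- species_tree_model(N = c(A = 1e4, B = 1e4, C = 1e4, O = 1e4,
                                AB = 1e-3, ABC = 1e4, root = 1e4))
  rows <- simulate_gene_trees(m, 500, seed = 13)
  expect_true(all(rows$topology == "AB"))
  expect_lt(max(rows$t_first - m$tau_AB), 1)
})

test_that("a vanishing internode gives the symmetric star-tree limit", {
  m <- model_T(0)
  counts <- simulate_topology_distribution(m, 30000, seed = 14)
  se <- binom_se(1 / 3, 30000)
  expect_true(all(abs(counts / 30000 - 1 / 3) < 4 * se))
})

test_that("topology frequencies match the closed form at T = 0.5", {
  counts <- simulate_topology_distribution(model_T(0.5), 1e5, seed = 15)
  p <- match_probability(0.5)
  expect_lt(abs(counts[["AB"]] / 1e5 - p), 4 * binom_se(p, 1e5))
})

test_that("the two mismatch classes are exchangeable", {
  m <- model_T(0.3)
  rows <- simulate_gene_trees(m, 1e5, seed = 16)
  pmis <- mismatch_probability(0.3)
  f <- table(factor(rows$topology, levels = c("AB", "AC", "BC"))) / 1e5
  se_diff <- sqrt(2 * pmis / 1e5)
  expect_lt(abs(f[["AC"]] - f[["BC"]]), 4 * se_diff)
  # equal mean first-coalescence times, both above the second split
  tAC <- rows$t_first[rows$topology == "AC"]
  tBC <- rows$t_first[rows$topology == "BC"]
  expect_true(min(tAC, tBC) >= m$tau_ABC)
  se_t <- sqrt(var(tAC) / length(tAC) + var(tBC) / length(tBC))
  expect_lt(abs(mean(tAC) - mean(tBC)), 4 * se_t)
})

test_that("one allele per species reduces the multi-allele simulator to the single-allele law", {
  m <- model_T(0.5)
  calls <- simulate_species_calls(m, k = 1, n = 3000, seed = 17)
  expect_equal(sum(calls), 3000)
  expect_equal(calls[["unresolved"]], 0)
  p <- match_probability(0.5)
  expect_lt(abs(calls[["AB"]] / 3000 - p), 4 * binom_se(p, 3000))
})

test_that("tiny ancestral populations make the species-level call deterministic", {
  m <- species_tree_model(N = c(A = 1e-3, B = 1e-3, C = 1e-3, O = 1e-3,
                                AB = 1e-3, ABC = 1e-3, root = 1e-3))
  calls <- simulate_species_calls(m, k = 3, n = 20, seed = 18)
  expect_equal(calls[["AB"]], 20)
})

test_that("multi-allele genealogies are ultrametric with consistent pair times", {
  g <- simulate_multi_allele(model_T(0.3), k = 3, seed = 19)
  expect_equal(length(g$tree$tip.label), 12)
  expect_true(all(g$tree$edge.length >= 0))
  expect_true(ape::is.ultrametric(g$tree, tol = 1e-8))
  # pairwise coalescence times agree with the tree's cophenetic depths
  coph <- ape::cophenetic.phylo(g$tree) / (2 * model_T(0.3)$mu)
  M <- g$pair_times
  dimnames(M) <- list(g$tree$tip.label, g$tree$tip.label)
  for (i in c(1, 5, 9)) for (j in c(3, 7, 12)) {
    expect_equal(M[g$tree$tip.label[i], g$tree$tip.label[j]],
                 coph[g$tree$tip.label[i], g$tree$tip.label[j]],
                 tolerance = 1e-8)
  }
  expect_true(g$call %in% c("AB", "AC", "BC", "unresolved"))
  expect_equal(sum(g$quartet_counts), 3^4)
})
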