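test_that("column classification agrees with exhaustive enumeration", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(A = bases, B = bases, C = bases, O = bases,
                      stringsAsFactors = FALSE)
  # independent brute-force classification
  oracle <- apply(grid, 1L, function(r) {
    if (r[1] == r[2] && r[3] == r[4] && r[1] != r[3]) "AB"
    else if (r[1] == r[3] && r[2] == r[4] && r[1] != r[2]) "AC"
    else if (r[2] == r[3] && r[1] == r[4] && r[1] != r[2]) "BC"
    else "none"
  })
  ours <- apply(grid, 1L, classify_column)
  expect_identical(ours, oracle)
  expect_equal(unname(table(oracle)[c("AB", "AC", "BC")]),
               rep(12L, 3), ignore_attr = TRUE)
  expect_equal(sum(oracle != "none"), 36L)
})

test_that("gaps and ambiguity codes void a column", {
  expect_equal(classify_column(c("A", "A", "-", "C")), "none")
  expect_equal(classify_column(c("A", "A", "N", "N")), "none")
  expect_equal(classify_column(c("A", "A", "C", "C")), "AB")
  expect_error(classify_column(c("A", "A", "C")), "4 bases")
})

test_that("alignment scans are positionally correct and additive", {
  mk <- function(id, a, b, c, o)
    list(locus_id = id, seqs = c(A = a, B = b, C = c, O = o))
  l1 <- mk("x", "AACT", "AACT", "CACT", "CACT")   # AB site at position 0
  expect_equal(scan_alignment(l1),
               data.frame(locus_id = "x", position = 0L, topology = "AB",
                          stringsAsFactors = FALSE))
  l_empty <- mk("y", "ACGT", "ACGT", "ACGT", "ACGT")
  expect_equal(nrow(scan_alignment(l_empty)), 0L)
  # concatenation = union of scans with offset positions
  l2 <- mk("x", "GGTT", "GGCC", "TGTC", "TGCT")
  cat12 <- mk("x", "AACTGGTT", "AACTGGCC", "CACTTGTC", "CACTTGCT")
  s1 <- scan_alignment(l1); s2 <- scan_alignment(l2)
  s2$position <- s2$position + 4L
  expect_equal(scan_alignment(cat12), rbind(s1, s2), ignore_attr = TRUE)
})

test_that("a strong AB history makes AB sites the plurality class", {
  tr <- manual_gene_tree("AB", tips = rep(0.02, 4), internal = 0.05)
  seqs <- evolve_sequences(tr, 1e4, seed = 61)
  rec <- scan_alignment(list(locus_id = "sim", seqs = seqs))
  counts <- table(factor(rec$topology, levels = c("AB", "AC", "BC")))
  expect_true(counts[["AB"]] > counts[["AC"]])
  expect_true(counts[["AB"]] > counts[["BC"]])
})

test_that("adjacent same-topology distances are computed within loci only", {
  rec <- data.frame(
    locus_id = c("l1", "l1", "l1", "l2", "l2"),
    position = c(5L, 105L, 300L, 7L, 20L),
    topology = c("AB", "AB", "AC", "AB", "AB"),
    stringsAsFactors = FALSE
  )
  d <- adjacent_same_topology_distances(rec)
  expect_equal(d$AB, c(100L, 13L))
  expect_equal(d$AC, integer(0))      # single record: no pair
  expect_equal(d$BC, integer(0))
})

test_that("random record sets match a brute-force distance recomputation", {
  set.seed(62)
  rec <- data.frame(
    locus_id = sample(paste0("l", 1:5), 200, replace = TRUE),
    position = sample.int(2000, 200),
    topology = sample(c("AB", "AC", "BC"), 200, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rec <- rec[!duplicated(rec[c("locus_id", "position")]), ]
  d <- adjacent_same_topology_distances(rec)
  for (topo in c("AB", "AC", "BC")) {
    brute <- c()
    for (loc in unique(rec$locus_id)) {
      p <- sort(rec$position[rec$locus_id == loc & rec$topology == topo])
      if (length(p) > 1) for (i in 2:length(p)) brute <- c(brute, p[i] - p[i - 1])
    }
    expect_equal(sort(d[[topo]]), sort(as.integer(brute)),
                 ignore_attr = TRUE)
  }
})

test_that("binned topology frequencies normalise within bins", {
  rec <- data.frame(locus_id = "l1",
                    position = c(0L, 10L, 30L, 500L, 900L),
                    topology = c("AB", "AB", "AB", "AB", "AB"),
                    stringsAsFactors = FALSE)
  tab <- distance_binned_topology_freq(rec, bin_edges = c(0, 100, 1000))
  expect_equal(tab$freq_AB[!tab$empty], rep(1, sum(!tab$empty)))
  rowsum <- rowSums(tab[!tab$empty, c("freq_AB", "freq_AC", "freq_BC")])
  expect_equal(rowsum, rep(1, sum(!tab$empty)), ignore_attr = TRUE)
  expect_error(distance_binned_topology_freq(rec, bin_edges = c(5, 2)),
               "increasing")
  rec0 <- rec[1, ]
  expect_error(distance_binned_topology_freq(rec0), "no adjacent")
})

test_that("unbiased single-history loci give symmetric mismatch PI classes at large distances", {
  loci <- generate_locus_set(model_T(0.3), 300, L = 3500,
                             linkage = linkage_params(3500, "msc", 1),
                             seed = 63)
  rec <- do.call(rbind, lapply(loci, scan_alignment))
  tab <- distance_binned_topology_freq(rec)
  big <- max(which(!tab$empty & tab$n >= 50))
  n_mis <- round(tab$n[big] * (tab$freq_AC[big] + tab$freq_BC[big]))
  se <- sqrt(0.25 / n_mis)
  p_ac <- tab$freq_AC[big] / (tab$freq_AC[big] + tab$freq_BC[big])
  expect_lt(abs(p_ac - 0.5), 4 * se)
})
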