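# Per-length-class discordance summaries: topology frequencies with
# Wilson intervals, mismatch-frequency imbalance with an exact binomial
# test (under the standard MSC the two mismatch topologies are equally
# probable, so their counts are Binomial(m, 1/2)), cherry-depth and
# support summaries, and the coalescent-unit internode estimate implied
# by the match frequency.

.mismatch_of <- function(species_topology) setdiff(.TOPOLOGIES,
                                                   species_topology)

.as_trees_df <- function(trees) {
  if (is.data.frame(trees)) {
    if (!"topology" %in% names(trees)) .stopf("trees need a 'topology' column")
    if (is.null(trees$support)) trees$support <- NA_real_
    if (is.null(trees$cherry_depth)) trees$cherry_depth <- NA_real_
    return(trees)
  }
  .stopf("trees must be a data frame (see infer_gene_trees())")
}

#' Summarise inferred gene trees of one fragment-length class
#'
#' @param trees Data frame of inferred gene trees (see
#'   [infer_gene_trees()]); minimally a `topology` column with values in
#'   `AB`, `AC`, `BC`, `unresolved`; `support` and `cherry_depth` are used
#'   when present.
#' @param length_class Fragment length in bp (annotation only).
#' @param species_topology The species-tree quartet topology (default
#'   `"AB"`).
#' @param min_support Optional support filter: resolved trees with
#'   support below this value are dropped before counting (default 0, no
#'   filter).
#' @return One-row data frame of class `length_class_report`:
#'   counts (`n_AB`, `n_AC`, `n_BC`, `n_unresolved`), frequencies over
#'   resolved trees with 95% Wilson CIs, the match frequency,
#'   `imbalance_delta` = |f_mismatch1 - f_mismatch2|, `imbalance_pvalue`
#'   (two-sided exact binomial test of the mismatch counts against 1/2),
#'   per-class mean/variance of `cherry_depth`, `mean_support`, and the
#'   internode estimate `T_hat` with CI from
#'   [internode_from_match_freq()] (`NA` when the match frequency is
#'   below the MSC minimum of 1/3).
#' @examples
#' trees <- data.frame(topology = rep(c("AB", "AC", "BC"), c(47, 29, 24)))
#' summarize_length_class(trees, length_class = 2000)$imbalance_delta
#' @export
summarize_length_class <- function(trees, length_class = NA,
                                   species_topology = "AB",
                                   min_support = 0) {
  trees <- .as_trees_df(trees)
  if (!species_topology %in% .TOPOLOGIES)
    .stopf("species_topology must be one of AB, AC, BC")
  if (min_support > 0) {
    keep <- trees$topology == "unresolved" |
      (!is.na(trees$support) & trees$support >= min_support)
    trees <- trees[keep, , drop = FALSE]
  }
  resolved <- trees[trees$topology %in% .TOPOLOGIES, , drop = FALSE]
  n_res <- nrow(resolved)
  if (n_res == 0L) .stopf("zero resolved trees in this length class")
  counts <- table(factor(resolved$topology, levels = .TOPOLOGIES))
  mm <- .mismatch_of(species_topology)
  f <- as.numeric(counts) / n_res
  names(f) <- .TOPOLOGIES
  ci <- vapply(.TOPOLOGIES, function(t) .wilson_ci(counts[[t]], n_res),
               numeric(2))
  m1 <- counts[[mm[1]]]; m2 <- counts[[mm[2]]]
  pval <- if (m1 + m2 == 0L) NA_real_ else
    binom.test(m1, m1 + m2, p = 0.5)$p.value
  depth_stats <- lapply(.TOPOLOGIES, function(t) {
    d <- resolved$cherry_depth[resolved$topology == t]
    d <- d[!is.na(d)]
    c(mean = if (length(d)) mean(d) else NA_real_,
      var = if (length(d) > 1L) var(d) else NA_real_)
  })
  names(depth_stats) <- .TOPOLOGIES
  p_match <- f[[species_topology]]
  est <- if (p_match >= 1 / 3 && p_match < 1)
    internode_from_match_freq(p_match, n_trees = n_res) else NULL
  out <- data.frame(
    length_class = length_class,
    n_total = nrow(trees), n_resolved = n_res,
    n_AB = counts[["AB"]], n_AC = counts[["AC"]], n_BC = counts[["BC"]],
    n_unresolved = sum(trees$topology == "unresolved"),
    freq_AB = f[["AB"]], freq_AB_lo = ci[1, "AB"], freq_AB_hi = ci[2, "AB"],
    freq_AC = f[["AC"]], freq_AC_lo = ci[1, "AC"], freq_AC_hi = ci[2, "AC"],
    freq_BC = f[["BC"]], freq_BC_lo = ci[1, "BC"], freq_BC_hi = ci[2, "BC"],
    match_freq = p_match,
    imbalance_delta = abs(f[[mm[1]]] - f[[mm[2]]]),
    imbalance_pvalue = pval,
    depth_mean_AB = depth_stats$AB[["mean"]],
    depth_mean_AC = depth_stats$AC[["mean"]],
    depth_mean_BC = depth_stats$BC[["mean"]],
    depth_var_AB = depth_stats$AB[["var"]],
    depth_var_AC = depth_stats$AC[["var"]],
    depth_var_BC = depth_stats$BC[["var"]],
    mean_support = mean(resolved$support, na.rm = TRUE),
    T_hat = if (is.null(est)) NA_real_ else est$T_hat,
    T_ci_low = if (is.null(est)) NA_real_ else est$ci_low,
    T_ci_high = if (is.null(est)) NA_real_ else est$ci_high,
    stringsAsFactors = FALSE
  )
  class(out) <- c("length_class_report", class(out))
  out
}

#' Cherry-depth difference between the two mismatch topologies
#'
#' Signed difference of the mean cherry depth (coalescence-time proxy in
#' substitutions/site) between the two mismatch topology classes, with
#' per-class summaries and the standard error of the difference.
#'
#' @inheritParams summarize_length_class
#' @return List with `difference` (mean depth of the first mismatch class
#'   minus the second, in the order given by
#'   `setdiff(c("AB","AC","BC"), species_topology)`), `se`, and a
#'   `classes` data frame (`topology`, `n`, `mean`, `sd`).  A mismatch
#'   class with no trees yields `difference = NA` and is flagged via
#'   `n = 0`.
#' @export
mismatch_depth_difference <- function(trees, species_topology = "AB") {
  trees <- .as_trees_df(trees)
  mm <- .mismatch_of(species_topology)
  cls <- lapply(mm, function(t) {
    d <- trees$cherry_depth[trees$topology == t]
    d[!is.na(d)]
  })
  n <- lengths(cls)
  stats <- data.frame(
    topology = mm, n = n,
    mean = vapply(cls, function(d) if (length(d)) mean(d) else NA_real_,
                  numeric(1)),
    sd = vapply(cls, function(d) if (length(d) > 1) sd(d) else NA_real_,
                numeric(1)),
    stringsAsFactors = FALSE
  )
  diff_val <- if (all(n > 0L)) stats$mean[1] - stats$mean[2] else NA_real_
  se <- if (all(n > 1L)) sqrt(sum(stats$sd^2 / stats$n)) else NA_real_
  list(difference = diff_val, se = se, classes = stats)
}

#' Trend of mismatch imbalance across fragment-length classes
#'
#' Spearman rank correlation between `imbalance_delta` and the fragment
#' length class, with a one-sided (increasing-trend) permutation p-value:
#' exact enumeration of all permutations when there are at most 7 classes,
#' otherwise 10^4 seeded random permutations.
#'
#' @param reports A list of [summarize_length_class()] reports, or a data
#'   frame with columns `length_class` and `imbalance_delta`.
#' @param n_perm Number of random permutations when exact enumeration is
#'   not used.
#' @param seed Optional seed for the random permutations.
#' @return List with `table` (classes and deltas), `rho`, `p_value`, and
#'   `method` (`"exact"` or `"permutation"`).  Constant deltas give
#'   `rho = 0`, `p_value = 1`.
#' @export
trend_across_classes <- function(reports, n_perm = 1e4, seed = NULL) {
  tab <- if (is.data.frame(reports)) reports else
    do.call(rbind, lapply(reports, as.data.frame))
  if (!all(c("length_class", "imbalance_delta") %in% names(tab)))
    .stopf("reports must provide length_class and imbalance_delta")
  tab <- tab[order(tab$length_class), , drop = FALSE]
  k <- nrow(tab)
  if (k < 3L) .stopf("need at least 3 length classes for a trend")
  x <- as.numeric(tab$length_class)
  y <- as.numeric(tab$imbalance_delta)
  if (sd(y) == 0) {
    return(list(table = tab, rho = 0, p_value = 1, method = "degenerate"))
  }
  rho <- cor(x, y, method = "spearman")
  rx <- rank(x)
  ry <- rank(y)
  stat <- function(perm) cor(rx, ry[perm])   # Spearman = Pearson on ranks
  if (k <= 7L) {
    perms <- .all_permutations(k)
    stats <- apply(perms, 1L, stat)
    p <- mean(stats >= rho - 1e-12)
    method <- "exact"
  } else {
    p <- .with_seed(seed, {
      stats <- replicate(n_perm, stat(sample.int(k)))
      (sum(stats >= rho - 1e-12) + 1) / (n_perm + 1)
    })
    method <- "permutation"
  }
  list(table = tab, rho = rho, p_value = p, method = method)
}

.all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (pos in seq_len(k)) {
    block <- cbind(sub, k)[, append(seq_len(k - 1L), k, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}
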