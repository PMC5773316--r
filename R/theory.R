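#' Probability that a quartet gene tree matches the species tree
#'
#' Under the multispecies coalescent for a rooted species tree
#' `(((A,B),C),O)` with an internal branch of `T` coalescent units (one
#' coalescent unit = 2N generations for a diploid population of effective
#' size N), the probability that a gene tree displays the species-tree
#' quartet `AB | CO` is
#' \deqn{p(T) = 1 - \frac{2}{3} e^{-T}.}
#' The two discordant (mismatch) topologies each have probability
#' \eqn{\frac{1}{3} e^{-T}}, so the three probabilities sum to one and the
#' mismatch topologies are equally frequent for every `T`.
#'
#' @param T Internal ("internode") branch length in coalescent units;
#'   non-negative, finite.  Vectorised.
#' @return `match_probability`: probability in `[1/3, 1)`, strictly
#'   increasing in `T`.  `mismatch_probability`: the probability of *each*
#'   of the two discordant topologies, in `(0, 1/3]`, strictly decreasing.
#' @examples
#' match_probability(0)        # 1/3, the star-tree limit
#' match_probability(0.1924)   # 0.45
#' mismatch_probability(1.1)   # ~0.111: deep-split regime
#' @seealso [internode_from_match_freq()] for the inverse mapping.
#' @export
match_probability <- function(T) {
  .check_internode(T)
  1 - (2 / 3) * exp(-T)
}

#' @rdname match_probability
#' @export
mismatch_probability <- function(T) {
  .check_internode(T)
  (1 / 3) * exp(-T)
}

.check_internode <- function(T) {
  if (!is.numeric(T) || length(T) < 1L)
    .stopf("internode length must be numeric")
  if (any(!is.finite(T)) || any(T < 0))
    .stopf("invalid internode length: T must be finite and >= 0")
  invisible(T)
}

#' Internode length in coalescent units from a gene-tree match frequency
#'
#' Inverts the match-probability curve of the multispecies coalescent:
#' given the proportion `p_match` of gene trees whose quartet topology
#' matches the species tree, the internal branch between the two ingroup
#' splits is estimated as
#' \deqn{\hat T = -\ln\!\left(\tfrac{3}{2} (1 - p)\right).}
#' When the number of gene trees `n_trees` is supplied, a 95% Wilson score
#' interval for `p_match` is pushed through the same inversion to give a
#' confidence interval for `T` (bounds below the MSC minimum of 1/3 are
#' clamped to `T = 0`).
#'
#' @param p_match Observed match proportion; must satisfy
#'   `1/3 <= p_match < 1`.  A frequency below 1/3 is impossible under the
#'   MSC and raises an error.
#' @param n_trees Optional number of gene trees behind `p_match`, used for
#'   the confidence interval.
#' @param conf Confidence level for the Wilson interval (default 0.95).
#' @return An object of class `msc_estimate`: a list with `p_match`,
#'   `n_trees`, `T_hat`, `ci_low`, `ci_high`.
#' @examples
#' internode_from_match_freq(0.450)            # T_hat ~ 0.19
#' internode_from_match_freq(0.621, n_trees = 15744)
#' @export
internode_from_match_freq <- function(p_match, n_trees = NULL, conf = 0.95) {
  if (!is.numeric(p_match) || length(p_match) != 1L || !is.finite(p_match))
    .stopf("p_match must be a single finite number")
  if (p_match >= 1)
    .stopf("p_match must be < 1: a match frequency of 1 implies an infinite internode")
  if (p_match < 1 / 3)
    .stopf("anomalous match frequency below MSC minimum (p_match < 1/3)")
  T_hat <- .invert_match(p_match)
  ci_low <- ci_high <- NA_real_
  if (!is.null(n_trees)) {
    if (!is.numeric(n_trees) || length(n_trees) != 1L || n_trees < 1)
      .stopf("n_trees must be a positive count")
    ci_p <- .wilson_ci(round(p_match * n_trees), n_trees, conf)
    ci_low <- .invert_match(max(ci_p[1], 1 / 3))
    ci_high <- if (ci_p[2] >= 1) Inf else .invert_match(ci_p[2])
  }
  structure(
    list(p_match = p_match, n_trees = n_trees, T_hat = T_hat,
         ci_low = ci_low, ci_high = ci_high),
    class = "msc_estimate"
  )
}

.invert_match <- function(p) {
  if (p <= 1 / 3) return(0)
  -log(1.5 * (1 - p))
}

#' @export
print.msc_estimate <- function(x, ...) {
  cat(sprintf("MSC internode estimate: T_hat = %.4f coalescent units (p_match = %.4f",
              x$T_hat, x$p_match))
  if (!is.null(x$n_trees)) {
    cat(sprintf(", n = %d)\n  95%% CI: [%.4f, %.4f]\n",
                as.integer(x$n_trees), x$ci_low, x$ci_high))
  } else cat(")\n")
  invisible(x)
}
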