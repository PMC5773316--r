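# Shared fixtures: models with a given internode, hand-built gene trees,
# and an independent JC likelihood oracle based on matrix exponentials.

model_T <- function(T, ...) model_with_internode(species_tree_model(...), T)

# Gene tree with prescribed branch lengths (substitutions/site).
# topology in AB/AC/BC; tips = lengths for A,B,C,O; internal as given.
# Built as the caterpillar ((cherry):internal, third):outer, O.
manual_gene_tree <- function(topology = "AB", tips = rep(0.02, 4),
                             internal = 0.01, outer = 0.005) {
  first_pair <- match(topology, c("AB", "AC", "BC"))
  row <- data.frame(topology = topology, t_first = 1, t_second = 2,
                    t_third = 3, first_pair = first_pair, second_code = 1L)
  tr <- gene_tree_from_row(row, species_tree_model())
  cherry <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))[[first_pair]]
  third <- setdiff(1:3, cherry)
  len <- numeric(6)
  for (i in seq_len(6)) {
    ch <- tr$edges$child[i]
    len[i] <- if (ch <= 4L) tips[ch] else if (ch == 5L) internal else outer
  }
  tr$edges$length <- len
  tr$edges$time_length <- len / tr$mu
  tr
}

# JC transition matrix by matrix exponential of the rate matrix
# (spectral decomposition; independent of the closed form in the package).
jc_pmat_expm <- function(d) {
  Q <- matrix(1 / 3, 4, 4)
  diag(Q) <- -1
  es <- eigen(Q, symmetric = TRUE)
  es$vectors %*% diag(exp(es$values * d)) %*% t(es$vectors)
}

# Brute-force JC log-likelihood of a quartet topology: explicit sum over
# the two internal-node states for every site.
brute_force_lnl <- function(seqs, topology, bl) {
  code <- setNames(1:4, c("A", "C", "G", "T"))
  mat <- do.call(rbind, lapply(seqs, function(s)
    code[strsplit(s, "")[[1]]]))
  pair <- list(AB = c(1, 2), AC = c(1, 3), BC = c(2, 3))[[topology]]
  far <- setdiff(1:4, pair)
  P <- lapply(bl[1:4], jc_pmat_expm)
  P5 <- jc_pmat_expm(bl[5])
  lnl <- 0
  for (site in seq_len(ncol(mat))) {
    s <- mat[, site]
    prob <- 0
    for (x in 1:4) for (y in 1:4) {
      prob <- prob + 0.25 *
        P[[pair[1]]][x, s[pair[1]]] * P[[pair[2]]][x, s[pair[2]]] *
        P5[x, y] *
        P[[far[1]]][y, s[far[1]]] * P[[far[2]]][y, s[far[2]]]
    }
    lnl <- lnl + log(prob)
  }
  lnl
}

# p-distance between two sequences
pdist <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  mean(x != y)
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)
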