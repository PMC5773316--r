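# quartetcoal

Simulation and inference toolkit for studying how **sequence fragment
length** interacts with the **multispecies coalescent (MSC)** in
four-taxon phylogenies.

## The problem

For a rooted species tree `(((A,B),C),O)` whose internal branch between
the `(A,B)` and `((A,B),C)` splits spans `T` coalescent units
(1 unit = 2N generations, diploid), the MSC predicts the gene-tree
quartet frequencies

```
P(AB | CO) = 1 - (2/3) e^(-T)        (match)
P(AC | BO) = P(BC | AO) = (1/3) e^(-T)   (the two mismatch topologies)
```

so the two mismatch topologies are equally frequent, and the observed
match frequency `p` can be inverted, `T = -ln((3/2)(1 - p))`, to
estimate the internode in coalescent units.  These predictions assume
every locus carries a single coalescent history.  In genomes reshaped by
extensive chromosomal rearrangement, long fragments mix sites with
different histories, and the mismatch-frequency *imbalance* becomes a
length-dependent diagnostic of that violation.

`quartetcoal` implements the full analysis for people working on
gene-tree discordance and phylogenomic experimental design:

* closed-form MSC quartet probabilities and their inversion (with
  Wilson-interval CIs) — `match_probability()`,
  `internode_from_match_freq()`;
* a four-species MSC genealogy simulator, single- and multi-allele
  (per-branch effective sizes, structured coalescent) —
  `simulate_gene_trees()`, `simulate_multi_allele()`,
  `unequal_ne_model()`;
* a synthetic-locus generator whose geometric segments may follow
  different genealogies, with an optional biased topology mixture
  (0.47/0.29/0.24) emulating shuffled karyotypes —
  `generate_locus_set()`, `linkage_params()`;
* the fragment-length-class design (50–2,000 bp, one uniform fragment
  per locus per class) — `sample_fragments()`;
* native quartet maximum-likelihood inference (JC69, Felsenstein
  pruning in C++, Brent branch-length optimisation, likelihood-weight
  support) plus a parsimony cross-check — `infer_topology_ml()`,
  `infer_topology_parsimony()`;
* "1100"-type phylogenetically informative site classification and
  adjacent-distance statistics — `classify_column()`,
  `scan_alignment()`, `distance_binned_topology_freq()`;
* per-class discordance reports, exact binomial imbalance tests, trend
  tests, and quartet/concatenation species-tree estimation —
  `summarize_length_class()`, `trend_across_classes()`,
  `quartet_species_tree()`, `concat_infer()`;
* an end-to-end driver writing TSV reports and a seeded manifest —
  `run_pipeline()`.

## Worked example

```r
library(quartetcoal)

m <- species_tree_model()   # (((A,B),C),O), internode 0.3 coalescent units
internode_from_match_freq(0.450, n_trees = 25955)
#> MSC internode estimate: T_hat = 0.1924 coalescent units (p_match = 0.4500, n = 25955)
#>   95% CI: [0.1815, 0.2035]

# simulated discordance matches the closed form
simulate_topology_distribution(model_with_internode(m, 0.1924), 1e5, seed = 42) / 1e5
#>      AB      AC      BC
#> 0.45275 0.27418 0.27307

# single-history loci -> infer -> summarise one length class
loci  <- generate_locus_set(m, n_loci = 300, L = 2000,
                            linkage = linkage_params(2000, "msc", 1), seed = 11)
trees <- infer_gene_trees(loci)
rep1  <- summarize_length_class(trees, length_class = 2000)
rep1[, c("n_AB", "n_AC", "n_BC", "match_freq", "imbalance_delta", "T_hat")]
#>    n_AB n_AC n_BC match_freq imbalance_delta    T_hat
#> AB  140   70   80  0.4827586      0.03448276 0.2537805
```

The report says: of 300 loci, 290 were resolved, 140 matched the
species tree (48.3%), the two mismatch topologies differed by 3.4
percentage points (exact binomial p = 0.46, consistent with the MSC),
and inverting the match frequency estimates an internode of 0.25
coalescent units with a 95% CI of [0.15, 0.37] — covering the
generating value of 0.3.

A full seven-class run, including the PI-site table and species-tree
estimates, is one call:

```r
res <- run_pipeline(pipeline_config(preset = "shuffled", seed = 1), "out/")
res$trend$rho         # imbalance trend across length classes
```

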