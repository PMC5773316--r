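---
title: "Fragment length and the multispecies coalescent in four-taxon phylogenies"
author: "quartetcoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment length and the multispecies coalescent in four-taxon phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetcoal)
```

## The scientific problem

Gene genealogies sampled across a genome do not all follow the species
tree.  For a rooted four-species phylogeny `(((A,B),C),O)` the
multispecies coalescent (MSC) predicts exactly how often they disagree:
if the internal branch between the `(A,B)` split and the `((A,B),C)`
split spans `T` coalescent units (one unit = `2N` generations for a
diploid population of effective size `N`), a gene tree matches the
species-tree quartet `AB|CO` with probability

$$p(T) = 1 - \tfrac{2}{3}e^{-T},$$

and each of the two *mismatch* topologies (`AC|BO`, `BC|AO`) occurs with
probability $\tfrac{1}{3}e^{-T}$ (Pamilo & Nei's classic result).  Two
consequences are testable on real data: the two mismatch topologies
should be *equally frequent* (their frequency difference — the
"imbalance" — has expectation zero), and the observed match frequency
can be inverted,

$$\hat T = -\ln\!\big(\tfrac{3}{2}(1 - p)\big),$$

to estimate the internode in coalescent units
(`internode_from_match_freq()`).

These predictions assume each locus is a single, freely recombining
draw from the coalescent.  In genomes reorganised by extensive
chromosomal rearrangement ("karyotypic shuffling"), physically adjacent
sites may descend from different genealogies, and the longer the
analysed fragment the more such histories it mixes.  This package
implements a complete, simulation-based version of that analysis: it
generates four-taxon loci whose internal segments can follow different
genealogies, samples fragments of increasing length classes from them,
re-infers quartet gene trees natively, and computes the discordance,
imbalance, informative-site, and coalescent-unit statistics that the
fragment-length design is built around.

## The model and its parameters

`species_tree_model()` fixes the species tree `(((A,B),C),O)` with:

* `tau_AB`, `tau_ABC`, `tau_root` — split times in generations
  (defaults 1.6e6, 1.75e6, 5.8e6).  The first two follow the
  Neotropical-primate calibration used for the demography experiment;
  published analyses of that radiation place the first two splits about
  0.15 Myr of generations apart.  The root age is not separately
  calibrated here; it only needs to be comfortably older than
  `tau_ABC`, and with the very large outgroup population sizes used in
  the demography sweep the results are insensitive to it.
* `N` — diploid effective sizes for the four tip branches and the
  `AB`, `ABC`, and root ancestral populations (default 2.5e5
  everywhere, which puts the internode at
  `(tau_ABC - tau_AB)/(2 N_AB) = 0.3` coalescent units, the scale
  previously estimated for that radiation).
* `mu` — substitutions per site per generation (default 1e-8, a
  primate-like per-generation rate).  Time is simulated in generations
  throughout and converted to substitutions/site only when sequences or
  Newick output are produced.

`model_with_internode(model, T)` rescales `N_AB` so the internode is
exactly `T`; `T = 0` is realised with an effectively infinite ancestral
size, giving the star-tree limit `p = 1/3`.

## Simulators

**Single-allele genealogies** (`simulate_gene_trees()`): the standard
continuous-time approximation of the Wright–Fisher coalescent.  With one
allele per species the first coalescence fully determines the quartet
topology, which allows an exactly vectorised implementation; the
returned merge codes reconstruct the full labelled genealogy
(`gene_tree_from_row()`).

**Multi-allele genealogies** (`simulate_multi_allele()`): `k` alleles
per species run through the structured coalescent in every tip and
ancestral population.  The species-level topology is called as the
plurality quartet topology over all `k^4` one-allele-per-species
quartets read from the genealogy; exact plurality ties are reported as
unresolved and excluded (with their count) rather than broken
arbitrarily.  This summary is a deliberate design choice — a
multi-allele genealogy does not carry a unique species-level topology,
and the plurality-over-quartets rule is the natural 4-taxon analogue of
quartet-frequency species-tree estimation.  `unequal_ne_model()`
packages the demography sweep in which lineage A keeps `N_A = 10^4`
Wright–Fisher individuals while every other branch has size `x` up to
`10^8`; at large `x` essentially all coalescences occur in the root
population and the three topologies become equally likely, which the
acceptance suite verifies at `x = 10^8` with 10 alleles per branch and
2,000 replicates.

## The synthetic-locus generator

`generate_locus_set()` emulates multi-kilobase genomic fragments whose
sites need not share one history.  Each locus of length `L` is cut into
segments with geometric lengths (mean `mean_segment_length`, truncated
at the locus end — so the expected segment count is `1 + (L-1)/mean`,
slightly above the naive `L/mean`); each segment receives a genealogy
drawn from the MSC, and with probability `persistence_rho` an adjacent
segment reuses the previous one.  A biased `topology_mixture` (the
0.47/0.29/0.24 preset) resamples segment topologies while coalescence
times are obtained by rejection sampling from the plain MSC, so times
remain exactly MSC-distributed given the topology.

Two presets bracket the study conditions: the *stable* regime
(`persistence_rho = 1`, segments at least as long as the locus) gives
classic single-history loci, and the *shuffled* regime (mean segment
350 bp, the biased mixture, independent adjacent segments) reproduces
the qualitative signature of karyotypic shuffling: the mismatch
imbalance grows with fragment length while the species-tree-supporting
PI sites decay fastest across adjacent-site distances.

This segmental mechanism is a surrogate, not a mechanistic model of
rearrangement or recombination: no generative model for the linkage
heterogeneity is specified by the underlying theory, so the generator
makes the simplest choice with the right two limits.  It also omits
indels, rate variation across sites, base-composition drift, and
alignment error.  Passing tests therefore demonstrate internal
consistency of the method under MSC assumptions plus this mixing
mechanism — not that real genomes satisfy them.

Default scale: 2,000 loci of 3,500 bp, matching the order of magnitude
of the genomic datasets this design emulates (tens of thousands of
~3.5-kb loci) while keeping a full pipeline run on one CPU in minutes.

## Fragmenting and inference

`sample_fragments()` draws, for each length class (default 50, 100,
200, 500, 1,000, 1,500, 2,000 bp), one fragment per locus with a
uniform start; loci shorter than a class are skipped and counted.
"Without replacement" is interpreted at the locus level — one region
per locus per class, positions independent across classes; overlap
between classes is not prevented, since nothing in the design requires
it.  All coordinates are 0-based and half-open.

`infer_topology_ml()` replaces external ML software with a native
quartet engine: JC69 likelihoods by explicit summation over the two
internal-node states (Felsenstein pruning specialised to four taxa,
implemented in C++ over the 256 possible site patterns), and the five
branch lengths of each of the three unrooted topologies optimised by
cyclic Brent line searches on `[0, 10]` substitutions/site to a
tolerance of `1e-8`.  Because each site-pattern probability is
multilinear in `exp(-4t/3)` for every branch, each line search costs
two pattern passes plus O(#patterns) per evaluation.  Numerical
choices:

* **Support** is the likelihood weight
  `exp(lnL_t) / sum(exp(lnL_t))`, computed stably; it replaces
  aLRT/posterior supports and is used only comparatively.
* **Ties**: if the top two log-likelihoods agree within `1e-6` the
  fragment is *unresolved* rather than broken arbitrarily; an alignment
  with no discriminating signal is unresolved with support 1/3.
* **Cherry depth**, the proxy for the coalescence time of the most
  inclusive pair, is half the patristic distance between the two
  ingroup-cherry taxa of the best tree.
* The generator and the inference engine share JC69 by default, so
  inference is correctly specified in simulations; GTR+Gamma is out of
  scope by design, and HKY85 is available on the generator side to
  probe mild misspecification.

`infer_topology_parsimony()` (plurality of "1100" informative-site
votes) provides a model-free cross-check; on resolved single-history
fragments it agrees with the ML engine in well over 90% of cases.

## Discordance statistics and species trees

`summarize_length_class()` reports, per length class, topology counts
and frequencies (Wilson 95% intervals) over resolved trees, the
mismatch imbalance with a two-sided exact binomial test of the two
mismatch counts against 1/2, cherry-depth means/variances, mean
support, and the internode estimate obtained by pushing the match
frequency (and its Wilson bounds) through the inversion.  Unresolved
trees are excluded from denominators but logged; no support filter is
applied by default (`min_support` is available).  The imbalance test is
an addition for calibration purposes — its type-I error is verified to
sit at the nominal 5% under unbiased simulation.

`trend_across_classes()` tests for an increasing imbalance trend with
Spearman's rho and a one-sided permutation p-value (exact enumeration
of all permutations for up to 7 classes, 10^4 seeded permutations
otherwise; constant imbalances define rho = 0, p = 1).

`quartet_species_tree()` is the 4-taxon reduction of
quartet-frequency species-tree estimation: the plurality topology, with
support computed by a multinomial parametric bootstrap at the observed
frequencies — chosen over a local-posterior-style support because it is
simple, seedable, and exactly testable against trinomial enumeration.
`concat_infer()` concatenates a whole length class and runs the ML
engine once.

## PI sites

`classify_column()` implements the "1100" rule: a column supports `AB`
iff base(A) = base(B) differs from base(C) = base(O), and so on; of the
256 ungapped columns exactly 12 support each topology.  Any non-ACGT
symbol voids a column (conservative).  Adjacent-site distances are
measured as differences of column positions of consecutive same-class
sites within a locus (never across loci), and the distance-binned table
normalises topology frequencies *within* half-open distance bins
(default edges 0, 100, 250, 500, 1,000, 1,500, 2,000, Inf); both
conventions are stated because alternatives (counting intervening
sites, normalising within classes) are equally defensible.

## Problem sizes and reproducibility

Every stochastic entry point takes a `seed`; `run_pipeline()` derives
one sub-seed per stage from a single master seed and records all of
them in a YAML manifest, so a pipeline run is reproducible
byte-for-byte.  The test suite verifies the analytic results exactly,
Monte-Carlo results within four standard errors at `n = 10^5`
genealogies per internode setting, the demography experiment at 2,000
ten-allele replicates, mismatch symmetry on 4,000 inferred 2,000-bp
fragments, imbalance-test calibration over 1,000 replicate datasets,
the shuffled-regime trend on 12,000 seven-class loci (the
imbalance amplification is a few percentage points, so this check is
run near the ~26,000-locus scale of the genomic datasets it emulates
rather than at the 2,000-locus default), and estimator
consistency over 20 replicate datasets of 2,000 loci per length class —
sizes chosen to keep the full suite within a desk-scale run while
leaving the Monte-Carlo bounds sharp.

## Known limitations

* Only the four-taxon case: no anomalous-zone analysis for larger
  trees, and no >4-taxon PI-site definitions.
* JC69 inference (likelihood weights, not aLRT or posteriors); support
  values are comparable within this package, not with external tools.
* The segment mixture is a surrogate for rearrangement-induced linkage
  heterogeneity; it does not model recombination, migration, selection,
  or population growth.
* Real-genome analyses (orthologue extraction, alignment, karyotype
  reconstruction) are out of scope; the package consumes or generates
  four-taxon FASTA alignments only.
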