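---
title: "Methods: allele-specific correlation networks and bloc association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific correlation networks and bloc association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blocnet)
```

## The problem

Single-marker association scans miss disease signals that live in
*combinations* of SNP alleles, and direct enumeration of multi-marker
combinations is hopeless at genome scale (`choose(1e6, 2)` is about
5 x 10^11 pairs; triples approach 1.7 x 10^17). blocnet takes the network
route: score every SNP *pair* with a correlation metric, keep only the
strongest values as edges, and read off higher-order structure from the
connected components. Two design constraints shape everything else:

1. **Genetic heterogeneity.** The same phenotype can arise from different
   allele combinations in different subgroups. A correlation measured over
   the whole sample (Pearson's r, or the r^2 LD statistic) is dragged
   toward zero by the subgroups in which the correlation is absent.
2. **Allele specificity.** A correlation belongs to a specific pair of
   alleles, not to a pair of SNPs. Merging both alleles of a SNP into one
   node conflates a risk pattern with its mirrored protective pattern and
   can manufacture false connections.

Consequently each SNP is represented by **two nodes**, one per allele, and
each SNP pair is scored by a **four-facet custom correlation coefficient
(CCC)**: one value in [0, 1] per allele combination (AB, Ab, aB, ab), each
facet measuring only its own pair of alleles.

## The facet metric

For a pair of SNPs, blocnet first tallies allele co-occurrence over the
samples genotyped at both SNPs (missing data are never imputed; samples
missing at either SNP are dropped for that pair, and pairs that lose more
than `warn_missing_fraction` of the sample are flagged). With `d_u`,
`d_v` in {0, 1, 2} the dosages of alleles u and v, a sample contributes
`d_u * d_v / 2` to the (u, v) cell: 2 for a double homozygote, 1 for a
homozygote-heterozygote pair, and 1/2 for a double heterozygote — its
expected co-occurrence under random phase, since an unphased double
heterozygote is ambiguous. The four cells always sum to twice the
pairwise-complete sample count, so the table is a (pseudo-count) 2x2
allele co-occurrence table. `het_weight` exposes the conservative (0) and
liberal (1) phase assignments.

The default facet value is **Yule's association coefficient** of that
table, Q = (ad - bc)/(ad + bc), assigned to the two corners of the
associated diagonal and clipped to [0, 1] (the other diagonal gets -Q,
clipped). Three properties motivated this choice over the raw normalised
tally `T_uv / min(N_u, N_v)` that is also available (`method = "tally"`):

* **Chance calibration across the frequency spectrum.** Under
  independence the raw tally facet concentrates around the larger allele
  frequency — for common alleles it approaches 1 with no correlation
  present, so ranking facets for edge selection would reward allele
  frequency, not association. Q is a monotone function of the odds ratio,
  so independent SNPs score near 0 whether their alleles are rare or
  common. In simulations under the default study conditions (below), the
  largest facet over half a million independent facets stays around
  0.2-0.45, while perfectly co-inherited 17-SNP patterns score about
  0.88.
* **Heterogeneity robustness.** Q is concave in the co-occurrence
  frequency, so diluting a perfectly correlated subgroup with an equal
  number of samples carrying the alleles independently (at the same
  marginal frequencies) lowers the facet only modestly (about 0.88 to
  0.64 at minor-allele frequency 0.15) while Pearson's r falls in
  proportion to the diluting fraction (1.0 to about 0.5) and r^2
  quadratically. Appending samples that carry neither allele never lowers
  a facet.
* **Degenerate-table behaviour.** One pseudo-tally is added to each cell
  (Laplace smoothing). Without it, a single empty cell — expected counts
  as low as ~8 occur for rare x common pairs even at 1,550 samples —
  fixes Q at exactly 1 and chance edges would saturate the ranking. A
  pair in which either SNP lacks one of its alleles carries no contrast
  and scores 0 on all facets, the same convention Pearson's r uses for a
  constant vector.

The raw tally form is kept (`method = "tally"`, with `min`, `geom` and
`2n` denominators) because it is the natural effect-size reading of the
tallies ("what fraction of the rarer allele's copies co-occur with the
partner allele") and is the right tool for point questions about a known
pattern, as several worked examples in the test suite show. The scan and
network default is the calibrated Q form.

## Network construction and blocs

`ccc_scan()` computes all `4 * choose(m, 2)` facets by blocked matrix
cross-products (O(m^2 n) time; only three m x m cross-products are needed
because the four tallies share their margins) and streams a running top-k
selection. `build_network()` keeps the `n_edges` strongest facets as
edges; the default `n_edges = n_snps` gives an average node degree of
one, the most stringent density at which every node could in principle be
connected. Ties at the cutoff are broken deterministically (value
descending, then SNP indices, then facet order AB, Ab, aB, ab), so
repeated runs give identical networks.

Blocs are simply the connected components with at least two nodes
(`extract_blocs()`, via igraph); no clustering or partitioning is
applied, and components containing both alleles of one SNP are flagged
but retained. Density is a sensitivity parameter, not a result:
`density_sweep()` rebuilds the network over a range of edge counts and
tracks a bloc of interest by Jaccard index on node sets (>= 0.5 counts as
the same bloc). Components only merge as edges are added, so the tracked
bloc grows monotonically.

## Whole-pattern association

A bloc is tested as an entire allele pattern. Each diploid sample carries
0, 1 or 2 of its allelic combinations consistent with the full pattern:
the **minimum** over the bloc's (SNP, allele) pairs of the sample's
allele dosage (`pattern_dosage()`). The whole pattern must be present —
lacking the allele at any single SNP gives 0. Samples missing more than
5% (configurable) of the bloc's genotypes are excluded from the tables
(but are shown in the inspection plots); missing genotypes within the
allowance do not constrain the minimum, since presence is judged on
observed genotypes.

From the 2x2 table (pattern/non-pattern x case/control): odds ratio
OR = ad/bc with the Wald 95% interval
exp(ln OR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d)) — no continuity
correction; a zero cell leaves the OR flagged as undefined — and the
G-test of independence G = 2 sum O ln(O/E) against chi-squared with one
degree of freedom. Only blocs carried by at least ten individuals are
tested; the Bonferroni family size is the number of blocs passing that
filter. Each bloc's complement pattern (all alternate alleles) is tested
alongside it; the complement is not counted as an additional independent
test. For a genome-scale family of 54,425 blocs at alpha 0.05 the
analytic critical G is `critical_g(0.05, 54425)` = 24.1.

## Validation procedures

* **Phenotype-label permutation** (`permute_phenotype_null()`): reassign
  samples into groups of the original sizes, recompute every bloc's G,
  record the per-trial maximum. The empirical family-wise threshold is
  the (1 - alpha) quantile of the maxima; a bloc's corrected p is the
  fraction of trial maxima reaching its observed G (max-statistic
  method). On independent null blocs this threshold agrees with the
  analytic Bonferroni critical G to within about 15%.
* **Genotype shuffling** (`shuffle_genotypes()`, `null_max_ccc()`):
  permute each SNP's genotype column independently (missing entries
  travel with the column, so allele frequencies and genotype-state
  balance are preserved exactly), then scan for the maximum facet. If
  that maximum stays below the original network's edge cutoff, chance
  correlations are unlikely to have produced edges. This comparison is
  informative only at densities where the edges reflect genuine
  correlations: once `n_edges` exceeds the number of truly correlated
  facets in the data, the cutoff itself sits inside the null facet
  distribution and a fresh null maximum will exceed it almost surely.
  The synthetic study conditions embed one 17-SNP pattern, i.e.
  2 * choose(17, 2) = 272 correlated facets (pattern plus mirror), so
  the screen is meaningful up to roughly that density, and
  `run_pipeline()` reports the per-trial pass fraction against whatever
  cutoff is in force.
* **Bootstrap stability** (`bootstrap_bloc()`): subsample half of the
  cases and half of the controls without replacement (the "half" design,
  not a with-replacement bootstrap), recompute OR and p each time, and
  report the mean OR with the 95% interval of the trial mean.
* **Visual inspection** (`order_individuals_for_plot()`,
  `plot_bloc_genotypes()`): per phenotype group, order individuals by a
  greedy nearest-neighbour chain on Hamming distance between their bloc
  genotype rows, improved by windowed 2-opt segment reversal, with
  optional cluster cut points at the largest adjacent distances. An
  exact travelling-salesman solver would be overkill for a cosmetic
  ordering; on small instances the heuristic tour is within 1.5x of the
  exhaustive optimum. Cells are coloured homozygous-pattern /
  heterozygous / homozygous-alternate / missing, and every individual is
  shown, including those excluded from the tables.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a case/control GWAS panel
without reproducing any real data: biallelic autosomal SNPs, two
phenotype groups, and embedded multi-SNP patterns.

* Background SNPs are independent with allele frequencies uniform on
  [0.05, 0.95] and genotypes in Hardy-Weinberg proportions.
* An embedded bloc (`bloc_spec()`) is placed haplotype-style: each
  sample draws k ~ Binomial(2, f_group) pattern haplotypes; those carry
  the pattern allele at *every* bloc SNP, and non-pattern haplotypes
  carry the alternate allele, so the per-SNP marginal frequency of a
  pattern allele equals the pattern frequency. Within an optional
  carrier subgroup the placement is joint (all-or-none per haplotype);
  outside it the same marginal frequencies apply with co-occurrence
  broken — the heterogeneity scenario `simulate_het_pair()` isolates
  for a single pair.
* Missing genotypes are sprinkled i.i.d.; allele-slot orientation of
  each pattern allele is randomised so downstream code cannot rely on
  which slot carries the pattern.

The default study conditions used by the acceptance checks are 900 cases
and 650 controls, 500 background SNPs, one embedded 17-SNP pattern at
frequencies 0.22 (cases) and 0.072 (controls) — an implied whole-pattern
odds ratio of 3.64 — and 2% missingness. What the generator does *not*
emulate: background linkage disequilibrium (real genomes supply as many
true correlations as there are SNPs, which is why a genome-scale network
can spend one edge per SNP entirely on real signal; the independent
background here cannot), population stratification, ascertainment, and
genotyping-batch artefacts. Passing tests on these simulations therefore
demonstrate correctness of the machinery and recoverability of planted
patterns, not performance on any particular real cohort.

## Numerical and design choices

* Scan tie-breaking, bloc ordering (by smallest node id) and record
  ordering are fully deterministic; every stochastic procedure takes a
  seed and restores the caller's RNG state.
* Pattern-allele facets of a planted pattern sit near 0.88 rather than
  at 1.0: the random-phase tally halves the contribution of double
  heterozygotes, and the Q transform maps the resulting odds ratio of
  about 16 to 0.88. This is a known, documented discount, not noise.
* `qc_filter()` removes SNPs above the missingness threshold first, then
  samples (recomputed on surviving SNPs), and flags but keeps
  monomorphic SNPs. A second pass is a no-op at study-like missingness;
  under extreme missingness the recomputed fractions can shift, which is
  inherent to any fixed-order two-stage filter.
* PED files carry no reference-allele designation, so allele slots are
  assigned first-observed on reading; all downstream quantities are
  labelled by nucleotide, so orientation affects labels only.
* Problem sizes in the tests and acceptance script (500 background SNPs,
  1,550 samples, 200 permutations, 20 shuffle trials, 1,000-instance
  oracle sweeps) were chosen so the full analysis of a dataset at these
  conditions completes in seconds to a couple of minutes on one CPU
  while keeping every statistical check well-powered.

## Known limitations

* The facet metric is an association measure on unphased tallies; it
  does not estimate haplotype frequencies (no EM step), so facets of
  perfectly co-inherited patterns are discounted as described above.
* Chance facets involving the rarest alleles have the largest sampling
  noise even after smoothing; at network densities beyond the signal
  content these form hub-like components around rare alleles, which the
  carrier filter excludes from testing and a density sweep disentangles.
* Only biallelic autosomal SNPs are supported; covariate adjustment,
  trend tests and quantitative traits are out of scope.
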