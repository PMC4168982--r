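# blocnet

Allele-specific SNP correlation networks and whole-pattern ("bloc")
case/control association testing.

Genome-wide association studies routinely miss signals that live in
*combinations* of SNP alleles rather than in single markers, and two
obstacles block the direct search for such combinations: the
combinatorial explosion (about 5 × 10¹¹ pairs, 1.7 × 10¹⁷ triples for a
million SNPs) and genetic heterogeneity — a correlation that is perfect
in one subgroup of patients is averaged away by global measures like
Pearson's r or r² when other subgroups lack it. blocnet is for
statistical geneticists who want an unbiased, phenotype-blind network
view of multi-SNP structure in case/control genotype data.

## The method

Every SNP pair is scored with a four-facet **custom correlation
coefficient (CCC)**: one value in [0, 1] per allele combination
(AB, Ab, aB, ab), computed from fast allele co-occurrence tallies over
the samples genotyped at both SNPs. With dosages d_u, d_v ∈ {0, 1, 2},
a sample contributes d_u·d_v/2 to the (u, v) cell — the ½ for a double
heterozygote is its expected co-occurrence under random phase. The
default facet value is Yule's Q = (ad − bc)/(ad + bc) of the resulting
2×2 allele table (Laplace-smoothed, clipped to [0, 1] per diagonal), so
independent SNPs score near 0 at *any* allele frequency while
subgroup-restricted correlations retain high scores; the raw normalised
tally T_uv / min(N_u, N_v) is available as `method = "tally"`.

The n strongest facets become edges of a network with **two nodes per
SNP** (one per allele; default n = number of SNPs, average degree one).
Connected components with ≥ 2 nodes — **blocs** — are multi-SNP allele
patterns that arise naturally separated, with no clustering step. Each
bloc's entire pattern is then tested for association: per sample the
pattern dosage is min over the bloc's (SNP, allele) pairs of the allele
dosage (0/1/2 of the sample's two allelic combinations), giving a 2×2
table with odds ratio OR = ad/bc,
CI = exp(ln OR ± 1.96·√(1/a + 1/b + 1/c + 1/d)), the G-test
G = 2·Σ O·ln(O/E) against χ²(1), Bonferroni correction over the blocs
carried by ≥ 10 individuals, and a permutation (max-statistic)
family-wise threshold. Validation tools include genotype shuffling
(type-I screen for the edge cutoff), bootstrap subsampling of the odds
ratio, network density sweeps, and similarity-ordered genotype heatmaps.

## Worked example

```r
library(blocnet)

# 300 cases / 250 controls, 80 background SNPs, one embedded 5-SNP
# pattern at frequencies 0.25 (cases) vs 0.08 (controls), 2% missingness
sim <- simulate_dataset(300, 250, 80,
                        bloc_specs = bloc_spec(5, 0.25, 0.08),
                        missing_rate = 0.02, seed = 8)
gm <- sim$genotypes
gm
#> <genotype_matrix> 550 samples x 85 SNPs (300 cases, 250 controls, 0 unknown)
#>   missing genotypes: 1.94%

rec   <- ccc_scan(gm, top_k = n_snps(gm))        # all-pairs CCC, top facets
net   <- build_network(rec, n_snps(gm), n_edges = 30)
blocs <- extract_blocs(net)
network_summary(net, blocs)
#>   n_nodes n_edges n_blocs pct_singletons n_doubletons mean_bloc_size ...
#> 1     170      30       6           85.9            2              4

assoc <- test_all_blocs(gm, blocs)
dplyr::select(assoc, bloc_id, n_snps, p_freq, q_freq, odds_ratio, g, p_corrected)
#>   bloc_id n_snps p_freq q_freq odds_ratio     g  p_corrected
#> 1       5      5 0.249  0.0796      3.83   53.1  5e-12 ...
#> 2       6      5 0.751  0.920       0.261  53.1  ...     (mirror pattern)
#> 3       3      2 0.0997 0.124       0.778   1.64 ...
```

The top bloc is the planted 5-SNP pattern: carried at frequency 0.249 in
cases vs 0.080 in controls, odds ratio 3.83 (the simulation's implied OR
is 3.83), G = 53.1 — far beyond both the Bonferroni critical G of 6.63
for the 5 tested blocs and the empirical family-wise threshold from 200
phenotype permutations (5.7). Its mirrored complement appears as the
protective bloc 6 (OR 0.26). Recovery scoring and stability:

```r
evaluate_recovery(sim$truth, blocs, assoc)
#>   bloc jaccard precision recall matched_bloc_id estimated_or implied_or
#> 1    1       1         1      1               5         3.83       3.83

bootstrap_bloc(gm, blocs[blocs$bloc_id == 5, ], n_trials = 200, seed = 10)
#> <bloc_bootstrap> 200 trials at fraction 0.50: OR mean 3.987 (CI 3.867-4.107)

plot_bloc_genotypes(gm, blocs[blocs$bloc_id == 5, ])   # inspection heatmap
```

A command-line front end (`inst/scripts/blocnet`) exposes the stages as
subcommands (`simulate`, `scan`, `network`, `blocs`, `assoc`,
`validate`, `run`, `compare-pcc`); see `blocnet_cli()`.

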