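test_that("genotype shuffling preserves each SNP's dosage multiset exactly", {
  set.seed(401)
  gm <- random_gm(30, 8, miss = 0.1)
  sh <- shuffle_genotypes(gm, seed = 5)
  for (j in 1:8) {
    expect_equal(sort(table(gm$dosage[, j], useNA = "always")),
                 sort(table(sh$dosage[, j], useNA = "always")))
  }
  # reproducible under a fixed seed, and a 1-sample matrix cannot move
  expect_identical(shuffle_genotypes(gm, seed = 5)$dosage, sh$dosage)
  one <- random_gm(1, 4, miss = 0)
  expect_identical(shuffle_genotypes(one, seed = 1)$dosage, one$dosage)
})

test_that("phenotype permutation keeps group sizes and yields valid p-values", {
  set.seed(402)
  sim <- simulate_dataset(60, 40, 10, bloc_specs = bloc_spec(3, 0.5, 0.5),
                          seed = 19)
  gm <- sim$genotypes
  blocs <- tibble::tibble(
    bloc_id = 1:2, n_nodes = c(3L, 2L), n_edges = c(3L, 1L),
    n_snps = c(3L, 2L),
    snp_indices = list(sim$truth$blocs$snp_indices[[1]], 1:2),
    allele_slots = list(sim$truth$blocs$allele_slots[[1]], c(1L, 1L)),
    node_ids = list(sim$truth$blocs$node_ids[[1]], c(1L, 3L)),
    both_alleles = FALSE
  )
  null <- permute_phenotype_null(gm, blocs, n_trials = 50, seed = 23)
  expect_equal(null$n_trials, 50)
  expect_length(null$maxima, 50)
  expect_true(all(null$bloc_stats$p_corrected >= 0 &
                    null$bloc_stats$p_corrected <= 1))
  # identical seed, identical trials
  null2 <- permute_phenotype_null(gm, blocs, n_trials = 50, seed = 23)
  expect_identical(null$maxima, null2$maxima)
  # a bloc whose observed G is below every trial maximum gets p = 1
  weak <- which(null$bloc_stats$observed_g < min(null$maxima))
  expect_true(all(null$bloc_stats$p_corrected[weak] == 1))
  expect_error(permute_phenotype_null(gm, blocs[0, ], 10), "no blocs")
})

test_that("the empirical family-wise threshold approaches the Bonferroni G", {
  # 150 disjoint null doubleton patterns over independent SNPs
  set.seed(403)
  sim <- simulate_dataset(250, 250, 300, missing_rate = 0, seed = 29)
  gm <- sim$genotypes
  blocs <- purrr::map_dfr(seq_len(150), function(k) tibble::tibble(
    bloc_id = k, n_nodes = 2L, n_edges = 1L, n_snps = 2L,
    snp_indices = list(c(2L * k - 1L, 2L * k)),
    allele_slots = list(c(1L, 1L)),
    node_ids = list(node_id_pair <- c(4L * k - 3L, 4L * k - 1L)),
    both_alleles = FALSE
  ))
  null <- permute_phenotype_null(gm, blocs, n_trials = 400, seed = 31)
  analytic <- critical_g(0.05, 150)
  expect_lt(abs(null$threshold - analytic) / analytic, 0.15)
  # on null data the share of blocs called significant stays near alpha
  frac_sig <- mean(null$bloc_stats$p_corrected <= 0.05)
  expect_lte(frac_sig, 0.05 + 2 * sqrt(0.05 / 400))
})

test_that("shuffle-null maxima are reproducible and the verdict uses the cutoff", {
  set.seed(404)
  gm <- random_gm(40, 12, miss = 0.02)
  null <- suppressWarnings(null_max_ccc(gm, n_trials = 5, seed = 37,
                                        cutoff = 0.99))
  expect_length(null$maxima, 5)
  null2 <- suppressWarnings(null_max_ccc(gm, n_trials = 5, seed = 37,
                                         cutoff = 0.99))
  expect_identical(null$maxima, null2$maxima)
  expect_equal(null$pass, max(null$maxima) < 0.99)
  expect_equal(null$prop_below, mean(null$maxima < 0.99))

  # a monomorphic SNP contributes nothing: facets of an absent allele are 0
  mono <- genotype_matrix(matrix(c(2L, 2L, 2L, 2L, 0L, 1L, 2L, 1L), 4, 2))
  nm <- null_max_ccc(mono, n_trials = 2, seed = 1, method = "tally")
  expect_true(all(nm$maxima <= 1))
})

test_that("embedded perfect correlations survive the shuffle screen", {
  # strong embedded blocs with all edges truly correlated: the shuffled
  # maximum stays below the (dense-signal) network cutoff
  sim <- simulate_dataset(120, 100, 60,
                          bloc_specs = bloc_spec(6, 0.35, 0.35),
                          seed = 41)
  gm <- sim$genotypes
  k_true <- 2 * choose(6, 2) # pattern + mirrored complement facets
  rec <- ccc_scan(gm, top_k = k_true)
  cutoff <- scan_cutoff(rec)
  null <- null_max_ccc(gm, n_trials = 8, seed = 43, cutoff = cutoff)
  expect_gte(null$prop_below, 7 / 8)
})

test_that("bootstrap subsampling is stable, seeded, and exact at fraction 1", {
  sim <- simulate_dataset(80, 60, 5, bloc_specs = bloc_spec(3, 0.4, 0.15),
                          seed = 47)
  gm <- sim$genotypes
  bloc <- list(snp_indices = sim$truth$blocs$snp_indices[[1]],
               allele_slots = sim$truth$blocs$allele_slots[[1]])
  tab <- bloc_contingency(gm, bloc)
  full_or <- odds_ratio_ci(tab$a, tab$b, tab$c, tab$d)$odds_ratio

  exact <- bootstrap_bloc(gm, bloc, n_trials = 20, fraction = 1, seed = 53)
  expect_equal(unique(exact$trials$odds_ratio), full_or)
  expect_equal(exact$or_ci[1], exact$or_ci[2])

  bt <- bootstrap_bloc(gm, bloc, n_trials = 100, fraction = 0.5, seed = 53)
  bt2 <- bootstrap_bloc(gm, bloc, n_trials = 100, fraction = 0.5, seed = 53)
  expect_identical(bt$trials, bt2$trials)
  expect_true(bt$or_ci[1] <= bt$or_mean && bt$or_mean <= bt$or_ci[2])
  # subsampled estimate consistent with the full-sample odds ratio
  expect_lt(abs(log(bt$or_mean) - log(full_or)),
            3 * sd(log(bt$trials$odds_ratio), na.rm = TRUE))
  expect_error(bootstrap_bloc(gm, bloc, n_trials = 5, fraction = 0.001),
               "too small")
})

test_that("similarity ordering places identical rows together and is near-optimal", {
  d <- matrix(c(2L, 2L, 0L, 2L, 1L, 0L,
                2L, 2L, 0L, 0L, 1L, 2L), 6, 2)
  gm <- genotype_matrix(d)
  bloc <- list(snp_indices = 1:2, allele_slots = c(1L, 1L))
  ord <- order_individuals_for_plot(gm, bloc)
  pos <- match(c(1, 2), ord$ordering) # rows 1 and 2 are identical
  expect_equal(abs(diff(pos)), 1)
  expect_setequal(ord$ordering, 1:6)
  expect_true(all(ord$codes %in% c(0L, 1L, 2L, 9L)))

  single <- order_individuals_for_plot(subset_genotypes(gm, samples = 1),
                                       bloc)
  expect_equal(single$ordering, 1)

  # against exhaustive search on small instances: within 1.5x of optimum
  set.seed(405)
  for (rep in 1:12) {
    n <- sample(5:7, 1)
    x <- matrix(sample(c(0:2, 9L), n * 4, replace = TRUE), n, 4)
    dm <- hamming_rows_oracle(x)
    heur <- blocnet:::order_by_similarity(dm)
    best <- min(vapply(all_perms(n), function(p) tour_length(dm, p),
                       numeric(1)))
    expect_lte(tour_length(dm, heur), 1.5 * best + 1e-9)
  }
})

test_that("missing genotypes are shown for excluded individuals in plots", {
  d <- matrix(2L, 4, 3)
  d[2, ] <- NA # excluded from tables, still plotted
  gm <- genotype_matrix(d)
  gm$samples$phenotype <- c("case", "case", "control", "control")
  bloc <- list(snp_indices = 1:3, allele_slots = rep(1L, 3))
  ord <- order_individuals_for_plot(gm, bloc)
  expect_equal(nrow(ord$codes), 4)
  expect_equal(unname(ord$codes[match(2, ord$ordering), ]), rep(9L, 3))
})
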