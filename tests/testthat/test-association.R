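test_that("pattern dosage follows the minimum rule over bloc alleles", {
  # 3-SNP bloc, pattern = allele1 everywhere
  d <- rbind(
    c(2L, 2L, 2L), # pattern homozygote -> 2
    c(2L, 1L, 2L), # heterozygous at one SNP -> 1
    c(2L, 0L, 2L), # lacks the allele at one SNP -> 0
    c(1L, 1L, 1L)  # heterozygous throughout -> 1
  )
  gm <- genotype_matrix(d)
  bloc <- list(snp_indices = 1:3, allele_slots = rep(1L, 3))
  expect_equal(pattern_dosage(gm, bloc), c(2L, 1L, 0L, 1L))
  # allele slots flip the counted allele: slot 2 of SNP 1 scores 2 - d
  bloc2 <- list(snp_indices = 1:3, allele_slots = c(2L, 1L, 1L))
  expect_equal(pattern_dosage(gm, bloc2), c(0L, 0L, 0L, 1L))
  expect_error(pattern_dosage(gm, list(snp_indices = c(1L, 9L),
                                       allele_slots = c(1L, 1L))),
               "absent")
})

test_that("one missing genotype in a 17-SNP bloc exceeds the 5% allowance", {
  d <- matrix(2L, 2, 17)
  d[2, 5] <- NA # 1/17 = 5.9% > 5%
  gm <- genotype_matrix(d)
  bloc <- list(snp_indices = 1:17, allele_slots = rep(1L, 17))
  expect_equal(pattern_dosage(gm, bloc), c(2L, NA))
  # a larger allowance readmits the sample; the missing SNP does not
  # constrain the minimum
  expect_equal(pattern_dosage(gm, bloc, max_missing = 0.10), c(2L, 2L))
})

test_that("contingency tables count both allelic combinations per sample", {
  d <- matrix(c(2L, 2L, 0L, 0L), 4, 2)
  gm <- genotype_matrix(d)
  gm$samples$phenotype <- c("case", "case", "control", "control")
  bloc <- list(snp_indices = 1:2, allele_slots = c(1L, 1L))
  tab <- bloc_contingency(gm, bloc)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 4, b = 0, c = 0, d = 4))
  expect_equal(tab$p_freq, 1)
  expect_equal(tab$q_freq, 0)

  gm$dosage[, 1] <- NA # every sample excluded
  expect_error(bloc_contingency(gm, list(snp_indices = 1L,
                                         allele_slots = 1L)),
               "no usable samples")
})

test_that("contingency equals a hand tally on a 50-sample fixture", {
  set.seed(301)
  for (rep in 1:10) {
    gm <- random_gm(50, 6, miss = 0.06)
    bloc <- list(snp_indices = sample(6, 3),
                 allele_slots = sample(1:2, 3, replace = TRUE))
    tab <- bloc_contingency(gm, bloc, max_missing = 0.34)
    # hand tally
    a <- b <- ncu <- nku <- 0
    for (s in seq_len(50)) {
      doses <- integer(0)
      nmiss <- 0
      for (t in seq_along(bloc$snp_indices)) {
        x <- gm$dosage[s, bloc$snp_indices[t]]
        if (bloc$allele_slots[t] == 2L && !is.na(x)) x <- 2L - x
        if (is.na(x)) nmiss <- nmiss + 1 else doses <- c(doses, x)
      }
      if (nmiss / 3 > 0.34) next
      pd <- if (length(doses)) min(doses) else 2L
      if (gm$samples$phenotype[s] == "case") {
        a <- a + pd
        ncu <- ncu + 1
      } else {
        b <- b + pd
        nku <- nku + 1
      }
    }
    expect_equal(unlist(tab[c("a", "b", "c", "d")]),
                 c(a = a, b = b, c = 2 * ncu - a, d = 2 * nku - b))
  }
})

test_that("odds ratios reproduce the frequency form and its exact cases", {
  expect_equal(round(odds_ratio_from_freq(0.220, 0.072), 2), 3.64)
  expect_equal(round(odds_ratio_from_freq(0.179, 0.265), 3), 0.605)
  expect_equal(odds_ratio_from_freq(0.3, 0.3), 1)

  tab <- odds_ratio_ci(40, 10, 60, 90)
  expect_equal(tab$odds_ratio, (40 * 90) / (10 * 60))
  se <- sqrt(1 / 40 + 1 / 10 + 1 / 60 + 1 / 90)
  expect_equal(tab$ci_low, exp(log(6) - 1.96 * se))
  expect_equal(tab$ci_high, exp(log(6) + 1.96 * se))
  # counts and frequencies give the same ratio
  expect_equal(tab$odds_ratio,
               odds_ratio_from_freq(40 / 100, 10 / 100))
})

test_that("odds-ratio invariants: row swap inverts, zero cells are flagged", {
  set.seed(302)
  for (rep in 1:50) {
    cells <- sample(1:200, 4)
    or1 <- odds_ratio_ci(cells[1], cells[2], cells[3], cells[4])
    # swapping case/control columns inverts the ratio
    or2 <- odds_ratio_ci(cells[2], cells[1], cells[4], cells[3])
    expect_equal(or1$odds_ratio * or2$odds_ratio, 1)
    # frequency form agrees with the count form to floating precision
    p <- cells[1] / (cells[1] + cells[3])
    q <- cells[2] / (cells[2] + cells[4])
    expect_equal(or1$odds_ratio, odds_ratio_from_freq(p, q))
  }
  z <- odds_ratio_ci(0, 5, 10, 20)
  expect_false(z$or_defined)
  expect_true(is.na(z$odds_ratio))
})

test_that("the G-test matches an independent log-likelihood oracle", {
  # proportional rows: exact independence
  g0 <- g_test(10, 20, 30, 60)
  expect_equal(g0$g, 0)
  expect_equal(g0$p_raw, 1)

  g1 <- g_test(40, 10, 60, 90)
  expect_equal(g1$g, oracle_g(40, 10, 60, 90), tolerance = 1e-10)

  set.seed(303)
  for (rep in 1:300) {
    cells <- sample(0:100, 4, replace = TRUE)
    if (min(cells[1] + cells[2], cells[3] + cells[4],
            cells[1] + cells[3], cells[2] + cells[4]) == 0) next
    got <- g_test(cells[1], cells[2], cells[3], cells[4])
    expect_lt(abs(got$g - oracle_g(cells[1], cells[2], cells[3], cells[4])),
              1e-10)
    # invariance under row and column swaps
    expect_equal(got$g, g_test(cells[3], cells[4], cells[1], cells[2])$g)
    expect_equal(got$g, g_test(cells[2], cells[1], cells[4], cells[3])$g)
  }
  # empty margin: undefined and flagged
  ge <- g_test(0, 0, 10, 20)
  expect_false(ge$g_defined)
})

test_that("null G scores follow chi-squared with one degree of freedom", {
  set.seed(304)
  n_case <- 450
  n_ctrl <- 350
  g <- replicate(10000, {
    a <- rbinom(1, 2 * n_case, 0.3) # pattern independent of phenotype
    b <- rbinom(1, 2 * n_ctrl, 0.3)
    g_test(a, b, 2 * n_case - a, 2 * n_ctrl - b)$g
  })
  q95 <- quantile(g, 0.95, na.rm = TRUE)
  expect_gt(q95, 3.5)
  expect_lt(q95, 4.2)
})

test_that("bonferroni correction and the critical G behave as stated", {
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(1e-6, 54425), 0.054425)
  expect_equal(round(critical_g(0.05, 54425), 1), 24.1)
  expect_error(critical_g(1.2, 10), "alpha")
})

test_that("complementing a bloc flips alleles and mirrors the odds ratio", {
  bloc <- list(snp_indices = c(3L, 5L), allele_slots = c(1L, 2L))
  comp <- complement_bloc(bloc)
  expect_equal(comp$allele_slots, c(2L, 1L))
  expect_equal(complement_bloc(comp)$allele_slots, bloc$allele_slots)

  # protective embedded pattern: complement trends to risk
  sim <- simulate_dataset(150, 150, 0, bloc_specs = bloc_spec(3, 0.1, 0.4),
                          seed = 13)
  bl <- list(snp_indices = sim$truth$blocs$snp_indices[[1]],
             allele_slots = sim$truth$blocs$allele_slots[[1]])
  tab <- bloc_contingency(sim$genotypes, bl)
  ctab <- bloc_contingency(sim$genotypes, complement_bloc(bl))
  or <- odds_ratio_ci(tab$a, tab$b, tab$c, tab$d)$odds_ratio
  cor_ <- odds_ratio_ci(ctab$a, ctab$b, ctab$c, ctab$d)$odds_ratio
  expect_lt(or, 1)
  expect_gt(cor_, 1)
})

test_that("test_all_blocs applies the carrier filter and ranks true signals", {
  # a bloc carried by fewer than min_carriers individuals is skipped
  d <- matrix(0L, 30, 2)
  d[1:9, ] <- 2L # 9 carriers
  gm <- genotype_matrix(d)
  gm$samples$phenotype <- rep(c("case", "control"), 15)
  blocs <- tibble::tibble(
    bloc_id = 1L, n_nodes = 2L, n_edges = 1L, n_snps = 2L,
    snp_indices = list(1:2), allele_slots = list(c(1L, 1L)),
    node_ids = list(c(1L, 3L)), both_alleles = FALSE
  )
  expect_equal(nrow(test_all_blocs(gm, blocs, min_carriers = 10)), 0)
  res <- test_all_blocs(gm, blocs, min_carriers = 9)
  expect_equal(nrow(res), 1)
  expect_equal(res$m_tests, 1)

  # empty bloc list
  expect_equal(nrow(test_all_blocs(gm, blocs[0, ])), 0)

  # an enriched bloc ranks first with an odds ratio near the simulated one
  sim <- simulate_dataset(400, 300, 40,
                          bloc_specs = bloc_spec(5, 0.25, 0.08),
                          missing_rate = 0.01, seed = 17)
  gm2 <- sim$genotypes
  rec <- suppressWarnings(ccc_scan(gm2, top_k = n_snps(gm2)))
  net <- build_network(rec, n_snps(gm2))
  blocs2 <- suppressWarnings(extract_blocs(net))
  assoc <- test_all_blocs(gm2, blocs2, min_carriers = 10)
  recov <- evaluate_recovery(sim$truth, blocs2, assoc)
  expect_equal(recov$recall, 1)
  top_two <- assoc$bloc_id[1:2] # pattern bloc and its complement mirror
  expect_true(recov$matched_bloc_id %in% top_two)
  implied <- sim$truth$blocs$implied_or[1]
  row <- assoc[assoc$bloc_id == recov$matched_bloc_id, ]
  expect_lt(abs(log(row$odds_ratio) - log(implied)), 3 * row$log_se)
  # complement statistics mirror the pattern on the same margins
  expect_equal(row$comp_g, row$g, tolerance = 0.3)
})
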