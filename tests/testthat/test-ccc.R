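test_that("perfect co-occurrence gives a facet of 1 and empty facets give 0", {
  di <- rep(2L, 10)
  dj <- rep(2L, 10)
  cp <- ccc_pair(di, dj, method = "tally")
  expect_equal(cp$value, c(1, 0, 0, 0)) # T = 20 / min(20, 20)
  expect_equal(cp$tally, c(20, 0, 0, 0))
  # the odds-ratio facet needs contrast: a pair monomorphic at both SNPs
  # carries no correlation evidence (the constant-vector convention)
  expect_equal(ccc_pair(di, dj, method = "yule")$value, rep(0, 4))
  # with contrast present, perfect co-occurrence saturates the tally form
  # and comes within the smoothing pseudo-tallies of 1 for the Q form
  di2 <- c(rep(2L, 8), 0L, 0L)
  expect_gt(ccc_pair(di2, di2, method = "yule")$value[1], 0.95)
  expect_equal(ccc_pair(di2, di2, method = "tally")$value[1], 1)
})

test_that("samples carrying neither allele do not dilute a facet", {
  di <- c(rep(2L, 5), rep(0L, 5))
  dj <- c(rep(2L, 5), rep(0L, 5))
  expect_equal(ccc_pair(di, dj, method = "tally")$value[1], 1) # 10/min(10,10)
  expect_gt(ccc_pair(di, dj, method = "yule")$value[1], 0.95)
})

test_that("the worked tally example matches its brute-force oracle", {
  di <- c(2L, 1L, 1L, 0L)
  dj <- c(2L, 2L, 1L, 0L)
  cp <- ccc_pair(di, dj, method = "tally", denominator = "min")
  o <- oracle_facet_tally(di, dj, 1, 1)
  expect_equal(o$tally, 3.5)
  expect_equal(o$nu, 4)
  expect_equal(o$nv, 5)
  expect_equal(cp$value[1], 3.5 / 4) # 0.875
  expect_equal(cp$value[1], o$tally / min(o$nu, o$nv))
})

test_that("ccc_pair agrees with the per-sample oracle on random pairs", {
  set.seed(101)
  for (rep in 1:250) {
    n <- sample(4:25, 1)
    di <- sample(c(0:2, NA), n, replace = TRUE)
    dj <- sample(c(0:2, NA), n, replace = TRUE)
    if (!any(!is.na(di) & !is.na(dj))) next
    cp_t <- suppressWarnings(ccc_pair(di, dj, method = "tally"))
    expect_equal(cp_t$value, oracle_ccc_min(di, dj))
    cp_y <- suppressWarnings(ccc_pair(di, dj, method = "yule"))
    expect_equal(cp_y$value, oracle_ccc_yule(di, dj))
    # het weights 0 and 1 against the loop oracle, min denominator
    for (w in c(0, 1)) {
      cp_w <- suppressWarnings(ccc_pair(di, dj, method = "tally",
                                        het_weight = w))
      expect_equal(cp_w$value, oracle_ccc_min(di, dj, het_weight = w))
    }
  }
})

test_that("facet symmetry and allele-label equivariance hold", {
  set.seed(102)
  for (rep in 1:50) {
    di <- sample(c(0:2, NA), 30, replace = TRUE, prob = c(4, 3, 3, 1))
    dj <- sample(c(0:2, NA), 30, replace = TRUE, prob = c(3, 4, 3, 1))
    for (m in c("tally", "yule")) {
      ab <- suppressWarnings(ccc_pair(di, dj, method = m))
      ba <- suppressWarnings(ccc_pair(dj, di, method = m))
      # c[u,v] of (i,j) equals c[v,u] of (j,i)
      expect_equal(ab$value, ba$value[match(paste(ab$allele_j, ab$allele_i),
                                            paste(ba$allele_i, ba$allele_j))])
      # swapping allele labels at SNP i permutes facets without changing them
      sw <- suppressWarnings(ccc_pair(2L - di, dj, method = m))
      expect_equal(sw$value, ab$value[c(3, 4, 1, 2)])
    }
  }
})

test_that("appending samples without either allele never lowers a facet", {
  set.seed(103)
  for (rep in 1:25) {
    di <- sample(0:2, 20, replace = TRUE)
    dj <- sample(0:2, 20, replace = TRUE)
    base_t <- ccc_pair(di, dj, method = "tally")$value[1]
    base_y <- ccc_pair(di, dj, method = "yule")$value[1]
    di2 <- c(di, rep(0L, 15))
    dj2 <- c(dj, rep(0L, 15))
    # the raw tally facet is exactly invariant (tallies and margins frozen)
    expect_equal(ccc_pair(di2, dj2, method = "tally")$value[1], base_t)
    # the odds-ratio facet can only move up as the allele pair gets rarer
    expect_gte(ccc_pair(di2, dj2, method = "yule")$value[1], base_y - 1e-12)
  }
  # and a saturated facet stays saturated
  di <- c(rep(2L, 6), rep(0L, 4), rep(0L, 20))
  dj <- c(rep(2L, 6), rep(0L, 4), rep(0L, 20))
  expect_gt(ccc_pair(di, dj, method = "yule")$value[1], 0.99)
})

test_that("degenerate pairs are handled: length mismatch and all-missing", {
  expect_error(ccc_pair(c(0L, 1L), c(0L, 1L, 2L)), "equal length")
  expect_warning(cp <- ccc_pair(c(NA_integer_, NA), c(0L, NA)), "all facets")
  expect_equal(cp$value, rep(0, 4))
  expect_error(pcc_pair(c(0L, 1L), c(0L, 1L, 2L)), "equal length")
  expect_warning(p0 <- pcc_pair(c(NA_integer_, NA), c(0L, 1L)), "returning 0")
  expect_equal(p0, 0)
})

test_that("pcc_pair matches the textbook computation and its exact cases", {
  x <- c(0L, 1L, 2L, 1L, 0L, 2L)
  expect_equal(pcc_pair(x, x), 1)
  expect_equal(pcc_pair(x, 2L - x), -1)
  expect_equal(pcc_pair(rep(1L, 5), c(0L, 1L, 2L, 1L, 0L)), 0)
  set.seed(104)
  for (rep in 1:50) {
    a <- sample(c(0:2, NA), 100, replace = TRUE)
    b <- sample(c(0:2, NA), 100, replace = TRUE)
    expect_equal(suppressWarnings(pcc_pair(a, b)), oracle_pcc(a, b))
  }
})

test_that("ccc_scan equals full materialisation plus sort-and-cut", {
  set.seed(105)
  gm <- random_gm(30, 20, miss = 0.04)
  for (m in c("yule", "tally")) {
    full <- oracle_all_records(gm, method = m)
    for (k in c(1, 7, 40)) {
      got <- suppressWarnings(ccc_scan(gm, top_k = k, method = m))
      expect_equal(got$snp_i, full$snp_i[1:k])
      expect_equal(got$snp_j, full$snp_j[1:k])
      expect_equal(got$allele_i, full$allele_i[1:k])
      expect_equal(got$allele_j, full$allele_j[1:k])
      expect_equal(got$value, full$value[1:k])
      expect_equal(got$n_valid, full$n_valid[1:k])
      expect_equal(scan_cutoff(got), full$value[k])
    }
    thr <- suppressWarnings(ccc_scan(gm, threshold = 0.4, method = m))
    expect_equal(thr$value, full$value[full$value >= 0.4])
  }
  # blocked execution must give identical results
  one <- suppressWarnings(ccc_scan(gm, top_k = 25, block_size = 7L))
  two <- suppressWarnings(ccc_scan(gm, top_k = 25, block_size = 512L))
  expect_equal(as.data.frame(one), as.data.frame(two))
})

test_that("scan edge cases: cutoff definition, impossible thresholds, bad k", {
  set.seed(106)
  gm <- random_gm(15, 3, miss = 0)
  res <- ccc_scan(gm, top_k = 3)
  all12 <- oracle_all_records(gm)
  expect_equal(nrow(all12), 12)
  expect_equal(scan_cutoff(res), sort(all12$value, decreasing = TRUE)[3])

  expect_equal(nrow(ccc_scan(gm, threshold = 1.1)), 0) # facets are <= 1
  expect_error(ccc_scan(gm, top_k = 0), "positive")
  expect_error(ccc_scan(gm, top_k = 13), "available facet")
  expect_error(ccc_scan(gm, top_k = 2, threshold = 0.5), "exactly one")
  expect_error(ccc_scan(subset_genotypes(gm, snps = 1), top_k = 1),
               "at least 2 SNPs")
})

test_that("pair-missingness warnings fire above the configured fraction", {
  d <- matrix(1L, 10, 3)
  d[1:3, 1] <- NA # pair (1,2) and (1,3) exclude 30% of samples
  gm <- genotype_matrix(d)
  expect_warning(res <- ccc_scan(gm, top_k = 2, warn_missing_fraction = 0.2),
                 "2 SNP pair")
  mp <- attr(res, "missing_pairs")
  expect_equal(nrow(mp), 2)
  expect_equal(mp$excluded_fraction, c(0.3, 0.3))
  expect_silent(ccc_scan(gm, top_k = 2, warn_missing_fraction = 0.5))
})
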