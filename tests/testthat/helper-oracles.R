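# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorised code paths: explicit per-sample loops,
# union-find instead of graph traversal, and an algebraically different
# G-test formula.

# per-sample tally loop for one facet (u = slot of SNP i, v = slot of SNP j)
oracle_facet_tally <- function(di, dj, u, v, het_weight = 0.5) {
  t <- 0
  nu <- 0
  nv <- 0
  for (s in seq_along(di)) {
    if (is.na(di[s]) || is.na(dj[s])) next
    du <- if (u == 1) di[s] else 2 - di[s]
    dv <- if (v == 1) dj[s] else 2 - dj[s]
    nu <- nu + du
    nv <- nv + dv
    if (du == 2 && dv == 2) t <- t + 2
    else if ((du == 2 && dv == 1) || (du == 1 && dv == 2)) t <- t + 1
    else if (du == 1 && dv == 1) t <- t + het_weight
  }
  list(tally = t, nu = nu, nv = nv)
}

# all four facet values under the raw tally form with min denominator
oracle_ccc_min <- function(di, dj, het_weight = 0.5) {
  vals <- numeric(4)
  k <- 0
  for (u in 1:2) for (v in 1:2) {
    k <- k + 1
    o <- oracle_facet_tally(di, dj, u, v, het_weight)
    vals[k] <- if (min(o$nu, o$nv) == 0) 0 else o$tally / min(o$nu, o$nv)
  }
  vals # order (1,1), (1,2), (2,1), (2,2)
}

# odds-ratio-based facets from the per-sample tally table, with one
# pseudo-tally per cell and the no-contrast (absent allele) guard
oracle_ccc_yule <- function(di, dj) {
  o11 <- oracle_facet_tally(di, dj, 1, 1)
  o12 <- oracle_facet_tally(di, dj, 1, 2)
  o21 <- oracle_facet_tally(di, dj, 2, 1)
  o22 <- oracle_facet_tally(di, dj, 2, 2)
  ad <- (o11$tally + 1) * (o22$tally + 1)
  bc <- (o12$tally + 1) * (o21$tally + 1)
  q <- (ad - bc) / (ad + bc)
  if (o11$nu == 0 || o21$nu == 0 || o11$nv == 0 || o12$nv == 0) q <- 0
  c(max(q, 0), max(-q, 0), max(-q, 0), max(q, 0))
}

# textbook two-pass Pearson correlation
oracle_pcc <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  mx <- mean(x)
  my <- mean(y)
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  if (den == 0) 0 else sum((x - mx) * (y - my)) / den
}

# union-find connected components; returns membership vector
oracle_union_find <- function(n_nodes, edge_i, edge_j) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (e in seq_along(edge_i)) {
    ri <- find(edge_i[e])
    rj <- find(edge_j[e])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

# G statistic via the cell/margin entropy decomposition:
# G = 2 * (sum O ln O - sum_rows R ln R - sum_cols C ln C + n ln n)
oracle_g <- function(a, b, c, d) {
  xlx <- function(x) if (x == 0) 0 else x * log(x)
  n <- a + b + c + d
  2 * (xlx(a) + xlx(b) + xlx(c) + xlx(d) -
         xlx(a + b) - xlx(c + d) - xlx(a + c) - xlx(b + d) + xlx(n))
}

# full materialisation of every facet of every pair through ccc_pair(),
# sorted by the deterministic tie order
oracle_all_records <- function(gm, ...) {
  m <- n_snps(gm)
  rows <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      cp <- suppressWarnings(
        ccc_pair(gm$dosage[, i], gm$dosage[, j], ...))
      rows[[length(rows) + 1]] <- tibble::tibble(
        snp_i = i, snp_j = j, allele_i = cp$allele_i,
        allele_j = cp$allele_j, value = cp$value, n_valid = cp$n_valid
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out[order(-out$value, out$snp_i, out$snp_j, out$allele_i, out$allele_j), ]
}

# pairwise Hamming distances by double loop (9 = missing symbol)
hamming_rows_oracle <- function(x) {
  x[is.na(x)] <- 9L
  n <- nrow(x)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d[i, j] <- sum(x[i, ] != x[j, ])
  }
  d
}

# length of an open tour through rows of a distance matrix
tour_length <- function(d, ord) {
  if (length(ord) < 2) return(0)
  sum(d[cbind(ord[-length(ord)], ord[-1])])
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# a random small genotype matrix with missingness and both phenotypes
random_gm <- function(n = 20, m = 5, miss = 0.05) {
  d <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)[rep(1:m, each = n)]), n, m)
  d[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  a2 <- vapply(a1, function(x) sample(setdiff(bases, x), 1), "")
  genotype_matrix(
    d,
    snps = tibble::tibble(snp_id = sprintf("rs%03d", 1:m),
                          chrom = as.character(rep_len(1:22, m)),
                          pos = 1000L * (1:m), allele1 = a1,
                          allele2 = unname(a2)),
    samples = tibble::tibble(
      sample_id = sprintf("s%03d", 1:n),
      phenotype = rep(c("case", "control"), length.out = n)
    )
  )
}
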