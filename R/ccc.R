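# Facet tallies for one SNP pair. The half-weight tally T_uv counts
# guaranteed allele co-occurrences: a sample contributes d_u*d_v/2, i.e. 2
# for a double homozygote carrying both alleles twice, 1 for hom x het, and
# 1/2 for a double heterozygote (the expected co-occurrence under random
# phase). The four corner tallies always sum to twice the number of
# pairwise-complete samples.
ccc_tallies <- function(dosage_i, dosage_j) {
  if (length(dosage_i) != length(dosage_j)) {
    abort("dosage vectors must have equal length")
  }
  keep <- !is.na(dosage_i) & !is.na(dosage_j)
  di <- as.numeric(dosage_i[keep])
  dj <- as.numeric(dosage_j[keep])
  n_valid <- length(di)
  t11 <- sum(di * dj) / 2
  n1i <- sum(di)
  n1j <- sum(dj)
  list(
    t = c(`11` = t11, `12` = n1i - t11, `21` = n1j - t11,
          `22` = 2 * n_valid - n1i - n1j + t11),
    margin_i = c(n1i, 2 * n_valid - n1i),
    margin_j = c(n1j, 2 * n_valid - n1j),
    n_het = sum(di == 1 & dj == 1),
    n_valid = n_valid
  )
}

# corner-wise facet values from tallies; vectorised over matrices so the
# same algebra serves ccc_pair() and the blockwise scan
facet_values <- function(t11, t12, t21, t22, nu1, nu2, nv1, nv2, n_het,
                         method, denominator, het_weight) {
  if (het_weight != 0.5) {
    # reassign double heterozygotes: weight w to each facet of interest for
    # the tally form; for the odds-ratio form, w to the diagonal corners and
    # 1 - w to the off-diagonal corners (a phase assignment)
    dh <- (het_weight - 0.5) * n_het
  } else {
    dh <- 0
  }
  if (method == "yule") {
    # one pseudo-tally per cell (Laplace smoothing) keeps a single empty
    # cell in a rare x common pair from saturating the facet at 1 by chance
    a <- t11 + dh + 1
    d <- t22 + dh + 1
    b <- t12 - dh + 1
    cc <- t21 - dh + 1
    ad <- a * d
    bc <- b * cc
    q <- (ad - bc) / (ad + bc)
    # no contrast without both alleles observed at both SNPs
    q <- q * (nu1 > 0 & nu2 > 0 & nv1 > 0 & nv2 > 0)
    list(`11` = pmax(q, 0), `12` = pmax(-q, 0),
         `21` = pmax(-q, 0), `22` = pmax(q, 0))
  } else {
    den <- switch(denominator,
      min = list(pmin(nu1, nv1), pmin(nu1, nv2), pmin(nu2, nv1), pmin(nu2, nv2)),
      geom = list(sqrt(nu1 * nv1), sqrt(nu1 * nv2), sqrt(nu2 * nv1),
                  sqrt(nu2 * nv2)),
      `2n` = {
        tot <- (nu1 + nu2 + nv1 + nv2) / 2
        list(tot, tot, tot, tot)
      }
    )
    val <- function(t, dn) ifelse(dn <= 0, 0, pmin(pmax((t + dh) / dn, 0), 1))
    list(`11` = val(t11, den[[1]]), `12` = val(t12, den[[2]]),
         `21` = val(t21, den[[3]]), `22` = val(t22, den[[4]]))
  }
}

#' Four-facet custom correlation coefficient (CCC) for one SNP pair
#'
#' Computes one correlation value in \[0, 1\] for each of the four allele
#' combinations of two biallelic SNPs (allele1/allele1, allele1/allele2,
#' allele2/allele1, allele2/allele2), from fast co-occurrence tallies over
#' the samples with observed genotypes at both SNPs. Each facet measures its
#' own allele pair independently, so a correlation present in only a
#' subgroup of individuals is not diluted by unrelated samples the way a
#' single global coefficient would be.
#'
#' Samples missing at either SNP are omitted; missing data are never
#' imputed. A double heterozygote cannot be phased, so by default it
#' contributes weight 1/2 (its expected co-occurrence count under random
#' phase) to each facet; `het_weight` 0 and 1 give the conservative and
#' liberal assignments.
#'
#' Two facet parameterisations are available. The default,
#' `method = "yule"`, maps each pair's 2x2 tally table through Yule's
#' association coefficient Q = (ad - bc)/(ad + bc) and assigns Q (clipped to
#' \[0, 1\]) to the two corners on the associated diagonal. Because Q is a
#' function of the odds ratio it is calibrated against chance co-occurrence
#' at any allele frequency (independent SNPs score near 0 whether their
#' alleles are rare or common), yet remains concave in the co-occurrence
#' frequency, so a correlation confined to a subgroup retains a high score.
#' One pseudo-tally is added to every cell (Laplace smoothing) so that a
#' single empty cell of a rare x common pair cannot saturate the facet by
#' chance, and a pair where either SNP lacks one of its alleles carries no
#' contrast and scores 0 on all facets.
#' `method = "tally"` is the raw normalised tally T_uv / denom with
#' `denominator` choosing `min` (smaller allele count), `geom` (geometric
#' mean) or `2n` (twice the pairwise-complete sample count); it has no
#' chance correction and its null value grows with allele frequency.
#'
#' @param dosage_i,dosage_j Equal-length vectors of 0/1/2/`NA` allele1
#'   dosages.
#' @param method `"yule"` (default, odds-ratio based) or `"tally"`.
#' @param denominator Normalisation for `method = "tally"`: `"min"`,
#'   `"geom"` or `"2n"`.
#' @param het_weight Co-occurrence weight of a double heterozygote: 0, 0.5
#'   (default) or 1.
#' @return A tibble with one row per facet: `allele_i`, `allele_j` (slot 1
#'   or 2), `tally`, `value` and `n_valid`. Rows are ordered (1,1), (1,2),
#'   (2,1), (2,2).
#' @examples
#' ccc_pair(c(2, 1, 1, 0), c(2, 2, 1, 0), method = "tally")
#' @export
ccc_pair <- function(dosage_i, dosage_j, method = c("yule", "tally"),
                     denominator = c("min", "geom", "2n"), het_weight = 0.5) {
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  stopifnot(het_weight %in% c(0, 0.5, 1))
  tl <- ccc_tallies(dosage_i, dosage_j)
  if (tl$n_valid == 0L) {
    warn("no samples observed at both SNPs; all facets are 0")
  }
  f <- facet_values(tl$t[1], tl$t[2], tl$t[3], tl$t[4],
                    tl$margin_i[1], tl$margin_i[2],
                    tl$margin_j[1], tl$margin_j[2], tl$n_het,
                    method, denominator, het_weight)
  tibble(
    allele_i = c(1L, 1L, 2L, 2L),
    allele_j = c(1L, 2L, 1L, 2L),
    tally = unname(tl$t),
    value = unname(unlist(f)),
    n_valid = tl$n_valid
  )
}

#' Pearson correlation of two dosage vectors
#'
#' Ordinary Pearson correlation over pairwise-complete samples, the single
#' global coefficient CCC is contrasted with. Returns 0 when either vector
#' is constant on the complete pairs.
#'
#' @inheritParams ccc_pair
#' @return A single correlation in \[-1, 1\].
#' @export
pcc_pair <- function(dosage_i, dosage_j) {
  if (length(dosage_i) != length(dosage_j)) {
    abort("dosage vectors must have equal length")
  }
  keep <- !is.na(dosage_i) & !is.na(dosage_j)
  if (!any(keep)) {
    warn("no samples observed at both SNPs; returning 0")
    return(0)
  }
  x <- as.numeric(dosage_i[keep])
  y <- as.numeric(dosage_j[keep])
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(0)
  unname(cor(x, y))
}

#' Scan all SNP pairs and keep the strongest CCC facets
#'
#' Computes the four CCC facets for every pair of SNPs (via blocked matrix
#' cross-products, O(m^2 n) time) and returns either the `top_k` strongest
#' facet records or all records at or above a fixed `threshold`. Ties at the
#' cutoff are ordered deterministically by value (descending), then SNP
#' indices, then facet order (1,1), (1,2), (2,1), (2,2), and trimmed to
#' exactly `top_k`, so repeated runs produce identical record sets.
#'
#' One warning summarises SNP pairs whose excluded-sample fraction (missing
#' at either SNP) exceeds `warn_missing_fraction`; the offending pairs are
#' available in `attr(x, "missing_pairs")`.
#'
#' @param gm A [genotype_matrix()] with at least two SNPs.
#' @param top_k Number of facet records to keep (exactly one of `top_k`
#'   and `threshold` must be given). Must lie in \[1, 4 * choose(m, 2)\].
#' @param threshold Keep every facet with value >= `threshold`.
#' @param warn_missing_fraction Pair-missingness warning level (default
#'   0.05).
#' @inheritParams ccc_pair
#' @param block_size SNP-column block width for the crossproduct scan.
#' @return A tibble of correlation records: `snp_i`, `snp_j` (indices,
#'   `snp_i < snp_j`), `snp_id_i`, `snp_id_j`, `allele_i`, `allele_j`,
#'   `value`, `n_valid`, sorted by the deterministic tie order. Attributes:
#'   `cutoff` (the k-th value, or the threshold), `missing_pairs`, `method`,
#'   `denominator`, `het_weight`. See [scan_cutoff()].
#' @examples
#' gm <- simulate_dataset(30, 30, 6, seed = 1)$genotypes
#' rec <- ccc_scan(gm, top_k = 6)
#' scan_cutoff(rec)
#' @export
ccc_scan <- function(gm, top_k = NULL, threshold = NULL,
                     warn_missing_fraction = 0.05,
                     method = c("yule", "tally"),
                     denominator = c("min", "geom", "2n"),
                     het_weight = 0.5, block_size = 512L) {
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  stopifnot(het_weight %in% c(0, 0.5, 1))
  m <- n_snps(gm)
  if (m < 2L) abort("ccc_scan needs at least 2 SNPs")
  n_facets_total <- 4 * choose(m, 2)
  if (is.null(top_k) == is.null(threshold)) {
    abort("supply exactly one of `top_k` or `threshold`")
  }
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (top_k <= 0L) abort("`top_k` must be positive")
    if (top_k > n_facets_total) {
      abort(sprintf("`top_k` exceeds the %d available facet records",
                    n_facets_total))
    }
  }
  n <- n_samples(gm)
  M <- gm$dosage
  V <- (!is.na(M)) * 1
  D1 <- M
  D1[is.na(D1)] <- 0L
  storage.mode(D1) <- "double"
  Het <- if (het_weight != 0.5) (M == 1L & !is.na(M)) * 1 else NULL

  blocks <- split(seq_len(m), ceiling(seq_len(m) / block_size))
  acc <- list()
  acc_rows <- 0L
  lb <- if (is.null(threshold)) -Inf else threshold
  miss_pairs <- list()
  trim_at <- max(2e6, if (!is.null(top_k)) 4L * top_k else 0L)

  trim_acc <- function(recs, k) {
    df <- do.call(rbind, recs)
    o <- order(-df[, "value"], df[, "i"], df[, "j"], df[, "ai"], df[, "aj"])
    df <- df[o[seq_len(min(k, nrow(df)))], , drop = FALSE]
    df
  }

  for (bi in seq_along(blocks)) {
    for (bj in bi:length(blocks)) {
      I <- blocks[[bi]]
      J <- blocks[[bj]]
      t11 <- crossprod(D1[, I, drop = FALSE], D1[, J, drop = FALSE]) / 2
      a1 <- crossprod(D1[, I, drop = FALSE], V[, J, drop = FALSE])
      b1 <- crossprod(V[, I, drop = FALSE], D1[, J, drop = FALSE])
      nv <- crossprod(V[, I, drop = FALSE], V[, J, drop = FALSE])
      t12 <- a1 - t11
      t21 <- b1 - t11
      t22 <- 2 * nv - a1 - b1 + t11
      nh <- if (!is.null(Het)) {
        crossprod(Het[, I, drop = FALSE], Het[, J, drop = FALSE])
      } else 0
      fs <- facet_values(t11, t12, t21, t22,
                         nu1 = a1, nu2 = 2 * nv - a1,
                         nv1 = b1, nv2 = 2 * nv - b1,
                         n_het = nh, method, denominator, het_weight)
      mask <- if (bi == bj) upper.tri(t11) else
        matrix(TRUE, length(I), length(J))
      excl <- 1 - nv / n
      bad <- mask & excl > warn_missing_fraction
      if (any(bad)) {
        w <- which(bad)
        r <- (w - 1L) %% length(I) + 1L
        cc <- (w - 1L) %/% length(I) + 1L
        miss_pairs[[length(miss_pairs) + 1L]] <-
          cbind(i = I[r], j = J[cc], excluded_fraction = excl[w])
      }
      codes <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
      for (fc in 1:4) {
        vals <- fs[[fc]]
        sel <- which(mask & vals >= lb)
        if (!length(sel)) next
        r <- (sel - 1L) %% length(I) + 1L
        cc <- (sel - 1L) %/% length(I) + 1L
        acc[[length(acc) + 1L]] <- cbind(
          i = I[r], j = J[cc], ai = codes[[fc]][1], aj = codes[[fc]][2],
          value = vals[sel], n_valid = nv[sel]
        )
        acc_rows <- acc_rows + length(sel)
      }
      if (!is.null(top_k) && acc_rows > trim_at) {
        df <- trim_acc(acc, top_k)
        acc <- list(df)
        acc_rows <- nrow(df)
        if (acc_rows == top_k) lb <- df[top_k, "value"]
      }
    }
  }

  df <- if (length(acc)) do.call(rbind, acc) else
    matrix(numeric(0), 0, 6, dimnames = list(NULL,
      c("i", "j", "ai", "aj", "value", "n_valid")))
  o <- order(-df[, "value"], df[, "i"], df[, "j"], df[, "ai"], df[, "aj"])
  df <- df[o, , drop = FALSE]
  if (!is.null(top_k)) df <- df[seq_len(top_k), , drop = FALSE]
  out <- tibble(
    snp_i = as.integer(df[, "i"]), snp_j = as.integer(df[, "j"]),
    snp_id_i = gm$snps$snp_id[df[, "i"]],
    snp_id_j = gm$snps$snp_id[df[, "j"]],
    allele_i = as.integer(df[, "ai"]), allele_j = as.integer(df[, "aj"]),
    value = unname(df[, "value"]), n_valid = as.integer(df[, "n_valid"])
  )
  mp <- if (length(miss_pairs)) {
    mpm <- do.call(rbind, miss_pairs)
    mpm <- mpm[order(mpm[, "i"], mpm[, "j"]), , drop = FALSE]
    tibble(snp_i = as.integer(mpm[, "i"]), snp_j = as.integer(mpm[, "j"]),
           excluded_fraction = unname(mpm[, "excluded_fraction"]))
  } else {
    tibble(snp_i = integer(), snp_j = integer(),
           excluded_fraction = numeric())
  }
  if (nrow(mp)) {
    warn(sprintf(
      "%d SNP pair(s) exclude more than %.0f%% of samples for missing data",
      nrow(mp), 100 * warn_missing_fraction))
  }
  attr(out, "cutoff") <- if (!is.null(top_k)) {
    if (nrow(out)) min(out$value) else NA_real_
  } else threshold
  attr(out, "missing_pairs") <- mp
  attr(out, "method") <- method
  attr(out, "denominator") <- denominator
  attr(out, "het_weight") <- het_weight
  attr(out, "n_snps") <- m
  out
}

#' @rdname ccc_scan
#' @param records A record tibble returned by [ccc_scan()].
#' @export
scan_cutoff <- function(records) attr(records, "cutoff")
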