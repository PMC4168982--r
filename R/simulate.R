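#' Specify an embedded multi-SNP allele pattern
#'
#' Describes one bloc to be planted in a simulated dataset: a set of SNPs
#' whose pattern alleles travel together on a haplotype, carried at
#' different frequencies in cases and controls, optionally only within a
#' "carrier" subgroup of the sample (the rest of the sample receives the
#' same marginal allele frequencies with the co-occurrence broken —
#' subgroup heterogeneity).
#'
#' @param n_snps Number of SNPs in the pattern.
#' @param freq_cases,freq_controls Pattern haplotype frequency per group,
#'   in \[0, 1\]. The implied whole-pattern odds ratio is
#'   `odds_ratio_from_freq(freq_cases, freq_controls)`.
#' @param carrier_fraction Fraction of the sample in which the pattern's
#'   SNPs are mutually correlated (1 = homogeneous).
#' @param snp_indices Optional explicit column indices in the simulated
#'   matrix; by default blocs are placed after the background SNPs.
#' @return A `bloc_spec` list.
#' @export
bloc_spec <- function(n_snps, freq_cases, freq_controls,
                      carrier_fraction = 1, snp_indices = NULL) {
  stopifnot(n_snps >= 2, freq_cases >= 0, freq_cases <= 1,
            freq_controls >= 0, freq_controls <= 1,
            carrier_fraction >= 0, carrier_fraction <= 1)
  structure(list(n_snps = as.integer(n_snps), freq_cases = freq_cases,
                 freq_controls = freq_controls,
                 carrier_fraction = carrier_fraction,
                 snp_indices = snp_indices),
            class = "bloc_spec")
}

#' Simulate a case/control genotype dataset with embedded allele patterns
#'
#' Background SNPs are independent biallelic autosomal markers in
#' Hardy-Weinberg equilibrium with allele frequencies drawn uniformly on
#' \[0.05, 0.95\]. Each embedded pattern (see [bloc_spec()]) is placed
#' haplotype-style: a sample draws its pattern haplotype count k ~
#' Binomial(2, group frequency); within the carrier subgroup the k pattern
#' haplotypes carry the pattern allele at every bloc SNP jointly
#' (all-or-none), while outside the subgroup each haplotype carries the
#' pattern allele independently per SNP at the same marginal frequency, so
#' frequencies are preserved but co-occurrence is broken. Non-pattern
#' haplotypes carry the alternate allele. Missing genotypes are sprinkled
#' i.i.d. at `missing_rate`. Each bloc SNP's pattern allele is stored in
#' allele slot 1 or 2 at random, so downstream code cannot rely on
#' orientation. The same configuration and seed reproduce the dataset
#' exactly.
#'
#' @param n_cases,n_controls Group sizes.
#' @param n_background_snps Number of unassociated background SNPs.
#' @param bloc_specs A [bloc_spec()] or list of them.
#' @param missing_rate Per-genotype missing probability in \[0, 1).
#' @param seed Optional integer seed (caller RNG untouched).
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth`: a
#'   list holding `blocs` (tibble with `snp_indices`, `allele_slots`,
#'   frequencies, `implied_or`, `carrier_fraction` and per-bloc node ids),
#'   `pattern_haplotypes` (samples x blocs matrix of drawn k), `background_freq`,
#'   `carrier_samples` (list of index vectors) and `seed`.
#' @examples
#' sim <- simulate_dataset(50, 50, 20,
#'   bloc_specs = bloc_spec(4, 0.3, 0.1), seed = 7)
#' sim$truth$blocs
#' @export
simulate_dataset <- function(n_cases, n_controls, n_background_snps,
                             bloc_specs = list(), missing_rate = 0,
                             seed = NULL) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_background_snps >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (inherits(bloc_specs, "bloc_spec")) bloc_specs <- list(bloc_specs)
  run <- function() {
    n <- n_cases + n_controls
    is_case <- c(rep(TRUE, n_cases), rep(FALSE, n_controls))
    # resolve bloc SNP placement
    next_free <- n_background_snps
    for (i in seq_along(bloc_specs)) {
      if (is.null(bloc_specs[[i]]$snp_indices)) {
        bloc_specs[[i]]$snp_indices <- next_free + seq_len(bloc_specs[[i]]$n_snps)
        next_free <- next_free + bloc_specs[[i]]$n_snps
      }
    }
    all_bloc_cols <- unlist(lapply(bloc_specs, `[[`, "snp_indices"))
    if (anyDuplicated(all_bloc_cols)) {
      abort("embedded blocs may not share SNP indices")
    }
    m <- max(c(n_background_snps, all_bloc_cols, 0L))
    bg_cols <- setdiff(seq_len(m), all_bloc_cols)
    p_bg <- runif(length(bg_cols), 0.05, 0.95)
    dosage <- matrix(NA_integer_, n, m)
    for (jj in seq_along(bg_cols)) {
      dosage[, bg_cols[jj]] <- rbinom(n, 2L, p_bg[jj])
    }
    # SNP metadata: autosomes round-robin, increasing positions, random
    # allele letters; slot 1 is the stored-dosage allele
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, m, replace = TRUE)
    a2 <- vapply(a1, function(x) sample(setdiff(bases, x), 1), "")
    snps <- tibble(
      snp_id = sprintf("snp%05d", seq_len(m)),
      chrom = as.character(rep_len(1:22, m)),
      pos = 10000L + 500L * (seq_len(m) - 1L),
      allele1 = a1, allele2 = unname(a2)
    )
    khap <- matrix(NA_integer_, n, length(bloc_specs))
    slots_per_bloc <- vector("list", length(bloc_specs))
    carriers <- vector("list", length(bloc_specs))
    for (i in seq_along(bloc_specs)) {
      bs <- bloc_specs[[i]]
      f <- ifelse(is_case, bs$freq_cases, bs$freq_controls)
      k <- rbinom(n, 2L, f)
      khap[, i] <- k
      in_sub <- sample.int(n) <= round(bs$carrier_fraction * n)
      carriers[[i]] <- which(in_sub)
      cols <- bs$snp_indices
      pat <- matrix(0L, n, length(cols))
      pat[in_sub, ] <- k[in_sub] # joint placement: all-or-none per haplotype
      if (any(!in_sub)) {
        # same marginal frequency, independent per SNP and haplotype
        idx <- which(!in_sub)
        pat[idx, ] <- rbinom(length(idx) * length(cols), 2L, f[idx])
      }
      slots <- sample(1:2, length(cols), replace = TRUE)
      slots_per_bloc[[i]] <- slots
      for (jj in seq_along(cols)) {
        dosage[, cols[jj]] <- if (slots[jj] == 1L) pat[, jj] else 2L - pat[, jj]
      }
    }
    if (missing_rate > 0 && length(dosage)) {
      dosage[matrix(runif(n * m) < missing_rate, n, m)] <- NA_integer_
    }
    samples <- tibble(
      sample_id = sprintf("ind%05d", seq_len(n)),
      phenotype = ifelse(is_case, "case", "control")
    )
    gm <- genotype_matrix(dosage, snps = snps, samples = samples)
    truth_blocs <- purrr::imap_dfr(bloc_specs, function(bs, i) {
      slots <- slots_per_bloc[[i]]
      tibble(
        bloc = i, n_snps = bs$n_snps,
        freq_cases = bs$freq_cases, freq_controls = bs$freq_controls,
        implied_or = odds_ratio_from_freq(bs$freq_cases, bs$freq_controls),
        carrier_fraction = bs$carrier_fraction,
        snp_indices = list(bs$snp_indices),
        allele_slots = list(slots),
        node_ids = list(node_id(bs$snp_indices, slots))
      )
    })
    list(genotypes = gm,
         truth = list(blocs = truth_blocs, pattern_haplotypes = khap,
                      background_freq = setNames(p_bg, snps$snp_id[bg_cols]),
                      carrier_samples = carriers, seed = seed))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a two-SNP pair with subgroup-restricted correlation
#'
#' The classic heterogeneity scenario: in the first `n_correlated` samples
#' the two minor alleles co-occur perfectly on haplotypes (dosages are
#' identical); in the remaining samples the alleles are carried
#' independently at the same marginal frequency. A global coefficient such
#' as Pearson's r is dragged down by the uncorrelated samples roughly in
#' proportion to their share, while the allele-specific CCC facet for the
#' correlated pair stays high.
#'
#' @param n_correlated,n_uncorrelated Sample counts for the two subgroups.
#' @param p Marginal minor-allele frequency of both SNPs.
#' @param seed Optional integer seed.
#' @return A [genotype_matrix()] with two SNPs; samples are phenotype
#'   "unknown" (the scenario concerns correlation, not association).
#' @export
simulate_het_pair <- function(n_correlated, n_uncorrelated, p = 0.15,
                               seed = NULL) {
  stopifnot(n_correlated >= 0, n_uncorrelated >= 0, p >= 0, p <= 1)
  run <- function() {
    k <- rbinom(n_correlated, 2L, p)
    du <- c(k, rbinom(n_uncorrelated, 2L, p))
    dv <- c(k, rbinom(n_uncorrelated, 2L, p))
    genotype_matrix(
      cbind(du, dv),
      snps = tibble(snp_id = c("snpA", "snpB"), chrom = c("1", "2"),
                    pos = c(10000L, 20000L), allele1 = c("T", "G"),
                    allele2 = c("C", "A"))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Score recovery of embedded blocs by the pipeline
#'
#' Matches each embedded bloc from [simulate_dataset()] truth to the
#' extracted bloc with the highest Jaccard index on allele-node sets and
#' reports node precision and recall, plus (when association results are
#' supplied) the absolute error of the estimated odds ratio against the
#' odds ratio implied by the simulated group frequencies.
#'
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @param blocs [extract_blocs()] tibble from the pipeline run.
#' @param associations Optional [test_all_blocs()] tibble.
#' @return A tibble with one row per embedded bloc: `bloc`, `jaccard`,
#'   `precision`, `recall`, `matched_bloc_id`, and when available
#'   `estimated_or`, `implied_or`, `or_abs_error`.
#' @export
evaluate_recovery <- function(truth, blocs, associations = NULL) {
  purrr::pmap_dfr(truth$blocs, function(...) {
    tb <- list(...)
    ref <- tb$node_ids
    if (!nrow(blocs)) {
      return(tibble(bloc = tb$bloc, jaccard = 0, precision = NA_real_,
                    recall = 0, matched_bloc_id = NA_integer_))
    }
    jac <- purrr::map_dbl(blocs$node_ids, function(nodes) {
      length(intersect(nodes, ref)) / length(union(nodes, ref))
    })
    best <- which.max(jac)
    hit <- length(intersect(blocs$node_ids[[best]], ref))
    out <- tibble(
      bloc = tb$bloc, jaccard = jac[best],
      precision = hit / blocs$n_nodes[best],
      recall = hit / length(ref),
      matched_bloc_id = blocs$bloc_id[best]
    )
    if (!is.null(associations) && nrow(associations)) {
      row <- associations[associations$bloc_id == blocs$bloc_id[best], ]
      if (nrow(row) == 1L) {
        est <- row$odds_ratio
        # the matched bloc may be oriented as the complement pattern; its
        # association row carries the complement OR in that case
        out$estimated_or <- est
        out$implied_or <- tb$implied_or
        out$or_abs_error <- abs(est - tb$implied_or)
      }
    }
    out
  })
}
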