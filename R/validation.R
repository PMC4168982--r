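#' Shuffle genotypes within each SNP
#'
#' Independently permutes every SNP's dosage column (missing entries
#' included) across samples, destroying inter-SNP correlations while each
#' SNP keeps exactly its original allele frequencies and balance of
#' genotype states. Used to estimate the largest correlation value that
#' random chance can produce from these marginals.
#'
#' @param gm A [genotype_matrix()].
#' @param seed Optional integer; when given the shuffle is reproducible and
#'   the caller's RNG state is untouched.
#' @return A [genotype_matrix()] with shuffled columns.
#' @export
shuffle_genotypes <- function(gm, seed = NULL) {
  shuffle <- function() {
    d <- gm$dosage
    n <- nrow(d)
    if (n > 1L) for (j in seq_len(ncol(d))) d[, j] <- d[sample.int(n), j]
    gm$dosage <- d
    gm
  }
  if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
}

new_permutation_null <- function(kind, maxima, seed, extra = list()) {
  structure(c(list(kind = kind, n_trials = length(maxima), maxima = maxima,
                   seed = seed), extra),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> kind=%s trials=%d max=%.4f\n",
              x$kind, x$n_trials, max(x$maxima)))
  if (!is.null(x$threshold)) {
    cat(sprintf("  empirical threshold: %.4f\n", x$threshold))
  }
  if (!is.null(x$pass)) cat(sprintf("  verdict: %s\n",
                                    if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @method tidy permutation_null
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble(trial = seq_along(x$maxima), maximum = x$maxima)
}

#' @method glance permutation_null
#' @export
glance.permutation_null <- function(x, ...) {
  tibble(kind = x$kind, n_trials = x$n_trials, max = max(x$maxima),
         threshold = x$threshold %||% NA_real_,
         pass = x$pass %||% NA)
}

#' Phenotype-label permutation null for bloc G scores
#'
#' Each trial reassigns the samples at random into groups of the original
#' case and control sizes, recomputes the G score of every bloc, and
#' records the trial maximum. The empirical family-wise threshold is the
#' (1 - alpha) quantile of the per-trial maxima, and each bloc's corrected
#' p-value is the fraction of trials whose maximum reaches its observed G
#' (the max-statistic method). Pattern dosages do not depend on phenotype,
#' so they are computed once and only the labels move.
#'
#' @param gm A [genotype_matrix()] with case and control labels.
#' @param blocs Tibble from [extract_blocs()]; must be non-empty.
#' @param n_trials Number of permutations.
#' @param alpha Family-wise level for the empirical threshold.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param max_missing Bloc missingness allowance, as in [pattern_dosage()].
#' @return A `permutation_null` object with elements `maxima`, `threshold`
#'   (empirical G at `alpha`), `observed_g` and `p_corrected` per bloc
#'   (tibble `bloc_stats`), and `seed`.
#' @export
permute_phenotype_null <- function(gm, blocs, n_trials, alpha = 0.05,
                                   seed = NULL, max_missing = 0.05) {
  if (!nrow(blocs)) abort("no blocs to permute")
  stopifnot(n_trials >= 1)
  ph <- gm$samples$phenotype
  labelled <- which(ph != "unknown")
  is_case <- ph[labelled] == "case"
  n_case <- sum(is_case)
  if (n_case == 0L || n_case == length(labelled)) {
    abort("phenotype permutation needs both cases and controls")
  }
  pd <- pattern_dosage_matrix(gm, blocs, max_missing = max_missing)[labelled, ,
                                                                    drop = FALSE]
  ok <- !is.na(pd)
  pd0 <- pd
  pd0[!ok] <- 0L
  g_for <- function(case_mask) {
    a <- colSums(pd0 * case_mask)
    ncu <- colSums(ok * case_mask)
    b <- colSums(pd0 * !case_mask)
    nku <- colSums(ok * !case_mask)
    g_stat_vec(a, b, 2 * ncu - a, 2 * nku - b)
  }
  observed <- g_for(is_case)
  run <- function() {
    vapply(seq_len(n_trials), function(t) {
      perm <- is_case[sample.int(length(labelled))]
      max(g_for(perm), na.rm = TRUE)
    }, numeric(1))
  }
  maxima <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  threshold <- sort(maxima)[ceiling((1 - alpha) * n_trials)]
  p_corr <- vapply(observed, function(g) {
    if (is.na(g)) NA_real_ else mean(maxima >= g)
  }, numeric(1))
  new_permutation_null(
    "phenotype_labels", maxima, seed,
    extra = list(threshold = threshold, alpha = alpha,
                 bloc_stats = tibble(bloc_id = blocs$bloc_id,
                                     observed_g = observed,
                                     p_corrected = p_corr))
  )
}

#' Genotype-shuffle null of the maximum CCC facet
#'
#' Each trial shuffles every SNP's genotypes across samples (see
#' [shuffle_genotypes()]) and scans all pairs for the maximum facet value.
#' If no correlation survives shuffling above the original network's edge
#' cutoff, false-positive edges are unlikely in the original network; the
#' verdict is PASS when the overall maximum stays below `cutoff`.
#'
#' @param gm A [genotype_matrix()].
#' @param n_trials Number of shuffle trials.
#' @param seed Optional integer seed.
#' @param cutoff The original network's minimum edge value to compare
#'   against (optional).
#' @inheritParams ccc_scan
#' @return A `permutation_null` object with per-trial maxima, `max_overall`,
#'   and when `cutoff` is given, `cutoff`, `pass` (overall max < cutoff)
#'   and `prop_below` (fraction of trials whose maximum is below the
#'   cutoff).
#' @export
null_max_ccc <- function(gm, n_trials, seed = NULL, cutoff = NULL,
                         method = c("yule", "tally"),
                         denominator = c("min", "geom", "2n"),
                         het_weight = 0.5) {
  stopifnot(n_trials >= 1)
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  run <- function() {
    vapply(seq_len(n_trials), function(t) {
      sh <- shuffle_genotypes(gm)
      rec <- ccc_scan(sh, top_k = 1L, method = method,
                      denominator = denominator, het_weight = het_weight,
                      warn_missing_fraction = 1)
      rec$value[1]
    }, numeric(1))
  }
  maxima <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  extra <- list(max_overall = max(maxima))
  if (!is.null(cutoff)) {
    extra$cutoff <- cutoff
    extra$pass <- max(maxima) < cutoff
    extra$prop_below <- mean(maxima < cutoff)
  }
  new_permutation_null("genotype_shuffle", maxima, seed, extra = extra)
}

#' Bootstrap stability of a bloc's odds ratio
#'
#' Repeatedly subsamples a fraction of the cases and of the controls
#' without replacement, recomputing the bloc's odds ratio and raw G-test
#' p-value each time. Reports the mean odds ratio over trials with the 95%
#' interval of the trial mean (mean +/- 1.96 sd/sqrt(n_trials)) and the
#' mean p-value. A stable pattern keeps a tight interval around the
#' full-sample estimate.
#'
#' @inheritParams pattern_dosage
#' @param n_trials Number of subsampling trials.
#' @param fraction Fraction of each group drawn per trial, in (0, 1\].
#' @param seed Optional integer seed.
#' @return A `bloc_bootstrap` object (list): `n_trials`, `fraction`,
#'   `or_mean`, `or_ci`, `p_mean`, `trials` (tibble of per-trial
#'   `odds_ratio` and `p_raw`), `seed`.
#' @export
bootstrap_bloc <- function(gm, bloc, n_trials = 1000, fraction = 0.5,
                           seed = NULL, max_missing = 0.05) {
  stopifnot(n_trials >= 1, fraction > 0, fraction <= 1)
  d <- pattern_dosage(gm, bloc, max_missing = max_missing)
  ph <- gm$samples$phenotype
  cases <- which(ph == "case")
  controls <- which(ph == "control")
  n_ca <- floor(fraction * length(cases))
  n_co <- floor(fraction * length(controls))
  if (n_ca < 1L || n_co < 1L) abort("subsample too small to form a table")
  one_trial <- function() {
    sc <- if (n_ca == length(cases)) cases else cases[sample.int(length(cases), n_ca)]
    sk <- if (n_co == length(controls)) controls else
      controls[sample.int(length(controls), n_co)]
    dc <- d[sc]
    dk <- d[sk]
    ncu <- sum(!is.na(dc))
    nku <- sum(!is.na(dk))
    if (ncu == 0L || nku == 0L) return(c(NA_real_, NA_real_))
    a <- sum(dc, na.rm = TRUE)
    b <- sum(dk, na.rm = TRUE)
    or <- odds_ratio_ci(a, b, 2 * ncu - a, 2 * nku - b)$odds_ratio
    g <- g_stat_vec(a, b, 2 * ncu - a, 2 * nku - b)
    c(or, pchisq(g, 1, lower.tail = FALSE))
  }
  run <- function() t(vapply(seq_len(n_trials), function(i) one_trial(),
                             numeric(2)))
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ors <- res[, 1]
  se <- if (n_trials > 1) sd(ors, na.rm = TRUE) / sqrt(sum(!is.na(ors))) else 0
  or_mean <- mean(ors, na.rm = TRUE)
  structure(list(
    n_trials = n_trials, fraction = fraction, or_mean = or_mean,
    or_ci = c(or_mean - 1.96 * se, or_mean + 1.96 * se),
    p_mean = mean(res[, 2], na.rm = TRUE),
    trials = tibble(odds_ratio = ors, p_raw = res[, 2]), seed = seed
  ), class = "bloc_bootstrap")
}

#' @export
print.bloc_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<bloc_bootstrap> %d trials at fraction %.2f: OR mean %.3f (CI %.3f-%.3f), mean p %.3g\n",
    x$n_trials, x$fraction, x$or_mean, x$or_ci[1], x$or_ci[2], x$p_mean))
  invisible(x)
}

#' @method glance bloc_bootstrap
#' @export
glance.bloc_bootstrap <- function(x, ...) {
  tibble(n_trials = x$n_trials, fraction = x$fraction, or_mean = x$or_mean,
         or_ci_low = x$or_ci[1], or_ci_high = x$or_ci[2], p_mean = x$p_mean)
}

# Hamming distance between rows of an integer matrix (NA = its own symbol)
hamming_rows <- function(x) {
  x[is.na(x)] <- 9L
  n <- nrow(x)
  d <- matrix(0L, n, n)
  for (j in seq_len(ncol(x))) d <- d + outer(x[, j], x[, j], "!=")
  d
}

# greedy nearest-neighbour chain + 2-opt improvement on a distance matrix;
# returns a row ordering. 2-opt reversals are restricted to a sliding
# window so the improvement stays near-linear in the number of rows.
order_by_similarity <- function(d, max_sweeps = 3L, window = 60L) {
  n <- nrow(d)
  if (n <= 2L) return(seq_len(n))
  visited <- logical(n)
  tour <- integer(n)
  tour[1] <- 1L
  visited[1] <- TRUE
  for (i in 2:n) {
    cand <- d[tour[i - 1L], ]
    cand[visited] <- Inf
    tour[i] <- which.min(cand)
    visited[tour[i]] <- TRUE
  }
  # 2-opt on the open path: reverse segments while that shortens the path
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in 1:(n - 2L)) {
      for (j in (i + 1L):min(n, i + window)) {
        old <- (if (i == 1L) 0 else d[tour[i - 1L], tour[i]]) +
          (if (j == n) 0 else d[tour[j], tour[j + 1L]])
        new <- (if (i == 1L) 0 else d[tour[i - 1L], tour[j]]) +
          (if (j == n) 0 else d[tour[i], tour[j + 1L]])
        if (new < old) {
          tour[i:j] <- rev(tour[i:j])
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  tour
}

#' Order individuals for visual inspection of a bloc
#'
#' Extracts the bloc's genotype submatrix, encodes each cell by pattern
#' allele dosage (2 = homozygous pattern, 1 = heterozygous, 0 = homozygous
#' alternate, 9 = missing), and orders the samples within each phenotype
#' group so that similar rows sit together: a greedy nearest-neighbour
#' chain on Hamming distance between rows, improved by 2-opt segment
#' reversal, with `k_clusters - 1` cut points placed at the largest
#' adjacent distances. All samples are included, including those the
#' contingency table excluded for missingness.
#'
#' @inheritParams pattern_dosage
#' @param k_clusters Number of visual clusters per group (>= 1).
#' @return A list with `ordering` (sample indices into `gm`, cases first),
#'   `codes` (ordered integer matrix, samples x bloc SNPs, values 0/1/2/9),
#'   `group` (phenotype per ordered row) and `cuts` (ordered row indices
#'   after which a cluster boundary falls).
#' @seealso [plot_bloc_genotypes()]
#' @export
order_individuals_for_plot <- function(gm, bloc, k_clusters = 1L) {
  b <- as_bloc(bloc)
  sub <- gm$dosage[, b$snp_indices, drop = FALSE]
  flip <- which(b$allele_slots == 2L)
  if (length(flip)) sub[, flip] <- 2L - sub[, flip, drop = FALSE]
  ph <- gm$samples$phenotype
  ordering <- integer(0)
  cuts <- integer(0)
  for (grp in c("case", "control", "unknown")) {
    idx <- which(ph == grp)
    if (!length(idx)) next
    d <- hamming_rows(sub[idx, , drop = FALSE])
    ord <- order_by_similarity(d)
    if (k_clusters > 1L && length(ord) > 1L) {
      adj <- d[cbind(ord[-length(ord)], ord[-1])]
      brk <- order(-adj)[seq_len(min(k_clusters - 1L, length(adj)))]
      cuts <- c(cuts, length(ordering) + sort(brk))
    }
    ordering <- c(ordering, idx[ord])
  }
  codes <- sub[ordering, , drop = FALSE]
  codes[is.na(codes)] <- 9L
  colnames(codes) <- gm$snps$snp_id[b$snp_indices]
  list(ordering = ordering, codes = codes, group = ph[ordering], cuts = cuts)
}
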