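#' Per-sample pattern dosage for a bloc
#'
#' A bloc's allele pattern is carried 0, 1 or 2 times by a diploid sample:
#' the number of its two allelic combinations consistent with the entire
#' pattern, computed as the minimum over the bloc's (SNP, allele) pairs of
#' the sample's dosage of that allele. The whole pattern must be present to
#' count: lacking the allele at any single SNP gives 0. Samples missing
#' more than `max_missing` of the bloc's genotypes are excluded (`NA`);
#' missing genotypes within the allowance are non-constraining (they enter
#' the minimum as 2, since presence is judged on observed genotypes only).
#'
#' @param gm A [genotype_matrix()].
#' @param bloc A row of [extract_blocs()] output, or a list with
#'   `snp_indices` and `allele_slots`.
#' @param max_missing Per-sample missing-fraction allowance within the bloc
#'   (default 0.05; strictly greater is excluded).
#' @return Integer vector over samples: 0/1/2, or `NA` for excluded
#'   samples.
#' @export
pattern_dosage <- function(gm, bloc, max_missing = 0.05) {
  b <- as_bloc(bloc)
  if (any(b$snp_indices > n_snps(gm)) || any(b$snp_indices < 1L)) {
    abort("bloc references a SNP absent from the genotype matrix")
  }
  sub <- gm$dosage[, b$snp_indices, drop = FALSE]
  flip <- which(b$allele_slots == 2L)
  if (length(flip)) sub[, flip] <- 2L - sub[, flip, drop = FALSE]
  miss <- rowMeans(is.na(sub))
  sub[is.na(sub)] <- 2L
  d <- sub[, 1]
  for (jj in seq_len(ncol(sub))[-1]) d <- pmin(d, sub[, jj])
  d[miss > max_missing] <- NA_integer_
  as.integer(d)
}

# pattern dosages for many blocs at once: samples x blocs matrix
pattern_dosage_matrix <- function(gm, blocs, max_missing = 0.05) {
  out <- matrix(NA_integer_, n_samples(gm), nrow(blocs))
  for (k in seq_len(nrow(blocs))) {
    out[, k] <- pattern_dosage(gm, blocs[k, ], max_missing = max_missing)
  }
  colnames(out) <- as.character(blocs$bloc_id)
  out
}

#' Whole-pattern 2x2 contingency table for a bloc
#'
#' Tallies the bloc pattern over the two allelic combinations of every
#' usable case and control: `a`/`b` are the pattern counts in cases and
#' controls, `c`/`d` the non-pattern counts, so `a + c` is twice the number
#' of usable cases. Samples excluded by the bloc missingness rule, and
#' samples of unknown phenotype, are ignored.
#'
#' @inheritParams pattern_dosage
#' @return One-row tibble: `a`, `b`, `c`, `d`, `n_cases_used`,
#'   `n_controls_used`, `p_freq` (= a/(a+c)), `q_freq` (= b/(b+d)).
#' @export
bloc_contingency <- function(gm, bloc, max_missing = 0.05) {
  d <- pattern_dosage(gm, bloc, max_missing = max_missing)
  ph <- gm$samples$phenotype
  dc <- d[ph == "case"]
  dk <- d[ph == "control"]
  ncu <- sum(!is.na(dc))
  nku <- sum(!is.na(dk))
  if (ncu == 0L || nku == 0L) {
    abort("no usable samples in cases and/or controls for this bloc")
  }
  a <- sum(dc, na.rm = TRUE)
  b <- sum(dk, na.rm = TRUE)
  tibble(a = a, b = b, c = 2L * ncu - a, d = 2L * nku - b,
         n_cases_used = ncu, n_controls_used = nku,
         p_freq = a / (2 * ncu), q_freq = b / (2 * nku))
}

#' Odds ratio with 95% confidence interval
#'
#' OR = ad/(bc) with the standard log-scale Wald interval
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). No continuity
#' correction is applied: any zero cell leaves the odds ratio undefined and
#' is flagged instead.
#'
#' @param a,b,c,d Non-negative cell counts (pattern/non-pattern in
#'   cases/controls).
#' @return One-row tibble: `odds_ratio`, `ci_low`, `ci_high`, `log_se`,
#'   `or_defined`.
#' @examples
#' odds_ratio_from_freq(0.220, 0.072) # 3.64
#' @export
odds_ratio_ci <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (min(a, b, c, d) == 0) {
    return(tibble(odds_ratio = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, log_se = NA_real_, or_defined = FALSE))
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(odds_ratio = or, ci_low = exp(log(or) - 1.96 * se),
         ci_high = exp(log(or) + 1.96 * se), log_se = se, or_defined = TRUE)
}

#' @rdname odds_ratio_ci
#' @param p,q Pattern frequencies in cases and controls; the equivalent
#'   frequency form OR = p(1-q) / (q(1-p)).
#' @export
odds_ratio_from_freq <- function(p, q) {
  stopifnot(p >= 0, p <= 1, q >= 0, q <= 1)
  p * (1 - q) / (q * (1 - p))
}

#' G-test of independence for a 2x2 table
#'
#' G = 2 sum O ln(O/E) over the four cells, with expected counts from the
#' marginal products; observed zeros contribute nothing. G converges to a
#' chi-squared distribution with one degree of freedom, giving the
#' upper-tail p-value. A zero expected count (an empty margin) leaves the
#' test undefined and is flagged.
#'
#' @inheritParams odds_ratio_ci
#' @return One-row tibble: `g`, `p_raw`, `df`, `g_defined`.
#' @export
g_test <- function(a, b, c, d) {
  g <- g_stat_vec(a, b, c, d)
  tibble(g = g, p_raw = pchisq(g, df = 1, lower.tail = FALSE), df = 1L,
         g_defined = !is.na(g))
}

# vectorised G statistic; NA when any expected count is 0
g_stat_vec <- function(a, b, c, d) {
  n <- a + b + c + d
  e_a <- (a + c) * (a + b) / n
  e_b <- (b + d) * (a + b) / n
  e_c <- (a + c) * (c + d) / n
  e_d <- (b + d) * (c + d) / n
  term <- function(o, e) ifelse(o == 0, 0, o * log(o / e))
  g <- 2 * (term(a, e_a) + term(b, e_b) + term(c, e_c) + term(d, e_d))
  ifelse(e_a <= 0 | e_b <= 0 | e_c <= 0 | e_d <= 0, NA_real_, g)
}

#' Bonferroni correction and the critical G score
#'
#' `bonferroni()` multiplies a raw p-value by the number of tests (capped
#' at 1). `critical_g()` is the G score whose Bonferroni-corrected p equals
#' `alpha`: the chi-squared(1) quantile at 1 - alpha/m. With the 54,425
#' blocs of a genome-wide network and alpha 0.05 this is 24.1.
#'
#' @param p_raw Raw p-value(s).
#' @param m_tests Number of tests (>= 1).
#' @param alpha Family-wise significance level in (0, 1).
#' @return Corrected p-value(s) / the critical G score.
#' @examples
#' critical_g(0.05, 54425) # 24.1
#' @export
bonferroni <- function(p_raw, m_tests) {
  stopifnot(m_tests >= 1)
  pmin(1, p_raw * m_tests)
}

#' @rdname bonferroni
#' @export
critical_g <- function(alpha, m_tests) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  stopifnot(m_tests >= 1)
  qchisq(1 - alpha / m_tests, df = 1)
}

#' Complement of a bloc's allele pattern
#'
#' The same SNPs with every allele replaced by its alternate. When a bloc
#' pattern is protective its complement is typically a risk pattern on the
#' same table margins, so significant blocs are tested in both directions.
#' `complement_bloc()` is an involution.
#'
#' @inheritParams pattern_dosage
#' @return A bloc list with `snp_indices` and flipped `allele_slots`.
#' @export
complement_bloc <- function(bloc) {
  b <- as_bloc(bloc)
  b$allele_slots <- 3L - b$allele_slots
  b
}

#' Test every bloc's allele pattern for case/control association
#'
#' For each bloc carried by at least `min_carriers` individuals in the
#' entire sample (pattern dosage >= 1, any phenotype), computes the
#' whole-pattern contingency table, pattern frequencies, odds ratio with
#' 95% CI, the G-test with its Bonferroni-corrected p-value, and the same
#' statistics for the complement pattern. The number of tests `m_tests` is
#' the number of blocs passing the carrier filter; a complement is the same
#' 2x2 table with relabelled columns, not an independent test.
#'
#' @param gm A [genotype_matrix()].
#' @param blocs Tibble from [extract_blocs()].
#' @param min_carriers Carrier filter (default 10 individuals).
#' @param alpha Significance level used for the reported critical G.
#' @param max_missing Bloc missingness allowance per sample (default 0.05).
#' @return A tibble sorted by corrected p with one row per tested bloc:
#'   identity and size columns, `n_carriers`, table counts, `p_freq`,
#'   `q_freq`, `odds_ratio`, `ci_low`, `ci_high`, `or_defined`, `g`,
#'   `p_raw`, `p_corrected`, complement columns (`comp_*`), and `m_tests`.
#'   Attribute `critical_g` holds the Bonferroni critical G for
#'   (`alpha`, `m_tests`).
#' @export
test_all_blocs <- function(gm, blocs, min_carriers = 10, alpha = 0.05,
                           max_missing = 0.05) {
  if (!nrow(blocs)) {
    out <- tibble(bloc_id = integer(), n_snps = integer(),
                  n_carriers = integer(), m_tests = integer())
    attr(out, "critical_g") <- NA_real_
    return(out)
  }
  pd <- pattern_dosage_matrix(gm, blocs, max_missing = max_missing)
  carriers <- colSums(pd >= 1L, na.rm = TRUE)
  keep <- which(carriers >= min_carriers)
  m_tests <- length(keep)
  rows <- purrr::map(keep, function(k) {
    bloc <- blocs[k, ]
    tab <- bloc_contingency(gm, bloc, max_missing = max_missing)
    orci <- odds_ratio_ci(tab$a, tab$b, tab$c, tab$d)
    gt <- g_test(tab$a, tab$b, tab$c, tab$d)
    comp <- complement_bloc(bloc)
    ctab <- bloc_contingency(gm, comp, max_missing = max_missing)
    corci <- odds_ratio_ci(ctab$a, ctab$b, ctab$c, ctab$d)
    cgt <- g_test(ctab$a, ctab$b, ctab$c, ctab$d)
    dplyr::bind_cols(
      tibble(bloc_id = bloc$bloc_id, n_snps = bloc$n_snps,
             n_nodes = bloc$n_nodes, n_carriers = unname(carriers[k])),
      tab, orci, gt[c("g", "p_raw", "g_defined")],
      tibble(comp_p_freq = ctab$p_freq, comp_q_freq = ctab$q_freq,
             comp_odds_ratio = corci$odds_ratio,
             comp_ci_low = corci$ci_low, comp_ci_high = corci$ci_high,
             comp_g = cgt$g, comp_p_raw = cgt$p_raw)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$p_corrected <- bonferroni(out$p_raw, m_tests)
    out$m_tests <- m_tests
    out <- dplyr::arrange(out, .data$p_corrected, .data$p_raw, .data$bloc_id)
    out <- dplyr::relocate(out, "p_corrected", .after = "p_raw")
  }
  attr(out, "critical_g") <- critical_g(alpha, max(m_tests, 1))
  out
}
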