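#' Construct a genotype matrix object
#'
#' The canonical in-memory container used throughout blocnet: an integer
#' dosage matrix (samples in rows, SNPs in columns) counting copies of each
#' SNP's `allele1`, together with SNP and sample metadata. Missing genotypes
#' are `NA` and are never imputed by any blocnet operation.
#'
#' @param dosage Integer matrix of 0/1/2/`NA` allele1 counts, samples x SNPs.
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`, `allele1`,
#'   `allele2`. Defaults are generated from column names when omitted.
#' @param samples Tibble with columns `sample_id` and `phenotype`
#'   (`"case"`, `"control"` or `"unknown"`). Defaults are generated from row
#'   names when omitted.
#' @param phenotype Optional character/factor shortcut for
#'   `samples$phenotype`, recycled checks applied.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `snps` and `samples`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, NA), 2, 2,
#'          dimnames = list(c("s1", "s2"), c("rs1", "rs2"))),
#'   phenotype = c("case", "control")
#' )
#' n_snps(gm)
#' snp_missingness(gm)
#' @export
genotype_matrix <- function(dosage, snps = NULL, samples = NULL,
                            phenotype = NULL) {
  if (!is.matrix(dosage)) abort("`dosage` must be a matrix")
  storage.mode(dosage) <- "integer"
  m <- ncol(dosage)
  n <- nrow(dosage)
  if (is.null(snps)) {
    ids <- colnames(dosage) %||% sprintf("snp%05d", seq_len(m))
    snps <- tibble(
      snp_id = ids, chrom = "1", pos = seq_len(max(m, 1L)),
      allele1 = "A", allele2 = "C"
    )
    if (m == 0L) snps <- snps[0, ]
  }
  snps <- as_tibble(snps)
  if (is.null(samples)) {
    ids <- rownames(dosage) %||% sprintf("sample%05d", seq_len(n))
    samples <- tibble(
      sample_id = ids,
      phenotype = if (is.null(phenotype)) rep("unknown", n) else
        as.character(phenotype)
    )
  }
  samples <- as_tibble(samples)
  dimnames(dosage) <- list(samples$sample_id, snps$snp_id)
  gm <- structure(list(dosage = dosage, snps = snps, samples = samples),
                  class = "genotype_matrix")
  validate_genotypes(gm)
}

#' Validate a genotype matrix object
#'
#' Checks the container invariants: dosages in \{0, 1, 2, `NA`\}, metadata
#' dimensions matching the matrix, distinct A/C/G/T alleles and positive
#' positions per SNP, and recognised phenotype labels.
#'
#' @param gm A [genotype_matrix()].
#' @return `gm`, invisibly classed, or an error describing the violation.
#' @export
validate_genotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  bad <- d[!is.na(d) & !(d %in% 0:2)]
  if (length(bad)) abort("dosage values must be 0, 1, 2 or NA")
  if (nrow(gm$snps) != ncol(d)) abort("snps metadata does not match dosage columns")
  if (nrow(gm$samples) != nrow(d)) abort("sample metadata does not match dosage rows")
  need <- c("snp_id", "chrom", "pos", "allele1", "allele2")
  if (!all(need %in% names(gm$snps))) {
    abort(paste("snps tibble must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(gm$snps)) {
    ok <- gm$snps$allele1 != gm$snps$allele2 &
      gm$snps$allele1 %in% c("A", "C", "G", "T") &
      gm$snps$allele2 %in% c("A", "C", "G", "T")
    if (!all(ok)) {
      abort(sprintf("SNP %s: alleles must be two distinct bases in {A,C,G,T}",
                    gm$snps$snp_id[which(!ok)[1]]))
    }
    if (any(gm$snps$pos < 1)) abort("positions must be >= 1 (1-based)")
  }
  if (!all(gm$samples$phenotype %in% c("case", "control", "unknown"))) {
    abort('phenotype labels must be "case", "control" or "unknown"')
  }
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d SNPs (%d cases, %d controls, %d unknown)\n",
    nrow(x$dosage), ncol(x$dosage),
    sum(x$samples$phenotype == "case"),
    sum(x$samples$phenotype == "control"),
    sum(x$samples$phenotype == "unknown")
  ))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Dimensions and missingness of a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @return `n_snps()`/`n_samples()` return counts; `snp_missingness()` and
#'   `sample_missingness()` return named fractions in \[0, 1\].
#' @export
n_snps <- function(gm) ncol(gm$dosage)

#' @rdname n_snps
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname n_snps
#' @export
snp_missingness <- function(gm) colMeans(is.na(gm$dosage))

#' @rdname n_snps
#' @export
sample_missingness <- function(gm) rowMeans(is.na(gm$dosage))

#' Subset a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param samples,snps Index vectors (integer, logical or names) selecting
#'   rows/columns; `NULL` keeps everything.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(gm))
  if (is.null(snps)) snps <- seq_len(n_snps(gm))
  if (is.character(samples)) samples <- match(samples, gm$samples$sample_id)
  if (is.character(snps)) snps <- match(snps, gm$snps$snp_id)
  structure(list(
    dosage = gm$dosage[samples, snps, drop = FALSE],
    snps = gm$snps[snps, ],
    samples = gm$samples[samples, ]
  ), class = "genotype_matrix")
}

#' Missingness quality-control filter
#'
#' Removes SNPs whose missing fraction exceeds `max_snp_missing`, then
#' samples whose missing fraction (computed over the surviving SNPs) exceeds
#' `max_sample_missing`. Monomorphic SNPs (an allele entirely absent from the
#' surviving data) are flagged in the report but retained. Nothing is ever
#' imputed. The filter is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param max_snp_missing,max_sample_missing Missing-fraction thresholds in
#'   \[0, 1\]; the defaults mirror the common 10% rule.
#' @return A list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (a tibble with columns `id`, `type`,
#'   `action`, `reason`, `value`).
#' @examples
#' gm <- simulate_dataset(20, 20, 5, missing_rate = 0.3, seed = 1)$genotypes
#' qc <- qc_filter(gm, 0.2, 0.2)
#' qc$report
#' @export
qc_filter <- function(gm, max_snp_missing = 0.10, max_sample_missing = 0.10) {
  stopifnot(max_snp_missing >= 0, max_snp_missing <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1)
  smiss <- snp_missingness(gm)
  drop_snp <- smiss > max_snp_missing
  report <- tibble(
    id = gm$snps$snp_id[drop_snp], type = "snp", action = "removed",
    reason = sprintf("missing fraction %.3f > %.3f",
                     smiss[drop_snp], max_snp_missing),
    value = unname(smiss[drop_snp])
  )
  gm2 <- subset_genotypes(gm, snps = which(!drop_snp))
  pmiss <- sample_missingness(gm2)
  if (n_snps(gm2) == 0L) pmiss[] <- 0 # no SNPs left: nothing to judge samples on
  drop_sample <- pmiss > max_sample_missing
  report <- dplyr::bind_rows(report, tibble(
    id = gm2$samples$sample_id[drop_sample], type = "sample",
    action = "removed",
    reason = sprintf("missing fraction %.3f > %.3f",
                     pmiss[drop_sample], max_sample_missing),
    value = unname(pmiss[drop_sample])
  ))
  gm2 <- subset_genotypes(gm2, samples = which(!drop_sample))
  if (n_snps(gm2) > 0L && n_samples(gm2) > 0L) {
    cnt1 <- colSums(gm2$dosage, na.rm = TRUE)
    tot <- 2L * colSums(!is.na(gm2$dosage))
    mono <- tot == 0L | cnt1 == 0L | cnt1 == tot
    report <- dplyr::bind_rows(report, tibble(
      id = gm2$snps$snp_id[mono], type = "snp", action = "flagged",
      reason = "monomorphic in surviving data",
      value = NA_real_
    ))
  }
  if (n_snps(gm2) == 0L || n_samples(gm2) == 0L) {
    warn("qc_filter removed all SNPs and/or samples")
  }
  list(genotypes = gm2, report = report)
}
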