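#' Read case/control genotypes from standard formats
#'
#' Parses PLINK text PED/MAP, VCF (GT field only; phased and unphased calls
#' are accepted and phase is ignored) or blocnet's tab-separated dosage
#' matrix dialect into a [genotype_matrix()]. Dosage counts copies of
#' `allele1`: the first allele observed for the SNP in a PED file, the REF
#' allele of a VCF, or the allele declared in the matrix-text header. Half
#' missing or unresolvable calls become `NA`; SNPs with more than two
#' distinct alleles, or non-ACGT alleles, are rejected with a message.
#'
#' The matrix-text dialect is one header row of SNP identifiers preceded by
#' optional `#SNP id chrom pos allele1 allele2` comment lines, then one row
#' per sample: sample id, phenotype code (1 = control, 2 = case, NA), and
#' the 0/1/2/NA allele1 dosages.
#'
#' @param path Input file. For `ped_map`, the `.ped` file; a companion
#'   `.map` with the same stem must exist.
#' @param format One of `"ped_map"`, `"vcf"`, `"matrix_text"`.
#' @param phenotype_file Optional sidecar phenotype table: two tab-separated
#'   columns (sample id, 1 = control / 2 = case). Used for VCF and
#'   matrix-text input (for matrix text it overrides the embedded column).
#' @return A [genotype_matrix()].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("matrix_text", "ped_map", "vcf"),
                           phenotype_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gm <- switch(format,
    matrix_text = read_matrix_text(path),
    ped_map = read_ped_map(path),
    vcf = read_vcf(path)
  )
  if (!is.null(phenotype_file)) {
    ph <- read_phenotype_sidecar(phenotype_file)
    idx <- match(gm$samples$sample_id, ph$sample_id)
    gm$samples$phenotype <- ifelse(is.na(idx), "unknown", ph$phenotype[idx])
  }
  validate_genotypes(gm)
}

#' Write genotypes to a standard format
#'
#' Inverse of [read_genotypes()]: the round trip is lossless for dosages,
#' alleles, positions and phenotype. PED files carry no reference-allele
#' designation, so on re-reading a PED the allele-slot orientation is
#' whichever allele appears first in the file; dosages are complemented
#' consistently with the swapped labels and the represented genotypes are
#' unchanged.
#'
#' @inheritParams read_genotypes
#' @param gm A [genotype_matrix()].
#' @return `path`, invisibly. For `ped_map` the companion `.map` file is
#'   written next to the `.ped`.
#' @export
write_genotypes <- function(gm, path, format = c("matrix_text", "ped_map", "vcf")) {
  format <- match.arg(format)
  validate_genotypes(gm)
  switch(format,
    matrix_text = write_matrix_text(gm, path),
    ped_map = write_ped_map(gm, path),
    vcf = write_vcf(gm, path)
  )
  invisible(path)
}

pheno_to_code <- function(x) c(case = "2", control = "1", unknown = "0")[x]
code_to_pheno <- function(x) {
  dplyr::case_match(as.character(x), "2" ~ "case", "1" ~ "control",
                    .default = "unknown")
}

read_phenotype_sidecar <- function(path) {
  if (!file.exists(path)) abort(sprintf("phenotype file not found: %s", path))
  tab <- read.table(path, header = FALSE, sep = "\t",
                    colClasses = "character")
  if (ncol(tab) < 2) abort("phenotype sidecar needs two tab-separated columns")
  tibble(sample_id = tab[[1]], phenotype = code_to_pheno(tab[[2]]))
}

# ---- matrix_text ----------------------------------------------------------

read_matrix_text <- function(path) {
  lines <- readLines(path)
  meta_idx <- grepl("^#", lines)
  meta <- lines[meta_idx & grepl("^#SNP\t", lines)]
  body <- lines[!meta_idx]
  if (!length(body)) abort("matrix_text file has no header row")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "sample_id") {
    abort("malformed matrix_text header (line 1): expected 'sample_id\\tphenotype\\t<snp ids>'")
  }
  snp_ids <- header[-(1:2)]
  m <- length(snp_ids)
  snps <- tibble(snp_id = snp_ids, chrom = "1",
                 pos = seq_len(max(m, 1L))[seq_len(m)],
                 allele1 = "A", allele2 = "C")
  if (length(meta)) {
    parts <- strsplit(sub("^#SNP\t", "", meta), "\t", fixed = TRUE)
    ok <- lengths(parts) == 5
    if (!all(ok)) abort("malformed #SNP metadata line in matrix_text file")
    md <- tibble(
      snp_id = vapply(parts, `[`, "", 1),
      chrom = vapply(parts, `[`, "", 2),
      pos = as.integer(vapply(parts, `[`, "", 3)),
      allele1 = vapply(parts, `[`, "", 4),
      allele2 = vapply(parts, `[`, "", 5)
    )
    idx <- match(snps$snp_id, md$snp_id)
    hit <- !is.na(idx)
    snps[hit, c("chrom", "pos", "allele1", "allele2")] <-
      md[idx[hit], c("chrom", "pos", "allele1", "allele2")]
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != m + 2L)
  if (length(bad)) {
    abort(sprintf("malformed matrix_text line %d: expected %d fields, found %d",
                  which(!meta_idx)[bad[1] + 1L], m + 2L,
                  lengths(rows)[bad[1]]))
  }
  n <- length(rows)
  sample_id <- vapply(rows, `[`, "", 1)
  phenotype <- code_to_pheno(vapply(rows, `[`, "", 2))
  dosage <- matrix(NA_integer_, n, m)
  if (n && m) {
    vals <- suppressWarnings(
      as.integer(unlist(lapply(rows, `[`, -(1:2)), use.names = FALSE)))
    dosage <- matrix(vals, n, m, byrow = TRUE)
    bad <- !is.na(dosage) & !(dosage %in% 0:2)
    if (any(bad)) abort("matrix_text dosages must be 0, 1, 2 or NA")
  }
  genotype_matrix(dosage, snps = snps,
                  samples = tibble(sample_id = sample_id, phenotype = phenotype))
}

write_matrix_text <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (n_snps(gm)) {
    writeLines(sprintf("#SNP\t%s\t%s\t%d\t%s\t%s", gm$snps$snp_id,
                       gm$snps$chrom, gm$snps$pos, gm$snps$allele1,
                       gm$snps$allele2), con)
  }
  writeLines(paste(c("sample_id", "phenotype", gm$snps$snp_id),
                   collapse = "\t"), con)
  if (n_samples(gm)) {
    ph <- pheno_to_code(gm$samples$phenotype)
    ph[ph == "0"] <- "NA"
    dm <- gm$dosage
    body <- apply(cbind(gm$samples$sample_id, ph, dm), 1, paste,
                  collapse = "\t")
    writeLines(body, con)
  }
}

# ---- PED/MAP --------------------------------------------------------------

map_path_for <- function(ped_path) sub("\\.ped$", ".map", ped_path)

read_ped_map <- function(path) {
  map_path <- map_path_for(path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map")
  if (!file.exists(map_path)) {
    abort(sprintf("companion .map file not found: %s", map_path))
  }
  map <- read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) < 4) abort("malformed .map file: expected 4 columns")
  snps <- tibble(snp_id = map[[2]], chrom = map[[1]],
                 pos = as.integer(map[[4]]), allele1 = NA_character_,
                 allele2 = NA_character_)
  m <- nrow(snps)
  lines <- readLines(path)
  rows <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(rows) != 6L + 2L * m)
  if (length(bad)) {
    abort(sprintf("malformed PED line %d: expected %d fields, found %d",
                  bad[1], 6L + 2L * m, lengths(rows)[bad[1]]))
  }
  n <- length(rows)
  ped <- matrix(unlist(rows, use.names = FALSE), nrow = n, byrow = TRUE)
  samples <- tibble(sample_id = ped[, 2],
                    phenotype = code_to_pheno(ped[, 6]))
  dosage <- matrix(NA_integer_, n, m)
  keep <- rep(TRUE, m)
  for (j in seq_len(m)) {
    a <- ped[, 5L + 2L * j]
    b <- ped[, 6L + 2L * j]
    obs <- c(rbind(a, b)) # sample-major order of observed alleles
    letters_seen <- unique(obs[obs != "0"])
    if (length(letters_seen) > 2L) {
      inform(sprintf("rejecting SNP %s: %d distinct alleles observed",
                     snps$snp_id[j], length(letters_seen)))
      keep[j] <- FALSE
      next
    }
    a1 <- if (length(letters_seen) >= 1L) letters_seen[1] else "A"
    a2 <- if (length(letters_seen) == 2L) letters_seen[2] else
      setdiff(c("A", "C", "G", "T"), a1)[1]
    snps$allele1[j] <- a1
    snps$allele2[j] <- a2
    full <- a != "0" & b != "0" # half-missing calls cannot yield a dosage
    dosage[full, j] <- (a[full] == a1) + (b[full] == a1)
    if (any(!full & (a != "0" | b != "0"))) {
      inform(sprintf("SNP %s: half-missing genotype call(s) set to missing",
                     snps$snp_id[j]))
    }
  }
  genotype_matrix(dosage[, keep, drop = FALSE], snps = snps[keep, ],
                  samples = samples)
}

write_ped_map <- function(gm, path) {
  map_path <- map_path_for(path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map")
  writeLines(sprintf("%s\t%s\t0\t%d", gm$snps$chrom, gm$snps$snp_id,
                     gm$snps$pos), map_path)
  n <- n_samples(gm)
  m <- n_snps(gm)
  geno <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    d <- gm$dosage[, j]
    a1 <- gm$snps$allele1[j]
    a2 <- gm$snps$allele2[j]
    geno[, 2L * j - 1L] <- ifelse(is.na(d), "0", ifelse(d >= 1L, a1, a2))
    geno[, 2L * j] <- ifelse(is.na(d), "0", ifelse(d == 2L, a1, a2))
  }
  body <- cbind(gm$samples$sample_id, gm$samples$sample_id, "0", "0", "0",
                pheno_to_code(gm$samples$phenotype), geno)
  writeLines(apply(body, 1, paste, collapse = " "), path)
}

# ---- VCF ------------------------------------------------------------------

read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!keep)) {
    inform(sprintf("rejecting %d VCF record(s) that are not biallelic ACGT SNPs",
                   sum(!keep)))
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  snps <- tibble(snp_id = ids, chrom = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]),
                 allele1 = ref, allele2 = alt)[keep, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  # count REF alleles; phase ignored; anything unresolvable is missing
  lut <- c("0/0" = 2L, "0/1" = 1L, "1/0" = 1L, "1/1" = 0L)
  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(lut[gt_norm], nrow = nrow(gt_norm))
  dosage <- t(dosage) # samples x SNPs
  samples <- tibble(sample_id = colnames(gt), phenotype = "unknown")
  genotype_matrix(dosage, snps = snps, samples = samples)
}

write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", "##source=blocnet",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples$sample_id),
                   collapse = "\t"), con)
  if (n_snps(gm)) {
    gt <- matrix("./.", n_snps(gm), n_samples(gm))
    d <- t(gm$dosage) # SNPs x samples
    gt[!is.na(d) & d == 2L] <- "0/0"
    gt[!is.na(d) & d == 1L] <- "0/1"
    gt[!is.na(d) & d == 0L] <- "1/1"
    lead <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT", gm$snps$chrom,
                    gm$snps$pos, gm$snps$snp_id, gm$snps$allele1,
                    gm$snps$allele2)
    body <- paste(lead, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    if (n_samples(gm) == 0L) body <- lead
    writeLines(body, con)
  }
}
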