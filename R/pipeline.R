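#' Configuration for an end-to-end blocnet run
#'
#' Collects and validates every knob of the pipeline. Either `genotypes`
#' (an in-memory [genotype_matrix()]) or `input`/`format` must be given.
#'
#' @param input Path to a genotype file, or `NULL` when `genotypes` is
#'   supplied.
#' @param format Input format for [read_genotypes()].
#' @param genotypes Optional [genotype_matrix()] used directly.
#' @param phenotype_file Optional sidecar phenotype file.
#' @param out_dir Output directory for artifacts; `NULL` writes nothing.
#' @param n_edges Number of network edges; `NULL` means one per SNP.
#' @param max_snp_missing,max_sample_missing QC thresholds
#'   ([qc_filter()]).
#' @param warn_missing Pair-missingness warning level ([ccc_scan()]).
#' @param method,denominator,het_weight CCC facet options ([ccc_pair()]).
#' @param min_carriers,alpha,bloc_missing_max Association options
#'   ([test_all_blocs()]).
#' @param n_permutations Phenotype-label permutation trials (0 = skip).
#' @param n_shuffles Genotype-shuffle trials (0 = skip).
#' @param bootstrap_trials Bootstrap trials for the top bloc (0 = skip).
#' @param bootstrap_fraction Subsample fraction per bootstrap trial.
#' @param seed Integer seed governing all randomness in the run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, format = "matrix_text",
                       genotypes = NULL, phenotype_file = NULL,
                       out_dir = NULL, n_edges = NULL,
                       max_snp_missing = 0.10, max_sample_missing = 0.10,
                       warn_missing = 0.05, method = "yule",
                       denominator = "min", het_weight = 0.5,
                       min_carriers = 10, alpha = 0.05,
                       bloc_missing_max = 0.05, n_permutations = 0,
                       n_shuffles = 0, bootstrap_trials = 0,
                       bootstrap_fraction = 0.5, seed = 1L) {
  if (is.null(genotypes) && is.null(input)) {
    abort("run_config needs `input` or `genotypes`")
  }
  if (!is.null(n_edges) && n_edges < 1) {
    abort("`n_edges` must be >= 1")
  }
  for (nm in c("max_snp_missing", "max_sample_missing", "warn_missing",
               "bloc_missing_max")) {
    v <- get(nm)
    if (v < 0 || v > 1) abort(sprintf("`%s` must be in [0, 1]", nm))
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (bootstrap_fraction <= 0 || bootstrap_fraction > 1) {
    abort("`bootstrap_fraction` must be in (0, 1]")
  }
  structure(list(
    input = input, format = format, genotypes = genotypes,
    phenotype_file = phenotype_file, out_dir = out_dir, n_edges = n_edges,
    max_snp_missing = max_snp_missing, max_sample_missing = max_sample_missing,
    warn_missing = warn_missing, method = method, denominator = denominator,
    het_weight = het_weight, min_carriers = min_carriers, alpha = alpha,
    bloc_missing_max = bloc_missing_max, n_permutations = n_permutations,
    n_shuffles = n_shuffles, bootstrap_trials = bootstrap_trials,
    bootstrap_fraction = bootstrap_fraction, seed = as.integer(seed)
  ), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full blocnet pipeline
#'
#' Read (or accept) genotypes, QC-filter, scan all SNP pairs for the
#' strongest CCC facets, build the allele network, extract blocs, test
#' every bloc's pattern for case/control association, and optionally run
#' the permutation, shuffle and bootstrap validations. All randomness flows
#' from `config$seed`; a rerun with the same configuration produces
#' byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list: `config`, `genotypes` (post-QC),
#'   `qc_report`, `records`, `network`, `blocs`, `associations`,
#'   `phenotype_null`, `shuffle_null`, `bootstrap`, and `paths` of written
#'   artifacts (when `out_dir` is set: correlations.tsv, edges.tsv,
#'   blocs.tsv, associations.tsv, null distributions, run_log.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  gm <- stage("read", {
    if (!is.null(cfg$genotypes)) cfg$genotypes else
      read_genotypes(cfg$input, cfg$format, cfg$phenotype_file)
  })
  qc <- stage("qc", qc_filter(gm, cfg$max_snp_missing, cfg$max_sample_missing))
  gm <- qc$genotypes
  if (n_snps(gm) < 2L) abort("pipeline stage 'qc' left fewer than 2 SNPs")
  n_edges <- cfg$n_edges %||% n_snps(gm)
  if (n_edges > 4 * choose(n_snps(gm), 2)) {
    abort("pipeline stage 'scan': n_edges exceeds available facet records")
  }
  records <- stage("scan", ccc_scan(
    gm, top_k = n_edges, warn_missing_fraction = cfg$warn_missing,
    method = cfg$method, denominator = cfg$denominator,
    het_weight = cfg$het_weight
  ))
  net <- stage("network", build_network(records, n_snps(gm), n_edges))
  blocs <- stage("blocs", extract_blocs(net))
  assoc <- stage("association", test_all_blocs(
    gm, blocs, min_carriers = cfg$min_carriers, alpha = cfg$alpha,
    max_missing = cfg$bloc_missing_max
  ))
  ph_null <- NULL
  sh_null <- NULL
  boot <- NULL
  if (cfg$n_permutations > 0 && nrow(blocs)) {
    ph_null <- stage("permutation", permute_phenotype_null(
      gm, blocs, n_trials = cfg$n_permutations, alpha = cfg$alpha,
      seed = cfg$seed + 1L, max_missing = cfg$bloc_missing_max
    ))
  }
  if (cfg$n_shuffles > 0) {
    sh_null <- stage("shuffle", null_max_ccc(
      gm, n_trials = cfg$n_shuffles, seed = cfg$seed + 2L,
      cutoff = net$cutoff, method = cfg$method,
      denominator = cfg$denominator, het_weight = cfg$het_weight
    ))
  }
  if (cfg$bootstrap_trials > 0 && nrow(assoc)) {
    top <- blocs[blocs$bloc_id == assoc$bloc_id[1], ]
    boot <- stage("bootstrap", bootstrap_bloc(
      gm, top, n_trials = cfg$bootstrap_trials,
      fraction = cfg$bootstrap_fraction, seed = cfg$seed + 3L,
      max_missing = cfg$bloc_missing_max
    ))
  }
  paths <- character(0)
  if (!is.null(cfg$out_dir)) {
    paths <- stage("write", write_artifacts(
      cfg, gm, qc$report, records, net, blocs, assoc, ph_null, sh_null, boot
    ))
  }
  invisible(list(
    config = cfg, genotypes = gm, qc_report = qc$report, records = records,
    network = net, blocs = blocs, associations = assoc,
    phenotype_null = ph_null, shuffle_null = sh_null, bootstrap = boot,
    paths = paths
  ))
}

comment_header <- function(cfg, extra = character(0)) {
  c(sprintf("# blocnet %s",
            as.character(utils::packageVersion("blocnet"))),
    sprintf("# seed=%d method=%s denominator=%s het_weight=%g",
            cfg$seed, cfg$method, cfg$denominator, cfg$het_weight),
    extra)
}

write_tsv_commented <- function(x, path, header) {
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  path
}

allele_letter <- function(gm, snp_index, slot) {
  ifelse(slot == 1L, gm$snps$allele1[snp_index], gm$snps$allele2[snp_index])
}

blocs_to_table <- function(gm, blocs) {
  tibble(
    bloc_id = blocs$bloc_id, n_nodes = blocs$n_nodes,
    n_edges = blocs$n_edges, n_snps = blocs$n_snps,
    nodes = purrr::map_chr(seq_len(nrow(blocs)), function(k) {
      paste(bloc_labels(gm, blocs[k, ]), collapse = "|")
    })
  )
}

table_to_blocs <- function(gm, tab) {
  purrr::pmap_dfr(tab, function(bloc_id, n_nodes, n_edges, n_snps, nodes) {
    tok <- strsplit(strsplit(nodes, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    ids <- vapply(tok, `[`, "", 1)
    letters <- vapply(tok, `[`, "", 2)
    idx <- match(ids, gm$snps$snp_id)
    if (anyNA(idx)) abort(sprintf("bloc %d references unknown SNP ids", bloc_id))
    slots <- ifelse(letters == gm$snps$allele1[idx], 1L,
                    ifelse(letters == gm$snps$allele2[idx], 2L, NA_integer_))
    if (anyNA(slots)) abort(sprintf("bloc %d references unknown alleles", bloc_id))
    tibble(bloc_id = bloc_id, n_nodes = n_nodes, n_edges = n_edges,
           n_snps = n_snps, snp_indices = list(idx),
           allele_slots = list(slots),
           node_ids = list(node_id(idx, slots)),
           both_alleles = anyDuplicated(idx) > 0L)
  })
}

write_null_distribution <- function(x, path) {
  hdr <- jsonlite::toJSON(
    list(kind = x$kind, seed = x$seed %||% NA, n_trials = x$n_trials),
    auto_unbox = TRUE, na = "null")
  writeLines(c(paste0("#", hdr), format(x$maxima, digits = 15, trim = TRUE)),
             path)
  path
}

write_artifacts <- function(cfg, gm, qc_report, records, net, blocs, assoc,
                            ph_null, sh_null, boot) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  paths <- c(
    correlations = write_tsv_commented(
      dplyr::mutate(records,
        allele_i = allele_letter(gm, .data$snp_i, .data$allele_i),
        allele_j = allele_letter(gm, .data$snp_j, .data$allele_j)) |>
        dplyr::select("snp_id_i", "allele_i", "snp_id_j", "allele_j",
                      "value", "n_valid"),
      p("correlations.tsv"), comment_header(cfg)),
    edges = write_tsv_commented(
      dplyr::mutate(net$edges,
        allele_i = allele_letter(gm, .data$snp_i, .data$allele_i),
        allele_j = allele_letter(gm, .data$snp_j, .data$allele_j)) |>
        dplyr::select("snp_id_i", "allele_i", "snp_id_j", "allele_j",
                      "value"),
      p("edges.tsv"),
      comment_header(cfg, sprintf("# n_edges=%d cutoff=%.10g",
                                  nrow(net$edges), net$cutoff))),
    blocs = write_tsv_commented(blocs_to_table(gm, blocs), p("blocs.tsv"),
                                comment_header(cfg)),
    associations = write_tsv_commented(
      assoc, p("associations.tsv"),
      comment_header(cfg, sprintf("# m_tests=%d critical_g=%.10g",
                                  if (nrow(assoc)) assoc$m_tests[1] else 0L,
                                  attr(assoc, "critical_g")))),
    qc = write_tsv_commented(qc_report, p("qc_report.tsv"),
                             comment_header(cfg))
  )
  if (!is.null(ph_null)) {
    paths["phenotype_null"] <- write_null_distribution(ph_null,
                                                       p("phenotype_null.txt"))
  }
  if (!is.null(sh_null)) {
    paths["shuffle_null"] <- write_null_distribution(sh_null,
                                                     p("shuffle_null.txt"))
  }
  if (!is.null(boot)) {
    paths["bootstrap"] <- write_tsv_commented(
      glance(boot), p("bootstrap.tsv"), comment_header(cfg))
  }
  log <- list(
    package = "blocnet",
    version = as.character(utils::packageVersion("blocnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    n_samples = n_samples(gm), n_snps = n_snps(gm),
    n_edges = nrow(net$edges), cutoff = net$cutoff,
    method = cfg$method, denominator = cfg$denominator,
    het_weight = cfg$het_weight,
    thresholds = list(
      max_snp_missing = cfg$max_snp_missing,
      max_sample_missing = cfg$max_sample_missing,
      warn_missing = cfg$warn_missing, min_carriers = cfg$min_carriers,
      alpha = cfg$alpha, bloc_missing_max = cfg$bloc_missing_max
    )
  )
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(paths, run_log = file.path(cfg$out_dir, "run_log.json"))
}
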