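# node numbering: SNP s, allele slot a (1 or 2) -> node 2*(s-1)+a in 1..2m
node_id <- function(snp, slot) 2L * (as.integer(snp) - 1L) + as.integer(slot)

# normalise the various ways a bloc can be passed around (a row of the
# extract_blocs() tibble, or a bare list) into list(snp_indices, allele_slots)
as_bloc <- function(bloc) {
  if (is.data.frame(bloc)) {
    if (nrow(bloc) != 1L) abort("expected a single bloc (one row)")
    out <- list(snp_indices = bloc$snp_indices[[1]],
                allele_slots = bloc$allele_slots[[1]])
    if ("bloc_id" %in% names(bloc)) out$bloc_id <- bloc$bloc_id
    return(out)
  }
  if (is.list(bloc) && all(c("snp_indices", "allele_slots") %in% names(bloc))) {
    return(bloc)
  }
  abort("`bloc` must be a row of extract_blocs() output or a list with snp_indices and allele_slots")
}

bloc_node_ids <- function(bloc) {
  b <- as_bloc(bloc)
  node_id(b$snp_indices, b$allele_slots)
}

#' Build the allele-specific network
#'
#' Places the `n_edges` strongest facet records as edges between allele
#' nodes. Each SNP contributes two nodes, one per allele, so a network on m
#' SNPs has 2m nodes; one SNP pair can contribute up to four edges (one per
#' facet). Ties at the cutoff are resolved by the deterministic record
#' order of [ccc_scan()].
#'
#' @param records Correlation records from [ccc_scan()] (or any tibble with
#'   `snp_i`, `snp_j`, `allele_i`, `allele_j`, `value`).
#' @param n_snps Number of SNPs indexed by the records.
#' @param n_edges Number of edges; defaults to `n_snps`, which gives an
#'   average node degree of one.
#' @return An `allele_network` object: list with `n_snps`, `n_nodes`,
#'   `edges` (tibble with node ids and facet columns) and `cutoff` (the
#'   minimum edge value).
#' @export
build_network <- function(records, n_snps, n_edges = n_snps) {
  n_edges <- as.integer(n_edges)
  if (n_edges < 1L) abort("`n_edges` must be >= 1")
  if (nrow(records) < n_edges) {
    abort(sprintf("only %d facet records available for %d requested edges",
                  nrow(records), n_edges))
  }
  o <- order(-records$value, records$snp_i, records$snp_j,
             records$allele_i, records$allele_j)
  edges <- records[o[seq_len(n_edges)], ]
  edges <- dplyr::mutate(edges,
    node_i = node_id(.data$snp_i, .data$allele_i),
    node_j = node_id(.data$snp_j, .data$allele_j)
  )
  structure(list(n_snps = as.integer(n_snps), n_nodes = 2L * as.integer(n_snps),
                 edges = edges, cutoff = min(edges$value)),
            class = "allele_network")
}

#' @export
print.allele_network <- function(x, ...) {
  cat(sprintf("<allele_network> %d SNPs, %d nodes, %d edges, cutoff %.4f\n",
              x$n_snps, x$n_nodes, nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Extract blocs (connected components) from an allele network
#'
#' Blocs are the connected components with at least two nodes; they arise
#' naturally separated in the network, so no clustering or partitioning is
#' applied. Component extraction is order-independent. A warning is issued
#' if a bloc contains both alleles of one SNP (such blocs are retained).
#'
#' @param net An [build_network()] result.
#' @return A tibble with one row per bloc: `bloc_id`, `n_nodes`, `n_edges`,
#'   `n_snps`, list-columns `snp_indices`, `allele_slots`, `snp_ids`,
#'   `alleles`, `node_ids`, and `both_alleles` (TRUE when a SNP appears with
#'   both of its alleles). Blocs are ordered by their smallest node id.
#' @export
extract_blocs <- function(net) {
  stopifnot(inherits(net, "allele_network"))
  g <- igraph::make_empty_graph(n = net$n_nodes, directed = FALSE)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$node_i, net$edges$node_j))
  }
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2)
  snp_ids <- attr(net, "snp_ids")
  blocs <- purrr::map(keep, function(k) {
    nodes <- sort(which(comp$membership == k))
    snp <- (nodes - 1L) %/% 2L + 1L
    slot <- (nodes - 1L) %% 2L + 1L
    ecount <- sum(comp$membership[net$edges$node_i] == k)
    tibble(
      n_nodes = length(nodes), n_edges = ecount,
      n_snps = length(unique(snp)),
      snp_indices = list(snp), allele_slots = list(slot),
      node_ids = list(nodes),
      both_alleles = anyDuplicated(snp) > 0L
    )
  })
  out <- dplyr::bind_rows(blocs)
  if (!nrow(out)) {
    return(tibble(bloc_id = integer(), n_nodes = integer(),
                  n_edges = integer(), n_snps = integer(),
                  snp_indices = list(), allele_slots = list(),
                  node_ids = list(), both_alleles = logical()))
  }
  o <- order(purrr::map_int(out$node_ids, 1))
  out <- out[o, ]
  out$bloc_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "bloc_id")
  if (any(out$both_alleles)) {
    warn(sprintf("%d bloc(s) contain both alleles of one SNP",
                 sum(out$both_alleles)))
  }
  out
}

# human-readable "rs123:A" labels for a bloc, given the genotype metadata
bloc_labels <- function(gm, bloc) {
  b <- as_bloc(bloc)
  al <- ifelse(b$allele_slots == 1L, gm$snps$allele1[b$snp_indices],
               gm$snps$allele2[b$snp_indices])
  paste0(gm$snps$snp_id[b$snp_indices], ":", al)
}

#' Community-structure summary of an allele network
#'
#' @param net An [build_network()] result.
#' @param blocs The [extract_blocs()] tibble for `net`.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `n_blocs`,
#'   `pct_singletons` (percent of nodes with no edges), `n_doubletons`
#'   (blocs of exactly two nodes joined by one edge), `mean_bloc_size`
#'   (mean node count over blocs) and the node/edge counts of the largest
#'   bloc. A perfectly uniform edge distribution consists entirely of
#'   doubletons.
#' @export
network_summary <- function(net, blocs) {
  in_blocs <- if (nrow(blocs)) sum(blocs$n_nodes) else 0L
  largest <- if (nrow(blocs)) {
    o <- order(-blocs$n_nodes, -blocs$n_edges, blocs$bloc_id)
    blocs[o[1], ]
  } else tibble(n_nodes = 0L, n_edges = 0L)
  tibble(
    n_nodes = net$n_nodes,
    n_edges = nrow(net$edges),
    n_blocs = nrow(blocs),
    pct_singletons = 100 * (net$n_nodes - in_blocs) / net$n_nodes,
    n_doubletons = if (nrow(blocs)) {
      sum(blocs$n_nodes == 2L & blocs$n_edges == 1L)
    } else 0L,
    mean_bloc_size = if (nrow(blocs)) mean(blocs$n_nodes) else NA_real_,
    largest_bloc_nodes = largest$n_nodes,
    largest_bloc_edges = largest$n_edges
  )
}

#' Collapse an allele network to one node per SNP
#'
#' A SNP pair is connected in the collapsed graph if any of its four facet
#' edges is present in the allele network. Used for comparisons against
#' single-node-per-SNP correlation networks such as one built from Pearson
#' correlations.
#'
#' @param net An [build_network()] result.
#' @return A `snp_graph` object: list with `n_snps` and `edges` (tibble
#'   `snp_i`, `snp_j`, `n_facets`, `value` = strongest facet).
#' @export
collapse_to_snp_graph <- function(net) {
  if (!nrow(net$edges)) {
    return(structure(list(
      n_snps = net$n_snps,
      edges = tibble(snp_i = integer(), snp_j = integer(),
                     n_facets = integer(), value = numeric())
    ), class = "snp_graph"))
  }
  edges <- net$edges |>
    dplyr::group_by(.data$snp_i, .data$snp_j) |>
    dplyr::summarise(n_facets = dplyr::n(), value = max(.data$value),
                     .groups = "drop")
  structure(list(n_snps = net$n_snps, edges = edges), class = "snp_graph")
}

#' @export
print.snp_graph <- function(x, ...) {
  cat(sprintf("<snp_graph> %d SNPs, %d edges\n", x$n_snps, nrow(x$edges)))
  invisible(x)
}

#' Community-structure summary of a one-node-per-SNP graph
#'
#' @param sg A `snp_graph` from [collapse_to_snp_graph()] or
#'   [compare_with_pcc()].
#' @return One-row tibble with the same statistics as [network_summary()],
#'   computed on SNP nodes.
#' @export
snp_graph_summary <- function(sg) {
  g <- igraph::make_empty_graph(n = sg$n_snps, directed = FALSE)
  if (nrow(sg$edges)) {
    g <- igraph::add_edges(g, rbind(sg$edges$snp_i, sg$edges$snp_j))
  }
  comp <- igraph::components(g)
  keep <- comp$csize >= 2
  sizes <- comp$csize[keep]
  ecount <- tabulate(comp$membership[sg$edges$snp_i], nbins = comp$no)
  largest <- if (any(keep)) {
    o <- order(-comp$csize, -ecount)
    o <- o[keep[o]][1]
    c(comp$csize[o], ecount[o])
  } else c(0L, 0L)
  tibble(
    n_nodes = sg$n_snps, n_edges = nrow(sg$edges),
    n_blocs = sum(keep),
    pct_singletons = 100 * sum(comp$csize == 1) / sg$n_snps,
    n_doubletons = sum(comp$csize == 2 & ecount[seq_along(comp$csize)] == 1),
    mean_bloc_size = if (any(keep)) mean(sizes) else NA_real_,
    largest_bloc_nodes = largest[1], largest_bloc_edges = largest[2]
  )
}

#' Compare CCC and Pearson SNP networks on the same data
#'
#' Builds two one-node-per-SNP networks with the same number of edges: one
#' connecting the SNP pairs with the strongest best-facet CCC values, one
#' connecting the pairs with the strongest absolute Pearson correlations of
#' dosages, and summarises the community structure of each. Stronger
#' community structure (fewer scattered doubletons, more concentrated
#' clusters) indicates a metric that groups genuinely inter-correlated SNPs.
#'
#' @param gm A [genotype_matrix()].
#' @param n_edges Edges per network; defaults to the number of SNPs.
#' @inheritParams ccc_pair
#' @return A list with `summary` (two-row tibble, one per metric, with the
#'   [snp_graph_summary()] statistics plus `metric` and `threshold`), and
#'   the two `snp_graph` objects `ccc` and `pcc`.
#' @export
compare_with_pcc <- function(gm, n_edges = NULL, method = c("yule", "tally"),
                             denominator = c("min", "geom", "2n"),
                             het_weight = 0.5) {
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  m <- n_snps(gm)
  if (is.null(n_edges)) n_edges <- m
  if (n_edges > choose(m, 2)) abort("`n_edges` exceeds the number of SNP pairs")
  rec <- ccc_scan(gm, top_k = min(4 * n_edges, 4 * choose(m, 2)),
                  method = method, denominator = denominator,
                  het_weight = het_weight, warn_missing_fraction = 1)
  best <- rec |>
    dplyr::group_by(.data$snp_i, .data$snp_j) |>
    dplyr::summarise(n_facets = dplyr::n(), value = max(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$value), .data$snp_i, .data$snp_j)
  # top_k = 4*n_edges facet records always cover >= n_edges distinct pairs
  ccc_sg <- structure(list(n_snps = m, edges = best[seq_len(n_edges), ]),
                      class = "snp_graph")
  pc <- suppressWarnings(cor(gm$dosage, use = "pairwise.complete.obs"))
  pc[is.na(pc)] <- 0
  ut <- which(upper.tri(pc))
  pi <- (ut - 1L) %% m + 1L
  pj <- (ut - 1L) %/% m + 1L
  pv <- abs(pc[ut])
  o <- order(-pv, pi, pj)[seq_len(n_edges)]
  pcc_sg <- structure(list(
    n_snps = m,
    edges = tibble(snp_i = pi[o], snp_j = pj[o], n_facets = 1L, value = pv[o])
  ), class = "snp_graph")
  summary <- dplyr::bind_rows(
    dplyr::mutate(snp_graph_summary(ccc_sg), metric = "ccc",
                  threshold = min(ccc_sg$edges$value), .before = 1),
    dplyr::mutate(snp_graph_summary(pcc_sg), metric = "pcc",
                  threshold = min(pcc_sg$edges$value), .before = 1)
  )
  list(summary = summary, ccc = ccc_sg, pcc = pcc_sg)
}

#' Track a bloc across network densities
#'
#' Rebuilds the network at each requested edge count, extracts blocs, and
#' reports the bloc best matching `reference_bloc` by Jaccard index on node
#' sets (the same bloc is declared when Jaccard >= 0.5). Adding edges can
#' only merge components, so the matched bloc grows monotonically along the
#' sweep.
#'
#' @param records Correlation records covering at least `max(edge_counts)`
#'   rows.
#' @param n_snps Number of SNPs.
#' @param edge_counts Ascending vector of edge counts.
#' @param reference_bloc The bloc to track (a row of [extract_blocs()]
#'   output or a list with `snp_indices` and `allele_slots`).
#' @param gm Optional [genotype_matrix()]; when given, the matched bloc's
#'   association statistics are included.
#' @param ... Passed to [test_all_blocs()]'s contingency step when `gm` is
#'   given (e.g. `max_missing`).
#' @return A tibble with one row per density: `n_edges`, `cutoff`,
#'   `jaccard`, `same_bloc`, `bloc_n_nodes`, `bloc_n_edges`, and odds
#'   ratio/G columns when `gm` is supplied.
#' @export
density_sweep <- function(records, n_snps, edge_counts, reference_bloc,
                          gm = NULL, ...) {
  if (is.unsorted(edge_counts, strictly = FALSE)) {
    abort("`edge_counts` must be ascending")
  }
  ref_nodes <- bloc_node_ids(reference_bloc)
  purrr::map_dfr(edge_counts, function(k) {
    net <- build_network(records, n_snps, n_edges = k)
    blocs <- suppressWarnings(extract_blocs(net))
    if (!nrow(blocs)) {
      return(tibble(n_edges = k, cutoff = net$cutoff, jaccard = 0,
                    same_bloc = FALSE, bloc_n_nodes = NA_integer_,
                    bloc_n_edges = NA_integer_))
    }
    jac <- purrr::map_dbl(blocs$node_ids, function(nodes) {
      length(intersect(nodes, ref_nodes)) / length(union(nodes, ref_nodes))
    })
    best <- which.max(jac)
    out <- tibble(
      n_edges = k, cutoff = net$cutoff, jaccard = jac[best],
      same_bloc = jac[best] >= 0.5,
      bloc_n_nodes = blocs$n_nodes[best], bloc_n_edges = blocs$n_edges[best]
    )
    if (!is.null(gm)) {
      tab <- bloc_contingency(gm, blocs[best, ], ...)
      orci <- odds_ratio_ci(tab$a, tab$b, tab$c, tab$d)
      gt <- g_test(tab$a, tab$b, tab$c, tab$d)
      out <- dplyr::bind_cols(out, orci["odds_ratio"], gt[c("g", "p_raw")])
    }
    out
  })
}

#' @method tidy allele_network
#' @export
tidy.allele_network <- function(x, ...) x$edges

#' @method glance allele_network
#' @export
glance.allele_network <- function(x, ...) {
  tibble(n_snps = x$n_snps, n_nodes = x$n_nodes, n_edges = nrow(x$edges),
         cutoff = x$cutoff)
}
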