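lcc_stats <- function(graph) {
  if (igraph::vcount(graph) == 0L) return(c(nodes = 0L, edges = 0L))
  comp <- igraph::components(graph)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(graph, which(comp$membership == big))
  c(nodes = igraph::vcount(sub), edges = igraph::ecount(sub))
}

null_pair <- function(observed, null_nodes, null_edges, reps, plus_one) {
  p_of <- function(null, obs) {
    if (plus_one) (sum(null >= obs) + 1) / (reps + 1) else
      sum(null >= obs) / reps
  }
  list(nodes = list(statistic = "lcc_nodes", observed = observed[["nodes"]],
                    null = null_nodes,
                    empirical_p = p_of(null_nodes, observed[["nodes"]])),
       edges = list(statistic = "lcc_edges", observed = observed[["edges"]],
                    null = null_edges,
                    empirical_p = p_of(null_edges, observed[["edges"]])))
}

#' Random-sampling null model for a network module
#'
#' Compares the largest-connected-component (LCC) node and edge counts of
#' the module-induced subgraph against the same statistics for repeated
#' uniform samples of equally many nodes from the network.  The empirical
#' p-value is the fraction of null samples whose statistic is at least the
#' observed one (`count / reps`; `plus_one = TRUE` applies the
#' (count+1)/(reps+1) small-sample correction).
#'
#' @param network igraph network with vertex names.
#' @param module Character vector of module node identifiers.
#' @param reps Number of random samples.
#' @param seed Integer seed.
#' @param plus_one Logical; apply the small-sample correction.
#' @return List with elements `nodes` and `edges`, each holding
#'   `statistic`, `observed`, `null` (length `reps`) and `empirical_p`.
#' @export
random_module_null <- function(network, module, reps = 1000L, seed = 1L,
                               plus_one = FALSE) {
  if (reps < 1L) stop("reps must be at least 1")
  vn <- igraph::V(network)$name
  module <- intersect(unique(module), vn)
  if (length(module) > length(vn)) stop("module larger than the network")
  obs <- lcc_stats(igraph::induced_subgraph(network, module))
  set.seed(seed)
  null_nodes <- integer(reps)
  null_edges <- integer(reps)
  for (r in seq_len(reps)) {
    s <- lcc_stats(igraph::induced_subgraph(
      network, sample(vn, length(module))))
    null_nodes[r] <- s[["nodes"]]
    null_edges[r] <- s[["edges"]]
  }
  null_pair(obs, null_nodes, null_edges, reps, plus_one)
}

#' Degree-preserving rewiring null model for a network module
#'
#' Rewires the network by repeated double-edge swaps (rejecting swaps that
#' would create self-loops or multi-edges), which preserves the full degree
#' sequence — a stricter construction than preserving only the average
#' degree.  The module's node identifiers are mapped onto each rewired
#' network and the LCC node and edge counts recorded; empirical p-values as
#' in [random_module_null()].  Degree-sequence preservation is asserted on
#' every replicate.
#'
#' @param network igraph network with vertex names and at least 2 edges.
#' @param module Character vector of module node identifiers.
#' @param reps Number of rewired replicates.
#' @param swaps_per_edge Attempted swaps per edge in each replicate.
#' @param seed Integer seed.
#' @param plus_one Logical; apply the (count+1)/(reps+1) correction.
#' @return List with elements `nodes` and `edges` as in
#'   [random_module_null()].
#' @export
degree_preserving_null <- function(network, module, reps = 1000L,
                                   swaps_per_edge = 10L, seed = 1L,
                                   plus_one = FALSE) {
  if (reps < 1L) stop("reps must be at least 1")
  if (igraph::ecount(network) < 2L) {
    stop("degree-preserving rewiring needs at least 2 edges")
  }
  vn <- igraph::V(network)$name
  module <- intersect(unique(module), vn)
  obs <- lcc_stats(igraph::induced_subgraph(network, module))
  deg0 <- igraph::degree(network)
  niter <- swaps_per_edge * igraph::ecount(network)
  set.seed(seed)
  null_nodes <- integer(reps)
  null_edges <- integer(reps)
  for (r in seq_len(reps)) {
    g2 <- igraph::rewire(network, igraph::keeping_degseq(niter = niter))
    stopifnot(identical(igraph::degree(g2), deg0))
    s <- lcc_stats(igraph::induced_subgraph(g2, module))
    null_nodes[r] <- s[["nodes"]]
    null_edges[r] <- s[["edges"]]
  }
  null_pair(obs, null_nodes, null_edges, reps, plus_one)
}

#' Condition-specificity profile of a gene set
#'
#' Mean Z-score of the set's genes in every condition, with the conditions
#' ranked by decreasing profile value and the disease conditions flagged —
#' a specific disease module peaks in the disease conditions and stays
#' near zero elsewhere.
#'
#' @param module_genes Character vector of gene identifiers.
#' @param z Z-score matrix.
#' @param disease_conditions Character vector of disease condition ids.
#' @return Data frame (`condition_id`, `mean_z`, `rank`, `is_disease`)
#'   sorted by rank.
#' @export
condition_specificity <- function(module_genes, z, disease_conditions) {
  found <- intersect(unique(module_genes), rownames(z))
  if (length(found) == 0L) {
    stop("no module gene has expression data")
  }
  prof <- colMeans(z[found, , drop = FALSE])
  out <- data.frame(condition_id = names(prof), mean_z = unname(prof),
                    rank = rank(-prof, ties.method = "min"),
                    is_disease = names(prof) %in% disease_conditions,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$condition_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster exposure conditions on a gene set's log-ratio profiles
#'
#' Hierarchical clustering of condition columns (distance 1 - Pearson
#' correlation, average linkage) restricted to the given genes, with flat
#' clusters obtained by the cut that maximizes the mean silhouette width
#' over `k_range`.
#'
#' @param mat Genes x conditions log-ratio matrix (already restricted to
#'   the genes of interest, or subset with `mat[genes, ]`).
#' @param k_range Candidate numbers of flat clusters.
#' @return List with `hclust`, `k`, `clusters` (named membership vector)
#'   and `silhouette` (mean width per candidate k).
#' @export
cluster_conditions <- function(mat, k_range = 2:20) {
  if (ncol(mat) < 2L) stop("need at least 2 conditions to cluster")
  d <- stats::as.dist(1 - cor(mat))
  h <- hclust(d, method = "average")
  ks <- k_range[k_range >= 2L & k_range <= ncol(mat) - 1L]
  if (length(ks) == 0L) ks <- 2L
  widths <- vapply(ks, function(k) {
    mean(cluster::silhouette(cutree(h, k = k), d)[, "sil_width"])
  }, numeric(1L))
  k_best <- ks[which.max(widths)]
  list(hclust = h, k = k_best, clusters = cutree(h, k = k_best),
       silhouette = setNames(widths, ks))
}

#' Time-course activation profile of a gene set
#'
#' Mean log2 ratio per gene within each timepoint group, and the number of
#' activated genes (mean strictly above `threshold`; 0.6 corresponds to
#' roughly a 1.5-fold change) per timepoint.
#'
#' @param module_genes Character vector of gene identifiers.
#' @param mat Genes x conditions log-ratio matrix.
#' @param groups Named vector mapping condition id to timepoint label.
#' @param threshold Activation threshold on the mean log2 ratio (strict).
#' @return List with `per_gene` (genes x timepoints matrix of means),
#'   `activated` (named count per timepoint) and `threshold`.
#' @export
timepoint_profile <- function(module_genes, mat, groups, threshold = 0.6) {
  unknown <- setdiff(names(groups), colnames(mat))
  if (length(unknown)) {
    stop("unknown condition id(s) in groups: ",
         paste(unknown, collapse = ", "))
  }
  genes <- intersect(unique(module_genes), rownames(mat))
  labels <- unique(unname(groups))
  per_gene <- vapply(labels, function(lb) {
    cols <- names(groups)[groups == lb]
    rowMeans(mat[genes, cols, drop = FALSE])
  }, numeric(length(genes)))
  per_gene <- matrix(per_gene, nrow = length(genes),
                     dimnames = list(genes, labels))
  list(per_gene = per_gene,
       activated = setNames(colSums(per_gene > threshold), labels),
       threshold = threshold)
}

#' Correlation of a module's expression response with an external study
#'
#' Pearson correlation between the module genes' internal mean log2 ratios
#' and matched log2 ratios from an external dataset.
#'
#' @param module_genes Character vector of gene identifiers.
#' @param internal Named numeric vector (gene -> mean log2 ratio).
#' @param external Named numeric vector (gene -> log2 ratio).
#' @return List with `r` and `n_matched`.
#' @export
external_correlation <- function(module_genes, internal, external) {
  matched <- Reduce(intersect, list(unique(module_genes), names(internal),
                                    names(external)))
  if (length(matched) < 3L) {
    stop("fewer than 3 matched genes between internal and external data")
  }
  list(r = cor(internal[matched], external[matched]),
       n_matched = length(matched))
}
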