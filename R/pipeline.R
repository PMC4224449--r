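#' Parameters for the end-to-end pipeline
#'
#' Collects every stage's tunables with the pipeline defaults: median IQR
#' filtering, 25% present-call fraction, histopathology score > 1,
#' rank-product FDR < 0.05 in at least 2 conditions with 100 permutations,
#' minimum co-expression cluster size 16, activation-score magnitude
#' cutoff 2, node-exception budget 100 per extraction run, seed cliques of
#' size 3, and BH-FDR 0.05 for enrichment.
#'
#' @param iqr_quantile,present_frac See [filter_probes()].
#' @param score_threshold See [select_disease_conditions()].
#' @param n_perm,fdr_cutoff,min_conditions See [rank_product_test()] and
#'   [aggregate_deg()].
#' @param min_cluster_size,deep_split,activation_cutoff See
#'   [coexpression_clusters()] and [select_active_clusters()].
#' @param k_exceptions See [extract_subnetwork()].
#' @param min_clique See [eagle_modules()].
#' @param alpha BH-FDR level for module enrichment.
#' @param background_n Enrichment background size; `NULL` uses the full
#'   network node count.
#' @param seed Integer seed driving every randomized stage.
#' @return Named list of class `pipeline_params`.
#' @export
pipeline_params <- function(iqr_quantile = 0.5, present_frac = 0.25,
                            score_threshold = 1L, n_perm = 100L,
                            fdr_cutoff = 0.05, min_conditions = 2L,
                            min_cluster_size = 16L, deep_split = TRUE,
                            activation_cutoff = 2, k_exceptions = 100L,
                            min_clique = 3L, alpha = 0.05,
                            background_n = NULL, seed = 1L) {
  structure(list(iqr_quantile = iqr_quantile, present_frac = present_frac,
                 score_threshold = score_threshold, n_perm = n_perm,
                 fdr_cutoff = fdr_cutoff, min_conditions = min_conditions,
                 min_cluster_size = min_cluster_size,
                 deep_split = deep_split,
                 activation_cutoff = activation_cutoff,
                 k_exceptions = k_exceptions, min_clique = min_clique,
                 alpha = alpha, background_n = background_n,
                 seed = as.integer(seed)),
            class = "pipeline_params")
}

#' Run the full module-discovery pipeline
#'
#' Chains every stage: probe filtering, per-condition log-ratios, probe
#' collapsing, disease-condition selection with replicate-clustering QC,
#' per-condition rank-product differential expression with the
#' at-least-two-conditions aggregation, co-expression clustering with
#' activation-based cluster selection, the union of both gene lists,
#' ortholog mapping, four subnetwork extractions (up/down x DEG/
#' co-expressed) merged by union, overlapping module detection, module
#' activation and curated-set enrichment, and module prioritization.
#'
#' @param study List with `intensity`, `presence`, `samples` and
#'   `probe2gene` (e.g. from [generate_study()]).
#' @param netbundle List with `network`, `orthologs` and `gene_sets`
#'   (e.g. from [generate_network()]).
#' @param params A [pipeline_params()] list.
#' @return List of class `fibronet_result` holding every stage's output;
#'   the headline result is `prioritized` (ranked module table) and
#'   `modules` (the module set), with `top_module_nodes` the node set of
#'   the rank-1 module.
#' @export
run_pipeline <- function(study, netbundle, params = pipeline_params()) {
  p <- params

  filt <- filter_probes(study$intensity, study$presence, study$samples,
                        study$probe2gene, iqr_quantile = p$iqr_quantile,
                        present_frac = p$present_frac)
  lr_probe <- condition_log_ratios(filt$intensity, study$samples)
  lr <- collapse_probes(lr_probe, filt$probe2gene)
  kept_probes <- attr(lr, "kept_probes")
  gene_int <- filt$intensity[unname(kept_probes), , drop = FALSE]
  rownames(gene_int) <- names(kept_probes)
  gene_int <- gene_int[rownames(lr), , drop = FALSE]

  disease <- select_disease_conditions(study$samples, p$score_threshold)
  if (length(disease) == 0L) stop("no disease-producing condition found")
  qc <- NULL
  if (length(disease) >= 2L) {
    qc <- qc_replicate_clustering(gene_int, study$samples, disease)
    disease <- qc$condition_id[qc$pass]
  }
  if (length(disease) < p$min_conditions) {
    stop("fewer disease conditions passed QC (", length(disease),
         ") than min_conditions (", p$min_conditions, ")")
  }

  rp <- lapply(seq_along(disease), function(i) {
    cc <- disease[i]
    rows <- study$samples[study$samples$condition_id == cc, , drop = FALSE]
    ctrl <- unique(rows$control_condition_id)
    ctrl <- ctrl[!is.na(ctrl)]
    rank_product_test(
      gene_int[, rows$sample_id, drop = FALSE],
      gene_int[, condition_sample_ids(study$samples, ctrl), drop = FALSE],
      n_perm = p$n_perm, seed = p$seed + i)
  })
  names(rp) <- disease
  deg <- aggregate_deg(rp, fdr_cutoff = p$fdr_cutoff,
                       min_conditions = p$min_conditions)

  z <- zscore_standardize(lr)
  clusters <- coexpression_clusters(lr, min_size = p$min_cluster_size,
                                    deep_split = p$deep_split)
  act <- select_active_clusters(clusters, z, disease,
                                cutoff = p$activation_cutoff)
  combined <- combine_gene_sets(deg, act$genes)

  query_lists <- list(deg_up = deg$up, deg_down = deg$down,
                      coexpr_up = act$up_genes,
                      coexpr_down = act$down_genes)
  mapped <- lapply(query_lists, function(g) {
    if (length(g) == 0L) return(list(nodes = character(0), report = NULL))
    suppressWarnings(map_to_network(g, netbundle$orthologs,
                                    netbundle$network))
  })
  subnets <- lapply(Filter(function(m) length(m$nodes) > 0L, mapped),
                    function(m) extract_subnetwork(netbundle$network,
                                                   m$nodes,
                                                   k_exceptions = p$k_exceptions,
                                                   seed = p$seed))
  if (length(subnets) == 0L) {
    stop("no gene list mapped onto the network; cannot extract subnetworks")
  }
  merged <- union_subnetworks(subnets)

  modules <- eagle_modules(merged$graph, min_clique = p$min_clique)
  activations <- module_activation(modules, z, disease,
                                   netbundle$orthologs)
  bg <- if (is.null(p$background_n)) igraph::vcount(netbundle$network) else
    p$background_n
  enrichments <- module_enrichment(modules, netbundle$gene_sets, bg,
                                   alpha = p$alpha)
  prioritized <- prioritize_modules(activations, enrichments)
  top_id <- prioritized$module[1L]

  structure(list(filter_report = filt$report, log_ratios = lr,
                 zscores = z, disease_conditions = disease, qc = qc,
                 rank_products = rp, deg = deg, clusters = clusters,
                 cluster_activation = act, combined = combined,
                 mapping = lapply(mapped, `[[`, "report"),
                 subnetworks = subnets, merged_subnetwork = merged,
                 modules = modules, activations = activations,
                 enrichments = enrichments, prioritized = prioritized,
                 top_module = top_id,
                 top_module_nodes = modules$modules[[top_id]],
                 params = p),
            class = "fibronet_result")
}

#' Leave-one-quarter-out stability of the prioritized module
#'
#' Partitions the replicate samples into `n_folds` folds, stratified by
#' condition so that every condition keeps at least one treated and one
#' control replicate when a fold is removed, re-runs the whole pipeline
#' without each fold, and reports the overlap fraction of each re-run's
#' top-module node set with the full-data top module.
#'
#' @param study,netbundle,params As in [run_pipeline()].
#' @param n_folds Number of folds.
#' @param seed Integer seed for the stratified fold assignment.
#' @return List with `overlaps` (per-fold fractions), `mean_overlap`,
#'   `full` (the full-data result) and `fold_assignment`.
#' @export
subsample_stability <- function(study, netbundle,
                                params = pipeline_params(),
                                n_folds = 4L, seed = 1L) {
  samples <- study$samples
  set.seed(seed)
  fold <- integer(nrow(samples))
  for (cc in unique(samples$condition_id)) {
    idx <- which(samples$condition_id == cc)
    if (length(idx) < 2L) {
      stop("condition '", cc,
           "' has fewer than 2 replicates; a fold would remove all of them")
    }
    if (length(idx) <= n_folds) {
      fold[idx] <- sample(n_folds, length(idx))
    } else {
      fold[idx] <- sample(rep(seq_len(n_folds),
                              length.out = length(idx)))
    }
  }
  names(fold) <- samples$sample_id

  full <- run_pipeline(study, netbundle, params)
  ref <- full$top_module_nodes

  overlaps <- vapply(seq_len(n_folds), function(f) {
    keep <- samples$sample_id[fold != f]
    sub <- study
    sub$intensity <- study$intensity[, keep, drop = FALSE]
    sub$presence <- study$presence[, keep, drop = FALSE]
    sub$samples <- samples[samples$sample_id %in% keep, , drop = FALSE]
    res <- run_pipeline(sub, netbundle, params)
    length(intersect(res$top_module_nodes, ref)) / length(ref)
  }, numeric(1L))

  list(overlaps = overlaps, mean_overlap = mean(overlaps), full = full,
       fold_assignment = fold)
}
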