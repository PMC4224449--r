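#' Configuration for the synthetic study generator
#'
#' Builds the parameter set for [generate_study()] and [generate_network()].
#' Defaults emulate a DrugMatrix-like toxicogenomics compendium at benchmark
#' scale: replicated treated/control exposure conditions on a log2 intensity
#' scale, a small disease-condition subset with planted differential
#' expression, correlated co-expression blocks driven by latent condition
#' profiles, and a scale-free background interaction network with a planted
#' dense module.
#'
#' @param n_genes Number of genes (one probe per gene is emitted).
#' @param n_conditions Number of chemical exposure conditions (each a
#'   chemical at one dose and duration, with a matched control group).
#' @param n_disease_conditions Number of conditions that produce the disease
#'   phenotype (histopathology severity 2).
#' @param replicates_per_condition Replicate arrays per treated and per
#'   control group.
#' @param n_planted_deg Number of purely differentially expressed planted
#'   genes (split evenly up/down).  Genes of the disease co-expression
#'   block respond as well and are counted in the up ground truth.
#' @param deg_log2_shift Mean log2 shift of planted DEGs in treated samples
#'   of disease conditions.
#' @param n_coexpr_blocks Number of co-expression blocks; block 1 is the
#'   disease-responsive block.
#' @param block_size Genes per co-expression block.
#' @param block_correlation Target pairwise Pearson correlation of log-ratio
#'   profiles within a block, in (0, 1).
#' @param noise_sd Replicate-level measurement noise SD (log2 units).
#' @param network_nodes Nodes in the background interaction network.
#' @param network_attach_degree Edges attached per node during preferential
#'   attachment growth.
#' @param planted_module_size Nodes in the planted dense module.
#' @param planted_module_edge_prob Wiring probability among module nodes,
#'   in (0, 1].
#' @param curated_set_sizes Integer vector of curated gene-set sizes.
#' @param curated_set_overlap_frac Fraction of each curated set drawn from
#'   the planted module, in \[0, 1\].
#' @param seed Integer seed; every generator draw derives from it.
#' @param effect_sd Condition-effect SD of unresponsive background genes
#'   (log2 units).
#' @param responsive_effect_sd Condition-effect SD of planted DEGs: genes
#'   that respond to the disease exposures also vary more across the other
#'   exposures, which is the premise of IQR-based non-specific filtering.
#' @param disease_block_amplitude Value of the disease block's latent
#'   condition factor in disease conditions (in latent-factor SD units).
#' @param frac_absent Fraction of genes flagged as largely absent on the
#'   array (exercises the present-call filter); drawn from non-planted genes.
#' @param baseline_mean,baseline_sd Mean and SD of per-gene baseline log2
#'   intensity.
#' @return A validated list of class `fibronet_config`.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_conditions = 100L,
                             n_disease_conditions = 4L,
                             replicates_per_condition = 3L,
                             n_planted_deg = 100L,
                             deg_log2_shift = 1.0,
                             n_coexpr_blocks = 8L,
                             block_size = 30L,
                             block_correlation = 0.6,
                             noise_sd = 0.4,
                             network_nodes = 1500L,
                             network_attach_degree = 3L,
                             planted_module_size = 60L,
                             planted_module_edge_prob = 0.3,
                             curated_set_sizes = c(26L, 95L),
                             curated_set_overlap_frac = 0.5,
                             seed = 1L,
                             effect_sd = 0.2,
                             responsive_effect_sd = 0.3,
                             disease_block_amplitude = 4,
                             frac_absent = 0.05,
                             baseline_mean = 8,
                             baseline_sd = 1.5) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_conditions = as.integer(n_conditions),
              n_disease_conditions = as.integer(n_disease_conditions),
              replicates_per_condition = as.integer(replicates_per_condition),
              n_planted_deg = as.integer(n_planted_deg),
              deg_log2_shift = deg_log2_shift,
              n_coexpr_blocks = as.integer(n_coexpr_blocks),
              block_size = as.integer(block_size),
              block_correlation = block_correlation,
              noise_sd = noise_sd,
              network_nodes = as.integer(network_nodes),
              network_attach_degree = as.integer(network_attach_degree),
              planted_module_size = as.integer(planted_module_size),
              planted_module_edge_prob = planted_module_edge_prob,
              curated_set_sizes = as.integer(curated_set_sizes),
              curated_set_overlap_frac = curated_set_overlap_frac,
              seed = as.integer(seed),
              effect_sd = effect_sd,
              responsive_effect_sd = responsive_effect_sd,
              disease_block_amplitude = disease_block_amplitude,
              frac_absent = frac_absent,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd)
  class(cfg) <- "fibronet_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid configuration field '", field, "': ", why,
                          call. = FALSE)
  }
  pos <- function(field) chk(length(cfg[[field]]) == 1L && !is.na(cfg[[field]]) &&
                               cfg[[field]] >= 1L, field, "must be a positive count")
  for (f in c("n_genes", "n_conditions", "n_disease_conditions",
              "replicates_per_condition", "n_coexpr_blocks", "block_size",
              "network_nodes", "network_attach_degree", "planted_module_size"))
    pos(f)
  chk(cfg$n_planted_deg >= 0L, "n_planted_deg", "must be non-negative")
  chk(cfg$n_planted_deg <= cfg$n_genes, "n_planted_deg",
      "cannot exceed n_genes")
  chk(cfg$n_disease_conditions < cfg$n_conditions, "n_disease_conditions",
      "must be smaller than n_conditions")
  chk(cfg$planted_module_size <= cfg$network_nodes, "planted_module_size",
      "cannot exceed network_nodes")
  chk(cfg$block_correlation > 0 && cfg$block_correlation < 1,
      "block_correlation", "must lie in (0, 1)")
  chk(cfg$planted_module_edge_prob > 0 && cfg$planted_module_edge_prob <= 1,
      "planted_module_edge_prob", "must lie in (0, 1]")
  chk(cfg$curated_set_overlap_frac >= 0 && cfg$curated_set_overlap_frac <= 1,
      "curated_set_overlap_frac", "must lie in [0, 1]")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be non-negative")
  chk(cfg$deg_log2_shift >= 0, "deg_log2_shift", "must be non-negative")
  chk(cfg$frac_absent >= 0 && cfg$frac_absent < 1, "frac_absent",
      "must lie in [0, 1)")
  chk(cfg$n_coexpr_blocks * cfg$block_size + cfg$n_planted_deg <= cfg$n_genes,
      "block_size", "blocks plus planted DEGs exceed n_genes")
  chk(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed",
      "must be a single integer")
  invisible(cfg)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))
node_ids <- function(n) sprintf("n%05d", seq_len(n))

#' Generate a synthetic replicated exposure study with ground truth
#'
#' Emits a probe-level log2 intensity table (treated and matched control
#' replicates for every condition), a 0/1 presence-flag table of the same
#' shape, per-sample metadata, and the planted ground truth.  Planted
#' differential expression is applied at the replicate level in disease
#' conditions only; co-expression blocks share a latent per-condition
#' factor whose loading is calibrated so that the pairwise Pearson
#' correlation of log-ratio profiles within a block is approximately
#' `block_correlation` after measurement noise.  The disease block's latent
#' factor is elevated in disease conditions, which makes the block both
#' activated and differentially expressed there.
#'
#' @param config A [synthetic_config()] object.
#' @return A list of class `fibronet_study` with elements `intensity`
#'   (probes x samples matrix), `presence` (same shape, 0/1), `samples`
#'   (per-sample metadata data frame), `probe2gene` (named character
#'   vector), `truth` (planted ground truth) and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "fibronet_config"))
  validate_config(config)
  cfg <- config
  set.seed(cfg$seed)

  genes <- gene_ids(cfg$n_genes)
  probes <- paste0(genes, "_at")
  cond <- sprintf("cond_%03d", seq_len(cfg$n_conditions))
  ctrl <- sprintf("ctrl_%03d", seq_len(cfg$n_conditions))
  reps <- cfg$replicates_per_condition

  # planted gene roles
  perm <- sample.int(cfg$n_genes)
  n_block_genes <- cfg$n_coexpr_blocks * cfg$block_size
  block_idx <- perm[seq_len(n_block_genes)]
  block_of <- integer(cfg$n_genes)
  block_of[block_idx] <- rep(seq_len(cfg$n_coexpr_blocks), each = cfg$block_size)
  n_up <- ceiling(cfg$n_planted_deg / 2)
  n_down <- cfg$n_planted_deg - n_up
  up_idx <- perm[n_block_genes + seq_len(n_up)]
  down_idx <- perm[n_block_genes + n_up + seq_len(n_down)]
  free_idx <- perm[-seq_len(n_block_genes + cfg$n_planted_deg)]
  n_absent <- round(cfg$frac_absent * cfg$n_genes)
  absent_idx <- if (n_absent > 0L && length(free_idx) >= n_absent)
    free_idx[seq_len(n_absent)] else integer(0)

  disease_j <- sort(sample.int(cfg$n_conditions, cfg$n_disease_conditions))

  # condition effects: idiosyncratic + block latent factor
  idio_sd <- rep(cfg$effect_sd, cfg$n_genes)
  idio_sd[c(up_idx, down_idx)] <- cfg$responsive_effect_sd
  eff <- matrix(rnorm(cfg$n_genes * cfg$n_conditions), cfg$n_genes) * idio_sd
  # planted genes' elevated cross-exposure variability lives in the
  # non-disease conditions; in disease conditions their response is the
  # planted shift plus background-level variation, keeping the planted
  # effect size exactly as configured
  scal <- cfg$effect_sd / cfg$responsive_effect_sd
  eff[c(up_idx, down_idx), disease_j] <-
    eff[c(up_idx, down_idx), disease_j] * scal
  meas_var <- 2 * cfg$noise_sd^2 / reps  # log-ratio variance from replicate noise
  loading <- sqrt(cfg$block_correlation / (1 - cfg$block_correlation) *
                    (cfg$effect_sd^2 + meas_var))
  fac <- matrix(rnorm(cfg$n_coexpr_blocks * cfg$n_conditions),
                cfg$n_coexpr_blocks)
  # background blocks are orthogonal to the disease contrast so that the
  # planted DEG ground truth is exhaustive; only block 1 responds
  fac[, disease_j] <- 0
  if (cfg$n_coexpr_blocks >= 1L)
    fac[1L, disease_j] <- cfg$disease_block_amplitude
  eff[block_idx, ] <- eff[block_idx, ] +
    loading * fac[block_of[block_idx], , drop = FALSE]
  eff[up_idx, disease_j] <- eff[up_idx, disease_j] + cfg$deg_log2_shift
  eff[down_idx, disease_j] <- eff[down_idx, disease_j] - cfg$deg_log2_shift

  mu <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)

  t_samples <- as.vector(t(outer(cond, seq_len(reps),
                                 function(c, r) sprintf("%s_t%d", c, r))))
  c_samples <- as.vector(t(outer(ctrl, seq_len(reps),
                                 function(c, r) sprintf("%s_r%d", c, r))))
  n_t <- length(t_samples)
  treated <- mu + eff[, rep(seq_len(cfg$n_conditions), each = reps)] +
    matrix(rnorm(cfg$n_genes * n_t, sd = cfg$noise_sd), cfg$n_genes)
  control <- mu + matrix(rnorm(cfg$n_genes * n_t, sd = cfg$noise_sd),
                         cfg$n_genes)
  intensity <- cbind(treated, control)
  dimnames(intensity) <- list(probes, c(t_samples, c_samples))

  p_present <- rep(0.9, cfg$n_genes)
  p_present[absent_idx] <- 0.1
  presence <- matrix(rbinom(length(intensity), 1L,
                            rep(p_present, ncol(intensity))),
                     nrow = cfg$n_genes, dimnames = dimnames(intensity))

  chem <- sprintf("chem_%03d", seq_len(cfg$n_conditions))
  dose <- round(runif(cfg$n_conditions, 5, 800), 1)
  duration <- sample(c(0.25, 1, 3, 5, 7), cfg$n_conditions, replace = TRUE)
  duration[disease_j] <- sample(c(5, 7), cfg$n_disease_conditions,
                                replace = TRUE)
  histo <- sample(0:1, cfg$n_conditions, replace = TRUE, prob = c(0.8, 0.2))
  histo[disease_j] <- 2L

  per_cond <- function(x) rep(x, each = reps)
  samples <- rbind(
    data.frame(sample_id = t_samples,
               condition_id = per_cond(cond),
               chemical = per_cond(chem),
               dose = per_cond(dose),
               duration = per_cond(duration),
               group = "treated",
               control_condition_id = per_cond(ctrl),
               histopath_score = per_cond(histo),
               stringsAsFactors = FALSE),
    data.frame(sample_id = c_samples,
               condition_id = per_cond(ctrl),
               chemical = "vehicle",
               dose = 0,
               duration = per_cond(duration),
               group = "control",
               control_condition_id = NA_character_,
               histopath_score = NA_integer_,
               stringsAsFactors = FALSE))
  rownames(samples) <- NULL

  truth <- list(
    planted_deg_up = sort(c(genes[up_idx],
                            genes[block_idx[block_of[block_idx] == 1L]])),
    planted_deg_down = sort(genes[down_idx]),
    pure_deg_up = sort(genes[up_idx]),
    pure_deg_down = sort(genes[down_idx]),
    disease_block_genes = sort(genes[block_idx[block_of[block_idx] == 1L]]),
    block_membership = setNames(block_of, genes),
    disease_condition_ids = cond[disease_j],
    absent_genes = sort(genes[absent_idx]))

  structure(list(intensity = intensity, presence = presence,
                 samples = samples,
                 probe2gene = setNames(genes, probes),
                 truth = truth, config = cfg),
            class = "fibronet_study")
}

#' Generate a background interaction network with a planted module
#'
#' The background is an undirected preferential-attachment graph; the
#' planted module is an additional dense wiring (edge probability
#' `planted_module_edge_prob`) over `planted_module_size` nodes.  Curated
#' gene sets are drawn so that a fraction `curated_set_overlap_frac` of each
#' set lies inside the planted module, and an imperfect ortholog map links
#' expression gene identifiers to network nodes (around 5% unmapped, 3%
#' ambiguous; at least 90% map one-to-one).  When `truth` from
#' [generate_study()] is supplied, the module nodes are the orthologs of
#' planted up-regulated disease genes, which couples expression and network
#' ground truth for end-to-end recovery benchmarks.
#'
#' @param config A [synthetic_config()] object.
#' @param truth Optional ground-truth list from [generate_study()].
#' @return A list of class `fibronet_network` with elements `network`
#'   (igraph), `module_nodes`, `module_genes`, `gene_sets` (named list),
#'   `orthologs` (data frame `source_id`, `target_id`, `ambiguous`) and
#'   `config`.
#' @export
generate_network <- function(config, truth = NULL) {
  stopifnot(inherits(config, "fibronet_config"))
  validate_config(config)
  cfg <- config
  set.seed(cfg$seed + 101L)

  nodes <- node_ids(cfg$network_nodes)
  g <- igraph::sample_pa(cfg$network_nodes, power = 1,
                         m = cfg$network_attach_degree, directed = FALSE)
  igraph::V(g)$name <- nodes

  module_nodes <- sort(sample(nodes, cfg$planted_module_size))
  pairs <- utils::combn(module_nodes, 2L)
  keep <- runif(ncol(pairs)) < cfg$planted_module_edge_prob
  if (any(keep)) {
    g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
  }
  g <- igraph::simplify(g)

  genes <- gene_ids(cfg$n_genes)
  pool <- if (!is.null(truth)) truth$planted_deg_up else genes
  if (length(pool) < cfg$planted_module_size) {
    warning("fewer candidate disease genes than planted module nodes; ",
            "supplementing with background genes")
    pool <- c(pool, setdiff(genes, pool))
  }
  module_genes <- sort(sample(pool, cfg$planted_module_size))

  other_genes <- setdiff(genes, module_genes)
  n_other <- length(other_genes)
  n_unmapped <- round(0.05 * n_other)
  n_ambig <- round(0.03 * n_other)
  shuf <- sample(other_genes)
  unmapped <- shuf[seq_len(n_unmapped)]
  ambig <- shuf[n_unmapped + seq_len(n_ambig)]
  plain <- shuf[-seq_len(n_unmapped + n_ambig)]
  orthologs <- rbind(
    data.frame(source_id = module_genes, target_id = module_nodes,
               ambiguous = FALSE, stringsAsFactors = FALSE),
    data.frame(source_id = plain,
               target_id = sample(nodes, length(plain), replace = TRUE),
               ambiguous = FALSE, stringsAsFactors = FALSE),
    data.frame(source_id = rep(ambig, each = 2L),
               target_id = sample(nodes, 2L * length(ambig), replace = TRUE),
               ambiguous = TRUE, stringsAsFactors = FALSE))
  rownames(orthologs) <- NULL

  gene_sets <- list()
  for (i in seq_along(cfg$curated_set_sizes)) {
    s <- cfg$curated_set_sizes[i]
    k_in <- min(round(cfg$curated_set_overlap_frac * s),
                cfg$planted_module_size)
    members <- c(sample(module_nodes, k_in),
                 sample(setdiff(nodes, module_nodes), s - k_in))
    gene_sets[[sprintf("curated_set_%d", i)]] <-
      structure(sort(members),
                description = sprintf("synthetic curated set %d", i))
  }

  structure(list(network = g, module_nodes = module_nodes,
                 module_genes = module_genes, gene_sets = gene_sets,
                 orthologs = orthologs, config = cfg),
            class = "fibronet_network")
}

#' Set-overlap recovery metrics
#'
#' Precision, recall and Jaccard index of a detected identifier set against
#' a planted truth set.  Two empty sets have Jaccard 1 by convention;
#' precision and recall are `NA` whenever their denominator is empty.
#'
#' @param detected Character vector of detected identifiers.
#' @param truth Character vector of true identifiers.
#' @return Named list with `precision`, `recall`, `jaccard` and `overlap`.
#' @export
recovery_metrics <- function(detected, truth) {
  detected <- unique(detected)
  truth <- unique(truth)
  ov <- length(intersect(detected, truth))
  un <- length(union(detected, truth))
  list(precision = if (length(detected)) ov / length(detected) else NA_real_,
       recall = if (length(truth)) ov / length(truth) else NA_real_,
       jaccard = if (un) ov / un else 1,
       overlap = ov)
}
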