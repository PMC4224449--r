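test_that("study generation is reproducible from the seed", {
  a <- generate_study(small_cfg(seed = 3L))
  b <- generate_study(small_cfg(seed = 3L))
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$presence, b$presence)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_study(small_cfg(seed = 4L))
  expect_false(identical(a$intensity, c$intensity))
})

test_that("null generator plants no differential expression", {
  cfg <- small_cfg(seed = 2L, deg_log2_shift = 0, noise_sd = 0.1,
                   disease_block_amplitude = 0)
  st <- generate_study(cfg)
  lr <- condition_log_ratios(st$intensity, st$samples)
  dc <- st$truth$disease_condition_ids
  # per-gene disease mean log-ratio: condition effect + noise only;
  # bound = 5 SD of the per-gene disease mean under the generator model
  reps <- cfg$replicates_per_condition
  sdm <- sqrt((max(cfg$effect_sd, cfg$responsive_effect_sd)^2 +
                 2 * cfg$noise_sd^2 / reps) / length(dc) + 0.3^2)
  expect_lt(max(abs(rowMeans(lr[, dc]))), 5 * sdm)
})

test_that("planted up-genes hit the configured shift in disease conditions", {
  cfg <- small_cfg(seed = 1L)
  st <- generate_study(cfg)
  lr <- condition_log_ratios(st$intensity, st$samples)
  rownames(lr) <- st$probe2gene[rownames(lr)]
  up <- st$truth$pure_deg_up
  vals <- lr[up, st$truth$disease_condition_ids]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - cfg$deg_log2_shift), 3 * se)
  down <- st$truth$pure_deg_down
  vals_d <- lr[down, st$truth$disease_condition_ids]
  expect_lt(abs(mean(vals_d) + cfg$deg_log2_shift),
            3 * sd(vals_d) / sqrt(length(vals_d)))
})

test_that("within-block correlation margin grows with block_correlation", {
  margin <- function(rho) {
    cfg <- small_cfg(seed = 8L, block_correlation = rho)
    st <- generate_study(cfg)
    lr <- condition_log_ratios(st$intensity, st$samples)
    rownames(lr) <- st$probe2gene[rownames(lr)]
    bm <- st$truth$block_membership
    b2 <- names(bm)[bm == 2L]  # background block, no disease response
    b3 <- names(bm)[bm == 3L]
    r22 <- cor(t(lr[b2, ]))
    within <- median(r22[upper.tri(r22)])
    between <- median(cor(t(lr[b2, ]), t(lr[b3, ])))
    within - between
  }
  m_lo <- margin(0.3)
  m_hi <- margin(0.7)
  expect_gt(m_lo, 0.1)
  expect_gt(m_hi, m_lo)
})

test_that("network generator plants a clique at edge probability 1", {
  cfg <- small_cfg(seed = 5L, planted_module_size = 6L,
                   planted_module_edge_prob = 1)
  nb <- generate_network(cfg)
  sub <- igraph::induced_subgraph(nb$network, nb$module_nodes)
  expect_equal(igraph::ecount(sub), choose(6L, 2L))
})

test_that("network edge list round-trips and the graph is simple", {
  cfg <- small_cfg(seed = 1L)
  nb <- generate_network(cfg)
  expect_true(igraph::is_simple(nb$network))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(nb$network, path)
  n_lines <- length(readLines(path))
  expect_equal(n_lines, igraph::ecount(nb$network))
  expect_equal(igraph::ecount(read_edge_list(path)),
               igraph::ecount(nb$network))
})

test_that("background degree distribution is heavy-tailed", {
  nb <- generate_network(synthetic_config(seed = 2L))
  deg <- igraph::degree(nb$network)
  expect_gt(max(deg), 3 * median(deg))
})

test_that("ortholog map covers at least 90% of genes one-to-one", {
  cfg <- small_cfg(seed = 1L)
  nb <- generate_network(cfg)
  orth <- nb$orthologs
  ambig <- unique(orth$source_id[orth$ambiguous])
  one2one <- setdiff(unique(orth$source_id), ambig)
  expect_gte(length(one2one) / cfg$n_genes, 0.9)
  expect_gt(length(ambig), 0L)
  expect_gt(cfg$n_genes - length(unique(orth$source_id)), 0L)
})

test_that("network generation is reproducible and respects truth coupling", {
  cfg <- small_cfg(seed = 6L)
  st <- generate_study(cfg)
  a <- generate_network(cfg, st$truth)
  b <- generate_network(cfg, st$truth)
  expect_identical(igraph::as_edgelist(a$network),
                   igraph::as_edgelist(b$network))
  expect_identical(a$module_genes, b$module_genes)
  expect_true(all(a$module_genes %in% st$truth$planted_deg_up))
  # module genes map exactly onto module nodes
  lut <- a$orthologs[match(a$module_genes, a$orthologs$source_id), ]
  expect_setequal(lut$target_id, a$module_nodes)
})

test_that("curated sets overlap the planted module by the configured fraction", {
  cfg <- small_cfg(seed = 3L, curated_set_overlap_frac = 0.5)
  nb <- generate_network(cfg)
  for (s in nb$gene_sets) {
    frac <- length(intersect(s, nb$module_nodes)) / length(s)
    expect_equal(frac, 0.5, tolerance = 0.1)
  }
})

test_that("recovery metrics follow the set-overlap definitions", {
  expect_equal(recovery_metrics(c("a", "b"), c("a", "b")),
               list(precision = 1, recall = 1, jaccard = 1, overlap = 2L),
               tolerance = 1e-12)
  r <- recovery_metrics(c("a", "b"), c("c", "d"))
  expect_equal(c(r$precision, r$recall, r$jaccard), c(0, 0, 0))
  r2 <- recovery_metrics(sprintf("d%02d", 1:10),
                         c(sprintf("d%02d", 1:5), sprintf("t%02d", 1:15)))
  expect_equal(c(r2$precision, r2$recall, r2$jaccard), c(0.5, 0.25, 0.2))
  r3 <- recovery_metrics(character(0), character(0))
  expect_true(is.na(r3$precision) && is.na(r3$recall))
  expect_equal(r3$jaccard, 1)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(small_cfg(block_correlation = 1.2), "block_correlation")
  expect_error(small_cfg(planted_module_edge_prob = 0), "planted_module_edge_prob")
  expect_error(synthetic_config(n_genes = 100, n_planted_deg = 200),
               "n_planted_deg")
  expect_error(synthetic_config(n_conditions = 4, n_disease_conditions = 4),
               "n_disease_conditions")
  expect_error(small_cfg(network_nodes = 10, planted_module_size = 25),
               "planted_module_size")
})
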