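# Shared fixtures and independent oracles for the test suite.
# Heavy simulations use a reduced study scale; the default (acceptance)
# scale is exercised in test-acceptance.R.

small_cfg <- function(seed = 1L, ...) {
  args <- list(n_genes = 300L, n_conditions = 40L,
               n_disease_conditions = 2L, replicates_per_condition = 3L,
               n_planted_deg = 30L, n_coexpr_blocks = 3L,
               block_size = 20L, network_nodes = 250L,
               planted_module_size = 25L,
               curated_set_sizes = c(12L, 20L), seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

named_matrix <- function(data, nrow, genes = NULL, conds = NULL) {
  m <- matrix(data, nrow = nrow)
  rownames(m) <- if (is.null(genes)) sprintf("g%03d", seq_len(nrow)) else genes
  colnames(m) <- if (is.null(conds)) sprintf("c%03d", seq_len(ncol(m))) else conds
  m
}

# minimal two-condition sample sheet: `reps` treated + `reps` control per
# condition, matched controls, given histopathology scores
toy_samples <- function(n_cond = 2L, reps = 2L, scores = rep(2L, n_cond),
                        chemicals = sprintf("chem_%02d", seq_len(n_cond)),
                        dose = rep(10, n_cond),
                        duration = rep(5, n_cond)) {
  cond <- sprintf("cond_%02d", seq_len(n_cond))
  ctrl <- sprintf("ctrl_%02d", seq_len(n_cond))
  rbind(
    data.frame(sample_id = paste0(rep(cond, each = reps), "_t",
                                  seq_len(reps)),
               condition_id = rep(cond, each = reps),
               chemical = rep(chemicals, each = reps),
               dose = rep(dose, each = reps),
               duration = rep(duration, each = reps),
               group = "treated",
               control_condition_id = rep(ctrl, each = reps),
               histopath_score = rep(scores, each = reps),
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(rep(ctrl, each = reps), "_r",
                                  seq_len(reps)),
               condition_id = rep(ctrl, each = reps),
               chemical = "vehicle", dose = 0,
               duration = rep(duration, each = reps),
               group = "control",
               control_condition_id = NA_character_,
               histopath_score = NA_integer_,
               stringsAsFactors = FALSE))
}

# brute-force rank product: explicit loops over all treated x control
# pairings, independent of the package implementation
bf_rank_product <- function(treated, control) {
  n <- nrow(treated)
  rp_up <- rp_dn <- rep(1, n)
  K <- 0L
  lup <- ldn <- matrix(0, n, ncol(treated) * ncol(control))
  for (i in seq_len(ncol(treated))) {
    for (j in seq_len(ncol(control))) {
      K <- K + 1L
      l <- treated[, i] - control[, j]
      lup[, K] <- rank(-l, ties.method = "average")
      ldn[, K] <- rank(l, ties.method = "average")
    }
  }
  for (g in seq_len(n)) {
    rp_up[g] <- prod(lup[g, ])^(1 / K)
    rp_dn[g] <- prod(ldn[g, ])^(1 / K)
  }
  list(rp_up = rp_up, rp_down = rp_dn)
}

# exact pfp for small n and K = 2 by enumerating all permutation pairs
exact_pfp <- function(rp_obs, n) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  pp <- perms(seq_len(n))
  counts <- numeric(length(rp_obs))
  total <- 0L
  for (a in pp) {
    for (b in pp) {
      null_rp <- sqrt(a * b)
      total <- total + 1L
      for (g in seq_along(rp_obs)) {
        counts[g] <- counts[g] + sum(null_rp <= rp_obs[g])
      }
    }
  }
  e <- counts / total
  pos <- rank(rp_obs, ties.method = "max")
  raw <- e / pos
  ord <- order(rp_obs)
  adj <- raw
  adj[ord] <- rev(cummin(rev(raw[ord])))
  adj
}

# exhaustive optimum for the node-exception subnetwork problem (small K)
exhaustive_best_active <- function(g, query, K) {
  vn <- igraph::V(g)$name
  nonq <- setdiff(vn, query)
  subsets <- list(character(0))
  if (K >= 1L) subsets <- c(subsets, as.list(nonq))
  if (K >= 2L && length(nonq) >= 2L) {
    subsets <- c(subsets,
                 apply(utils::combn(nonq, 2L), 2L, identity,
                       simplify = FALSE))
  }
  best <- 0L
  for (E in subsets) {
    gi <- igraph::induced_subgraph(g, c(query, E))
    cmp <- igraph::components(gi)
    for (ci in seq_len(cmp$no)) {
      mem <- igraph::V(gi)$name[cmp$membership == ci]
      best <- max(best, length(intersect(mem, query)))
    }
  }
  best
}

# brute-force maximal clique enumeration by subset checking
bf_maximal_cliques <- function(g, min_size = 3L) {
  vn <- sort(igraph::V(g)$name)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[vn, vn]
  n <- length(vn)
  is_clique <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    all(A[idx, idx][upper.tri(diag(length(idx)))] == 1)
  }
  out <- list()
  for (k in seq(n, min_size)) {
    if (k > n) next
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      if (!is_clique(idx)) next
      maximal <- TRUE
      for (v in setdiff(seq_len(n), idx)) {
        if (all(A[v, idx] == 1)) {
          maximal <- FALSE
          break
        }
      }
      if (maximal) out[[length(out) + 1L]] <- vn[idx]
    }
  }
  key <- vapply(out, paste, character(1L), collapse = "\r")
  out[order(-lengths(out), key)]
}

# extended modularity recomputation from a module list (formula oracle)
bf_extended_modularity <- function(g, modules) {
  vn <- sort(igraph::V(g)$name)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[vn, vn]
  k <- rowSums(A)
  m <- sum(A) / 2
  ov <- table(unlist(modules))
  O <- setNames(as.numeric(ov), names(ov))
  tot <- 0
  for (mod in modules) {
    for (v in mod) {
      for (w in mod) {
        tot <- tot + (A[v, w] - k[v] * k[w] / (2 * m)) / (O[v] * O[w])
      }
    }
  }
  unname(tot) / (2 * m)
}

make_named_graph <- function(edges) {
  igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                              directed = FALSE)
}
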