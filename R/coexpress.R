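#' Standardize a log-ratio matrix into per-gene Z-scores
#'
#' Each row is centred by its mean and scaled by its standard deviation
#' (denominator n - 1) across all conditions.  Rows with zero standard
#' deviation carry no profile information and are dropped; their count is
#' reported via a message and the `"n_dropped"` attribute.
#'
#' @param mat Genes x conditions log-ratio matrix with at least 2 columns.
#' @return Z-score matrix whose rows have mean 0 and SD 1.
#' @export
zscore_standardize <- function(mat) {
  if (ncol(mat) < 2L) {
    stop("Z-score standardization needs at least 2 conditions")
  }
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, sd)
  drop <- sdv == 0
  if (any(drop)) {
    message(sum(drop), " constant row(s) dropped during standardization")
  }
  z <- (mat[!drop, , drop = FALSE] - mu[!drop]) / sdv[!drop]
  attr(z, "n_dropped") <- sum(drop)
  z
}

hclust_members <- function(merge) {
  n <- nrow(merge) + 1L
  members <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    get <- function(x) if (x < 0L) -x else members[[x]]
    members[[i]] <- c(get(merge[i, 1L]), get(merge[i, 2L]))
  }
  members
}

#' Co-expression clustering with a dynamic tree cut
#'
#' Builds an average-linkage dendrogram on the distance 1 - Pearson
#' correlation of gene log-ratio profiles across conditions, then cuts it
#' adaptively.  Starting at the root, a branch is split into its two
#' children as long as both children hold at least `min_size` genes (with
#' `deep_split = FALSE` the merge must additionally be separated from its
#' children by a height gap of at least a quarter of the dendrogram's
#' height range).  A branch that can no longer split becomes a cluster
#' built around its core: the descent continues along the dominant child,
#' shedding sub-`min_size` side branches, until no child reaches
#' `min_size`; shed side branches are then reattached only if they joined
#' the core branch at a height within `attach_frac` of the span between
#' the core's own height and the dendrogram root — this keeps coherent
#' clusters whole while excluding the loosely chained genes that average
#' linkage accretes near the top of a branch.  Constant-profile genes,
#' branches below `min_size` and non-reattached shed genes are left
#' unassigned (cluster 0).  Genes are ordered by identifier before
#' clustering so the result is invariant to input row order.
#'
#' @param mat Genes x conditions log-ratio matrix.
#' @param min_size Minimum cluster size.
#' @param deep_split `TRUE` (default) splits every eligible branch;
#'   `FALSE` requires a clear height gap, yielding coarser clusters.
#' @param attach_frac Fraction of the core-to-root height span within
#'   which shed side branches are reattached to the core.
#' @return Named integer vector (gene -> cluster id, 0 = unassigned),
#'   cluster ids 1..k ordered by decreasing size.  Class `cluster_set`.
#' @export
coexpression_clusters <- function(mat, min_size = 16L, deep_split = TRUE,
                                  attach_frac = 0.25) {
  if (min_size < 2L) stop("min_size must be at least 2")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  assign <- setNames(integer(nrow(mat)), rownames(mat))
  sdv <- apply(mat, 1L, sd)
  usable <- sdv > 0
  m <- mat[usable, , drop = FALSE]
  if (nrow(m) < min_size || nrow(m) < 2L) {
    return(structure(assign, class = "cluster_set", min_size = min_size))
  }
  d <- stats::as.dist(1 - cor(t(m)))
  h <- hclust(d, method = "average")
  members <- hclust_members(h$merge)
  node_h <- h$height
  h_root <- max(node_h)
  h_range <- diff(range(node_h))
  gap_frac <- if (deep_split) 0 else 0.25
  size_of <- function(x) if (x < 0L) 1L else length(members[[x]])
  members_of <- function(x) if (x < 0L) -x else members[[x]]
  child_h <- function(x) if (x < 0L) 0 else node_h[x]

  clusters <- list()
  emit_branch <- function(node) {
    if (node < 0L || size_of(node) < min_size) return(invisible())
    cur <- node
    shed_idx <- list()
    shed_h <- numeric(0)
    repeat {
      l <- h$merge[cur, 1L]
      r <- h$merge[cur, 2L]
      big <- if (size_of(l) >= size_of(r)) l else r
      small <- if (identical(big, l)) r else l
      if (size_of(big) < min_size) break  # no further core below
      if (size_of(small) >= min_size) {
        # a genuine split below the offshoot chain: recurse, drop the chain
        gap_ok <- h_range == 0 ||
          (node_h[cur] - max(child_h(l), child_h(r))) >= gap_frac * h_range
        if (gap_ok) {
          if (l > 0L) walk(l) else emit_branch(l)
          if (r > 0L) walk(r) else emit_branch(r)
          return(invisible())
        }
        break  # indistinct split: keep the whole branch as one core
      }
      shed_idx[[length(shed_idx) + 1L]] <- members_of(small)
      shed_h <- c(shed_h, node_h[cur])
      cur <- big
      if (cur < 0L) break
    }
    core <- members_of(cur)
    t_attach <- child_h(cur) + attach_frac * (h_root - child_h(cur))
    keep <- shed_h <= t_attach
    clusters[[length(clusters) + 1L]] <<-
      sort(c(core, unlist(shed_idx[keep])))
    invisible()
  }
  walk <- function(node) {
    if (node < 0L) return(invisible())
    l <- h$merge[node, 1L]
    r <- h$merge[node, 2L]
    gap_ok <- h_range == 0 ||
      (node_h[node] - max(child_h(l), child_h(r))) >= gap_frac * h_range
    if (min(size_of(l), size_of(r)) >= min_size && gap_ok) {
      if (l > 0L) walk(l) else emit_branch(l)
      if (r > 0L) walk(r) else emit_branch(r)
    } else {
      emit_branch(node)
    }
  }
  walk(nrow(h$merge))

  if (length(clusters)) {
    first_gene <- vapply(clusters, function(i) min(rownames(m)[i]),
                         character(1L))
    ord <- order(-lengths(clusters), first_gene)
    for (k in seq_along(ord)) {
      assign[rownames(m)[clusters[[ord[k]]]]] <- k
    }
  }
  structure(assign, class = "cluster_set", min_size = min_size)
}

#' Activation score of a gene set in a condition subset
#'
#' The arithmetic mean of the Z-scores of the set's genes over the given
#' conditions.  Genes without expression rows are excluded and counted.
#'
#' @param genes Character vector of gene identifiers.
#' @param z Z-score matrix from [zscore_standardize()].
#' @param conditions Character vector of condition identifiers.
#' @return List with `score`, `n_genes` (genes with expression data),
#'   `n_conditions` and `n_missing` (genes without expression data).
#' @export
activation_score <- function(genes, z, conditions) {
  genes <- unique(genes)
  conditions <- unique(conditions)
  found <- intersect(genes, rownames(z))
  conds <- intersect(conditions, colnames(z))
  if (length(found) == 0L) {
    stop("no gene in the set has expression data")
  }
  if (length(conds) == 0L) {
    stop("no requested condition is present in the Z-score matrix")
  }
  list(score = mean(z[found, conds, drop = FALSE]),
       n_genes = length(found),
       n_conditions = length(conds),
       n_missing = length(genes) - length(found))
}

#' Select clusters activated in the disease conditions
#'
#' Scores every non-zero cluster with [activation_score()] over the given
#' conditions and returns the union of genes in clusters whose absolute
#' score strictly exceeds `cutoff`.  Unassigned genes (cluster 0) are
#' never selected.
#'
#' @param clusters A `cluster_set` from [coexpression_clusters()].
#' @param z Z-score matrix.
#' @param conditions Disease condition identifiers.
#' @param cutoff Activation-score magnitude cutoff (strict).
#' @return List with `genes` (selected union), `up_genes`, `down_genes`
#'   (split by score sign) and `scores` (per-cluster data frame).
#' @export
select_active_clusters <- function(clusters, z, conditions, cutoff = 2) {
  ids <- sort(unique(clusters[clusters > 0L]))
  scores <- do.call(rbind, lapply(ids, function(k) {
    gk <- names(clusters)[clusters == k]
    a <- tryCatch(activation_score(gk, z, conditions),
                  error = function(e) list(score = NA_real_,
                                           n_genes = 0L,
                                           n_conditions = NA_integer_,
                                           n_missing = length(gk)))
    data.frame(cluster = k, score = a$score, n_genes = a$n_genes,
               n_missing = a$n_missing, size = length(gk))
  }))
  if (is.null(scores)) {
    scores <- data.frame(cluster = integer(), score = numeric(),
                         n_genes = integer(), n_missing = integer(),
                         size = integer())
  }
  scores$selected <- !is.na(scores$score) & abs(scores$score) > cutoff
  sel <- scores$cluster[scores$selected]
  up <- scores$cluster[scores$selected & scores$score > 0]
  genes_in <- function(ks) sort(names(clusters)[clusters %in% ks])
  list(genes = genes_in(sel),
       up_genes = genes_in(up),
       down_genes = genes_in(setdiff(sel, up)),
       scores = scores)
}

#' Combine differential-expression and co-expression gene lists
#'
#' The disease-relevant gene set is the union of the aggregated DEG lists
#' (up and down) and the activated co-expression cluster genes.
#'
#' @param deg A `deg_set` from [aggregate_deg()].
#' @param coexpr_genes Character vector of co-expressed disease genes.
#' @return List with `genes` (sorted union) and `report` (component and
#'   overlap sizes).
#' @export
combine_gene_sets <- function(deg, coexpr_genes) {
  deg_genes <- union(deg$up, deg$down)
  coexpr_genes <- unique(coexpr_genes)
  genes <- sort(union(deg_genes, coexpr_genes))
  list(genes = genes,
       report = list(n_deg = length(deg_genes),
                     n_coexpr = length(coexpr_genes),
                     n_overlap = length(intersect(deg_genes, coexpr_genes)),
                     n_union = length(genes)))
}
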