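#' Rank-product differential expression for one condition
#'
#' Two-class rank product over all treated-by-control replicate pairings.
#' For each of the `K = n_treated * n_control` pairwise log-ratios, genes
#' are ranked by descending log-ratio for the up direction (average ranks
#' on ties) and ascending for the down direction; the rank product of a
#' gene is the geometric mean of its ranks.  Significance is estimated by
#' permutation: in each of `n_perm` null replicates the ranks of every
#' comparison are drawn independently and uniformly (a random permutation
#' of 1..n per comparison), giving the expected number `E(g)` of null rank
#' products at or below the observed one; the proportion of false
#' positives is `pfp = E(g) / rank(RP_g)`, made monotone non-decreasing
#' along the RP-sorted gene list by the usual step-up adjustment.
#'
#' Because the pairwise comparisons share replicate arrays, their ranks
#' are positively correlated, which the rank-permutation null ignores —
#' it is mildly anti-conservative at the extreme tail.
#' `null_method = "array"` instead permutes the gene labels of every
#' array independently in each null replicate and recomputes the rank
#' products, preserving the shared-replicate correlation and giving a
#' calibrated pfp at a higher computational cost.
#'
#' @param treated Genes x replicates matrix of treated log2 intensities.
#' @param control Genes x replicates matrix of control log2 intensities
#'   (same genes).
#' @param n_perm Number of null permutation replicates (>= 1).
#' @param seed Integer seed for the permutation null.
#' @param null_method `"rank"` (independent uniform ranks per comparison,
#'   the cited method's convention and the default) or `"array"`
#'   (gene-label permutation per array).
#' @return Object of class `rank_product_result`: a list with `table` (data
#'   frame `gene`, `rp_up`, `pfp_up`, `rp_down`, `pfp_down`),
#'   `n_comparisons`, `n_perm`, `seed` and `null_method`.
#' @export
rank_product_test <- function(treated, control, n_perm = 100L, seed = 1L,
                              null_method = c("rank", "array")) {
  null_method <- match.arg(null_method)
  stopifnot(is.matrix(treated), is.matrix(control),
            nrow(treated) == nrow(control),
            ncol(treated) >= 1L, ncol(control) >= 1L)
  if (!identical(rownames(treated), rownames(control))) {
    stop("treated and control must share the same gene universe")
  }
  if (n_perm < 1L) stop("n_perm must be at least 1")
  n <- nrow(treated)
  genes <- rownames(treated)
  if (is.null(genes)) genes <- as.character(seq_len(n))

  idx <- expand.grid(t = seq_len(ncol(treated)), c = seq_len(ncol(control)))
  K <- nrow(idx)
  lr <- treated[, idx$t, drop = FALSE] - control[, idx$c, drop = FALSE]
  rank_up <- apply(-lr, 2L, rank, ties.method = "average")
  rank_dn <- apply(lr, 2L, rank, ties.method = "average")
  rank_up <- matrix(rank_up, nrow = n)
  rank_dn <- matrix(rank_dn, nrow = n)
  rp_up <- exp(rowMeans(log(rank_up)))
  rp_dn <- exp(rowMeans(log(rank_dn)))

  set.seed(seed)
  null_rp_up <- numeric(n * n_perm)
  null_rp_dn <- NULL
  if (null_method == "rank") {
    for (p in seq_len(n_perm)) {
      lranks <- matrix(0, n, K)
      for (k in seq_len(K)) lranks[, k] <- log(sample.int(n))
      null_rp_up[(p - 1L) * n + seq_len(n)] <- exp(rowMeans(lranks))
    }
    null_rp_dn <- null_rp_up  # symmetric by construction
  } else {
    null_rp_dn <- numeric(n * n_perm)
    for (p in seq_len(n_perm)) {
      tp <- apply(treated, 2L, sample)
      cp <- apply(control, 2L, sample)
      lp <- tp[, idx$t, drop = FALSE] - cp[, idx$c, drop = FALSE]
      ru <- matrix(apply(-lp, 2L, rank, ties.method = "average"), nrow = n)
      rd <- matrix(apply(lp, 2L, rank, ties.method = "average"), nrow = n)
      null_rp_up[(p - 1L) * n + seq_len(n)] <- exp(rowMeans(log(ru)))
      null_rp_dn[(p - 1L) * n + seq_len(n)] <- exp(rowMeans(log(rd)))
    }
  }

  pfp_of <- function(rp, null_sorted) {
    e <- findInterval(rp, null_sorted) / n_perm
    pos <- rank(rp, ties.method = "max")
    raw <- e / pos
    ord <- order(rp)
    adj <- raw
    adj[ord] <- rev(cummin(rev(raw[ord])))
    adj
  }

  ns_up <- sort(null_rp_up)
  ns_dn <- sort(null_rp_dn)
  structure(list(table = data.frame(gene = genes,
                                    rp_up = rp_up,
                                    pfp_up = pfp_of(rp_up, ns_up),
                                    rp_down = rp_dn,
                                    pfp_down = pfp_of(rp_dn, ns_dn),
                                    stringsAsFactors = FALSE),
                 n_comparisons = K, n_perm = n_perm, seed = seed,
                 null_method = null_method),
            class = "rank_product_result")
}

#' Aggregate per-condition rank-product results into a DEG set
#'
#' A gene enters the up (down) list when its up (down) pfp is below
#' `fdr_cutoff` in at least `min_conditions` of the supplied per-condition
#' results.  A gene may appear in both lists if it passes in opposite
#' directions in different conditions; the provenance table records every
#' gene/condition/direction hit.
#'
#' @param results Named list of [rank_product_test()] results (one per
#'   condition).
#' @param fdr_cutoff Per-condition pfp cutoff.
#' @param min_conditions Minimum number of conditions a gene must pass in.
#' @return Object of class `deg_set`: list with `up`, `down` (sorted gene
#'   id vectors) and `provenance` (data frame `gene`, `condition`,
#'   `direction`).
#' @export
aggregate_deg <- function(results, fdr_cutoff = 0.05, min_conditions = 2L) {
  stopifnot(is.list(results), length(results) >= 1L)
  if (min_conditions > length(results)) {
    stop("min_conditions (", min_conditions,
         ") exceeds the number of supplied results (", length(results), ")")
  }
  if (is.null(names(results))) {
    names(results) <- sprintf("condition_%d", seq_along(results))
  }
  hit_rows <- function(genes, cc, dir) {
    data.frame(gene = genes, condition = rep(cc, length(genes)),
               direction = rep(dir, length(genes)),
               stringsAsFactors = FALSE)
  }
  prov <- do.call(rbind, lapply(names(results), function(cc) {
    tab <- results[[cc]]$table
    rbind(hit_rows(tab$gene[tab$pfp_up < fdr_cutoff], cc, "up"),
          hit_rows(tab$gene[tab$pfp_down < fdr_cutoff], cc, "down"))
  }))
  pick <- function(dir) {
    sub <- prov[prov$direction == dir, , drop = FALSE]
    counts <- table(sub$gene)
    sort(names(counts)[counts >= min_conditions])
  }
  structure(list(up = pick("up"), down = pick("down"), provenance = prov,
                 fdr_cutoff = fdr_cutoff, min_conditions = min_conditions),
            class = "deg_set")
}
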