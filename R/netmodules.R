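#' All maximal cliques of at least a given size
#'
#' Maximal cliques (Bron-Kerbosch with pivoting, via igraph) returned in a
#' deterministic order: members sorted within each clique, cliques sorted
#' by decreasing size then lexicographically.
#'
#' @param graph Simple undirected igraph network with vertex names.
#' @param min_size Minimum clique size.
#' @return List of sorted character vectors.
#' @export
maximal_cliques <- function(graph, min_size = 3L) {
  cl <- igraph::max_cliques(graph, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(graph)$name[v]))
  key <- vapply(cl, paste, character(1L), collapse = "\r")
  cl[order(-lengths(cl), key)]
}

#' Overlapping module detection by maximal-clique agglomeration
#'
#' Initial communities are the maximal cliques of size at least
#' `min_clique`, after discarding subordinate cliques (cliques all of whose
#' members also occur in some larger retained clique), plus singleton
#' communities for uncovered nodes.  The pair of communities with maximal
#' similarity
#' \deqn{S(C_1, C_2) = \frac{1}{2m} \sum_{v \in C_1, w \in C_2}
#'   \left(A_{vw} - \frac{k_v k_w}{2m}\right)}
#' is merged repeatedly until one community remains, and the dendrogram
#' level maximizing the extended modularity
#' \deqn{EQ = \frac{1}{2m} \sum_{C} \sum_{v,w \in C}
#'   \frac{1}{O_v O_w}\left(A_{vw} - \frac{k_v k_w}{2m}\right)}
#' is returned, where \eqn{O_v} counts the communities containing node
#' \eqn{v} (modules may overlap).  Ties break lexicographically, so the
#' result is deterministic.
#'
#' @param graph Simple undirected igraph network with vertex names (may
#'   have several components).
#' @param min_clique Minimum size of seed cliques.
#' @return Object of class `module_set`: list with `modules` (named list,
#'   largest first, names `M1`, `M2`, ...), `eq` (extended modularity of
#'   the returned level), `eq_trace` (EQ at every dendrogram level),
#'   `membership_count` (named \eqn{O_v}) and `level` (index of the
#'   returned level).
#' @export
eagle_modules <- function(graph, min_clique = 3L) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("cannot cluster an empty graph")
  vn <- sort(igraph::V(graph)$name)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  A <- A[vn, vn]
  deg <- rowSums(A)
  m <- sum(A) / 2
  if (m == 0) {
    mods <- setNames(as.list(vn), sprintf("M%d", seq_len(n)))
    return(structure(list(modules = mods, eq = 0, eq_trace = 0,
                          membership_count = setNames(rep(1L, n), vn),
                          level = 1L),
                     class = "module_set"))
  }
  B <- A - outer(deg, deg) / (2 * m)

  cliques <- maximal_cliques(graph, min_size = min_clique)
  retained <- list()
  retained_sizes <- integer(0)
  covered_larger <- character(0)
  sizes <- lengths(cliques)
  for (s in sort(unique(sizes), decreasing = TRUE)) {
    covered_larger <- unique(unlist(retained[retained_sizes > s]))
    for (cl in cliques[sizes == s]) {
      if (!all(cl %in% covered_larger)) {
        retained[[length(retained) + 1L]] <- cl
        retained_sizes <- c(retained_sizes, s)
      }
    }
  }
  uncovered <- setdiff(vn, unique(unlist(retained)))
  comm <- c(retained, as.list(uncovered))
  comm <- lapply(comm, function(x) match(sort(x), vn))
  key <- vapply(comm, function(i) paste(vn[i], collapse = "\r"), character(1L))
  comm <- comm[order(-lengths(comm), key)]
  C <- length(comm)

  X <- matrix(0, n, C)
  for (j in seq_len(C)) X[comm[[j]], j] <- 1
  BX <- B %*% X
  S <- crossprod(X, BX) / (2 * m)
  alive <- rep(TRUE, C)

  eq_of <- function() {
    O <- rowSums(X[, alive, drop = FALSE] > 0)
    w <- 1 / O
    tot <- 0
    for (j in which(alive)) {
      idx <- comm[[j]]
      wi <- w[idx]
      tot <- tot + as.numeric(wi %*% B[idx, idx, drop = FALSE] %*% wi)
    }
    tot / (2 * m)
  }

  eq_trace <- eq_of()
  snapshots <- list(comm[alive])
  while (sum(alive) > 1L) {
    Sm <- S
    Sm[!alive, ] <- -Inf
    Sm[, !alive] <- -Inf
    Sm[lower.tri(Sm, diag = TRUE)] <- -Inf
    best <- arrayInd(which.max(Sm), dim(Sm))
    i <- best[1L]
    j <- best[2L]
    comm[[i]] <- sort(unique(c(comm[[i]], comm[[j]])))
    alive[j] <- FALSE
    X[, i] <- 0
    X[comm[[i]], i] <- 1
    v <- as.vector(B %*% X[, i]) / (2 * m)
    S[i, ] <- S[, i] <- as.vector(crossprod(X, v))
    eq_trace <- c(eq_trace, eq_of())
    snapshots[[length(snapshots) + 1L]] <- comm[alive]
  }

  level <- which.max(eq_trace)
  best_comm <- snapshots[[level]]
  mods <- lapply(best_comm, function(i) vn[i])
  key <- vapply(mods, paste, character(1L), collapse = "\r")
  mods <- mods[order(-lengths(mods), key)]
  names(mods) <- sprintf("M%d", seq_along(mods))
  ov <- table(unlist(mods))
  membership <- setNames(as.integer(ov), names(ov))

  structure(list(modules = mods, eq = eq_trace[level], eq_trace = eq_trace,
                 membership_count = membership, level = level),
            class = "module_set")
}

#' One-sided hypergeometric enrichment of a reference set in a module
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' module of `n` nodes and a reference set of `K` nodes drawn from a
#' background of `background_n` nodes (the Fisher exact test's one-sided
#' enrichment p-value).
#'
#' @param module Character vector of module node identifiers.
#' @param reference Character vector of reference node identifiers.
#' @param background_n Background population size.
#' @return One-row data frame with `n`, `x` (overlap), `K`, `N` and `p`.
#' @export
hypergeom_enrichment <- function(module, reference, background_n) {
  module <- unique(module)
  reference <- unique(reference)
  n <- length(module)
  K <- length(reference)
  if (n > background_n || K > background_n) {
    stop("module or reference set larger than the background population")
  }
  x <- length(intersect(module, reference))
  if (x > min(n, K)) stop("inconsistent overlap count")
  data.frame(n = n, x = x, K = K, N = background_n,
             p = phyper(x - 1L, K, background_n - K, n, lower.tail = FALSE))
}

#' Over-representation analysis of a gene list against a set collection
#'
#' [hypergeom_enrichment()] of the list against every set in the
#' collection, with Benjamini-Hochberg correction across the collection.
#'
#' @param genes Character vector (the query list).
#' @param collection Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background_n Background population size.
#' @param alpha BH-FDR significance level.
#' @return Data frame with one row per set: `set`, `n`, `x`, `K`, `N`,
#'   `p`, `bh_fdr`, `significant`.
#' @export
ora_collection <- function(genes, collection, background_n, alpha = 0.05) {
  stopifnot(length(collection) >= 1L, !is.null(names(collection)))
  rows <- do.call(rbind, lapply(names(collection), function(nm) {
    cbind(data.frame(set = nm, stringsAsFactors = FALSE),
          hypergeom_enrichment(genes, collection[[nm]], background_n))
  }))
  rows$bh_fdr <- p.adjust(rows$p, method = "BH")
  rows$significant <- rows$bh_fdr < alpha
  rows
}

#' Enrichment of curated reference sets across network modules
#'
#' For every reference set, computes the one-sided hypergeometric
#' enrichment p-value in every module and applies Benjamini-Hochberg
#' correction across modules within the set.
#'
#' @param modules A `module_set` from [eagle_modules()] or a named list of
#'   node-id vectors.
#' @param reference_sets Named list of reference node-id sets.
#' @param background_n Background population size (typically the full
#'   network's node count).
#' @param alpha BH-FDR significance level.
#' @return Data frame with columns `module`, `set`, `n`, `x`, `K`, `N`,
#'   `p`, `bh_fdr`, `significant`.
#' @export
module_enrichment <- function(modules, reference_sets, background_n,
                              alpha = 0.05) {
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  out <- do.call(rbind, lapply(names(reference_sets), function(sn) {
    rows <- do.call(rbind, lapply(names(mods), function(mn) {
      cbind(data.frame(module = mn, set = sn, stringsAsFactors = FALSE),
            hypergeom_enrichment(mods[[mn]], reference_sets[[sn]],
                                 background_n))
    }))
    rows$bh_fdr <- p.adjust(rows$p, method = "BH")
    rows
  }))
  out$significant <- out$bh_fdr < alpha
  rownames(out) <- NULL
  out
}

#' Back-translate network node identifiers to expression gene identifiers
#'
#' Inverse lookup through the unambiguous entries of the ortholog map.
#' Nodes mapped from several genes return all of them.
#'
#' @param nodes Character vector of network node identifiers.
#' @param orthologs Ortholog-map data frame (`source_id`, `target_id`,
#'   `ambiguous`).
#' @return Sorted character vector of gene identifiers.
#' @export
backmap_genes <- function(nodes, orthologs) {
  ambig_src <- unique(c(orthologs$source_id[orthologs$ambiguous],
                        orthologs$source_id[duplicated(orthologs$source_id)]))
  clean <- orthologs[!orthologs$source_id %in% ambig_src, , drop = FALSE]
  sort(unique(clean$source_id[clean$target_id %in% nodes]))
}

#' Activation scores of network modules
#'
#' Back-translates every module's nodes to expression gene identifiers
#' through the unambiguous entries of the ortholog map, excludes nodes
#' without expression data (counted), and applies the activation score
#' over the given conditions.  Modules with no expression-mapped node get
#' an `NA` score.
#'
#' @param modules A `module_set` or named list of node-id vectors.
#' @param z Z-score matrix from [zscore_standardize()].
#' @param conditions Disease condition identifiers.
#' @param orthologs Ortholog-map data frame (`source_id`, `target_id`,
#'   `ambiguous`).
#' @return Data frame with `module`, `size`, `score`, `n_genes` and
#'   `n_unmapped_nodes`.
#' @export
module_activation <- function(modules, z, conditions, orthologs) {
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  ambig_src <- unique(c(orthologs$source_id[orthologs$ambiguous],
                        orthologs$source_id[duplicated(orthologs$source_id)]))
  clean <- orthologs[!orthologs$source_id %in% ambig_src, , drop = FALSE]
  out <- do.call(rbind, lapply(names(mods), function(mn) {
    nodes <- mods[[mn]]
    genes <- intersect(backmap_genes(nodes, orthologs), rownames(z))
    mapped_nodes <- clean$target_id[clean$source_id %in% genes]
    if (length(genes) == 0L) {
      return(data.frame(module = mn, size = length(nodes),
                        score = NA_real_, n_genes = 0L,
                        n_unmapped_nodes = length(nodes),
                        stringsAsFactors = FALSE))
    }
    a <- activation_score(genes, z, conditions)
    data.frame(module = mn, size = length(nodes), score = a$score,
               n_genes = a$n_genes,
               n_unmapped_nodes = length(setdiff(nodes, mapped_nodes)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rank modules by enrichment support and activation
#'
#' Modules are ordered by the number of curated reference sets in which
#' they are significantly enriched, then by activation score, both
#' descending; ties break by module size (descending) then module id.
#'
#' @param activations Data frame from [module_activation()].
#' @param enrichments Data frame from [module_enrichment()].
#' @return `activations` with columns `n_enriched_sets` and `rank`, sorted
#'   by rank.
#' @export
prioritize_modules <- function(activations, enrichments) {
  sig <- enrichments[enrichments$significant, , drop = FALSE]
  n_sig <- tapply(sig$set, sig$module, function(x) length(unique(x)))
  out <- activations
  out$n_enriched_sets <- as.integer(n_sig[out$module])
  out$n_enriched_sets[is.na(out$n_enriched_sets)] <- 0L
  score <- ifelse(is.na(out$score), -Inf, out$score)
  ord <- order(-out$n_enriched_sets, -score, -out$size, out$module)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
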