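#' Map expression gene identifiers onto network nodes
#'
#' Translates genes through unambiguous ortholog-map entries and intersects
#' the targets with the network's node set.  Ambiguously mapped genes (flag
#' set, or several map rows for one source) are excluded and counted, as
#' are unmapped genes and genes whose target is absent from the network.
#'
#' @param genes Character vector of gene identifiers.
#' @param orthologs Data frame with columns `source_id`, `target_id` and
#'   logical `ambiguous`.
#' @param network igraph network with vertex names.
#' @return List with `nodes` (sorted node ids) and `report` (counts:
#'   `n_input`, `n_unmapped`, `n_ambiguous`, `n_not_in_network`,
#'   `n_mapped`).
#' @export
map_to_network <- function(genes, orthologs, network) {
  genes <- unique(genes)
  ambig_src <- unique(c(orthologs$source_id[orthologs$ambiguous],
                        orthologs$source_id[duplicated(orthologs$source_id)]))
  clean <- orthologs[!orthologs$source_id %in% ambig_src, , drop = FALSE]
  lut <- setNames(clean$target_id, clean$source_id)
  unmapped <- sum(!genes %in% orthologs$source_id)
  ambiguous <- sum(genes %in% ambig_src)
  targets <- unname(lut[genes[genes %in% names(lut)]])
  vn <- igraph::V(network)$name
  nodes <- sort(unique(targets[targets %in% vn]))
  not_in_net <- sum(!unique(targets) %in% vn)
  if (length(nodes) == 0L) {
    warning("no gene mapped onto the network")
  }
  list(nodes = nodes,
       report = list(n_input = length(genes), n_unmapped = unmapped,
                     n_ambiguous = ambiguous,
                     n_not_in_network = not_in_net,
                     n_mapped = length(nodes)))
}

subnetwork_obj <- function(parent, nodes, query, k_exceptions) {
  nodes <- sort(nodes)
  structure(list(nodes = nodes,
                 active = sort(intersect(nodes, query)),
                 exceptions = sort(setdiff(nodes, query)),
                 graph = igraph::induced_subgraph(parent, nodes),
                 parent = parent,
                 k_exceptions = k_exceptions),
            class = "subnetwork")
}

#' Extract a maximally connected subnetwork with node exceptions
#'
#' Finds a connected induced subgraph containing as many query (active)
#' nodes as possible while admitting at most `k_exceptions` non-query
#' nodes.  Deterministic greedy heuristic: (1) take the connected
#' components of the query-induced subgraph; (2) growing from a seed
#' component, repeatedly apply the most exception-efficient affordable
#' join — either a minimum-exception-cost path to a remaining component
#' (path cost = number of non-query nodes it adds) or a hub move adding a
#' single non-query node adjacent to the current subnetwork and to one or
#' more remaining components — until nothing affordable remains; the
#' growth is restarted from several seed components and the best result
#' kept; (3) a local improvement pass first adds non-query nodes adjacent
#' to at least two active nodes while budget remains, then removes
#' exception nodes whose removal keeps the subgraph connected.  With
#' `refine = TRUE` a seeded stochastic local search perturbs the exception
#' set afterwards and keeps the best solution found.
#'
#' @param graph igraph network with vertex names.
#' @param query Character vector of query (active) node identifiers.
#' @param k_exceptions Maximum number of non-query nodes admitted.
#' @param seed Integer seed (used only by the stochastic refinement).
#' @param refine Logical; run the stochastic refinement pass.
#' @param refine_iter Number of refinement proposals.
#' @return Object of class `subnetwork`: list with `nodes`, `active`,
#'   `exceptions`, the induced `graph`, the `parent` network and the
#'   budget `k_exceptions`.  The induced subgraph is always connected and
#'   `length(exceptions) <= k_exceptions`.
#' @export
extract_subnetwork <- function(graph, query, k_exceptions = 100L,
                               seed = 1L, refine = FALSE,
                               refine_iter = 200L) {
  vn <- igraph::V(graph)$name
  query <- sort(intersect(unique(query), vn))
  if (length(query) == 0L) stop("no query node is present in the network")

  is_q <- setNames(vn %in% query, vn)
  en <- igraph::as_edgelist(graph, names = TRUE)
  # half the endpoint penalty per edge counts each non-query interior node
  # once along a path; the epsilon prefers shorter paths among equals
  ew <- 0.5 * ((!is_q[en[, 1L]]) + (!is_q[en[, 2L]])) + 1e-9

  qsub <- igraph::induced_subgraph(graph, query)
  cmp <- igraph::components(qsub)
  comps <- split(igraph::V(qsub)$name, cmp$membership)
  comps <- lapply(comps, sort)
  comps <- comps[order(-lengths(comps),
                       vapply(comps, `[[`, character(1L), 1L))]

  vnames <- igraph::V(graph)$name
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  adj <- setNames(lapply(adj, function(v) vnames[v]), vnames)
  comp_id <- setNames(rep(seq_along(comps), lengths(comps)),
                      unlist(comps))
  comp_sizes <- lengths(comps)

  grow_from <- function(seed_idx) {
    in_S <- setNames(logical(length(vnames)), vnames)
    S <- comps[[seed_idx]]
    in_S[S] <- TRUE
    left_ids <- setdiff(seq_along(comps), seed_idx)
    budget <- k_exceptions
    repeat {
      if (length(left_ids) == 0L || budget == 0L) break
      # candidate moves: pick max gain per exception spent
      best <- NULL
      consider <- function(cost, gain, key, type, payload) {
        if (cost > budget || gain == 0L) return(invisible())
        if (is.null(best) ||
            gain / cost > best$gain / best$cost + 1e-12 ||
            (abs(gain / cost - best$gain / best$cost) <= 1e-12 &&
             (gain > best$gain ||
              (gain == best$gain && key < best$key)))) {
          best <<- list(cost = cost, gain = gain, key = key, type = type,
                        payload = payload)
        }
        invisible()
      }
      # hub moves: one non-query node touching S and remaining components
      hub_cand <- unique(unlist(adj[S], use.names = FALSE))
      hub_cand <- sort(hub_cand[!in_S[hub_cand] & !is_q[hub_cand]])
      for (v in hub_cand) {
        qnb <- adj[[v]]
        qnb <- qnb[is_q[qnb] & !in_S[qnb]]
        tids <- unique(unname(comp_id[qnb]))
        gain <- sum(comp_sizes[tids])
        if (gain > 0L) consider(1L, gain, v, "hub", tids)
      }
      # path moves: cheapest path from each remaining component to S
      src <- unlist(comps[left_ids])
      d <- igraph::distances(graph, v = src, to = S, weights = ew)
      dmin <- apply(d, 1L, min)
      for (ci in left_ids) {
        dc <- min(dmin[comps[[ci]]])
        if (!is.finite(dc)) next
        consider(max(1L, as.integer(round(dc))), comp_sizes[ci],
                 comps[[ci]][1L], "path", ci)
      }
      if (is.null(best)) break
      if (best$type == "hub") {
        add <- c(best$key, unlist(comps[best$payload]))
        budget <- budget - 1L
        left_ids <- setdiff(left_ids, best$payload)
      } else {
        ci <- best$payload
        dsub <- d[comps[[ci]], , drop = FALSE]
        at <- arrayInd(which.min(dsub), dim(dsub))
        sp <- igraph::shortest_paths(graph, from = comps[[ci]][at[1L]],
                                     to = S[at[2L]],
                                     weights = ew)$vpath[[1L]]
        sp <- vnames[sp]
        new_exc <- sp[!is_q[sp] & !in_S[sp]]
        if (length(new_exc) > budget) break
        add <- c(comps[[ci]], sp)
        budget <- budget - length(new_exc)
        on_path <- sp[is_q[sp]]
        left_ids <- setdiff(left_ids, c(ci, unique(comp_id[on_path])))
      }
      S <- union(S, add)
      in_S[add] <- TRUE
    }
    list(S = S, budget = budget)
  }

  n_starts <- if (length(comps) <= 8L) length(comps) else 3L
  results <- lapply(seq_len(n_starts), grow_from)
  score <- vapply(results, function(r) sum(is_q[r$S]), numeric(1L))
  keyv <- vapply(results, function(r) paste(sort(r$S), collapse = "\r"),
                 character(1L))
  pick <- order(-score, lengths(lapply(results, `[[`, "S")), keyv)[1L]
  S <- results[[pick]]$S
  budget <- results[[pick]]$budget

  # improvement: non-query nodes touching >= 2 active nodes
  if (budget > 0L) {
    active <- intersect(S, query)
    nb <- unlist(lapply(
      igraph::adjacent_vertices(graph, active),
      function(v) vnames[v]), use.names = FALSE)
    nb <- nb[!nb %in% S & !is_q[nb]]
    if (length(nb)) {
      counts <- sort(table(nb), decreasing = TRUE)
      cand <- names(counts)[counts >= 2L]
      cand <- cand[order(-counts[cand], cand)]
      S <- union(S, head(cand, budget))
    }
  }

  # pruning: drop exceptions whose removal keeps the subgraph connected
  repeat {
    removed <- FALSE
    for (v in sort(setdiff(S, query))) {
      rest <- setdiff(S, v)
      if (igraph::is_connected(igraph::induced_subgraph(graph, rest))) {
        S <- rest
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  best_component <- function(nodes) {
    gi <- igraph::induced_subgraph(graph, nodes)
    cc <- igraph::components(gi)
    parts <- split(igraph::V(gi)$name, cc$membership)
    parts <- lapply(parts, sort)
    score <- vapply(parts, function(p) sum(is_q[p]), numeric(1L))
    ord <- order(-score, -lengths(parts),
                 vapply(parts, `[[`, character(1L), 1L))
    parts[[ord[1L]]]
  }
  S <- best_component(S)

  if (isTRUE(refine)) {
    set.seed(seed)
    score_of <- function(nodes) sum(is_q[best_component(nodes)])
    best_S <- S
    best_score <- score_of(S)
    cur <- S
    for (it in seq_len(refine_iter)) {
      exc <- setdiff(cur, query)
      nb <- unlist(lapply(
        igraph::adjacent_vertices(graph, cur),
        function(v) igraph::V(graph)$name[v]), use.names = FALSE)
      add_pool <- setdiff(unique(nb), cur)
      if (length(exc) && (length(add_pool) == 0L || runif(1) < 0.5)) {
        prop <- setdiff(cur, sample(exc, 1L))
      } else if (length(add_pool)) {
        v <- sample(add_pool, 1L)
        if (!is_q[v] && length(exc) >= k_exceptions) next
        prop <- union(cur, v)
      } else next
      prop <- best_component(prop)
      if (length(setdiff(prop, query)) > k_exceptions) next
      s <- sum(is_q[prop])
      if (s >= sum(is_q[best_component(cur)])) cur <- prop
      if (s > best_score) {
        best_score <- s
        best_S <- prop
      }
    }
    S <- best_S
  }

  out <- subnetwork_obj(graph, S, query, k_exceptions)
  stopifnot(length(out$exceptions) <= k_exceptions,
            igraph::is_connected(out$graph))
  out
}

same_graph <- function(a, b) {
  igraph::vcount(a) == igraph::vcount(b) &&
    igraph::ecount(a) == igraph::ecount(b) &&
    identical(igraph::V(a)$name, igraph::V(b)$name)
}

#' Merge subnetworks extracted from the same parent network
#'
#' Node union with edges induced from the parent; a node active in any
#' input is active in the union.  The union is not required to be
#' connected.
#'
#' @param subnets List of `subnetwork` objects sharing one parent network.
#' @return A `subnetwork`-like list (`nodes`, `active`, `exceptions`,
#'   induced `graph`, `parent`).
#' @export
union_subnetworks <- function(subnets) {
  stopifnot(length(subnets) >= 1L)
  parent <- subnets[[1L]]$parent
  for (s in subnets) {
    if (!same_graph(s$parent, parent)) {
      stop("subnetworks do not share the same parent network")
    }
  }
  nodes <- sort(unique(unlist(lapply(subnets, `[[`, "nodes"))))
  active <- sort(unique(unlist(lapply(subnets, `[[`, "active"))))
  structure(list(nodes = nodes, active = active,
                 exceptions = setdiff(nodes, active),
                 graph = igraph::induced_subgraph(parent, nodes),
                 parent = parent,
                 k_exceptions = NA_integer_),
            class = "subnetwork")
}
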