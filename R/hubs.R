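#' Hub centralities of an interaction network
#'
#' Computes up to 12 cytoHubba-style node centralities on a simple
#' undirected graph and returns, per metric, the scores and the ranking
#' (score descending, ties broken by node id ascending).  Conventions:
#'
#' * `degree`: neighbor count.
#' * `clustering`: local clustering coefficient `2 tri(v) / (deg (deg-1))`;
#'   0 for degree < 2.
#' * `closeness`: `(n_c - 1) / sum d(v, u)` within `v`'s component of size
#'   `n_c`; isolated nodes score 0.
#' * `eccentricity`: `1 / max_u d(v, u)` within the component.
#' * `radiality`: `sum_u (D + 1 - d(v, u)) / (n_c - 1)` with `D` the
#'   component diameter.
#' * `stress`: number of shortest paths (over unordered pairs) with `v`
#'   interior.
#' * `betweenness`: unnormalized shortest-path betweenness.
#' * `mnc`: size of the largest connected component of the subgraph induced
#'   on `v`'s neighbors.
#' * `dmnc`: edges of that component divided by its node count to the power
#'   1.7 (ties among equally large components broken toward more edges,
#'   then lexicographically smallest node set).
#' * `mcc`: sum over maximal cliques containing `v` of `(|C| - 1)!`
#'   (reduces to the degree when `v` lies only in 2-cliques).
#' * `bottleneck`: over shortest-path trees rooted at every node of the
#'   component (deterministic parents: smallest-id neighbor one BFS level
#'   up), the number of roots for which `v`'s subtree holds at least a
#'   quarter of the component.
#' * `epc`: Monte-Carlo edge-percolation closeness — mean, over `epc_trials`
#'   random subgraphs keeping each edge with probability `epc_p`, of the
#'   number of nodes still connected to `v`; seeded, hence reproducible.
#'
#' Distance-based metrics are computed within connected components;
#' cross-component pairs are excluded.
#'
#' @param graph a simple undirected [igraph] graph.
#' @param metrics character vector of metric names (default all 12).
#' @param epc_trials,epc_p,epc_seed edge-percolation parameters.
#' @return object of class `"hub_ranking"`: list with `scores` (node x
#'   metric data frame) and `rankings` (named list of node-id orderings).
#' @export
compute_centralities <- function(graph,
                                 metrics = c("degree", "clustering",
                                             "closeness", "eccentricity",
                                             "radiality", "stress",
                                             "betweenness", "mnc", "dmnc",
                                             "mcc", "bottleneck", "epc"),
                                 epc_trials = 1000, epc_p = 0.5,
                                 epc_seed = 1) {
  valid <- c("degree", "clustering", "closeness", "eccentricity", "radiality",
             "stress", "betweenness", "mnc", "dmnc", "mcc", "bottleneck", "epc")
  unknown <- setdiff(metrics, valid)
  if (length(unknown) > 0) {
    stop("unknown metric(s): ", paste(unknown, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "))
  }
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if (!igraph::is_simple(graph)) stop("graph must be simple (no loops/multi-edges)")
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
  }
  nodes <- sort(igraph::V(graph)$name)
  graph <- igraph::permute(graph, match(igraph::V(graph)$name, nodes))
  n <- length(nodes)
  D <- igraph::distances(graph)
  comp <- igraph::components(graph)$membership

  scores <- data.frame(node = nodes, stringsAsFactors = FALSE)
  for (m in metrics) {
    scores[[m]] <- switch(
      m,
      degree = as.numeric(igraph::degree(graph)),
      clustering = local_clustering(graph),
      closeness = dist_metric(D, comp, function(dv, nc)
        if (nc > 1) (nc - 1) / sum(dv) else 0),
      eccentricity = dist_metric(D, comp, function(dv, nc)
        if (nc > 1) 1 / max(dv) else 0),
      radiality = radiality_metric(D, comp),
      stress = stress_centrality(graph, D),
      betweenness = as.numeric(igraph::betweenness(graph, directed = FALSE)),
      mnc = neighborhood_component(graph)$mnc,
      dmnc = neighborhood_component(graph)$dmnc,
      mcc = mcc_centrality(graph),
      bottleneck = bottleneck_centrality(graph, D, comp),
      epc = epc_centrality(graph, trials = epc_trials, p = epc_p,
                           seed = epc_seed)
    )
  }
  rankings <- lapply(metrics, function(m)
    scores$node[order(-scores[[m]], scores$node)])
  names(rankings) <- metrics
  structure(list(scores = scores, rankings = rankings,
                 params = list(epc_trials = epc_trials, epc_p = epc_p,
                               epc_seed = epc_seed)),
            class = "hub_ranking")
}

#' @export
print.hub_ranking <- function(x, ...) {
  cat("Hub ranking over", nrow(x$scores), "nodes,",
      length(x$rankings), "metrics\n")
  top <- vapply(x$rankings, `[`, character(1), 1)
  cat("  top node per metric:\n")
  for (m in names(top)) cat(sprintf("    %-12s %s\n", m, top[m]))
  invisible(x)
}

#' Top-k consensus of hub rankings
#'
#' Intersection, over every computed metric, of the metric's top-k node
#' set.
#'
#' @param ranking a [compute_centralities()] result.
#' @param k cut-off per metric (>= 1; clamped to the node count with a
#'   warning).
#' @return sorted character vector of consensus nodes (possibly empty).
#' @export
top_k_intersection <- function(ranking, k) {
  stopifnot(inherits(ranking, "hub_ranking"))
  if (k < 1) stop("k must be >= 1")
  n <- nrow(ranking$scores)
  if (k > n) {
    warning("k > number of nodes; clamping to ", n)
    k <- n
  }
  sort(Reduce(intersect, lapply(ranking$rankings, utils::head, k)))
}

# metric internals -------------------------------------------------------

local_clustering <- function(graph) {
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  cc[igraph::degree(graph) < 2] <- 0
  as.numeric(cc)
}

# Apply f(finite distances to other nodes, component size) per node.
dist_metric <- function(D, comp, f) {
  vapply(seq_len(nrow(D)), function(v) {
    members <- which(comp == comp[v])
    dv <- D[v, setdiff(members, v)]
    f(dv, length(members))
  }, numeric(1))
}

radiality_metric <- function(D, comp) {
  vapply(seq_len(nrow(D)), function(v) {
    members <- which(comp == comp[v])
    if (length(members) < 2) return(0)
    diam <- max(D[members, members])
    dv <- D[v, setdiff(members, v)]
    sum(diam + 1 - dv) / (length(members) - 1)
  }, numeric(1))
}

# Numbers of shortest paths between all pairs, by BFS from each source.
shortest_path_counts <- function(graph, D) {
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph)
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig <- numeric(n)
    sig[s] <- 1
    ds <- D[s, ]
    for (d in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (w in which(ds == d)) {
        pred <- as.integer(adj[[w]])
        pred <- pred[ds[pred] == d - 1]
        sig[w] <- sum(sig[pred])
      }
    }
    nsp[s, ] <- sig
  }
  nsp
}

stress_centrality <- function(graph, D) {
  n <- igraph::vcount(graph)
  nsp <- shortest_path_counts(graph, D)
  vapply(seq_len(n), function(v) {
    through <- outer(D[, v], D[v, ], `+`) == D & is.finite(D)
    through[v, ] <- FALSE; through[, v] <- FALSE
    diag(through) <- FALSE
    paths <- outer(nsp[, v], nsp[v, ]) * through
    sum(paths[upper.tri(paths)])
  }, numeric(1))
}

# MNC / DMNC: largest connected component of the open neighborhood.
neighborhood_component <- function(graph) {
  n <- igraph::vcount(graph)
  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- as.integer(igraph::neighbors(graph, v))
    if (length(nb) == 0) next
    sub <- igraph::induced_subgraph(graph, nb)
    cmp <- igraph::components(sub)
    sizes <- cmp$csize
    big <- which(sizes == max(sizes))
    if (length(big) > 1) {   # tie: more edges, then smallest node set
      stats_ <- lapply(big, function(b) {
        mem <- which(cmp$membership == b)
        sg <- igraph::induced_subgraph(sub, mem)
        list(e = igraph::ecount(sg),
             key = paste(sort(igraph::V(sub)$name[mem]), collapse = ","))
      })
      ord <- order(-vapply(stats_, `[[`, numeric(1), "e"),
                   vapply(stats_, `[[`, character(1), "key"))
      big <- big[ord[1]]
    }
    mem <- which(cmp$membership == big)
    sg <- igraph::induced_subgraph(sub, mem)
    mnc[v] <- length(mem)
    dmnc[v] <- igraph::ecount(sg) / length(mem)^1.7
  }
  list(mnc = mnc, dmnc = dmnc)
}

mcc_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  out <- numeric(n)
  cliques <- igraph::max_cliques(graph, min = 2)
  for (cl in cliques) {
    idx <- as.integer(cl)
    out[idx] <- out[idx] + factorial(length(idx) - 1)
  }
  out
}

bottleneck_centrality <- function(graph, D, comp) {
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph)
  score <- numeric(n)
  for (r in seq_len(n)) {
    members <- which(comp == comp[r])
    if (length(members) < 2) next
    dr <- D[r, ]
    # deterministic shortest-path tree: parent = smallest-index neighbor
    # one level up (nodes are in sorted-name order)
    parent <- rep(NA_integer_, n)
    for (w in members) {
      if (w == r) next
      pred <- as.integer(adj[[w]])
      parent[w] <- min(pred[dr[pred] == dr[w] - 1])
    }
    size <- rep(1L, n)
    for (w in members[order(-dr[members])]) {
      if (w == r) next
      size[parent[w]] <- size[parent[w]] + size[w]
    }
    qualify <- members[members != r & size[members] >= length(members) / 4]
    score[qualify] <- score[qualify] + 1
  }
  score
}

epc_centrality <- function(graph, trials = 1000, p = 0.5, seed = 1) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  with_seed(seed, {
    acc <- numeric(n)
    for (t in seq_len(trials)) {
      keep <- stats::runif(m) < p
      sub <- igraph::subgraph_from_edges(graph, which(keep),
                                         delete.vertices = FALSE)
      cmp <- igraph::components(sub)
      acc <- acc + (cmp$csize[cmp$membership] - 1)
    }
    acc / trials
  })
}
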