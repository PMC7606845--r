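# Independent brute-force oracles.  Everything here is deliberately naive
# (explicit sums, loops, exhaustive enumeration) and shares no code with the
# implementation it checks.

oracle_pcc <- function(x, y) {
  xd <- x - mean(x); yd <- y - mean(y)
  sum(xd * yd) / (sqrt(sum(xd^2)) * sqrt(sum(yd^2)))
}

oracle_sd_in <- function(expr, refs, cases, module) {
  vals <- c()
  for (g in module) for (d in cases) {
    vals <- c(vals, abs(expr[g, d] - mean(expr[g, refs])))
  }
  mean(vals)
}

oracle_pcc_in <- function(expr, cases, module) {
  vals <- c()
  m <- length(module)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    vals <- c(vals, abs(oracle_pcc(expr[module[i], cases], expr[module[j], cases])))
  }
  mean(vals)
}

oracle_pcc_out <- function(expr, cases, module, background) {
  vals <- c()
  for (g in module) for (h in background) {
    vals <- c(vals, abs(oracle_pcc(expr[g, cases], expr[h, cases])))
  }
  mean(vals)
}

# BH step-up from its min-over-larger-p definition, ties included.
oracle_bh <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p[p >= pi], function(pj) pj * n / sum(p <= pj), numeric(1))
    min(1, cand)
  }, numeric(1))
}

oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { w[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    w[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(w) <- dimnames(a)
  w
}

# graph oracles ----------------------------------------------------------
# Graphs are passed as symmetric 0/1 adjacency matrices with dimnames in
# sorted node order.

graph_adjacency <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  ord <- order(rownames(A))
  A[ord, ord]
}

oracle_dists <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- min(D[i, j], D[i, k] + D[k, j])
  }
  dimnames(D) <- dimnames(A)
  D
}

# All shortest s->t paths as lists of vertex indices (exhaustive recursion).
oracle_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (w in which(A[, t] == 1 & D[s, ] == D[s, t] - 1)) {
    for (pp in oracle_paths(A, D, s, w)) out <- c(out, list(c(pp, t)))
  }
  out
}

oracle_stress_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_dists(A)
  stress <- numeric(n); btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_paths(A, D, s, t)
    if (length(paths) == 0) next
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      stress[v] <- stress[v] + through
      btw[v] <- btw[v] + through / length(paths)
    }
  }
  list(stress = stress, betweenness = btw)
}

oracle_closeness <- function(A) {
  D <- oracle_dists(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]; d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
}

oracle_eccentricity <- function(A) {
  D <- oracle_dists(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]; d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / max(d)
  }, numeric(1))
}

oracle_radiality <- function(A) {
  D <- oracle_dists(A)
  vapply(seq_len(nrow(A)), function(v) {
    memb <- which(is.finite(D[v, ]))
    if (length(memb) < 2) return(0)
    diam <- max(D[memb, memb])
    d <- D[v, setdiff(memb, v)]
    sum(diam + 1 - d) / (length(memb) - 1)
  }, numeric(1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2) return(0)
    tri <- sum(A[nb, nb]) / 2
    2 * tri / (length(nb) * (length(nb) - 1))
  }, numeric(1))
}

# connected components of an induced subgraph by BFS on the adjacency matrix
oracle_components <- function(A, nodes) {
  left <- nodes; comps <- list()
  while (length(left) > 0) {
    q <- left[1]; comp <- c()
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      q <- c(q, intersect(which(A[v, ] == 1), setdiff(left, comp)))
    }
    comps <- c(comps, list(sort(comp)))
    left <- setdiff(left, comp)
  }
  comps
}

oracle_mnc_dmnc <- function(A) {
  n <- nrow(A)
  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    if (length(nb) == 0) next
    comps <- oracle_components(A, nb)
    sizes <- lengths(comps)
    big <- comps[sizes == max(sizes)]
    edges <- vapply(big, function(cc) sum(A[cc, cc]) / 2, numeric(1))
    keys <- vapply(big, function(cc) paste(rownames(A)[cc], collapse = ","),
                   character(1))
    pick <- big[[order(-edges, keys)[1]]]
    mnc[v] <- length(pick)
    dmnc[v] <- (sum(A[pick, pick]) / 2) / length(pick)^1.7
  }
  list(mnc = mnc, dmnc = dmnc)
}

# maximal cliques by exhaustive subset enumeration (n <= 12)
oracle_mcc <- function(A) {
  n <- nrow(A)
  stopifnot(n <= 12)
  is_clique <- function(S) all(A[S, S][upper.tri(A[S, S])] == 1)
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) < 2 || !is_clique(S)) next
    maximal <- !any(vapply(setdiff(seq_len(n), S), function(v)
      is_clique(c(S, v)), logical(1)))
    if (maximal) cliques <- c(cliques, list(S))
  }
  out <- numeric(n)
  for (S in cliques) out[S] <- out[S] + factorial(length(S) - 1)
  out
}

# bottleneck under the deterministic smallest-id-parent tree convention
oracle_bottleneck <- function(A) {
  n <- nrow(A)
  D <- oracle_dists(A)
  score <- numeric(n)
  for (r in seq_len(n)) {
    memb <- which(is.finite(D[r, ]))
    if (length(memb) < 2) next
    parent <- rep(NA_integer_, n)
    for (w in setdiff(memb, r)) {
      pred <- which(A[w, ] == 1 & D[r, ] == D[r, w] - 1)
      parent[w] <- min(pred)
    }
    subtree <- function(v) {
      kids <- which(!is.na(parent) & parent == v)
      1 + sum(vapply(kids, subtree, numeric(1)))
    }
    for (v in setdiff(memb, r)) {
      if (subtree(v) >= length(memb) / 4) score[v] <- score[v] + 1
    }
  }
  score
}

# misc -------------------------------------------------------------------

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a); agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / total
}

# small deterministic expression fixture: genes x samples
rand_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples, mean = 7), n_genes, n_samples)
  rownames(x) <- sprintf("g%02d", seq_len(n_genes))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  x
}

# micro-fixture design without the size invariants (for 1-2-sample examples)
make_design_unchecked <- function(ref, stages) {
  data.frame(
    sample_id = c(ref, unlist(stages, use.names = FALSE)),
    group = c(rep("reference", length(ref)),
              rep("case", length(unlist(stages)))),
    stage = factor(c(rep(NA_character_, length(ref)),
                     rep(names(stages), lengths(stages))),
                   levels = names(stages), ordered = TRUE),
    stringsAsFactors = FALSE)
}

# design with one reference pool and labelled case stages
make_design <- function(ref, stages) {
  df <- data.frame(
    sample_id = c(ref, unlist(stages)),
    group = c(rep("reference", length(ref)),
              rep("case", length(unlist(stages)))),
    stage = c(rep(NA_character_, length(ref)),
              rep(names(stages), lengths(stages))),
    stringsAsFactors = FALSE)
  as_design(df, stage_levels = names(stages))
}
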