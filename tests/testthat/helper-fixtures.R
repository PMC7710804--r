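# Small builders and independent oracles used across the suite. The
# oracles are deliberately brute-force (path enumeration, transport-plan
# enumeration) and share no code with the package implementations.

make_parc <- function(n) {
  parcellation(data.frame(
    node_id = seq_len(n),
    label = sprintf("area_%02d", seq_len(n)),
    community = rep(c("ventral attention", "visual", "default mode"),
                    length.out = n),
    hemisphere = rep(c("L", "R"), length.out = n),
    x = seq_len(n), y = 0, z = 0))
}

cn_of <- function(W) connectome(W, make_parc(nrow(W)))

sym_matrix <- function(n, edges) {
  W <- matrix(0, n, n)
  for (e in edges) {
    W[e[1], e[2]] <- e[3]
    W[e[2], e[1]] <- e[3]
  }
  W
}

unit_triangle <- function() cn_of(sym_matrix(3, list(c(1, 2, 1), c(2, 3, 1),
                                                     c(1, 3, 1))))
unit_path3 <- function() cn_of(sym_matrix(3, list(c(1, 2, 1), c(2, 3, 1))))
unit_cycle <- function(n) {
  cn_of(sym_matrix(n, lapply(seq_len(n),
                             function(k) c(k, k %% n + 1, 1))))
}
unit_star <- function(k) {  # node 1 is the hub
  cn_of(sym_matrix(k + 1, lapply(seq_len(k) + 1, function(v) c(1, v, 1))))
}
complete_graph <- function(n) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  cn_of(W)
}

# random connected weighted graph on <= 7 nodes (spanning tree + extras)
random_small_graph <- function(n, p_extra = 0.4) {
  W <- matrix(0, n, n)
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    W[u, v] <- W[v, u] <- round(runif(1, 0.2, 3), 3)
  }
  for (u in 1:(n - 1)) for (v in (u + 1):n) {
    if (W[u, v] == 0 && runif(1) < p_extra)
      W[u, v] <- W[v, u] <- round(runif(1, 0.2, 3), 3)
  }
  cn_of(W)
}

# ---- exhaustive shortest-path / betweenness oracle (n <= 7) ----------

# all simple paths u -> v as node sequences, by depth-first enumeration
all_simple_paths <- function(W, u, v) {
  n <- nrow(W)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == v) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (W[last, nxt] > 0 && !(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(u)
  out
}

path_length <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(1 / W[cbind(path[-length(path)], path[-1])])
}

# geodesic lengths, shortest-path counts and betweenness by enumeration
oracle_paths <- function(W, tol = 1e-9) {
  n <- nrow(W)
  len <- matrix(Inf, n, n)
  diag(len) <- 0
  counts <- matrix(0, n, n)
  diag(counts) <- 1
  btw <- numeric(n)
  for (u in 1:(n - 1)) for (v in (u + 1):n) {
    paths <- all_simple_paths(W, u, v)
    if (length(paths) == 0) next
    lens <- vapply(paths, function(p) path_length(W, p), numeric(1))
    dmin <- min(lens)
    shortest <- paths[lens <= dmin * (1 + tol)]
    len[u, v] <- len[v, u] <- dmin
    counts[u, v] <- counts[v, u] <- length(shortest)
    for (w in setdiff(seq_len(n), c(u, v))) {
      through <- sum(vapply(shortest, function(p) w %in% p, logical(1)))
      btw[w] <- btw[w] + through / length(shortest)
    }
  }
  list(lengths = len, counts = counts, betweenness = btw)
}

# Onnela clustering coefficient, literal triple loop
oracle_clustering <- function(W) {
  n <- nrow(W)
  What <- W / max(W)
  k <- rowSums(W > 0)
  out <- numeric(n)
  for (i in 1:n) {
    if (k[i] < 2) next
    acc <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j != i && h != i && j != h)
        acc <- acc + (What[i, j] * What[i, h] * What[j, h])^(1 / 3)
    }
    out[i] <- acc / (k[i] * (k[i] - 1))
  }
  out
}

# ---- transport-plan enumeration oracle (supports <= 3) ---------------

# minimal cost over all extreme points of the transportation polytope:
# every basic feasible solution is supported on <= m + n - 1 cells, so
# enumerate cell subsets of that size, solve the balance equations and
# keep feasible solutions.
oracle_w1 <- function(cost, a, b) {
  m <- length(a)
  n <- length(b)
  cells <- expand.grid(i = 1:m, j = 1:n)
  nb <- m + n - 1
  best <- Inf
  for (sub in utils::combn(nrow(cells), min(nb, nrow(cells)),
                           simplify = FALSE)) {
    A <- matrix(0, m + n, length(sub))
    for (s in seq_along(sub)) {
      A[cells$i[sub[s]], s] <- 1
      A[m + cells$j[sub[s]], s] <- 1
    }
    rhs <- c(a, b)
    sol <- tryCatch(qr.solve(A[-(m + n), , drop = FALSE],
                             rhs[-(m + n)], tol = 1e-10),
                    error = function(e) NULL)
    if (is.null(sol)) next
    if (any(sol < -1e-9)) next
    if (max(abs(A %*% sol - rhs)) > 1e-9) next
    cc <- sum(sol * cost[cbind(cells$i[sub], cells$j[sub])])
    best <- min(best, cc)
  }
  best
}

# hop-distance matrix of a connectome, independent of the package path
hop_distances <- function(cn) {
  igraph::distances(
    igraph::graph_from_adjacency_matrix(cn$weights > 0, "undirected"))
}
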