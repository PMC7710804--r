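#' @title Weighted graph measures for connectomes
#'
#' @description Local measures (strength, betweenness centrality, Onnela
#'   weighted clustering coefficient) and global measures (density,
#'   diameter, global efficiency, characteristic path length, mean
#'   clustering, small-worldness) of a streamline-count connectome.
#'   Shortest-path measures use the standard length map `d = 1/w`: more
#'   streamlines mean a "shorter" (stronger) connection. Shortest paths
#'   and betweenness delegate to igraph's Dijkstra/Brandes routines.
#' @name graph-measures
NULL

# igraph view of a connectome, with edge attributes weight (streamline
# count) and length (1/weight) for shortest-path computations.
as_igraph <- function(cn) {
  stopifnot(inherits(cn, "connectome"))
  g <- igraph::graph_from_adjacency_matrix(cn$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Map connection weights to distances
#'
#' Elementwise `d_ij = 1 / w_ij` on positive weights; pairs with zero
#' weight get `Inf` (no edge); the diagonal is 0.
#'
#' @param cn a [connectome()].
#' @return An object of class `distance_graph`: list with `distances`
#'   (N x N matrix) and `parcellation`.
#' @export
weight_to_distance <- function(cn) {
  stopifnot(inherits(cn, "connectome"))
  D <- ifelse(cn$weights > 0, 1 / cn$weights, Inf)
  diag(D) <- 0
  structure(list(distances = D, parcellation = cn$parcellation),
            class = "distance_graph")
}

#' All-pairs geodesics with shortest-path counts
#'
#' Dijkstra-style all-pairs geodesic lengths on a distance graph, plus the
#' number of distinct shortest paths per pair. Ties in path length are
#' counted as multiple shortest paths, with a relative tolerance of
#' `1e-12` when comparing floating-point path lengths. Unreachable pairs
#' have length `Inf` and count 0.
#'
#' @param dg a [weight_to_distance()] result or a [connectome()].
#' @return list with `lengths` and `counts`, both N x N matrices.
#' @export
geodesics <- function(dg) {
  if (inherits(dg, "connectome")) dg <- weight_to_distance(dg)
  stopifnot(inherits(dg, "distance_graph"))
  D <- dg$distances
  N <- nrow(D)
  W <- ifelse(is.finite(D) & D > 0, 1 / D, 0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  dimnames(len) <- NULL
  tol <- 1e-12
  counts <- matrix(0, N, N)
  diag(counts) <- 1
  for (s in seq_len(N)) {
    d <- len[s, ]
    ord <- order(d)
    sigma <- numeric(N)
    sigma[s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(d[v])) next
      pred <- which(D[, v] < Inf)
      ok <- pred[abs(d[pred] + D[pred, v] - d[v]) <=
                   tol * pmax(1, d[v])]
      sigma[v] <- sum(sigma[ok])
    }
    counts[s, ] <- sigma
  }
  list(lengths = len, counts = counts)
}

#' Node strength
#'
#' The total weight of connections coming in and out of a node:
#' `s_i = sum_j w_ij`.
#'
#' @param cn a [connectome()].
#' @return numeric vector, one value per node.
#' @export
node_strength <- function(cn) {
  stopifnot(inherits(cn, "connectome"))
  rowSums(cn$weights)
}

#' Betweenness centrality
#'
#' Number of all-pairs shortest paths routing through each node (Brandes
#' accumulation on the `d = 1/w` distance graph, each unordered pair
#' counted once; fractional credit for tied shortest paths). The
#' normalized variant divides by `(N-1)(N-2)/2`, the number of pairs a
#' node could intermediate.
#'
#' @param cn a [connectome()].
#' @param normalized divide by `(N-1)(N-2)/2` (default `FALSE`).
#' @return numeric vector, one value per node.
#' @export
betweenness_centrality <- function(cn, normalized = FALSE) {
  g <- as_igraph(cn)
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = igraph::E(g)$length)
  b <- as.numeric(b)
  if (normalized) {
    N <- nrow(cn$weights)
    if (N > 2) b <- b / ((N - 1) * (N - 2) / 2)
  }
  b
}

#' Weighted clustering coefficient (Onnela form)
#'
#' Triangle intensity around each node on max-normalized weights
#' `what = w / max(w)`:
#' `c_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (what_ij what_ih what_jh)^{1/3}`
#' with `k_i` the binary degree; nodes with degree < 2 get 0. Values lie
#' in `[0, 1]` and reduce to the binary clustering coefficient when all
#' weights are equal.
#'
#' @param cn a [connectome()].
#' @return numeric vector in `[0, 1]`, one value per node.
#' @export
clustering_coefficient <- function(cn) {
  stopifnot(inherits(cn, "connectome"))
  W <- cn$weights
  mx <- max(W)
  if (mx == 0) return(numeric(nrow(W)))
  A3 <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  tri <- diag(A3 %*% A3 %*% A3)
  c_i <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  as.numeric(c_i)
}

#' Degree-and-weight-preserving rewired surrogate
#'
#' Maslov-Sneppen double-edge swaps; each edge carries its weight to its
#' new endpoints, so both the degree sequence and the edge-weight multiset
#' are preserved exactly. Driven by R's RNG (use `set.seed()` or the
#' `seed` argument for reproducibility).
#'
#' @param cn a [connectome()].
#' @param n_swaps number of swap attempts (default `10 * n_edges`).
#' @param seed optional integer seed.
#' @return a rewired [connectome()].
#' @export
rewired_null <- function(cn, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(cn, "connectome"))
  W <- cn$weights
  up <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(up)
  if (m < 2L) {
    warning("fewer than 2 edges; returning the input unchanged",
            call. = FALSE)
    return(cn)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m
  if (!is.null(seed)) set.seed(seed)
  wts <- W[up]
  new_edges <- .ms_rewire_cpp(cbind(up[, 1], up[, 2]), nrow(W),
                              as.integer(n_swaps))
  W2 <- matrix(0, nrow(W), ncol(W))
  W2[new_edges] <- wts
  W2[new_edges[, 2:1]] <- wts
  connectome(W2, cn$parcellation)
}

#' Global graph measures
#'
#' Whole-brain summaries of a connectome:
#' \describe{
#'   \item{density}{`2E / (N (N - 1))` over non-zero edges.}
#'   \item{global_efficiency}{mean over ordered node pairs of `1 / d_ij`
#'     (0 for unreachable pairs), `d` the `1/w` geodesic.}
#'   \item{characteristic_path_length}{mean finite geodesic over reachable
#'     pairs; the `disconnected` flag records whether any pair was
#'     unreachable.}
#'   \item{diameter}{largest finite geodesic.}
#'   \item{clustering_mean}{mean Onnela clustering coefficient.}
#'   \item{small_worldness}{`sigma = (C / C_rand) / (L / L_rand)` where
#'     `C_rand`, `L_rand` are means over `n_null` degree-and-weight
#'     preserving rewired surrogates; `sigma > 1` indicates small-world
#'     organization.}
#' }
#'
#' @param cn a [connectome()].
#' @param small_worldness compute the (costly) surrogate-based sigma
#'   statistic (default `TRUE`).
#' @param n_null number of rewired surrogates (default 100).
#' @param swaps_per_edge swap attempts per edge per surrogate (default 10).
#' @param seed optional integer seed for the surrogate ensemble.
#' @return list of class `global_measures` with the fields above plus
#'   `disconnected`.
#' @export
global_measures <- function(cn, small_worldness = TRUE, n_null = 100,
                            swaps_per_edge = 10, seed = NULL) {
  stopifnot(inherits(cn, "connectome"))
  W <- cn$weights
  N <- nrow(W)
  E <- sum(W[upper.tri(W)] > 0)
  if (E < 1L) stop("degenerate graph: no edges", call. = FALSE)
  g <- as_igraph(cn)
  D <- igraph::distances(g, weights = igraph::E(g)$length)
  off <- D[row(D) != col(D)]
  finite_off <- off[is.finite(off)]
  disconnected <- length(finite_off) < length(off)
  cc <- clustering_coefficient(cn)
  res <- list(
    density = 2 * E / (N * (N - 1)),
    global_efficiency = mean(ifelse(is.finite(off), 1 / off, 0)),
    characteristic_path_length = mean(finite_off),
    diameter = max(finite_off),
    clustering_mean = mean(cc),
    small_worldness = NA_real_,
    disconnected = disconnected
  )
  if (small_worldness) {
    if (!is.null(seed)) set.seed(seed)
    C_rand <- numeric(n_null)
    L_rand <- numeric(n_null)
    for (r in seq_len(n_null)) {
      surr <- rewired_null(cn, n_swaps = swaps_per_edge * E)
      gs <- as_igraph(surr)
      Ds <- igraph::distances(gs, weights = igraph::E(gs)$length)
      offs <- Ds[row(Ds) != col(Ds)]
      L_rand[r] <- mean(offs[is.finite(offs)])
      C_rand[r] <- mean(clustering_coefficient(surr))
    }
    res$small_worldness <-
      (res$clustering_mean / mean(C_rand)) /
      (res$characteristic_path_length / mean(L_rand))
  }
  class(res) <- "global_measures"
  res
}

#' @export
print.global_measures <- function(x, ...) {
  cat("global measures:\n")
  for (nm in setdiff(names(x), "disconnected"))
    cat(sprintf("  %-28s %.6g\n", nm, x[[nm]]))
  if (isTRUE(x$disconnected))
    cat("  (graph is disconnected; path measures over reachable pairs)\n")
  invisible(x)
}

#' Binarize a connectome
#'
#' Replaces every positive weight by 1, for sensitivity analyses of the
#' weighted-versus-binary choice.
#'
#' @param cn a [connectome()].
#' @return a [connectome()] with unit weights.
#' @export
binarize <- function(cn) {
  stopifnot(inherits(cn, "connectome"))
  connectome((cn$weights > 0) * 1, cn$parcellation)
}
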