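#' @title Ollivier-Ricci curvature of weighted graphs
#'
#' @description The direct robustness measure of the analysis. Each node
#'   carries a lazy random-walk probability measure: mass `idleness` stays
#'   on the node itself and the rest is spread over its neighbours in
#'   proportion to edge weights. The curvature of an edge (i, j) compares
#'   the Wasserstein-1 (optimal transport) distance between the two
#'   endpoint measures with the ground distance between the endpoints:
#'   `kappa_ij = 1 - W1(m_i, m_j) / d(i, j)`. Positive curvature means the
#'   neighbourhoods overlap (perturbations die out quickly; robustness),
#'   negative curvature means tree-like fragility. Node curvature is the
#'   strength-weighted mean of incident edge curvatures, and global
#'   curvature the plain mean of node curvatures.
#'
#'   W1 is computed exactly by an in-package min-cost-flow solver
#'   (successive shortest augmenting paths with potentials); no entropic
#'   or other approximation is involved.
#' @name curvature
NULL

#' Lazy random-walk measure of a node
#'
#' @param cn a [connectome()].
#' @param node node index (row of the parcellation, 1-based).
#' @param idleness probability mass retained at the node itself, in
#'   `[0, 1)` (default 0.5).
#' @return An object of class `neighbor_measure`: list with
#'   `anchor_node`, `support` (node indices; the anchor first), `masses`
#'   (summing to 1) and `idleness`.
#' @export
neighbor_measure <- function(cn, node, idleness = 0.5) {
  stopifnot(inherits(cn, "connectome"), idleness >= 0, idleness < 1)
  w <- cn$weights[node, ]
  nbr <- which(w > 0)
  if (length(nbr) == 0L)
    stop("no incident edges at node ", node, call. = FALSE)
  s <- sum(w[nbr])
  structure(list(anchor_node = node,
                 support = c(node, nbr),
                 masses = c(idleness, (1 - idleness) * w[nbr] / s),
                 idleness = idleness),
            class = "neighbor_measure")
}

#' Exact Wasserstein-1 distance between two node measures
#'
#' Solves the transportation linear program exactly (min-cost flow with
#' successive shortest paths). The cost of moving mass from support node u
#' of `mu` to support node v of `nu` is `ground_distances[u, v]`.
#'
#' @param mu,nu measures: [neighbor_measure()] objects or lists with
#'   elements `support` (node indices) and `masses` (non-negative, summing
#'   to 1 within `1e-12`).
#' @param ground_distances full N x N matrix of ground distances between
#'   nodes (e.g. hop counts or `1/w` geodesics); `Inf` entries between
#'   mass-carrying support points are an error ("supports disconnected").
#' @return the optimal transport cost (non-negative scalar).
#' @export
wasserstein1 <- function(mu, nu, ground_distances) {
  check_measure <- function(m) {
    stopifnot(length(m$support) == length(m$masses), all(m$masses >= 0))
    if (abs(sum(m$masses) - 1) > 1e-12)
      stop("masses must sum to 1", call. = FALSE)
  }
  check_measure(mu)
  check_measure(nu)
  cost <- ground_distances[mu$support, nu$support, drop = FALSE]
  .wasserstein1_cpp(cost, as.numeric(mu$masses), as.numeric(nu$masses))
}

# Ground metric matrix for curvature: hop counts (default) or 1/w
# geodesics on the connectome.
ground_metric_matrix <- function(cn, ground_metric = c("hop", "weighted")) {
  ground_metric <- match.arg(ground_metric)
  g <- as_igraph(cn)
  D <- if (ground_metric == "hop")
    igraph::distances(g, weights = NA)
  else
    igraph::distances(g, weights = igraph::E(g)$length)
  dimnames(D) <- NULL
  D
}

#' Curvature of a single edge
#'
#' `kappa_ij = 1 - W1(m_i, m_j) / d(i, j)`; always `<= 1`.
#'
#' @param cn a [connectome()].
#' @param i,j endpoints of an existing edge (`w_ij > 0`).
#' @param idleness lazy-walk idleness in `[0, 1)` (default 0.5).
#' @param ground_metric `"hop"` (unweighted shortest-path counts, the
#'   default) or `"weighted"` (`1/w` geodesics).
#' @return scalar curvature.
#' @export
edge_curvature <- function(cn, i, j, idleness = 0.5,
                           ground_metric = c("hop", "weighted")) {
  stopifnot(inherits(cn, "connectome"))
  if (!(cn$weights[i, j] > 0))
    stop("no edge between nodes ", i, " and ", j, call. = FALSE)
  D <- ground_metric_matrix(cn, ground_metric)
  mi <- neighbor_measure(cn, i, idleness)
  mj <- neighbor_measure(cn, j, idleness)
  1 - wasserstein1(mi, mj, D) / D[i, j]
}

#' Ollivier-Ricci curvature of every edge, node and the whole graph
#'
#' Computes all edge curvatures in one pass (shared ground-metric matrix,
#' C++ transport solver), then aggregates: node curvature is the
#' strength-weighted mean of incident edge curvatures
#' `kappa_i = sum_j (w_ij / s_i) kappa_ij` (missing for isolated nodes),
#' and global curvature is the unweighted mean of node curvatures over
#' non-isolated nodes.
#'
#' @inheritParams edge_curvature
#' @return An object of class `orc_result`: list with
#'   `edge_curvatures` (data frame `i`, `j`, `weight`, `kappa`),
#'   `node_curvatures` (numeric vector, `NA` for isolated nodes),
#'   `global_curvature` (scalar) and `params`.
#' @export
orc_curvature <- function(cn, idleness = 0.5,
                          ground_metric = c("hop", "weighted")) {
  stopifnot(inherits(cn, "connectome"), idleness >= 0, idleness < 1)
  ground_metric <- match.arg(ground_metric)
  W <- cn$weights
  if (!any(W > 0)) stop("edgeless graph", call. = FALSE)
  D <- ground_metric_matrix(cn, ground_metric)
  ed <- .orc_edges_cpp(W, D, idleness)
  edges <- data.frame(i = as.integer(ed[, 1]), j = as.integer(ed[, 2]),
                      weight = ed[, 3], kappa = ed[, 4])
  N <- nrow(W)
  s <- rowSums(W)
  acc <- numeric(N)
  wk <- edges$weight * edges$kappa
  for (k in seq_len(nrow(edges))) {
    acc[edges$i[k]] <- acc[edges$i[k]] + wk[k]
    acc[edges$j[k]] <- acc[edges$j[k]] + wk[k]
  }
  node_k <- ifelse(s > 0, acc / s, NA_real_)
  structure(list(edge_curvatures = edges,
                 node_curvatures = as.numeric(node_k),
                 global_curvature = mean(node_k[s > 0]),
                 params = list(idleness = idleness,
                               ground_metric = ground_metric)),
            class = "orc_result")
}

#' @export
print.orc_result <- function(x, ...) {
  cat(sprintf(paste0("Ollivier-Ricci curvature (idleness %.2f, %s ",
                     "ground metric)\n"),
              x$params$idleness, x$params$ground_metric))
  cat(sprintf("  %d edges, kappa in [%.4f, %.4f], global %.6g\n",
              nrow(x$edge_curvatures), min(x$edge_curvatures$kappa),
              max(x$edge_curvatures$kappa), x$global_curvature))
  invisible(x)
}

#' Node curvatures of a connectome
#'
#' @inheritParams edge_curvature
#' @return numeric vector of node curvatures (`NA` for isolated nodes).
#' @export
node_curvature <- function(cn, idleness = 0.5,
                           ground_metric = c("hop", "weighted")) {
  orc_curvature(cn, idleness, ground_metric)$node_curvatures
}

#' Global curvature of a connectome
#'
#' Unweighted mean of node curvatures over non-isolated nodes.
#'
#' @inheritParams edge_curvature
#' @return scalar.
#' @export
global_curvature <- function(cn, idleness = 0.5,
                             ground_metric = c("hop", "weighted")) {
  orc_curvature(cn, idleness, ground_metric)$global_curvature
}
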