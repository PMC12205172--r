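#' Weighted k-nearest-neighbour graph of cells
#'
#' Builds the undirected k-NN graph used to approximate the data manifold:
#' an edge joins `i` and `j` when either is among the other's `k` nearest
#' neighbours (union symmetrization), weighted by the feature-space distance.
#' If the graph is disconnected, `k` is incremented until it connects; the
#' neighbour count actually used is recorded as `k_used`.
#'
#' @param m A [modality()] object or numeric cell-by-feature matrix.
#' @param k Number of nearest neighbours (`1 <= k < n_cells`).
#' @param metric Feature-space distance; only `"euclidean"` is provided.
#' @return An object of class `sonata_graph`: list with `graph` (an
#'   [igraph::graph] with edge weights), `n`, `k_requested`, `k_used`.
#' @examples
#' g <- knn_graph(matrix(c(0, 1, 2), ncol = 1), k = 1)
#' g$k_used
#' @export
knn_graph <- function(m, k, metric = "euclidean") {
  m <- as_modality(m)
  metric <- match.arg(metric, "euclidean")
  n <- nrow(m$matrix)
  if (k < 1L || k >= n)
    stop(sprintf("`k` must be in [1, %d), got %s", n, k), call. = FALSE)
  D <- as.matrix(dist(m$matrix))
  if (any(D[upper.tri(D)] == 0)) {
    warning("duplicate cells produce zero-distance edges; ",
            "replacing with machine epsilon")
    D[D == 0] <- .Machine$double.eps
    diag(D) <- 0
  }
  k_used <- as.integer(k)
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(k_used + 1L)]
      adj[i, nb] <- D[i, nb]
    }
    adj <- pmax(adj, t(adj))  # union of directed k-NN relations
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    if (igraph::is_connected(g)) break
    if (k_used >= n - 1L)
      stop("graph cannot be connected", call. = FALSE)
    k_used <- k_used + 1L
  }
  structure(list(graph = g, n = n, k_requested = as.integer(k),
                 k_used = k_used),
            class = "sonata_graph")
}

#' @export
print.sonata_graph <- function(x, ...) {
  cat(sprintf("<sonata_graph> %d cells, %d edges, k = %d (requested %d)\n",
              x$n, igraph::ecount(x$graph), x$k_used, x$k_requested))
  invisible(x)
}

#' Geodesic distances by graph shortest paths
#'
#' All-pairs shortest weighted path lengths on a cell graph, the standard
#' approximation to geodesic distances on the data manifold. The result is
#' symmetric, hollow and finite.
#'
#' @param graph A `sonata_graph` (from [knn_graph()]) or an igraph object.
#' @return A symmetric `n x n` numeric matrix with zero diagonal.
#' @export
geodesic_distances <- function(graph) {
  g <- if (inherits(graph, "sonata_graph")) graph$graph else graph
  if (!igraph::is_connected(g)) {
    comp <- igraph::components(g)
    stop(sprintf("graph is disconnected (%d components; sizes %s)",
                 comp$no, paste(comp$csize, collapse = ", ")), call. = FALSE)
  }
  K <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(K) <- NULL
  K <- (K + t(K)) / 2  # guard against asymmetric float noise
  diag(K) <- 0
  K
}

#' Geodesic matrix of a modality in one call
#'
#' Convenience wrapper: k-NN graph plus shortest paths. The default
#' neighbour count is 10 percent of the cells (at least 5).
#'
#' @inheritParams knn_graph
#' @param k Neighbour count; default `max(5, floor(0.1 n))`.
#' @return List with `K` (geodesic matrix) and `k_used`.
#' @export
modality_geodesics <- function(m, k = NULL) {
  m <- as_modality(m)
  n <- nrow(m$matrix)
  if (is.null(k)) k <- max(5L, floor(0.1 * n))
  g <- knn_graph(m, k)
  list(K = geodesic_distances(g), k_used = g$k_used)
}

#' Variational copy of a modality
#'
#' Perturbs the feature matrix with Gaussian noise scaled per feature
#' (`sd = noise_sd * sd(feature)`) and rebuilds the geodesic matrix with a
#' possibly different neighbour count. Self-alignment against such copies is
#' what breaks the trivial identity solution and exposes which distant cell
#' pairs the manifold cannot distinguish.
#'
#' @param m A [modality()] object or matrix.
#' @param noise_sd Relative noise level (>= 0); 0 reproduces the input.
#' @param k Neighbour count for the copy's graph.
#' @param seed Integer seed; fixed seed gives bit-identical copies.
#' @return Class `sonata_replicate`: list with `data` (perturbed modality),
#'   `geodesic`, `noise_sd`, `k`, `k_used`, `seed`.
#' @export
make_variational <- function(m, noise_sd, k, seed) {
  m <- as_modality(m)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  X <- m$matrix
  if (noise_sd > 0) {
    sds <- apply(X, 2L, sd)
    eps <- with_seed(seed, matrix(rnorm(length(X)), nrow(X), ncol(X)))
    X <- X + sweep(eps, 2L, sds * noise_sd, `*`)
  }
  pert <- modality(X, cell_ids = m$cell_ids, labels = m$labels)
  g <- knn_graph(pert, k)
  structure(list(data = pert, geodesic = geodesic_distances(g),
                 noise_sd = noise_sd, k = as.integer(k), k_used = g$k_used,
                 seed = as.integer(seed)),
            class = "sonata_replicate")
}
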