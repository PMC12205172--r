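# Independent oracles and small fixture builders used across test files.

# all-pairs shortest paths by Floyd-Warshall on a weighted adjacency matrix
# (0 = no edge off the diagonal)
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj > 0, adj, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# brute-force union-of-kNN edge set from all-pairs distances
brute_knn_edges <- function(X, k) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  edges <- matrix(0L, 0L, 2L)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  unique(edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE])
}

edge_matrix <- function(g) {
  e <- igraph::as_edgelist(g$graph)
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e[order(e[, 1L], e[, 2L]), , drop = FALSE])
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# exhaustive permutation minimizer of the quadratic GW objective between
# two same-size metric spaces with uniform marginals
gw_perm_oracle <- function(K1, K2) {
  n <- nrow(K1)
  best <- NULL
  best_obj <- Inf
  for (p in all_permutations(seq_len(n))) {
    obj <- sum((K1 - K2[p, p])^2 / 2) / n^2
    if (obj < best_obj) {
      best_obj <- obj
      best <- p
    }
  }
  list(perm = best, objective = best_obj)
}

# pool-adjacent-violators antitonic fit (independent of the package's
# spline + projection path): isotonic regression on reversed order
pav_antitonic <- function(x, y) {
  ord <- order(x)
  fit <- rev(isoreg(rev(y[ord]))$yf)
  list(x = x[ord], y = fit)
}

# brute-force k-NN majority-vote classifier (loops, no vectorization)
brute_knn_classify <- function(train, labels, test, k) {
  labels <- as.character(labels)
  out <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    d <- sqrt(colSums((t(train) - test[i, ])^2))
    nb <- order(d)[seq_len(k)]
    tab <- table(labels[nb])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      w <- vapply(top, function(lb)
        sum(1 / pmax(d[nb][labels[nb] == lb], 1e-12)), numeric(1L))
      top <- top[which.max(w)]
    }
    out[i] <- top
  }
  out
}

# consensus matrix generated exactly from a monotone null plus noise
make_null_consensus <- function(K, f, noise_sd, seed) {
  n <- nrow(K)
  E <- matrix(0, n, n)
  set.seed(seed)
  E[upper.tri(E)] <- rnorm(sum(upper.tri(E)), 0, noise_sd)
  cons <- f(K) + E + t(E)
  diag(cons) <- 0
  cons
}

# small cached T-branch self-alignment shared by ambiguity/group tests
small_t_diagnosis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_branch_dataset("t_branch", n = 120, px = 150, py = 200,
                                     seed = 7)
      diag <- sonata_diagnose(sim$modality_x,
                              sonata_config(n_replicates = 6, seed = 7))
      cache <<- list(sim = sim, diag = diag)
    }
    cache
  }
})
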