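#' Entropy-regularized Gromov-Wasserstein coupling of two metric spaces
#'
#' Finds a probabilistic correspondence `gamma` between the points of two
#' metric spaces given only their internal distance matrices, by minimizing
#' the Gromov-Wasserstein objective
#' `sum_{i,j,k,l} L(K_src[i,k], K_dst[j,l]) gamma[i,j] gamma[k,l]`
#' with quadratic loss `L(a, b) = (a - b)^2 / 2` over couplings with fixed
#' marginals `p`, `q`, smoothed by an entropy term of weight `epsilon`.
#' The solver alternates linearization of the quadratic objective with
#' log-domain Sinkhorn projections (warm-started potentials); the loss
#' tensor is never materialized - the linearized cost is assembled from
#' matrix products of the two distance matrices.
#'
#' The problem is non-convex: the result is a local optimum, and on
#' self-similar spaces several local optima attain near-identical objective
#' values. That multiplicity is not a nuisance here - it is the manifold
#' ambiguity this package measures; see [self_align()].
#'
#' @param K_src,K_dst Square symmetric distance matrices (n x n and m x m).
#' @param p,q Marginal weight vectors (default uniform); strictly positive,
#'   summing to 1.
#' @param epsilon Entropic regularization on max-normalized distances.
#' @param max_iter Maximum outer (linearization) iterations.
#' @param inner_iter Maximum Sinkhorn iterations per outer step (iterations
#'   are cheap matrix-vector scalings; the warm-started typical call uses
#'   far fewer).
#' @param tol Outer convergence tolerance on the coupling (sup norm).
#' @param normalize Divide each distance matrix by its maximum before
#'   solving (makes `epsilon` transferable across datasets).
#' @param init `"product"` for the deterministic `p q^T` start, or an
#'   explicit nonnegative n x m matrix.
#' @param anneal Optional decreasing sequence of epsilon values solved
#'   first, each warm-starting the next (entropic continuation). Smooths
#'   away shallow local optima on small or near-symmetric instances; leave
#'   `NULL` (the default) when the multiplicity of local optima is itself
#'   of interest, as in [self_align()].
#' @param seed Unused for the deterministic product start; kept so callers
#'   can thread one seed through custom `init` construction.
#' @return Class `sonata_coupling`: list with `gamma`, `p`, `q`,
#'   `objective` (value at the returned coupling), `objective_trace`,
#'   `iterations`, `converged`, `marginal_error`, `epsilon`.
#' @examples
#' K <- as.matrix(dist(cbind(1:5, (1:5)^1.3)))
#' cpl <- gw_coupling(K, K, epsilon = 1e-3)
#' harden_coupling(cpl)  # identity permutation
#' @export
gw_coupling <- function(K_src, K_dst, p = NULL, q = NULL,
                        epsilon = 5e-3, max_iter = 100L, inner_iter = 1000L,
                        tol = 1e-7, normalize = TRUE, init = "product",
                        anneal = NULL, seed = NULL) {
  if (!is.null(anneal)) {
    for (e in anneal) {
      warm <- suppressWarnings(
        gw_coupling(K_src, K_dst, p, q, epsilon = e, max_iter = max_iter,
                    inner_iter = inner_iter, tol = tol,
                    normalize = normalize, init = init))
      init <- warm$gamma
    }
  }
  check_square(K_src, "K_src"); check_square(K_dst, "K_dst")
  n <- nrow(K_src); m <- nrow(K_dst)
  if (is.null(p)) p <- rep(1 / n, n)
  if (is.null(q)) q <- rep(1 / m, m)
  if (length(p) != n || length(q) != m)
    stop("marginal lengths must match the distance matrices", call. = FALSE)
  if (any(p <= 0) || any(q <= 0) || abs(sum(p) - 1) > 1e-8 ||
      abs(sum(q) - 1) > 1e-8)
    stop("`p` and `q` must be strictly positive and sum to 1", call. = FALSE)
  if (normalize) {
    if (max(K_src) > 0) K_src <- K_src / max(K_src)
    if (max(K_dst) > 0) K_dst <- K_dst / max(K_dst)
  }

  # quadratic-loss factorization: L(a,b) = a^2/2 + b^2/2 - ab, so the
  # linearized cost at G is constC - K_src %*% G %*% t(K_dst)
  constC <- outer(drop((K_src^2 / 2) %*% p), rep(1, m)) +
            outer(rep(1, n), drop((K_dst^2 / 2) %*% q))

  G <- if (is.matrix(init)) {
    if (!all(dim(init) == c(n, m)) || any(init < 0))
      stop("`init` must be a nonnegative n x m matrix", call. = FALSE)
    init / sum(init)
  } else {
    outer(p, q)
  }

  f <- numeric(n); g <- numeric(m)
  objective_trace <- numeric(0)
  converged <- FALSE
  marg_err <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    tens <- constC - K_src %*% G %*% t(K_dst)
    sk <- .sinkhorn_log_cpp(tens, p, q, epsilon, f, g,
                            as.integer(inner_iter), 1e-9)
    f <- sk$f; g <- sk$g
    G_new <- sk$gamma
    marg_err <- sk$marginal_error
    obj <- sum((constC - K_src %*% G_new %*% t(K_dst)) * G_new)
    prev_obj <- if (length(objective_trace)) objective_trace[length(objective_trace)]
                else Inf
    if (obj > prev_obj + 1e-12 + 1e-9 * abs(prev_obj)) {
      # fixed-point wiggle near convergence: keep the previous iterate
      converged <- TRUE
      break
    }
    objective_trace <- c(objective_trace, obj)
    delta <- max(abs(G_new - G))
    G <- G_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("GW solver did not converge in %d outer iterations", max_iter))

  structure(list(gamma = G, p = p, q = q,
                 objective = objective_trace[length(objective_trace)],
                 objective_trace = objective_trace,
                 iterations = it, converged = converged,
                 marginal_error = marg_err, epsilon = epsilon),
            class = "sonata_coupling")
}

#' @export
print.sonata_coupling <- function(x, ...) {
  cat(sprintf(
    "<sonata_coupling> %d x %d, objective %.4g, %s after %d iterations\n",
    nrow(x$gamma), ncol(x$gamma), x$objective,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Check coupling feasibility
#'
#' @param cpl A `sonata_coupling` or nonnegative matrix.
#' @param p,q Expected marginals (taken from the object when available).
#' @param tol Marginal tolerance.
#' @return `TRUE` invisibly; errors describe the violation.
#' @export
validate_coupling <- function(cpl, p = NULL, q = NULL, tol = 1e-6) {
  G <- if (inherits(cpl, "sonata_coupling")) cpl$gamma else cpl
  if (inherits(cpl, "sonata_coupling")) { p <- cpl$p; q <- cpl$q }
  if (any(G < 0)) stop("coupling has negative entries", call. = FALSE)
  if (!is.null(p) && max(abs(rowSums(G) - p)) > tol)
    stop(sprintf("row marginals violated (max error %.2g)",
                 max(abs(rowSums(G) - p))), call. = FALSE)
  if (!is.null(q) && max(abs(colSums(G) - q)) > tol)
    stop(sprintf("column marginals violated (max error %.2g)",
                 max(abs(colSums(G) - q))), call. = FALSE)
  invisible(TRUE)
}

#' Harden a coupling to a point map
#'
#' @param cpl A `sonata_coupling` or matrix.
#' @return Integer vector: for each row, the column receiving most mass.
#' @export
harden_coupling <- function(cpl) {
  G <- if (inherits(cpl, "sonata_coupling")) cpl$gamma else cpl
  apply(G, 1L, which.max)
}

# GW objective of an explicit coupling (internal; also used by tests)
gw_objective <- function(K_src, K_dst, G) {
  constC <- outer(drop((K_src^2 / 2) %*% rowSums(G)), rep(1, ncol(G))) +
            outer(rep(1, nrow(G)), drop((K_dst^2 / 2) %*% colSums(G)))
  sum((constC - K_src %*% G %*% t(K_dst)) * G)
}

# Permutation-seeded initial coupling used by multi-start exploration.
perm_init <- function(n, m, seed, blend = 0.5) {
  sigma <- with_seed(seed, sample(m, n, replace = n > m))
  P <- matrix(0, n, m)
  P[cbind(seq_len(n), sigma)] <- 1 / n
  (1 - blend) / (n * m) + blend * P
}

# Run gw_coupling from several initializations; average all solutions whose
# objective is within `slack` (relative) of the best. Near-ties are distinct
# local optima of equal quality - exactly the multiplicity self-alignment
# needs to expose - so they are averaged rather than discarded.
gw_multistart <- function(K_src, K_dst, epsilon, n_starts, seed,
                          slack = 0.01, ...) {
  n <- nrow(K_src); m <- nrow(K_dst)
  sols <- vector("list", n_starts)
  objs <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    init <- if (s == 1L) "product" else perm_init(n, m, derive_seed(seed, s))
    cpl <- gw_coupling(K_src, K_dst, epsilon = epsilon, init = init, ...)
    sols[[s]] <- cpl
    objs[s] <- cpl$objective
  }
  keep <- objs <= min(objs) * (1 + slack) + 1e-15
  G <- Reduce(`+`, lapply(sols[keep], `[[`, "gamma")) / sum(keep)
  list(gamma = G, n_kept = sum(keep), objectives = objs,
       converged = vapply(sols, `[[`, logical(1L), "converged"))
}

#' Self-alignment ensemble of a modality
#'
#' Aligns a modality against variational copies of itself (Gaussian noise,
#' varying neighbour counts; see [make_variational()]) with entropic
#' Gromov-Wasserstein transport. Each replicate is solved from several
#' seeded initializations (one deterministic product start plus
#' permutation-seeded starts) and all solutions within 1 percent relative
#' objective of the replicate best are averaged: on a self-similar manifold
#' the solver's near-optimal basins correspond to distinct partial
#' isometries, and the ensemble needs all of them represented. The
#' consensus coupling is the replicate mean, symmetrized as
#' `(G + t(G)) / 2`.
#'
#' @param m A [modality()] object or matrix.
#' @param n_replicates Number of variational copies.
#' @param noise_sd Relative per-feature noise of the copies.
#' @param k_schedule Neighbour counts cycled across replicates; default
#'   `floor(c(0.05, 0.1, 0.2) * n)`.
#' @param epsilon Entropic regularization (see [gw_coupling()]).
#' @param seed Single integer controlling all noise draws and solver
#'   initializations.
#' @param n_starts Solver initializations per replicate.
#' @param k_base Neighbour count for the reference geodesic matrix.
#' @param ... Passed on to [gw_coupling()].
#' @return Class `sonata_selfalign`: list with `consensus` (symmetric n x n
#'   matrix, total mass 1), `geodesic` (reference geodesic matrix,
#'   max-normalized), `couplings` (per-replicate averaged couplings),
#'   `replicate_meta`, `k_base_used`.
#' @export
self_align <- function(m, n_replicates = 10L, noise_sd = 0.1,
                       k_schedule = NULL, epsilon = 5e-3, seed = 0L,
                       n_starts = 4L, k_base = NULL, ...) {
  m <- as_modality(m)
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  n <- nrow(m$matrix)
  if (is.null(k_base)) k_base <- max(5L, floor(0.1 * n))
  if (is.null(k_schedule))
    k_schedule <- pmax(3L, floor(c(0.05, 0.1, 0.2) * n))
  ks <- rep(k_schedule, length.out = n_replicates)

  g0 <- knn_graph(m, k_base)
  K <- geodesic_distances(g0)
  K <- K / max(K)

  couplings <- vector("list", n_replicates)
  meta <- vector("list", n_replicates)
  acc <- matrix(0, n, n)
  n_ok <- 0L
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, 17L * r)
    res <- tryCatch({
      vr <- make_variational(m, noise_sd, ks[r], seed = rep_seed)
      Kv <- vr$geodesic / max(vr$geodesic)
      ms <- gw_multistart(K, Kv, epsilon = epsilon, n_starts = n_starts,
                          seed = derive_seed(seed, 1000L + r), ...)
      list(vr = vr, ms = ms)
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    couplings[[r]] <- res$ms$gamma
    meta[[r]] <- list(seed = rep_seed, noise_sd = noise_sd, k = ks[r],
                      k_used = res$vr$k_used, n_kept = res$ms$n_kept,
                      objectives = res$ms$objectives,
                      converged = res$ms$converged)
    acc <- acc + res$ms$gamma
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stop("all self-alignment replicates failed", call. = FALSE)
  consensus <- acc / n_ok
  consensus <- (consensus + t(consensus)) / 2

  structure(list(consensus = consensus, geodesic = K,
                 couplings = couplings[!vapply(couplings, is.null, TRUE)],
                 replicate_meta = meta[!vapply(meta, is.null, TRUE)],
                 k_base_used = g0$k_used, epsilon = epsilon,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sonata_selfalign")
}

#' @export
print.sonata_selfalign <- function(x, ...) {
  cat(sprintf(
    "<sonata_selfalign> %d cells, %d replicates (noise_sd %.3g, epsilon %.3g)\n",
    nrow(x$consensus), length(x$couplings), x$noise_sd, x$epsilon))
  invisible(x)
}

#' Baseline cross-modality alignment
#'
#' A plain entropic Gromov-Wasserstein alignment of two modalities from
#' their geodesic matrices with uniform marginals - the kind of diagonal
#' integration solution this package diagnoses. No shared features are
#' assumed.
#'
#' @param mx,my The two modalities ([modality()] or matrices).
#' @param k Neighbour count for both graphs (default 10 percent of cells).
#' @param epsilon Entropic regularization.
#' @param seed Seed (deterministic product initialization; kept for
#'   interface symmetry).
#' @param ... Passed to [gw_coupling()].
#' @return A `sonata_coupling` with the two geodesic matrices attached as
#'   attributes `K_src` and `K_dst`.
#' @export
cross_modality_align <- function(mx, my, k = NULL, epsilon = 5e-3,
                                 seed = 0L, ...) {
  mx <- as_modality(mx); my <- as_modality(my)
  Kx <- modality_geodesics(mx, k)$K
  Ky <- modality_geodesics(my, k)$K
  Kx <- Kx / max(Kx); Ky <- Ky / max(Ky)
  cpl <- gw_coupling(Kx, Ky, epsilon = epsilon, seed = seed, ...)
  attr(cpl, "K_src") <- Kx
  attr(cpl, "K_dst") <- Ky
  cpl
}
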