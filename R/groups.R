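# Aggregation of ambiguous cell pairs into substitutable groups via
# cannot-link constrained k-means with elbow selection of the group count.

#' Cannot-link constrained k-means assignment
#'
#' COP-k-means-style clustering: cells are assigned greedily (random order,
#' updated centroids) to their nearest centroid, except that a cell moves to
#' the nearest *conflict-free* centroid when one exists within `tau` times
#' the squared distance of the nearest - cannot-link pairs are separated
#' when geometrically feasible, but a constraint is never honoured at the
#' price of a grossly wrong geometric assignment (which would let banded
#' constraint graphs be near-2-coloured and flatten the elbow curve).
#' Best of `n_restarts` seeded restarts by violations, then inertia.
#'
#' @param embedding Numeric matrix of cell coordinates (rows = cells to
#'   cluster, typically a geodesic MDS embedding).
#' @param constraints Two-column integer matrix of cannot-link pairs
#'   (row indices into `embedding`).
#' @param n_groups Number of groups (`1 <= n_groups <= n`).
#' @param seed Integer seed (restart initializations and scan orders).
#' @param n_restarts Restarts.
#' @param max_iter Assignment/update sweeps per restart.
#' @param tau Geometric feasibility factor on squared distances.
#' @return List with `assignment` (integer vector), `violations`
#'   (cannot-link pairs sharing a group), `inertia`.
#' @export
cluster_with_constraints <- function(embedding, constraints, n_groups,
                                     seed = 0L, n_restarts = 10L,
                                     max_iter = 50L, tau = 2) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n_groups < 1L || n_groups > n)
    stop(sprintf("`n_groups` must be in [1, %d]", n), call. = FALSE)
  constraints <- matrix(as.integer(constraints), ncol = 2L)
  if (nrow(constraints) > 0 &&
      (any(constraints < 1L) || any(constraints > n) ||
       any(constraints[, 1L] == constraints[, 2L])))
    stop("constraints must index distinct embedding rows", call. = FALSE)

  conflict <- vector("list", n)
  for (r in seq_len(nrow(constraints))) {
    i <- constraints[r, 1L]; j <- constraints[r, 2L]
    conflict[[i]] <- c(conflict[[i]], j)
    conflict[[j]] <- c(conflict[[j]], i)
  }
  count_viol <- function(a) {
    if (nrow(constraints) == 0L) return(0L)
    sum(a[constraints[, 1L]] == a[constraints[, 2L]])
  }

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    sol <- with_seed(derive_seed(seed, rs), {
      cent <- embedding[sample(n, n_groups), , drop = FALSE]
      assign <- rep(NA_integer_, n)
      for (it in seq_len(max_iter)) {
        prev <- assign
        for (i in sample(n)) {
          d2 <- colSums((t(cent) - embedding[i, ])^2)
          pref <- order(d2)
          lim <- tau * d2[pref[1L]] + 1e-12
          pick <- pref[1L]
          for (g in pref) {
            if (d2[g] > lim) break
            cf <- conflict[[i]]
            if (is.null(cf) || !any(assign[cf] == g, na.rm = TRUE)) {
              pick <- g
              break
            }
          }
          assign[i] <- pick
        }
        for (g in seq_len(n_groups)) {
          memb <- assign == g
          if (any(memb)) cent[g, ] <- colMeans(embedding[memb, , drop = FALSE])
        }
        if (it > 1L && identical(assign, prev)) break
      }
      list(assignment = assign, violations = count_viol(assign),
           inertia = sum((embedding - cent[assign, , drop = FALSE])^2))
    })
    if (is.null(best) || sol$violations < best$violations ||
        (sol$violations == best$violations && sol$inertia < best$inertia))
      best <- sol
  }
  best
}

#' Select the number of ambiguous groups from an elbow curve
#'
#' The violation curve drops steeply while genuine substitutable groups are
#' still merged and plateaus once they are separated. The selected count is
#' the smallest `k` whose violations are within `tol` (default 5 percent) of
#' the curve's total drop above its minimum; a flat curve selects 1, and
#' curves shorter than 3 points fall back to the argmin. The tolerance sits
#' well below the smallest genuine off-plateau level an evenly covered
#' congruent-branch structure produces (one still-merged pair among four
#' groups leaves about one sixth of the constraints violated) and above the
#' violation noise observed at the true count.
#'
#' @param violations Integer/numeric vector of violation counts for
#'   `k = 1, 2, ...` (in order).
#' @param tol Plateau tolerance as a fraction of the total drop.
#' @return Selected group count (integer).
#' @examples
#' select_n_groups(c(12, 6, 1, 1, 1))  # 3
#' select_n_groups(c(5, 5, 5))         # 1 (flat)
#' select_n_groups(c(9, 0, 0, 0))      # 2
#' @export
select_n_groups <- function(violations, tol = 0.05) {
  stopifnot(length(violations) >= 1L)
  if (length(violations) < 3L) return(which.min(violations))
  vmin <- min(violations)
  drop_total <- violations[1L] - vmin
  if (drop_total <= 0) return(1L)
  for (k in seq_along(violations)) {
    if (violations[k] - vmin <= tol * drop_total) return(k)
  }
  length(violations)
}

#' Aggregate ambiguous pairs into substitutable cell groups
#'
#' Cells supported by at least `min_degree` significant pairs are embedded
#' by 3-D classical MDS of their geodesic submatrix (two dimensions can
#' fold the arms of multifurcating star-like manifolds) and clustered with
#' cannot-link constraints ([cluster_with_constraints()]) for
#' `k = 1 ... Kmax`; the best assignment at `k - 1` is carried forward as a
#' candidate at `k` so the violation curve is non-increasing. The group
#' count is chosen by [select_n_groups()]. Cells below the degree threshold
#' lack the neighbourhood support that genuine manifold ambiguity produces
#' (ambiguous cells are confused alongside their manifold neighbours, not
#' individually) and are treated as unambiguous.
#'
#' @param ambiguity A [ambiguity_pvalues()] result.
#' @param K Geodesic matrix of the same cells.
#' @param Kmax Largest group count tried.
#' @param seed Integer seed.
#' @param min_degree Minimum number of significant pairs a cell must
#'   participate in.
#' @param ... Passed to [cluster_with_constraints()].
#' @return Class `sonata_groups`: list with `groups` (list of cell-index
#'   vectors), `assignment` (length-n integer, `NA` = unambiguous),
#'   `chosen_n_groups`, `elbow` (data.frame `k`, `violations`), `cells`
#'   (clustered cells), `constraints`. Zero significant pairs give an empty
#'   group set (`chosen_n_groups = 0`).
#' @export
find_ambiguous_groups <- function(ambiguity, K, Kmax = 8L, seed = 0L,
                                  min_degree = 5L, ...) {
  stopifnot(inherits(ambiguity, "sonata_ambiguity"))
  check_square(K, "K")
  n <- ambiguity$n_cells
  empty <- structure(list(groups = list(),
                          assignment = rep(NA_integer_, n),
                          chosen_n_groups = 0L,
                          elbow = data.frame(k = integer(), violations = integer()),
                          cells = integer(), constraints = matrix(0L, 0L, 2L)),
                     class = "sonata_groups")
  sp <- significant_pairs(ambiguity)
  if (nrow(sp) == 0L) return(empty)

  deg <- table(factor(c(sp), levels = sort(unique(c(sp)))))
  strong <- as.integer(names(deg))[deg >= min_degree]
  keep <- sp[, 1L] %in% strong & sp[, 2L] %in% strong
  sp <- sp[keep, , drop = FALSE]
  if (nrow(sp) == 0L) return(empty)

  cells <- sort(unique(c(sp)))
  emb <- cmdscale(K[cells, cells, drop = FALSE], k = min(3L, length(cells) - 1L))
  local <- matrix(match(sp, cells), ncol = 2L)

  Kmax <- min(Kmax, length(cells))
  viols <- integer(Kmax)
  sols <- vector("list", Kmax)
  for (k in seq_len(Kmax)) {
    sol <- cluster_with_constraints(emb, local, k,
                                    seed = derive_seed(seed, 31L * k), ...)
    # a k-group assignment may leave groups empty: the best k-1 solution is
    # always admissible, keeping the curve non-increasing
    if (k > 1L) {
      prev <- sols[[k - 1L]]
      if (prev$violations < sol$violations ||
          (prev$violations == sol$violations && prev$inertia < sol$inertia))
        sol <- prev
    }
    sols[[k]] <- sol
    viols[k] <- sol$violations
  }
  chosen <- select_n_groups(viols)
  assign_local <- sols[[chosen]]$assignment
  # relabel groups consecutively in case some ended empty
  lev <- sort(unique(assign_local))
  assign_local <- match(assign_local, lev)

  assignment <- rep(NA_integer_, n)
  assignment[cells] <- assign_local
  groups <- split(cells, assign_local)
  names(groups) <- NULL

  structure(list(groups = groups, assignment = assignment,
                 chosen_n_groups = length(groups),
                 elbow = data.frame(k = seq_len(Kmax), violations = viols),
                 cells = cells, constraints = sp),
            class = "sonata_groups")
}

#' @export
print.sonata_groups <- function(x, ...) {
  if (x$chosen_n_groups == 0L) {
    cat("<sonata_groups> no ambiguous groups (integration not flagged as ambiguous)\n")
  } else {
    cat(sprintf("<sonata_groups> %d groups (sizes %s) over %d ambiguous cells\n",
                x$chosen_n_groups,
                paste(lengths(x$groups), collapse = ", "), length(x$cells)))
  }
  invisible(x)
}
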