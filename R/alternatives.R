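# Alternative integration solutions: soft permutation of ambiguous groups
# applied to an existing cross-modality coupling.

#' Build the soft permutation swapping two ambiguous groups
#'
#' Assembles the n x n matrix that exchanges groups `Gs` and `Gt` according
#' to their self-alignment correspondence: for `i` in `Gs`, row `i` carries
#' the consensus mass `gamma[i, Gt]` (and symmetrically for `i` in `Gt`),
#' every other row is the identity row. Rows in the swapped blocks are then
#' rescaled to sum to one so the product with a coupling remains a
#' transport-like matrix (the raw consensus rows are not stochastic). A
#' cell with no cross-group mass is mapped to the highest-mass cell of the
#' partner group, with a warning.
#'
#' @param Gs,Gt Disjoint, nonempty integer vectors of cell indices.
#' @param self_coupling Symmetric consensus self-coupling matrix.
#' @param n_cells Total number of cells (rows of the coupling to permute).
#' @return Class `sonata_permutation`: the row-stochastic n x n matrix with
#'   attributes `Gs`, `Gt`.
#' @export
build_soft_permutation <- function(Gs, Gt, self_coupling, n_cells) {
  Gs <- as.integer(Gs); Gt <- as.integer(Gt)
  if (length(Gs) == 0L || length(Gt) == 0L)
    stop("`Gs` and `Gt` must be nonempty", call. = FALSE)
  if (length(intersect(Gs, Gt)) > 0L)
    stop("`Gs` and `Gt` must be disjoint", call. = FALSE)
  check_square(self_coupling, "self_coupling")
  if (max(c(Gs, Gt)) > n_cells)
    stop("group indices exceed `n_cells`", call. = FALSE)

  P <- diag(n_cells)
  fill_rows <- function(P, from, to) {
    for (i in from) {
      w <- self_coupling[i, to]
      s <- sum(w)
      if (s <= 0) {
        warning(sprintf(
          "cell %d has no cross-group mass; mapped to the heaviest partner cell", i))
        heavy <- to[which.max(colSums(self_coupling[from, to, drop = FALSE]))]
        w <- as.numeric(to == heavy)
        s <- 1
      }
      P[i, ] <- 0
      P[i, to] <- w / s
    }
    P
  }
  P <- fill_rows(P, Gs, Gt)
  P <- fill_rows(P, Gt, Gs)
  structure(P, Gs = Gs, Gt = Gt, class = c("sonata_permutation", "matrix"))
}

#' Generate alternative cross-modality integration solutions
#'
#' For each unordered pair of ambiguous groups whose mean inter-group
#' consensus mass exceeds the null-spline expectation at the corresponding
#' geodesic distances (group pairs the self-alignment never actually
#' confused yield no candidate), the soft permutation of the pair is
#' applied to the given coupling: `gamma_alt = P %*% gamma_xy`. The
#' original coupling is always returned first, labelled `"original"`, so
#' callers can compare candidates; the package deliberately does not rank
#' them by biological plausibility - candidates reflect geometric
#' resemblance only.
#'
#' @param groups A [find_ambiguous_groups()] result.
#' @param self_coupling Symmetric consensus self-coupling.
#' @param gamma_xy Cross-modality coupling (`sonata_coupling` or matrix)
#'   with as many rows as diagnosed cells.
#' @param K Optional geodesic matrix for the expectation filter.
#' @param spline Optional fitted null spline (with `K`) for the filter;
#'   when either is missing every group pair yields a candidate.
#' @return List of candidates; each is a list with `gamma`, `label`,
#'   `provenance` (`NULL` for the original, else `c(s, t)`).
#' @export
generate_alternatives <- function(groups, self_coupling, gamma_xy,
                                  K = NULL, spline = NULL) {
  stopifnot(inherits(groups, "sonata_groups"))
  G_xy <- if (inherits(gamma_xy, "sonata_coupling")) gamma_xy$gamma else gamma_xy
  n <- nrow(G_xy)
  out <- list(list(gamma = G_xy, label = "original", provenance = NULL))
  ng <- groups$chosen_n_groups
  if (ng < 2L) {
    attr(out, "note") <- "no ambiguity detected"
    return(out)
  }
  check_square(self_coupling, "self_coupling")
  if (nrow(self_coupling) != n)
    stop("`gamma_xy` rows must match the diagnosed modality", call. = FALSE)

  for (s in seq_len(ng - 1L)) {
    for (t in (s + 1L):ng) {
      Gs <- groups$groups[[s]]; Gt <- groups$groups[[t]]
      if (!is.null(K) && !is.null(spline)) {
        obs <- mean(self_coupling[Gs, Gt])
        expd <- mean(predict(spline, as.vector(K[Gs, Gt])))
        if (obs <= expd) next
      }
      P <- build_soft_permutation(Gs, Gt, self_coupling, n)
      out[[length(out) + 1L]] <- list(gamma = unclass(P) %*% G_xy,
                                      label = sprintf("swap_%d_%d", s, t),
                                      provenance = c(s, t))
    }
  }
  out
}
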