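# Integration-quality metrics: FOSCTTM and label transfer accuracy.

cross_sqdist <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  pmax(d2, 0)
}

#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' For each cell of one modality in the shared aligned space, the fraction
#' of other-modality cells lying *strictly* closer than the cell's true
#' match (distance ties count as not-closer); averaged over all cells in
#' both directions. 0 means perfect recovery of the correspondence, 0.5 is
#' the random-pairing level, 1 the worst case.
#'
#' @param x_aligned,y_aligned Aligned embedding matrices (same column
#'   dimension).
#' @param correspondence Two-column matrix of matched (x-row, y-row) index
#'   pairs; defaults to identity when both modalities have the same cell
#'   count.
#' @return A number in `[0, 1]`.
#' @export
foscttm <- function(x_aligned, y_aligned, correspondence = NULL) {
  x_aligned <- as.matrix(x_aligned); y_aligned <- as.matrix(y_aligned)
  if (ncol(x_aligned) != ncol(y_aligned))
    stop("embeddings must share their dimension", call. = FALSE)
  if (is.null(correspondence)) {
    if (nrow(x_aligned) != nrow(y_aligned))
      stop("no correspondence given and cell counts differ; metric undefined",
           call. = FALSE)
    correspondence <- cbind(seq_len(nrow(x_aligned)), seq_len(nrow(x_aligned)))
  }
  correspondence <- matrix(as.integer(correspondence), ncol = 2L)
  D2 <- cross_sqdist(x_aligned, y_aligned)
  ny <- ncol(D2); nx <- nrow(D2)
  fr_x <- apply(correspondence, 1L, function(pr) {
    sum(D2[pr[1L], ] < D2[pr[1L], pr[2L]]) / (ny - 1L)
  })
  fr_y <- apply(correspondence, 1L, function(pr) {
    sum(D2[, pr[2L]] < D2[pr[1L], pr[2L]]) / (nx - 1L)
  })
  mean(c(fr_x, fr_y))
}

# k-NN majority-vote label prediction; ties broken by summed inverse
# distance to the tied labels' voters.
knn_vote <- function(train, train_labels, test, k) {
  D2 <- cross_sqdist(test, train)
  train_labels <- as.character(train_labels)
  apply(D2, 1L, function(row) {
    nb <- order(row)[seq_len(k)]
    votes <- table(train_labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    wt <- vapply(top, function(lb) {
      sum(1 / pmax(sqrt(row[nb][train_labels[nb] == lb]), 1e-12))
    }, numeric(1L))
    top[which.max(wt)]
  })
}

#' Label transfer accuracy (LTA)
#'
#' Each destination cell receives the majority label of its `k` nearest
#' source cells in the aligned space; the accuracy is the fraction of
#' destination cells whose own label is recovered. Both transfer directions
#' are computed; the headline value is their mean.
#'
#' @param x_aligned,y_aligned Aligned embedding matrices.
#' @param labels_x,labels_y Per-cell labels of the two modalities (shared
#'   vocabulary required).
#' @param k Neighbours used in the vote (default 5).
#' @return List with `x_to_y`, `y_to_x` and `mean`.
#' @export
label_transfer_accuracy <- function(x_aligned, y_aligned, labels_x, labels_y,
                                    k = 5L) {
  x_aligned <- as.matrix(x_aligned); y_aligned <- as.matrix(y_aligned)
  labels_x <- as.character(labels_x); labels_y <- as.character(labels_y)
  if (length(labels_x) != nrow(x_aligned) || length(labels_y) != nrow(y_aligned))
    stop("label lengths must match the embeddings", call. = FALSE)
  if (length(intersect(unique(labels_x), unique(labels_y))) == 0L)
    stop("label vocabularies are disjoint; transfer is undefined", call. = FALSE)
  if (k < 1L || k >= nrow(x_aligned) || k >= nrow(y_aligned))
    stop("`k` must satisfy 1 <= k < n_source", call. = FALSE)
  acc_xy <- mean(knn_vote(x_aligned, labels_x, y_aligned, k) == labels_y)
  acc_yx <- mean(knn_vote(y_aligned, labels_y, x_aligned, k) == labels_x)
  list(x_to_y = acc_xy, y_to_x = acc_yx, mean = mean(c(acc_xy, acc_yx)))
}

#' Barycentric projection of a coupling
#'
#' Places the row-modality cells into the column modality's space: each
#' cell goes to the coupling-weighted average of its partners,
#' `diag(1/rowSums(gamma)) %*% gamma %*% y_coords`. This is the standard
#' bridge from a transport plan to an aligned embedding for scoring.
#'
#' @param cpl A `sonata_coupling` or coupling matrix.
#' @param y_coords Coordinates of the column-modality cells.
#' @return Matrix of projected row-modality coordinates.
#' @export
barycentric_projection <- function(cpl, y_coords) {
  G <- if (inherits(cpl, "sonata_coupling")) cpl$gamma else cpl
  y_coords <- as.matrix(y_coords)
  if (ncol(G) != nrow(y_coords))
    stop("coupling columns must match `y_coords` rows", call. = FALSE)
  rs <- rowSums(G)
  rs[rs == 0] <- 1
  (G / rs) %*% y_coords
}

#' Score a cross-modality coupling against known correspondence
#'
#' Projects the row modality barycentrically into the column modality's
#' coordinates and evaluates [foscttm()] (and, when labels are given,
#' [label_transfer_accuracy()]).
#'
#' @param cpl Coupling (`sonata_coupling` or matrix).
#' @param y_coords Column-modality coordinates defining the shared space.
#' @param correspondence Matched index pairs (default identity).
#' @param labels_x,labels_y Optional per-cell labels.
#' @param k Neighbours for the label transfer.
#' @return List with `foscttm` and (if labels given) `lta`.
#' @export
score_coupling <- function(cpl, y_coords, correspondence = NULL,
                           labels_x = NULL, labels_y = NULL, k = 5L) {
  proj <- barycentric_projection(cpl, y_coords)
  out <- list(foscttm = foscttm(proj, as.matrix(y_coords), correspondence))
  if (!is.null(labels_x) && !is.null(labels_y))
    out$lta <- label_transfer_accuracy(proj, as.matrix(y_coords),
                                       labels_x, labels_y, k = k)
  out
}
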