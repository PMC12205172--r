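# Null model: correspondence probability as an antitonic function of
# geodesic distance, and per-pair significance calls against it.

# Equal-count distance bins shared by the spline fit and the
# standardization. Returns an integer bin id per pair.
distance_bins <- function(d, n_bins) {
  n_bins <- max(1L, min(n_bins, floor(length(d) / 5)))
  as.integer(cut(rank(d, ties.method = "first"), n_bins))
}

#' Fit the antitonic null spline of correspondence versus distance
#'
#' Models the expected self-correspondence probability of a cell pair as a
#' monotonically non-increasing function of its geodesic distance: nearby
#' cells naturally exchange transport mass, so only excess mass at *large*
#' distance is evidence of ambiguity. The fit is a cubic smoothing spline on
#' equal-count distance-bin means, projected through pool-adjacent-violators
#' onto the antitonic cone on a 1000-point grid and clamped at zero.
#'
#' @param consensus Symmetric self-coupling matrix (see [self_align()]).
#' @param K Geodesic matrix of the same cells.
#' @param n_bins Number of equal-count distance bins (reduced automatically
#'   for small inputs).
#' @param smoothing Optional `spar` passed to [stats::smooth.spline()].
#' @return Class `sonata_null_spline`: list with `grid_x`, `grid_y`
#'   (non-increasing), `range`, `n_bins_used`, `step_fallback`.
#' @export
fit_null_spline <- function(consensus, K, n_bins = 100L, smoothing = NULL) {
  check_square(consensus, "consensus"); check_square(K, "K")
  if (nrow(consensus) != nrow(K))
    stop("`consensus` and `K` must share dimensions", call. = FALSE)
  ut <- upper.tri(K)
  d <- K[ut]; gam <- consensus[ut]

  grid_x <- seq(min(d), max(d), length.out = 1000L)
  step_fallback <- length(unique(d)) < 10L
  if (step_fallback) {
    warning("fewer than 10 distinct distances; ",
            "falling back to antitonic step-function regression")
    ord <- order(d)
    iso <- isoreg(rev(gam[ord]))$yf  # antitonic = isotonic on reversed order
    fit_x <- d[ord]; fit_y <- rev(iso)
    grid_y <- approx(fit_x, fit_y, xout = grid_x, rule = 2,
                     ties = mean)$y
  } else {
    bins <- distance_bins(d, n_bins)
    bx <- as.numeric(tapply(d, bins, mean))
    by <- as.numeric(tapply(gam, bins, mean))
    fit <- tryCatch(
      if (is.null(smoothing)) smooth.spline(bx, by)
      else smooth.spline(bx, by, spar = smoothing),
      error = function(e) NULL)
    raw <- if (is.null(fit)) approx(bx, by, xout = grid_x, rule = 2)$y
           else predict(fit, grid_x)$y
    grid_y <- rev(isoreg(rev(raw))$yf)  # antitonic projection
  }
  grid_y <- pmax(grid_y, 0)
  # numerical guard: PAV output may carry float wiggle
  grid_y <- rev(cummax(rev(grid_y)))

  structure(list(grid_x = grid_x, grid_y = grid_y,
                 range = range(d),
                 n_bins_used = if (step_fallback) NA_integer_
                               else max(distance_bins(d, n_bins)),
                 step_fallback = step_fallback),
            class = "sonata_null_spline")
}

#' Evaluate a fitted null spline
#'
#' @param object A `sonata_null_spline`.
#' @param newdata Distances at which to evaluate (clamped to fitted range).
#' @param ... Ignored.
#' @return Expected correspondence probabilities.
#' @export
predict.sonata_null_spline <- function(object, newdata, ...) {
  approx(object$grid_x, object$grid_y, xout = newdata, rule = 2)$y
}

#' @export
print.sonata_null_spline <- function(x, ...) {
  cat(sprintf("<sonata_null_spline> range [%.3g, %.3g], f in [%.3g, %.3g]%s\n",
              x$range[1], x$range[2], min(x$grid_y), max(x$grid_y),
              if (x$step_fallback) " (step fallback)" else ""))
  invisible(x)
}

#' Call significantly ambiguous cell pairs
#'
#' For every upper-triangle cell pair, the deviation of its observed
#' consensus self-correspondence from the antitonic null expectation is
#' standardized within equal-count distance bins (median and MAD; the
#' per-bin MAD is floored at the median of the bin MADs so sparse far
#' strata cannot inflate scores) and converted to a one-sided upper-tail
#' normal p-value. A pair is called significant when all of the following
#' hold: `p <= alpha`; the pair's geodesic distance exceeds the
#' `local_quantile` of off-diagonal distances (geometrically close pairs
#' exchange mass for trivial reasons and are never ambiguous in the sense
#' used here); and, with `mass_guard`, the observed mass exceeds the
#' uniform-coupling baseline `1/n^2` (mass below the uninformative level
#' cannot evidence a correspondence).
#'
#' @param consensus Symmetric self-coupling matrix.
#' @param K Geodesic matrix.
#' @param spline Optional fitted [fit_null_spline()]; fitted here if `NULL`.
#' @param alpha Significance cutoff (default 0.01).
#' @param local_quantile Off-diagonal distance quantile below which pairs
#'   are exempt from calls.
#' @param n_bins Equal-count bins for the standardization.
#' @param adjust `"none"` (raw cutoff) or `"BH"` for Benjamini-Hochberg.
#' @param mass_guard Require observed mass above `1/n^2`.
#' @return Class `sonata_ambiguity`: list with `pairs` (data.frame: `i`,
#'   `j` 1-based with `i < j`, `distance`, `observed`, `expected`,
#'   `deviation`, `z`, `p_value`, `significant`), `alpha`,
#'   `local_quantile`, `exclusion_radius`, `n_cells`, `spline`.
#' @export
ambiguity_pvalues <- function(consensus, K, spline = NULL, alpha = 0.01,
                              local_quantile = 0.2, n_bins = 100L,
                              adjust = c("none", "BH"), mass_guard = TRUE) {
  adjust <- match.arg(adjust)
  check_square(consensus, "consensus"); check_square(K, "K")
  n <- nrow(K)
  if (nrow(consensus) != n)
    stop("`consensus` and `K` must share dimensions", call. = FALSE)
  if (max(abs(consensus - t(consensus))) > 1e-8)
    stop("`consensus` must be symmetric", call. = FALSE)
  if (is.null(spline)) spline <- fit_null_spline(consensus, K, n_bins)

  ij <- upper_pairs(n)
  d <- K[ij]; gam <- consensus[ij]
  expected <- predict(spline, d)
  dev <- gam - expected

  bins <- distance_bins(d, n_bins)
  med_b <- as.numeric(tapply(dev, bins, median))
  mad_b <- as.numeric(tapply(dev, bins, mad))
  # floor at the lower-quartile bin MAD: degenerate near-zero spreads in
  # sparse far strata cannot inflate scores, while typical bins keep their
  # own scale (flooring higher makes the test noticeably conservative)
  floor_val <- quantile(mad_b, 0.25, names = FALSE)
  if (max(mad_b) <= 0) {
    warning("zero deviation spread; all p-values set to 0.5")
    z <- rep(0, length(dev))
  } else {
    mad_b <- pmax(mad_b, floor_val)
    if (any(mad_b <= 0)) mad_b[mad_b <= 0] <- max(mad_b)
    z <- (dev - med_b[bins]) / mad_b[bins]
  }
  p <- pnorm(z, lower.tail = FALSE)
  if (adjust == "BH") p <- p.adjust(p, method = "BH")

  offdiag <- K[row(K) != col(K)]
  radius <- as.numeric(quantile(offdiag, local_quantile))
  sig <- p <= alpha & d > radius
  if (mass_guard) sig <- sig & gam > 1 / n^2

  pairs <- data.frame(i = ij[, 1L], j = ij[, 2L], distance = d,
                      observed = gam, expected = expected, deviation = dev,
                      z = z, p_value = p, significant = sig)
  structure(list(pairs = pairs, alpha = alpha,
                 local_quantile = local_quantile,
                 exclusion_radius = radius, n_cells = n, spline = spline),
            class = "sonata_ambiguity")
}

#' @export
print.sonata_ambiguity <- function(x, ...) {
  ns <- sum(x$pairs$significant)
  cat(sprintf(
    "<sonata_ambiguity> %d cells, %d pairs; %d significant (%.2f%%) at alpha = %g\n",
    x$n_cells, nrow(x$pairs), ns, 100 * ns / nrow(x$pairs), x$alpha))
  invisible(x)
}

#' Significant pairs of an ambiguity result
#'
#' @param x A `sonata_ambiguity`.
#' @return Two-column integer matrix of significant pairs (1-based, i < j).
#' @export
significant_pairs <- function(x) {
  stopifnot(inherits(x, "sonata_ambiguity"))
  as.matrix(x$pairs[x$pairs$significant, c("i", "j")])
}
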