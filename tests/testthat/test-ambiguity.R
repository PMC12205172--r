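rand_geodesics <- function(n, seed) {
  set.seed(seed)
  K <- as.matrix(dist(matrix(runif(n * 2), n, 2)))
  K / max(K)
}

test_that("constant consensus fits a constant null", {
  K <- rand_geodesics(40, 1)
  cons <- matrix(0.01, 40, 40); diag(cons) <- 0
  sp <- fit_null_spline(cons, K)
  d <- K[upper.tri(K)]
  expect_true(all(abs(predict(sp, d) - 0.01) < 1e-6))
})

test_that("fitted null tracks the antitonic regression oracle on a
           decreasing signal", {
  K <- rand_geodesics(60, 2)
  set.seed(3)
  g <- pmax(0, 1 - K) + matrix(rnorm(3600, 0, 0.02), 60, 60)
  g <- (g + t(g)) / 2; diag(g) <- 0
  sp <- fit_null_spline(g, K)
  ut <- upper.tri(K)
  bins <- sonata:::distance_bins(K[ut], 100)
  bx <- as.numeric(tapply(K[ut], bins, mean))
  by <- as.numeric(tapply(g[ut], bins, mean))
  oracle <- pav_antitonic(bx, by)
  expect_true(all(abs(predict(sp, oracle$x) - oracle$y) < 0.05))
})

test_that("an increasing signal degenerates toward a constant under the
           antitonic constraint", {
  K <- rand_geodesics(40, 4)
  g <- K * 0.5; diag(g) <- 0  # strictly increasing in distance
  sp <- fit_null_spline(g, K)
  expect_true(all(diff(sp$grid_y) <= 1e-9))
  # non-increasing fit of increasing data: the constraint binds hard
  expect_lt(max(sp$grid_y) - min(sp$grid_y), 0.5 * (max(g) - min(g[g > 0])))
})

test_that("every fitted null is monotonically non-increasing on a fine grid", {
  for (s in 1:20) {
    n <- sample(30:60, 1)
    K <- rand_geodesics(n, s)
    set.seed(s + 100)
    g <- matrix(abs(rnorm(n * n, 0, 0.05)), n, n)
    g <- (g + t(g)) / 2; diag(g) <- 0
    sp <- fit_null_spline(g, K)
    grid <- seq(sp$range[1], sp$range[2], length.out = 1000)
    expect_true(all(diff(predict(sp, grid)) <= 1e-9))
  }
})

test_that("few distinct distances fall back to a step function with warning", {
  K <- matrix(2, 6, 6); K[1:3, 1:3] <- 1; diag(K) <- 0
  cons <- matrix(0.02, 6, 6); diag(cons) <- 0
  expect_warning(sp <- fit_null_spline(cons, K), "distinct distances")
  expect_true(sp$step_fallback)
  expect_true(all(diff(sp$grid_y) <= 1e-9))
})

test_that("p-values behave as a one-sided normal test on the deviations", {
  K <- rand_geodesics(50, 5)
  cons <- make_null_consensus(K, function(d) 0.4 * exp(-2 * d), 0.02, 6)
  amb <- ambiguity_pvalues(cons, K, local_quantile = 0, mass_guard = FALSE)
  p <- amb$pairs
  # a deviation at its bin's null location scores exactly 0.5
  expect_equal(p$p_value[which.min(abs(p$z))], 0.5, tolerance = 0.02)
  # the z -> p map is the standard normal survival function
  expect_equal(p$p_value, pnorm(p$z, lower.tail = FALSE))
  # a standardized deviation of z = 3 sits at p ~ 1.35e-3, inside the 1%
  # cutoff
  expect_equal(pnorm(3, lower.tail = FALSE), 1.35e-3, tolerance = 0.01)
  near3 <- which.min(abs(p$z - 3))
  if (abs(p$z[near3] - 3) < 0.2)
    expect_equal(p$p_value[near3], 1.35e-3, tolerance = 0.05)
  expect_true(all(p$p_value >= 0 & p$p_value <= 1))
})

test_that("pairs inside the local-exclusion radius are never significant", {
  K <- rand_geodesics(50, 7)
  cons <- make_null_consensus(K, function(d) 0.4 * exp(-2 * d), 0.05, 8)
  amb <- ambiguity_pvalues(cons, K, local_quantile = 0.2)
  p <- amb$pairs
  expect_true(all(!p$significant[p$distance <= amb$exclusion_radius]))
  expect_true(all(p$p_value[p$significant] <= amb$alpha))
})

test_that("zero deviation spread yields flat p-values with a warning", {
  K <- rand_geodesics(30, 9)
  cons <- matrix(0.03, 30, 30); diag(cons) <- 0
  expect_warning(amb <- ambiguity_pvalues(cons, K), "spread")
  expect_true(all(amb$pairs$p_value == 0.5))
})

test_that("significant-pair rate is calibrated under the null", {
  # small-n version of the calibration property (the acceptance suite runs
  # the full-size one): rate within 3 binomial SEs of alpha
  K <- rand_geodesics(80, 10)
  f <- function(d) 0.5 * exp(-3 * d)
  npair <- choose(80, 2)
  for (alpha in c(0.05)) {
    rate <- mean(vapply(1:3, function(s) {
      cons <- make_null_consensus(K, f, 0.03, s)
      amb <- ambiguity_pvalues(cons, K, alpha = alpha, local_quantile = 0,
                               mass_guard = FALSE)
      mean(amb$pairs$p_value <= alpha)
    }, numeric(1)))
    se <- sqrt(alpha * (1 - alpha) / npair)
    expect_lt(abs(rate - alpha), 3 * se)
  }
})

test_that("planted mirrored-branch ambiguity dominates the significant pairs", {
  tc <- small_t_diagnosis()
  sp <- significant_pairs(tc$diag$ambiguity)
  labs <- as.character(tc$sim$branch_labels)
  mirrored <- (labs[sp[, 1]] == "branch1" & labs[sp[, 2]] == "branch2") |
              (labs[sp[, 1]] == "branch2" & labs[sp[, 2]] == "branch1")
  expect_gt(nrow(sp), 50)
  expect_gte(mean(mirrored), 0.8)
})

test_that("Benjamini-Hochberg adjustment only shrinks the significant set", {
  K <- rand_geodesics(50, 11)
  cons <- make_null_consensus(K, function(d) 0.4 * exp(-2 * d), 0.05, 12)
  raw <- ambiguity_pvalues(cons, K)
  bh <- ambiguity_pvalues(cons, K, adjust = "BH")
  expect_lte(sum(bh$pairs$significant), sum(raw$pairs$significant))
})
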