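test_that("quadratic loss values enter the objective as expected", {
  # 1x1 spaces: the objective reduces to the scalar loss L(a, b) = (a-b)^2/2
  expect_equal(sonata:::gw_objective(matrix(3), matrix(1), matrix(1)), 2)
  expect_equal(sonata:::gw_objective(matrix(2), matrix(2), matrix(1)), 0)
})

test_that("two identical 2-point spaces give feasible symmetric couplings", {
  K <- matrix(c(0, 1, 1, 0), 2, 2)
  cpl <- gw_coupling(K, K, epsilon = 1e-2)
  expect_equal(rowSums(cpl$gamma), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(colSums(cpl$gamma), c(0.5, 0.5), tolerance = 1e-6)
  # identity and swap attain the same (zero) unregularized objective - the
  # symmetry the entropic blend reflects
  ident <- diag(2) / 2
  swap <- (1 - diag(2)) / 2
  expect_equal(sonata:::gw_objective(K, K, ident), 0)
  expect_equal(sonata:::gw_objective(K, K, swap), 0)
})

test_that("hardened GW on identical distinct-distance spaces matches the
           exhaustive permutation oracle", {
  for (s in 1:6) {
    set.seed(s)
    n <- 5
    X <- matrix(runif(n * 2), n, 2)
    K <- as.matrix(dist(X))
    cpl <- gw_coupling(K, K, epsilon = 1e-3)
    oracle <- gw_perm_oracle(K / max(K), K / max(K))
    expect_equal(as.integer(harden_coupling(cpl)), oracle$perm)
  }
})

test_that("couplings are feasible at 1e-6 on random rectangular instances", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(5:12, 1); m <- sample(5:12, 1)
    K1 <- as.matrix(dist(matrix(runif(n * 2), n, 2)))
    K2 <- as.matrix(dist(matrix(runif(m * 2), m, 2)))
    cpl <- suppressWarnings(gw_coupling(K1, K2, epsilon = 5e-3))
    expect_silent(validate_coupling(cpl))
  }
})

test_that("solver objective is non-increasing across outer iterations", {
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    K1 <- as.matrix(dist(matrix(runif(n * 2), n, 2)))
    K2 <- as.matrix(dist(matrix(runif(n * 2), n, 2)))
    cpl <- suppressWarnings(gw_coupling(K1, K2, epsilon = 5e-3))
    expect_true(all(diff(cpl$objective_trace) <= 1e-8))
  }
})

test_that("rescaling both spaces scales the objective by c^2 and leaves the
           coupling pattern unchanged", {
  # quadratic loss: L(c a, c b) = c^2 L(a, b), so the optimal objective
  # scales by c^2 while the coupling (and its argmax pattern) is invariant
  # when epsilon is scaled along
  set.seed(4)
  n <- 6
  K <- as.matrix(dist(matrix(runif(n * 2), n, 2)))
  c0 <- 3
  a <- gw_coupling(K, K, epsilon = 1e-4, normalize = FALSE)
  b <- gw_coupling(c0 * K, c0 * K, epsilon = 1e-4 * c0^2, normalize = FALSE)
  expect_equal(harden_coupling(a), harden_coupling(b))
  expect_equal(b$objective / a$objective, c0^2, tolerance = 0.05)
})

test_that("non-square distance matrices are rejected", {
  expect_error(gw_coupling(matrix(0, 3, 2), matrix(0, 3, 3)), "square")
  expect_error(gw_coupling(matrix(0, 3, 3), matrix(0, 3, 3),
                           p = c(1, 0, 0)), "positive")
})

test_that("self-alignment of an unperturbed modality keeps mass near the
           identity and yields a symmetric unit-mass consensus", {
  set.seed(6)
  # quadratically spaced arc positions: the decaying point density breaks
  # the head-to-tail flip isometry a uniform curve would have, so the
  # identity is the single optimal self-map
  pos <- seq(0, 1, length.out = 40)^1.7
  lat <- cbind(pos, 0.3 * pos^2)
  X <- lat %*% t(qr.Q(qr(matrix(rnorm(40), 20, 2)))) * sqrt(20)
  sa <- self_align(X, n_replicates = 1, noise_sd = 0, n_starts = 1, seed = 1,
                   k_base = 5, k_schedule = 5)
  expect_equal(sum(sa$consensus), 1, tolerance = 1e-8)
  expect_equal(sa$consensus, t(sa$consensus))
  expect_true(all(sa$consensus >= 0))
  n <- nrow(sa$consensus)
  expect_equal(rowSums(sa$consensus), rep(1 / n, n), tolerance = 1e-6)
  # the self-map is the identity up to entropic blur: the hardened map
  # tracks the diagonal and most row mass sits in a near-diagonal band
  hard <- harden_coupling(sa$consensus)
  expect_lt(mean(abs(hard - seq_len(n))), 2)
  expect_gt(cor(hard, seq_len(n), method = "spearman"), 0.95)
  band <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - 3):min(n, i + 3)
    sum(sa$consensus[i, idx]) / sum(sa$consensus[i, ])
  }, numeric(1))
  expect_gt(mean(band), 0.6)
})

test_that("self-alignment consensus concentrates off-diagonal mass between
           mirrored branches", {
  tc <- small_t_diagnosis()
  cons <- tc$diag$selfalign$consensus
  labs <- as.character(tc$sim$branch_labels)
  K <- tc$diag$selfalign$geodesic
  far <- K > quantile(K[upper.tri(K)], 0.3)
  mirrored <- outer(labs, labs, function(a, b)
    (a == "branch1" & b == "branch2") | (a == "branch2" & b == "branch1"))
  other <- outer(labs, labs, function(a, b)
    xor(a == "branch3", b == "branch3"))
  expect_gt(mean(cons[mirrored & far]), mean(cons[other & far]))
})

test_that("cross-modality alignment of a modality with itself hardens to the
           identity", {
  set.seed(8)
  lat <- cbind(seq(0, 1, length.out = 30), sin(seq(0, 2, length.out = 30)))
  X <- lat %*% t(qr.Q(qr(matrix(rnorm(60), 30, 2)))) * sqrt(30)
  cpl <- cross_modality_align(X, X, k = 5, epsilon = 1e-3)
  expect_equal(as.integer(harden_coupling(cpl)), 1:30)
  expect_silent(validate_coupling(cpl))
})

test_that("entropic continuation recovers the global optimum on
           near-symmetric small instances", {
  set.seed(104)  # an instance where the plain product start lands in the
  n <- 4         # second-best basin
  X <- matrix(runif(n * 2), n, 2)
  K1 <- as.matrix(dist(X))
  K2 <- as.matrix(dist(X + matrix(rnorm(n * 2, 0, 0.02), n, 2)))
  plain <- gw_coupling(K1, K2, epsilon = 1e-3)
  annealed <- gw_coupling(K1, K2, epsilon = 1e-3,
                          anneal = c(0.05, 0.02, 0.01, 5e-3, 2e-3))
  oracle <- gw_perm_oracle(K1 / max(K1), K2 / max(K2))
  expect_equal(as.integer(harden_coupling(annealed)), oracle$perm)
  expect_lte(annealed$objective, plain$objective + 1e-12)
})
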