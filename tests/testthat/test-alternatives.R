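test_that("a 1x1 swapped block normalizes to a hard swap", {
  cons <- matrix(0, 3, 3)
  cons[1, 2] <- cons[2, 1] <- 0.37
  P <- build_soft_permutation(1L, 2L, cons, 3L)
  expect_equal(unclass(P),
               rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)),
               ignore_attr = TRUE)
})

test_that("soft permutations are row-stochastic with identity outside the
           swapped groups", {
  set.seed(1)
  for (s in 1:5) {
    n <- 10
    cons <- matrix(runif(n * n, 0.01, 1), n, n)
    cons <- (cons + t(cons)) / 2
    Gs <- 1:3; Gt <- 4:7
    P <- build_soft_permutation(Gs, Gt, cons, n)
    expect_equal(rowSums(P), rep(1, n), ignore_attr = TRUE)
    expect_equal(unclass(P)[8:10, ], diag(n)[8:10, ])
    expect_true(all(P[Gs, setdiff(1:n, Gt)] == 0))
    expect_true(all(P[Gt, setdiff(1:n, Gs)] == 0))
  }
})

test_that("a permutation-structured block gives a hard involutive swap", {
  # exhaustive over all equal-size disjoint group pairs of 5 cells
  n <- 5
  idx <- seq_len(n)
  for (sz in 1:2) {
    gs_sets <- combn(idx, sz, simplify = FALSE)
    for (Gs in gs_sets) {
      rest <- setdiff(idx, Gs)
      for (Gt in combn(rest, sz, simplify = FALSE)) {
        for (shift in seq_len(sz)) {
          cons <- matrix(0, n, n)
          perm <- ((seq_len(sz) + shift - 2L) %% sz) + 1L
          for (a in seq_len(sz)) {
            cons[Gs[a], Gt[perm[a]]] <- 0.3
            cons[Gt[perm[a]], Gs[a]] <- 0.3
          }
          P <- unclass(build_soft_permutation(Gs, Gt, cons, n))
          expect_true(all(P %in% c(0, 1)))
          expect_equal(P %*% P, diag(n))
        }
      }
    }
  }
})

test_that("cells without cross-group mass map to the heaviest partner cell
           with a warning", {
  cons <- matrix(0, 4, 4)
  cons[1, 3] <- cons[3, 1] <- 0.5
  cons[2, 3] <- cons[3, 2] <- 0   # cell 2 has no mass into Gt
  expect_warning(P <- build_soft_permutation(c(1L, 2L), 3L, cons, 4L),
                 "no cross-group mass")
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unclass(P)[2, 3], 1)
})

test_that("alternatives are exact matrix products preserving total mass", {
  set.seed(3)
  n <- 12; m <- 9
  cons <- matrix(runif(n * n, 0.01, 1), n, n); cons <- (cons + t(cons)) / 2
  G_xy <- matrix(runif(n * m), n, m); G_xy <- G_xy / sum(G_xy)
  groups <- structure(list(
    groups = list(1:4, 5:8), assignment = c(rep(1L, 4), rep(2L, 4), rep(NA, 4)),
    chosen_n_groups = 2L, elbow = data.frame(k = 1:2, violations = c(5L, 0L)),
    cells = 1:8, constraints = matrix(0L, 0, 2)), class = "sonata_groups")
  alts <- generate_alternatives(groups, cons, G_xy)
  expect_length(alts, 2L)
  expect_equal(alts[[1]]$label, "original")
  P <- build_soft_permutation(1:4, 5:8, cons, n)
  expect_equal(alts[[2]]$gamma, unclass(P) %*% G_xy)
  # exact mass conservation holds when the swapped block is doubly
  # stochastic, as for a hard (permutation-structured) swap
  hard_cons <- matrix(0, n, n)
  hard_cons[cbind(1:4, 5:8)] <- 0.25
  hard_cons <- hard_cons + t(hard_cons)
  Ph <- build_soft_permutation(1:4, 5:8, hard_cons, n)
  expect_equal(sum(unclass(Ph) %*% G_xy), sum(G_xy), tolerance = 1e-9)
  # row-normalized soft swaps stay close to mass-preserving
  expect_equal(sum(alts[[2]]$gamma), sum(G_xy), tolerance = 0.05)
})

test_that("candidate counts follow the unordered group pairs", {
  set.seed(4)
  n <- 12
  cons <- matrix(runif(n * n, 0.1, 1), n, n); cons <- (cons + t(cons)) / 2
  G_xy <- diag(n) / n
  mk_groups <- function(glist) {
    assignment <- rep(NA_integer_, n)
    for (i in seq_along(glist)) assignment[glist[[i]]] <- i
    structure(list(groups = glist, assignment = assignment,
                   chosen_n_groups = length(glist),
                   elbow = data.frame(), cells = sort(unlist(glist)),
                   constraints = matrix(0L, 0, 2)), class = "sonata_groups")
  }
  expect_length(generate_alternatives(mk_groups(list(1:3, 4:6)), cons, G_xy), 2L)
  expect_length(generate_alternatives(
    mk_groups(list(1:3, 4:6, 7:9, 10:12)), cons, G_xy), 7L)  # 1 + C(4,2)
  empty <- mk_groups(list())
  alts <- generate_alternatives(empty, cons, G_xy)
  expect_length(alts, 1L)
  expect_equal(attr(alts, "note"), "no ambiguity detected")
})

test_that("the expectation filter drops group pairs the self-alignment never
           confused", {
  n <- 12
  K <- as.matrix(dist(matrix(seq_len(n), ncol = 1))); K <- K / max(K)
  cons <- 0.2 * exp(-6 * K); diag(cons) <- 0  # mass decays with distance
  # groups 1 and 3 are far apart with no excess mass between them
  glist <- list(1:4, 5:8, 9:12)
  assignment <- rep(1:3, each = 4)
  groups <- structure(list(groups = glist, assignment = assignment,
                           chosen_n_groups = 3L, elbow = data.frame(),
                           cells = 1:n, constraints = matrix(0L, 0, 2)),
                      class = "sonata_groups")
  spline <- fit_null_spline(cons, K)
  alts <- generate_alternatives(groups, cons, diag(n) / n, K = K,
                                spline = spline)
  expect_lt(length(alts), 1L + choose(3, 2))
})
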