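# Simulated two-modality benchmarks: branched manifolds with planted
# ambiguity and an unambiguous decay-density path.

# Arc positions shared by congruent branches make the planted congruence
# exact in latent space (identical point sets up to the generating
# rotation/reflection), so the ambiguity ground truth is unambiguous.
branch_skeleton <- function(shape, n, seed) {
  n_branch <- if (shape == "x_branch") 4L else 3L
  if (n %% n_branch != 0L)
    stop(sprintf("`n` must be divisible by %d for shape '%s'",
                 n_branch, shape), call. = FALSE)
  np <- n %/% n_branch
  s <- with_seed(seed, sort(runif(np)))
  if (shape == "t_branch") {
    # two congruent unit arms along +-x and a shorter (0.5), denser stem:
    # a 3-star with three EQUAL arms would be fully S3-symmetric and plant
    # three-fold ambiguity; the short stem keeps the planted congruence
    # pairwise between the two arms only
    s_stem <- with_seed(derive_seed(seed, 1L), sort(runif(np)))
    lat <- rbind(cbind(-s, 0), cbind(s, 0), cbind(0, -0.5 * s_stem))
  } else if (shape == "y_branch") {
    ang <- pi / 2 + c(0, 2, 4) * pi / 3
    lat <- do.call(rbind, lapply(ang, function(a) cbind(s * cos(a), s * sin(a))))
  } else if (shape == "x_branch") {
    ang <- c(0, pi / 2, pi, 3 * pi / 2)
    lat <- do.call(rbind, lapply(ang, function(a) cbind(s * cos(a), s * sin(a))))
  } else stop(sprintf("unknown shape '%s'", shape), call. = FALSE)
  list(latent = lat,
       labels = factor(rep(paste0("branch", seq_len(n_branch)), each = np)),
       n_branch = n_branch)
}

# Random linear lift with orthonormalized columns, scaled so per-feature
# signal variance is O(1) and an absolute noise sd of 0.1 is a 10 percent
# perturbation; the lift is an isometry of the latent geometry up to the
# global sqrt(p) scale.
lift_map <- function(p_dim, seed) {
  with_seed(seed, qr.Q(qr(matrix(rnorm(2L * p_dim), p_dim, 2L)))) * sqrt(p_dim)
}

lift_modality <- function(latent, p_dim, noise_sd, seed) {
  Q <- lift_map(p_dim, seed)
  X <- latent %*% t(Q)
  if (noise_sd > 0)
    X <- X + with_seed(derive_seed(seed, 7L),
                       matrix(rnorm(length(X), 0, noise_sd),
                              nrow(X), p_dim))
  X
}

finish_pair <- function(latent, labels, shape, px, py, noise_sd, seed) {
  n <- nrow(latent)
  X <- lift_modality(latent, px, noise_sd, derive_seed(seed, 100L))
  Y <- lift_modality(latent, py, noise_sd, derive_seed(seed, 200L))
  structure(list(
    modality_x = modality(X, labels = labels),
    modality_y = modality(Y, labels = labels),
    manifold_coords_x = latent, manifold_coords_y = latent,
    correspondence = cbind(seq_len(n), seq_len(n)),
    branch_labels = labels, shape = shape,
    noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sonata_simpair")
}

#' @export
print.sonata_simpair <- function(x, ...) {
  cat(sprintf("<sonata_simpair> '%s': %d cells, %d + %d features, noise_sd %g\n",
              x$shape, nrow(x$modality_x$matrix),
              ncol(x$modality_x$matrix), ncol(x$modality_y$matrix),
              x$noise_sd))
  invisible(x)
}

#' Simulate a branched two-modality benchmark with planted ambiguity
#'
#' Cells lie on a shared 2-D branch skeleton mimicking bifurcating or
#' multifurcating differentiation: `"t_branch"` (two congruent collinear
#' arms plus a shorter stem; two resembling branches), `"y_branch"` (three
#' congruent arms at 120 degrees) or `"x_branch"` (four congruent arms at
#' 90 degrees). Congruent branches share identical arc positions, so the
#' planted resemblance is exact before noise. Each modality lifts the
#' latent coordinates through an independent random orthonormal linear map
#' to its own feature dimension and adds i.i.d. Gaussian feature noise.
#' The two modalities share cells (identity correspondence) but no
#' features.
#'
#' @param shape One of `"t_branch"`, `"y_branch"`, `"x_branch"`.
#' @param n Cells per modality (divisible by the branch count).
#' @param px,py Feature dimensions of the two modalities.
#' @param noise_sd Feature noise standard deviation.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Class `sonata_simpair`: `modality_x`, `modality_y`,
#'   `manifold_coords_x`, `manifold_coords_y`, `correspondence`,
#'   `branch_labels`, `shape`, `seed`.
#' @examples
#' sim <- simulate_branch_dataset("t_branch", n = 30, px = 40, py = 50, seed = 1)
#' sim
#' @export
simulate_branch_dataset <- function(shape = c("t_branch", "y_branch", "x_branch"),
                                    n = 300L, px = 1000L, py = 2000L,
                                    noise_sd = 0.1, seed = 0L) {
  shape <- match.arg(shape)
  sk <- branch_skeleton(shape, n, derive_seed(seed, 3L))
  finish_pair(sk$latent, sk$labels, shape, px, py, noise_sd, seed)
}

#' Simulate the unambiguous decay-path benchmark
#'
#' Cells trace a single hook-shaped arc (a straight run ending in a
#' half-circle bend) with sampling density decaying along the arc:
#' positions are drawn by exponential thinning so the first arc-length
#' quartile holds about `decay_ratio` times as many cells as the last. The
#' decaying density breaks the head-to-tail flip symmetry that any
#' uniform-density curve would retain in its intrinsic geodesic metric, so
#' the dataset has no planted ambiguity - the negative control. Lifting
#' and noise as in [simulate_branch_dataset()]; labels record the
#' arc-length quartile.
#'
#' @inheritParams simulate_branch_dataset
#' @param decay_ratio Target head-to-tail density ratio.
#' @return A `sonata_simpair` with shape `"decay_path"`.
#' @export
simulate_decay_path <- function(n = 300L, px = 1000L, py = 2000L,
                                noise_sd = 0.1, seed = 0L, decay_ratio = 4) {
  lambda <- log(decay_ratio)
  u <- with_seed(derive_seed(seed, 3L), runif(n))
  s <- sort(-log(1 - u * (1 - exp(-lambda))) / lambda)  # arc position, in [0,1]

  # straight run of length 0.6, then a half-circle hook of arc length 0.4
  r <- 0.4 / pi
  straight <- s <= 0.6
  lat <- matrix(0, n, 2L)
  lat[straight, ] <- cbind(0, s[straight])
  phi <- (s[!straight] - 0.6) / r
  lat[!straight, ] <- cbind(r - r * cos(phi), 0.6 + r * sin(phi))

  labels <- factor(paste0("q", findInterval(s, c(0.25, 0.5, 0.75)) + 1L),
                   levels = paste0("q", 1:4))
  finish_pair(lat, labels, "decay_path", px, py, noise_sd, seed)
}
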