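# End-to-end orchestration: configuration, in-memory diagnosis, and the
# file-based pipeline behind the command-line interface.

#' Pipeline configuration with package defaults
#'
#' Collects every tunable of the diagnosis chain in one list. Any field can
#' be overridden by name; unknown fields are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return Class `sonata_config` (a named list).
#' @export
sonata_config <- function(...) {
  cfg <- list(
    k_base = NULL,          # reference graph neighbours; default 0.1 n
    n_replicates = 10L,     # variational copies in self-alignment
    noise_sd = 0.1,         # relative per-feature noise of the copies
    k_schedule = NULL,      # neighbour ladder; default floor(c(.05,.1,.2) n)
    epsilon = 5e-3,         # entropic regularization (max-normalized K)
    n_starts = 4L,          # solver initializations per replicate
    alpha = 0.01,           # significance cutoff on ambiguous pairs
    local_quantile = 0.2,   # local-pair exclusion radius quantile
    n_bins = 100L,          # distance bins for spline fit / standardization
    adjust = "none",        # or "BH"
    Kmax = 8L,              # largest group count tried
    min_degree = 5L,        # constraint support required per cell
    lta_k = 5L,             # neighbours for label transfer
    seed = 0L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop(sprintf("unknown configuration field(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "sonata_config")
}

#' @export
print.sonata_config <- function(x, ...) {
  cat("<sonata_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (is.null(v)) "(auto)" else paste(v, collapse = " ")))
  }
  invisible(x)
}

#' Diagnose a modality for manifold ambiguity
#'
#' Runs the full chain on one modality: geodesic manifold construction and
#' self-alignment ([self_align()]), the antitonic null and per-pair
#' significance calls ([ambiguity_pvalues()]), constrained grouping
#' ([find_ambiguous_groups()]), and - when a cross-modality coupling is
#' supplied - alternative integration solutions
#' ([generate_alternatives()]).
#'
#' @param m The modality to diagnose ([modality()] or matrix).
#' @param config A [sonata_config()].
#' @param gamma_xy Optional cross-modality coupling to re-route.
#' @return Class `sonata_diagnosis`: list with `selfalign`, `ambiguity`,
#'   `groups`, `alternatives` (or `NULL`), `ambiguous` (logical), `config`.
#' @examples
#' \donttest{
#' sim <- simulate_branch_dataset("t_branch", n = 120, px = 150, py = 200,
#'                                seed = 1)
#' diag <- sonata_diagnose(sim$modality_x,
#'                         sonata_config(n_replicates = 4, seed = 1))
#' diag
#' }
#' @export
sonata_diagnose <- function(m, config = sonata_config(), gamma_xy = NULL) {
  stopifnot(inherits(config, "sonata_config"))
  m <- as_modality(m)
  sa <- self_align(m,
                   n_replicates = config$n_replicates,
                   noise_sd = config$noise_sd,
                   k_schedule = config$k_schedule,
                   epsilon = config$epsilon,
                   seed = derive_seed(config$seed, 1L),
                   n_starts = config$n_starts,
                   k_base = config$k_base)
  amb <- ambiguity_pvalues(sa$consensus, sa$geodesic,
                           alpha = config$alpha,
                           local_quantile = config$local_quantile,
                           n_bins = config$n_bins,
                           adjust = config$adjust)
  grp <- find_ambiguous_groups(amb, sa$geodesic, Kmax = config$Kmax,
                               seed = derive_seed(config$seed, 2L),
                               min_degree = config$min_degree)
  # a diagnosis is raised only when the significant-pair rate clearly
  # exceeds what the alpha-level test produces by chance (2 * alpha) AND at
  # least two substitutable groups emerge
  sig_fraction <- mean(amb$pairs$significant)
  ambiguous <- grp$chosen_n_groups >= 2L && sig_fraction > 2 * config$alpha
  alts <- if (!is.null(gamma_xy)) {
    grp_used <- if (ambiguous) grp else {
      g0 <- grp
      g0$groups <- list()
      g0$chosen_n_groups <- 0L
      g0
    }
    generate_alternatives(grp_used, sa$consensus, gamma_xy,
                          K = sa$geodesic, spline = amb$spline)
  }
  structure(list(selfalign = sa, ambiguity = amb, groups = grp,
                 alternatives = alts,
                 ambiguous = ambiguous, sig_fraction = sig_fraction,
                 config = config),
            class = "sonata_diagnosis")
}

#' @export
print.sonata_diagnosis <- function(x, ...) {
  ns <- sum(x$ambiguity$pairs$significant)
  cat("<sonata_diagnosis>\n")
  cat(sprintf("  significant ambiguous pairs: %d (%.2f%% of pairs)\n",
              ns, 100 * ns / nrow(x$ambiguity$pairs)))
  if (x$ambiguous) {
    cat(sprintf("  integration FLAGGED as ambiguous: %d substitutable groups (sizes %s)\n",
                x$groups$chosen_n_groups,
                paste(lengths(x$groups$groups), collapse = ", ")))
  } else {
    cat("  integration not flagged as ambiguous\n")
  }
  if (!is.null(x$alternatives))
    cat(sprintf("  candidate solutions: %d (including the original)\n",
                length(x$alternatives)))
  invisible(x)
}

#' Run the file-based diagnosis pipeline
#'
#' Reads the modality (and optional coupling), runs [sonata_diagnose()],
#' and writes every artifact - consensus and geodesic matrices, per-pair
#' calls, groups, elbow curve, null spline, alternative couplings, the
#' resolved configuration and a human-readable summary - into `out_dir`.
#'
#' @param data_path Modality matrix file (TSV/CSV/MTX).
#' @param out_dir Output directory (created if missing).
#' @param config A [sonata_config()].
#' @param coupling_path Optional cross-modality coupling to diagnose.
#' @param labels_path Optional per-cell label file.
#' @param format,header,id_column Passed to [read_modality()].
#' @return The `sonata_diagnosis`, invisibly.
#' @export
run_pipeline <- function(data_path, out_dir, config = sonata_config(),
                         coupling_path = NULL, labels_path = NULL,
                         format = "auto", header = FALSE, id_column = FALSE) {
  t0 <- Sys.time()
  m <- read_modality(data_path, format = format, header = header,
                     id_column = id_column, labels_file = labels_path)
  gamma_xy <- if (!is.null(coupling_path)) read_coupling(coupling_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  resolved <- config
  resolved$k_base <- resolved$k_base %||% max(5L, floor(0.1 * nrow(m$matrix)))
  resolved$k_schedule <- resolved$k_schedule %||%
    pmax(3L, floor(c(0.05, 0.1, 0.2) * nrow(m$matrix)))
  jsonlite::write_json(unclass(resolved), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  diag <- sonata_diagnose(m, config, gamma_xy = gamma_xy)

  write.table(diag$selfalign$consensus, file.path(out_dir, "consensus.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(diag$selfalign$geodesic, file.path(out_dir, "geodesic.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  write_ambiguity(diag$ambiguity, file.path(out_dir, "ambiguity.tsv"))
  write_null_spline(diag$ambiguity$spline, file.path(out_dir, "null_spline.json"))
  write_groups(diag$groups, file.path(out_dir, "groups.tsv"))
  write_elbow(diag$groups, file.path(out_dir, "elbow.tsv"))

  manifest <- list(n_candidates = 0L, candidates = list())
  if (!is.null(diag$alternatives)) {
    for (cand in diag$alternatives) {
      fn <- if (cand$label == "original") "original.tsv"
            else sprintf("alt_%d_%d.tsv", cand$provenance[1L] - 1L,
                         cand$provenance[2L] - 1L)
      write_coupling(cand$gamma, file.path(out_dir, fn))
      manifest$candidates[[length(manifest$candidates) + 1L]] <-
        list(file = fn, label = cand$label,
             provenance = if (is.null(cand$provenance)) NULL
                          else cand$provenance - 1L)
    }
    manifest$n_candidates <- length(diag$alternatives)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  summary_lines <- c(
    sprintf("cells: %d", nrow(m$matrix)),
    sprintf("significant ambiguous pairs: %d of %d",
            sum(diag$ambiguity$pairs$significant), nrow(diag$ambiguity$pairs)),
    if (diag$ambiguous)
      sprintf("integration FLAGGED as ambiguous: %d substitutable groups",
              diag$groups$chosen_n_groups)
    else "integration not flagged as ambiguous",
    if (!is.null(diag$alternatives))
      sprintf("candidate solutions (incl. original): %d",
              length(diag$alternatives)),
    sprintf("seed: %s", config$seed),
    sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  message(paste(summary_lines, collapse = "\n"))
  invisible(diag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
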