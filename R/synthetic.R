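# Synthetic benchmark data: expression matrices with planted,
# pathway-structured linear age effects, so the whole pipeline is testable
# without access-restricted cohort data.

#' Simulate an expression/age dataset with planted pathway age effects
#'
#' Linear-Gaussian generative model. Ages are drawn uniformly on `age_range`
#' (default 30-89 years, matching the modeled cohort). Pathways partition the
#' gene universe, optionally sharing `n_overlap` genes between consecutive
#' pathways ("crossroads" genes). Genes in the first `n_planted` pathways
#' carry a linear age effect: `x = b0 + b1 * age + N(0, sigma)`; all other
#' genes are age-independent noise around `b0`. The generated matrix is on
#' log2 scale (set `tpm_scale = TRUE` to exponentiate it to TPM-like values
#' for ingestion testing).
#'
#' @param n_samples Number of samples.
#' @param n_pathways Number of pathways.
#' @param genes_per_pathway Genes per pathway.
#' @param n_overlap Genes shared between consecutive pathways.
#' @param n_planted Number of pathways whose genes carry the age effect.
#' @param slope Per-gene age slope `b1` in expression units per year.
#' @param baseline Baseline log2 expression `b0`.
#' @param noise_sd Residual standard deviation `sigma` (> 0).
#' @param age_range Length-2 vector, minimum and maximum age in years.
#' @param nonlinear If `TRUE`, planted genes additionally carry a small
#'   quadratic age term, exercising the benefit of hidden layers.
#' @param tpm_scale If `TRUE`, return `2^x - 1` (linear TPM-like scale).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A list of class `aging_sim`: `expr` (samples x genes matrix),
#'   `ages` (named vector), `membership` (`membership_matrix`), and `truth`
#'   (planted pathways/genes, slopes, generator settings).
#' @export
simulate_aging_dataset <- function(n_samples = 500L, n_pathways = 4L,
                                   genes_per_pathway = 40L, n_overlap = 0L,
                                   n_planted = 1L, slope = 0.05,
                                   baseline = 5, noise_sd = 1,
                                   age_range = c(30, 89),
                                   nonlinear = FALSE, tpm_scale = FALSE,
                                   seed = 1L) {
  stopifnot(n_samples >= 2L, n_pathways >= 1L, genes_per_pathway >= 1L,
            n_overlap >= 0L, n_overlap < genes_per_pathway,
            n_planted >= 0L, n_planted <= n_pathways, noise_sd > 0,
            length(age_range) == 2L, age_range[2L] > age_range[1L])
  n_genes <- n_pathways * genes_per_pathway - (n_pathways - 1L) * n_overlap
  genes <- sprintf("g%04d", seq_len(n_genes))
  pathways <- sprintf("PW%02d", seq_len(n_pathways))
  m <- matrix(0L, n_genes, n_pathways, dimnames = list(genes, pathways))
  start <- 1L
  for (p in seq_len(n_pathways)) {
    m[start:(start + genes_per_pathway - 1L), p] <- 1L
    start <- start + genes_per_pathway - n_overlap
  }
  membership <- new_membership(m)
  planted_pathways <- pathways[seq_len(n_planted)]
  planted_genes <- if (n_planted > 0L) {
    rownames(m)[rowSums(m[, planted_pathways, drop = FALSE]) > 0L]
  } else character(0)
  slopes <- stats::setNames(rep(0, n_genes), genes)
  slopes[planted_genes] <- slope
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  ages <- stats::runif(n_samples, age_range[1L], age_range[2L])
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  names(ages) <- sample_ids
  expr <- outer(ages, slopes) + baseline +
    matrix(stats::rnorm(n_samples * n_genes, sd = noise_sd),
           n_samples, n_genes)
  if (nonlinear) {
    quad <- outer((ages - mean(age_range))^2 / 100,
                  slopes / 2)
    expr <- expr + quad
  }
  dimnames(expr) <- list(sample_ids, genes)
  if (tpm_scale) expr <- pmax(2^expr - 1, 0)
  structure(list(expr = expr, ages = ages, membership = membership,
                 truth = list(planted_pathways = planted_pathways,
                              planted_genes = planted_genes,
                              slopes = slopes, baseline = baseline,
                              noise_sd = noise_sd, age_range = age_range,
                              nonlinear = nonlinear,
                              scale = if (tpm_scale) "linear" else "log2",
                              seed = seed)),
            class = "aging_sim")
}

#' @export
print.aging_sim <- function(x, ...) {
  cat("Synthetic aging dataset:", nrow(x$expr), "samples x", ncol(x$expr),
      "genes (", x$truth$scale, "scale )\n")
  cat("  pathways:", ncol(x$membership), "; planted:",
      if (length(x$truth$planted_pathways)) {
        paste(x$truth$planted_pathways, collapse = ", ")
      } else "none",
      sprintf("(slope %g / year, sd %g)\n", max(x$truth$slopes),
              x$truth$noise_sd))
  invisible(x)
}

#' Derive a synthetic differential-expression signature from planted truth
#'
#' Builds a signature on the planted genes whose log2 fold-changes push
#' expression toward older-age (direction `"aging"`) or younger-age
#' (`"rejuvenating"`) values given the planted slopes; FDR is set to 0.001
#' so every record passes the default filter.
#'
#' @param truth The `truth` component of [simulate_aging_dataset()].
#' @param direction `"aging"` or `"rejuvenating"`.
#' @param magnitude Absolute log2 fold-change applied to each planted gene.
#' @return An `aging_signature`.
#' @export
simulate_signature <- function(truth, direction = c("aging", "rejuvenating"),
                               magnitude = 2) {
  direction <- match.arg(direction)
  genes <- truth$planted_genes
  if (length(genes) == 0L) stop("truth record has no planted genes")
  sgn <- sign(truth$slopes[genes])
  sgn[sgn == 0] <- 1
  fc <- magnitude * sgn * if (direction == "aging") 1 else -1
  signature_table(genes, unname(fc), rep(0.001, length(genes)),
                  label = paste0("synthetic-", direction),
                  species = "synthetic")
}
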