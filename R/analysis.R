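# Statistical interpretation: pathway-age correlation ranking against the
# random-gene control pathway, age-stratified perturbation tests, the
# crossroads association, and the tSNE pathway landscape.

#' Pearson correlation of pathway activations with age
#'
#' @param activations Samples x pathways matrix of pathway-neuron
#'   activations.
#' @param ages Chronological ages aligned to the rows.
#' @return Named vector of Pearson correlation coefficients.
#' @export
activation_age_correlation <- function(activations, ages) {
  stopifnot(is.matrix(activations), nrow(activations) == length(ages))
  if (nrow(activations) < 3L) stop("need at least 3 samples")
  if (stats::sd(ages) == 0) stop("ages have zero variance")
  sds <- apply(activations, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance activation in pathway(s): ",
         paste(colnames(activations)[sds == 0], collapse = ", "))
  }
  drop(stats::cor(activations, ages))
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down Holm adjustment: p-values are sorted ascending, multiplied by
#' `m - i + 1`, made monotone non-decreasing, capped at 1, and returned in
#' the original order.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02 0.04
#' @export
holm_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "holm")
}

#' Rank pathways against the random-gene control pathway
#'
#' Repeats the full training protocol `n_permutations` times; in each
#' permutation a fresh artificial control pathway of randomly sampled genes
#' is appended, a clock is trained, and every pathway's Pearson correlation
#' between its activation and chronological age is computed on the held-out
#' test fold. Each real pathway's correlation distribution is then compared
#' with the control's using a one-sided Wilcoxon rank-sum test (alternative:
#' greater), Holm-adjusted across pathways. Pathways whose adjusted p is
#' small capture the aging state significantly better than random genes.
#'
#' The published protocol uses 100 permutations and the full ensemble; that
#' is expensive, so permutation count, member count and epochs are all
#' arguments, allowing scaled-down runs.
#'
#' @param expr Samples x genes matrix.
#' @param ages Ages aligned to rows (or named by sample ID).
#' @param membership A `membership_matrix` without control column.
#' @param n_permutations Number of control resampling + retraining rounds.
#' @param n_control_genes Size of the control pathway.
#' @param exclude_pathways Optional pathway names whose genes are excluded
#'   from the control draw (see [add_control_pathway()]); useful when
#'   "unrelated genes" should mean genes outside known signal-carrying sets.
#' @param hyper,control,n_members,scale Passed to [pathclock()].
#' @param base_seed Base seed; permutation `i` samples control genes with
#'   seed `base_seed + i` and trains with seed `base_seed + 31000 + i`.
#' @return An object of class `pathway_ranking`: a data frame (`pathway`,
#'   `median_r`, `p`, `p_adj`) ordered by decreasing median correlation, with
#'   the permutations x pathways correlation matrix in `attr(, "r_matrix")`.
#' @export
rank_pathways_vs_control <- function(expr, ages, membership,
                                     n_permutations = 100L,
                                     n_control_genes = 150L,
                                     exclude_pathways = NULL,
                                     hyper = clock_hyper(),
                                     control = clock_control(),
                                     n_members = 1L,
                                     scale = c("log2", "linear"),
                                     base_seed = 1L) {
  scale <- match.arg(scale)
  if (n_permutations < 2L) stop("need at least 2 permutations")
  stopifnot(inherits(membership, "membership_matrix"))
  if ("CONTROL" %in% colnames(membership)) {
    stop("membership already contains a CONTROL column; ",
         "control genes are resampled per permutation")
  }
  pw <- colnames(membership)
  rmat <- matrix(NA_real_, n_permutations, length(pw) + 1L,
                 dimnames = list(NULL, c(pw, "CONTROL")))
  for (i in seq_len(n_permutations)) {
    m_i <- add_control_pathway(membership, n_control_genes,
                               seed = base_seed + i,
                               exclude_pathways = exclude_pathways)
    fit <- pathclock(expr, ages, membership = m_i, hyper = hyper,
                     control = control, n_members = n_members,
                     scale = scale, seed = base_seed + 31000L + i)
    act <- predict(fit, type = "pathways")
    rmat[i, ] <- activation_age_correlation(act,
                                            fit$data$ages[fit$data$test])
  }
  r_ctrl <- rmat[, "CONTROL"]
  p <- vapply(pw, function(pn) {
    suppressWarnings(stats::wilcox.test(rmat[, pn], r_ctrl,
                                        alternative = "greater")$p.value)
  }, numeric(1))
  out <- data.frame(pathway = pw,
                    median_r = apply(rmat[, pw, drop = FALSE], 2L,
                                     stats::median),
                    p = p, p_adj = holm_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$median_r, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "r_matrix") <- rmat
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("pathway_ranking", "data.frame")
  out
}

#' @export
print.pathway_ranking <- function(x, ...) {
  cat("Pathway-age correlation ranking vs control pathway (",
      attr(x, "n_permutations"), " permutations)\n", sep = "")
  cat("  control median r: ",
      sprintf("%.3f", stats::median(attr(x, "r_matrix")[, "CONTROL"])),
      "\n", sep = "")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Age-stratified perturbation effect test
#'
#' Bins the perturbed samples into chronological-age quantile strata and, in
#' each stratum, tests whether the median per-sample effect differs from 0
#' using a two-sided Wilcoxon signed-rank test (exact where sample size and
#' ties permit, normal approximation otherwise), Holm-adjusted across strata.
#'
#' @param effect A `perturbation_effect`.
#' @param ages Ages of the perturbed samples (named by sample ID or aligned).
#' @param n_strata Number of quantile strata (default quartiles).
#' @param min_n Minimum samples per stratum.
#' @return A data frame of class `stratified_effect`: one row per stratum
#'   with `n`, `median_delta`, `sd`, `p`, `p_adj`.
#' @export
stratified_effect_test <- function(effect, ages, n_strata = 4L, min_n = 5L) {
  stopifnot(inherits(effect, "perturbation_effect"))
  delta <- effect$delta_age
  if (!is.null(names(ages)) && !is.null(names(delta))) {
    if (!all(names(delta) %in% names(ages))) {
      stop("ages is missing entries for some perturbed samples")
    }
    ages <- ages[names(delta)]
  } else if (length(ages) != length(delta)) {
    stop("length mismatch between effect and ages")
  }
  breaks <- stats::quantile(ages, probs = seq(0, 1, length.out = n_strata + 1L))
  breaks[1L] <- -Inf
  breaks[length(breaks)] <- Inf
  stratum <- cut(ages, breaks = unique(breaks),
                 labels = sprintf("Q%d", seq_len(length(unique(breaks)) - 1L)))
  counts <- table(stratum)
  if (any(counts < min_n)) {
    stop("stratum below the minimum of ", min_n, " samples: ",
         paste(names(counts)[counts < min_n], collapse = ", "))
  }
  rows <- lapply(levels(stratum), function(s) {
    d <- delta[stratum == s]
    p <- suppressWarnings(stats::wilcox.test(d, mu = 0)$p.value)
    data.frame(stratum = s, n = length(d), median_delta = stats::median(d),
               sd = stats::sd(d), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_adjust(out$p)
  class(out) <- c("stratified_effect", "data.frame")
  out
}

#' Crossroads association: pathway multiplicity vs knockdown impact
#'
#' Tests whether genes annotated to several pathways ("crossroads" genes)
#' exert larger knockdown effects on the predicted age. Genes are split by
#' the sign of their knockdown effect; within each sign group the association
#' between the number of pathway memberships and the absolute effect size is
#' tested with a one-sided Spearman rank correlation (alternative: positive
#' association).
#'
#' @param kd_table Output of [genome_wide_knockdown()] (needs columns `gene`
#'   and `delta_age`).
#' @param membership A `membership_matrix` covering the scanned genes.
#' @param min_n Minimum group size; smaller sign groups are skipped with a
#'   warning.
#' @return Data frame with one row per sign group: `direction`, `n_genes`,
#'   `rho`, `p`.
#' @export
crossroads_association <- function(kd_table, membership, min_n = 10L) {
  stopifnot(is.data.frame(kd_table),
            all(c("gene", "delta_age") %in% names(kd_table)),
            inherits(membership, "membership_matrix"))
  if (!all(kd_table$gene %in% rownames(membership))) {
    stop("knockdown table contains genes absent from the membership matrix")
  }
  counts <- rowSums(unclass(membership))[kd_table$gene]
  groups <- list(positive = kd_table$delta_age > 0,
                 negative = kd_table$delta_age < 0)
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    if (sum(sel) < min_n) {
      warning("skipping ", g, " impact group: fewer than ", min_n, " genes",
              call. = FALSE)
      return(data.frame(direction = g, n_genes = sum(sel), rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    k <- counts[sel]
    a <- abs(kd_table$delta_age[sel])
    if (stats::sd(k) == 0) {
      warning("degenerate ", g, " group: all membership counts equal",
              call. = FALSE)
      return(data.frame(direction = g, n_genes = sum(sel), rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(k, a, method = "spearman",
                                           alternative = "greater",
                                           exact = FALSE))
    data.frame(direction = g, n_genes = sum(sel),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' tSNE embedding of the pathway perturbation landscape
#'
#' Embeds the genes x pathways matrix of knockdown effects on pathway
#' activations into two dimensions with t-distributed stochastic neighbor
#' embedding, arranging genes by similarity of their pathway-level impact.
#'
#' @param effect_matrix Genes x pathways numeric matrix (e.g. the pathway
#'   columns of [genome_wide_knockdown()], rownames = genes).
#' @param perplexity tSNE perplexity; requires more than `3 * perplexity`
#'   rows.
#' @param seed Integer seed making the embedding reproducible.
#' @param ... Passed to [Rtsne::Rtsne()].
#' @return Data frame with columns `gene`, `x`, `y`, rows aligned to the
#'   input gene order.
#' @export
pathway_landscape <- function(effect_matrix, perplexity = 30, seed = 1L,
                              ...) {
  effect_matrix <- as.matrix(effect_matrix)
  n <- nrow(effect_matrix)
  if (n - 1L < 3 * perplexity) {
    stop("too few rows (", n, ") for perplexity ", perplexity,
         "; choose perplexity < ", (n - 1L) / 3)
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  emb <- Rtsne::Rtsne(effect_matrix, dims = 2L, perplexity = perplexity,
                      check_duplicates = FALSE, pca = FALSE, ...)
  data.frame(gene = rownames(effect_matrix) %||% seq_len(n),
             x = emb$Y[, 1L], y = emb$Y[, 2L], stringsAsFactors = FALSE)
}
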