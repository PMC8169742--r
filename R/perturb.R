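# In silico perturbation: single-gene knockdown/overexpression, dose-response
# curves, genome-wide scans, and differential-expression signature
# perturbations. A log2 fold-change is an additive shift on the log2 scale,
# applied before the fitted z-scaling (the scaling belongs to the model, not
# the biology).

#' Shift gene expression by log2 fold-changes
#'
#' Applies additive shifts on the log2 scale: every sample's value for a
#' perturbed gene is moved by that gene's log2 fold-change. Genes absent from
#' the matrix are skipped and counted.
#'
#' @param expr_log Samples x genes matrix on log2 scale.
#' @param changes Named numeric vector of log2 fold-changes (names are gene
#'   symbols), or a data frame with columns `gene` and `log2fc`.
#' @return The shifted matrix, with attributes `n_applied` and `n_skipped`.
#' @export
perturb_expression <- function(expr_log, changes) {
  stopifnot(is.matrix(expr_log), !is.null(colnames(expr_log)))
  if (is.data.frame(changes)) {
    changes <- stats::setNames(changes$log2fc, changes$gene)
  }
  if (length(changes) == 0L) stop("empty change list")
  if (is.null(names(changes)) || any(!nzchar(names(changes)))) {
    stop("changes must be named by gene symbol")
  }
  present <- names(changes) %in% colnames(expr_log)
  out <- expr_log
  if (any(present)) {
    hits <- changes[present]
    out[, names(hits)] <- sweep(out[, names(hits), drop = FALSE], 2L,
                                hits, `+`)
  }
  attr(out, "n_applied") <- sum(present)
  attr(out, "n_skipped") <- sum(!present)
  out
}

# Shared machinery: predict baseline and perturbed, return the deltas.
perturbation_deltas <- function(clock, expr_log, changes, descriptor) {
  base <- clock_predict_log(clock, expr_log)
  pert_expr <- perturb_expression(expr_log, changes)
  pert <- clock_predict_log(clock, pert_expr)
  structure(list(delta_age = pert$age - base$age,
                 delta_activation = if (!is.null(base$pathways)) {
                   pert$pathways - base$pathways
                 } else NULL,
                 perturbation = descriptor,
                 n_applied = attr(pert_expr, "n_applied"),
                 n_skipped = attr(pert_expr, "n_skipped")),
            class = "perturbation_effect")
}

#' @export
print.perturbation_effect <- function(x, ...) {
  cat("In silico perturbation:", x$perturbation, "\n")
  cat(sprintf("  %d gene(s) applied, %d skipped; %d samples\n",
              x$n_applied, x$n_skipped, length(x$delta_age)))
  cat(sprintf("  median delta age: %+.3f years (IQR %.3f to %.3f)\n",
              stats::median(x$delta_age),
              stats::quantile(x$delta_age, 0.25),
              stats::quantile(x$delta_age, 0.75)))
  invisible(x)
}

# Resolve the expression matrix a perturbation runs on: user-supplied
# (converted to log2) or the clock's held-out test fold.
resolve_expr_log <- function(clock, expr, scale) {
  if (is.null(expr)) {
    if (is.null(clock$data)) stop("clock carries no data; supply expr")
    return(clock$data$expr_log[clock$data$test, , drop = FALSE])
  }
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  to_log2(expr, scale %||% clock$input_scale %||% "log2")
}

#' Single-gene knockdown / overexpression effect
#'
#' Shifts one gene by a common log2 fold-change (default -2, the knockdown
#' convention) in every sample and compares the clock's predictions with the
#' unperturbed baseline, per sample, for both the main age output and the
#' pathway-neuron activations.
#'
#' @param clock A fitted `pathclock`.
#' @param gene Gene symbol; must be in the clock's gene universe.
#' @param log2fc Log2 fold-change (negative = knockdown).
#' @param expr Optional samples x genes matrix (defaults to the clock's
#'   held-out test fold).
#' @param scale Input scale of `expr` if supplied.
#' @return A `perturbation_effect`: per-sample `delta_age`, per-sample x
#'   pathway `delta_activation`, and applied/skipped counts.
#' @export
knockdown_effect <- function(clock, gene, log2fc = -2, expr = NULL,
                             scale = NULL) {
  stopifnot(inherits(clock, "pathclock"), length(gene) == 1L)
  if (!gene %in% clock$spec$input_genes) {
    near <- utils::head(agrep(gene, clock$spec$input_genes, value = TRUE,
                              ignore.case = TRUE, max.distance = 0.2), 5L)
    stop("gene '", gene, "' is not in the clock's gene universe",
         if (length(near)) paste0("; nearest: ", paste(near, collapse = ", ")))
  }
  expr_log <- resolve_expr_log(clock, expr, scale)
  perturbation_deltas(clock, expr_log, stats::setNames(log2fc, gene),
                      sprintf("%s log2FC %+g", gene, log2fc))
}

#' Dose-response curve for one gene
#'
#' Simulates continuous knockdown and overexpression of a single gene over a
#' grid of log2 fold-changes, summarizing each dose by the median per-sample
#' change in predicted age. The zero dose yields a delta of exactly 0.
#'
#' @inheritParams knockdown_effect
#' @param log2fc_grid Numeric vector of doses.
#' @return Data frame with columns `log2fc` and `median_delta_age`.
#' @export
dose_response <- function(clock, gene, log2fc_grid, expr = NULL,
                          scale = NULL) {
  if (length(log2fc_grid) == 0L) stop("empty log2fc grid")
  expr_log <- resolve_expr_log(clock, expr, scale)
  med <- vapply(log2fc_grid, function(fc) {
    eff <- knockdown_effect(clock, gene, fc, expr = expr_log, scale = "log2")
    stats::median(eff$delta_age)
  }, numeric(1))
  data.frame(log2fc = log2fc_grid, median_delta_age = med)
}

#' Genome-wide knockdown scan
#'
#' Simulates the knockdown of every gene covered by the model by a common
#' log2 fold-change and records, per gene, the median change in predicted age
#' and the median change in each pathway-neuron activation. Genes at the
#' extremes of the resulting distribution are the model's most influential
#' features.
#'
#' @inheritParams knockdown_effect
#' @param genes Optional subset of genes to scan (defaults to the full gene
#'   universe of the clock).
#' @return Data frame ordered by decreasing `delta_age`: one row per gene,
#'   columns `gene`, `delta_age`, and one column per pathway.
#' @export
genome_wide_knockdown <- function(clock, log2fc = -2, expr = NULL,
                                  scale = NULL, genes = NULL) {
  stopifnot(inherits(clock, "pathclock"))
  expr_log <- resolve_expr_log(clock, expr, scale)
  genes <- genes %||% clock$spec$input_genes
  base <- clock_predict_log(clock, expr_log)
  P <- length(clock$spec$pathways %||% character(0))
  out <- matrix(0, length(genes), 1L + P)
  for (i in seq_along(genes)) {
    pert <- clock_predict_log(clock,
      perturb_expression(expr_log, stats::setNames(log2fc, genes[i])))
    out[i, 1L] <- stats::median(pert$age - base$age)
    if (P > 0L) {
      out[i, -1L] <- apply(pert$pathways - base$pathways, 2L, stats::median)
    }
  }
  df <- data.frame(gene = genes, delta_age = out[, 1L],
                   stringsAsFactors = FALSE)
  if (P > 0L) {
    act <- as.data.frame(out[, -1L, drop = FALSE])
    names(act) <- clock$spec$pathways
    df <- cbind(df, act)
  }
  df[order(df$delta_age, decreasing = TRUE), , drop = FALSE]
}

#' Construct / read a differential-expression signature
#'
#' A signature is a table of per-gene effects from a differential-expression
#' analysis: gene symbol, log2 fold-change and FDR. Applied as a perturbation
#' it shifts every passing gene by its own recorded fold-change.
#'
#' @param gene Character vector of gene symbols (one record per gene).
#' @param log2fc Numeric vector of log2 fold-changes.
#' @param fdr Numeric vector of false-discovery rates in `[0, 1]`.
#' @param label Signature name.
#' @param species Source species.
#' @return A data frame of class `aging_signature` with columns `gene`,
#'   `log2fc`, `fdr` and attributes `label`, `species`.
#' @export
signature_table <- function(gene, log2fc, fdr, label = "signature",
                            species = "Homo sapiens") {
  stopifnot(length(gene) == length(log2fc), length(gene) == length(fdr))
  if (anyDuplicated(gene)) stop("one record per gene required")
  if (any(fdr < 0 | fdr > 1)) stop("fdr must be in [0, 1]")
  out <- data.frame(gene = as.character(gene), log2fc = as.numeric(log2fc),
                    fdr = as.numeric(fdr), stringsAsFactors = FALSE)
  attr(out, "label") <- label
  attr(out, "species") <- species
  class(out) <- c("aging_signature", "data.frame")
  out
}

#' @rdname signature_table
#' @param path Path to a delimited table.
#' @param gene_col,log2fc_col,fdr_col Column names in the file.
#' @param sep Field separator.
#' @export
read_signature <- function(path, gene_col = "gene", log2fc_col = "log2fc",
                           fdr_col = "fdr", label = basename(path),
                           species = "Homo sapiens", sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c(gene_col, log2fc_col, fdr_col), names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  signature_table(d[[gene_col]], d[[log2fc_col]], d[[fdr_col]],
                  label = label, species = species)
}

#' Map a signature to homologous gene symbols
#'
#' Table-driven homolog mapping (e.g. rat to human): records are re-keyed via
#' a source-to-target symbol table. Records without a mapping are dropped and
#' counted; when several source genes map to one target symbol, the record
#' with the smallest FDR is kept.
#'
#' @param sig An `aging_signature`.
#' @param mapping Two-column data frame (source symbol, target symbol);
#'   source keys must be unique.
#' @return The mapped signature; `attr(, "n_unmapped")` counts dropped
#'   records.
#' @export
map_homologs <- function(sig, mapping) {
  stopifnot(inherits(sig, "aging_signature"), is.data.frame(mapping))
  if (nrow(mapping) == 0L) stop("empty mapping table")
  src <- as.character(mapping[[1L]])
  tgt <- as.character(mapping[[2L]])
  if (anyDuplicated(src)) stop("mapping source keys must be unique")
  idx <- match(sig$gene, src)
  n_unmapped <- sum(is.na(idx))
  if (n_unmapped > 0L) {
    message(n_unmapped, " record(s) without homolog mapping dropped")
  }
  keep <- !is.na(idx)
  out <- sig[keep, , drop = FALSE]
  out$gene <- tgt[idx[keep]]
  if (anyDuplicated(out$gene)) {
    message("resolving many-to-one homolog collisions by smallest FDR")
    out <- out[order(out$fdr), , drop = FALSE]
    out <- out[!duplicated(out$gene), , drop = FALSE]
  }
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  res <- signature_table(out$gene, out$log2fc, out$fdr,
                         label = attr(sig, "label"),
                         species = attr(sig, "species"))
  attr(res, "n_unmapped") <- n_unmapped
  res
}

#' Apply a differential-expression signature as a complex perturbation
#'
#' Filters the signature to records with `fdr < fdr_cutoff` (default 0.05),
#' shifts every passing gene present in the model by its own recorded log2
#' fold-change, and compares predictions with the unperturbed baseline per
#' sample.
#'
#' @inheritParams knockdown_effect
#' @param sig An `aging_signature`.
#' @param fdr_cutoff Significance cutoff on the signature's FDR column.
#' @return A `perturbation_effect`.
#' @export
apply_signature <- function(clock, sig, fdr_cutoff = 0.05, expr = NULL,
                            scale = NULL) {
  stopifnot(inherits(clock, "pathclock"), inherits(sig, "aging_signature"))
  pass <- sig[sig$fdr < fdr_cutoff, , drop = FALSE]
  if (nrow(pass) == 0L) {
    stop("no signature record passes fdr < ", fdr_cutoff)
  }
  expr_log <- resolve_expr_log(clock, expr, scale)
  perturbation_deltas(clock, expr_log,
                      stats::setNames(pass$log2fc, pass$gene),
                      sprintf("signature '%s' (%d genes at FDR < %g)",
                              attr(sig, "label") %||% "signature",
                              nrow(pass), fdr_cutoff))
}
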