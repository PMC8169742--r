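# Gene-set ingestion and the binary gene x pathway membership matrix that
# defines the clock's connectivity.

#' Read a gene-set collection from a GMT file
#'
#' Parses the Broad GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one or more gene symbols. Symbols are matched
#' case-sensitively throughout the package; no alias resolution is attempted.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors of gene
#'   symbols (file order preserved), with per-set descriptions in
#'   `attr(, "description")`.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("A\tna\tg1\tg2\tg3", "B\tna\tg3\tg4"), gmt)
#' gs <- read_gmt(gmt)
#' names(gs)
#' @seealso [build_membership()], [write_gmt()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated ",
           "fields (name, description, genes), got ", length(fields))
    }
    nms[i] <- fields[[1]]
    desc[i] <- fields[[2]]
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene symbols in set '", nms[i], "' (line ", i,
              ") removed", call. = FALSE)
      genes <- unique(genes)
    }
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(desc, nms)
  class(sets) <- "gene_set_collection"
  sets
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x), "sets,",
      length(unique(unlist(x))), "distinct genes\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-40s %d genes\n", names(x)[i], length(x[[i]])))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Build the binary gene x pathway membership matrix
#'
#' Restricts a gene-set collection to the measured transcriptome and encodes
#' it as the binary filter matrix that sets the gene-specific connections of
#' the first hidden layer of the clock. The gene universe is the intersection
#' of the union of all set genes with `measured_genes`, ordered
#' lexicographically so downstream mask construction and parameter counts are
#' reproducible; columns keep collection order.
#'
#' @param collection A `gene_set_collection` (see [read_gmt()]) or a named
#'   list of character vectors.
#' @param measured_genes Character vector of gene symbols present in the
#'   expression data.
#' @return A `membership_matrix`: binary integer matrix with genes as rows and
#'   pathways as columns. Every row and every column has at least one 1;
#'   pathways with no measured gene are dropped with a warning.
#' @examples
#' gs <- list(A = c("g1", "g2"), B = c("g2", "g3"))
#' build_membership(gs, c("g1", "g2", "g3", "g9"))
#' @export
build_membership <- function(collection, measured_genes) {
  stopifnot(is.list(collection), length(collection) > 0L)
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    stop("collection must have unique set names")
  }
  if (length(measured_genes) == 0L) stop("measured_genes is empty")
  universe <- sort(intersect(unique(unlist(collection)), measured_genes))
  if (length(universe) == 0L) {
    stop("no annotated genes measured: gene-set collection and ",
         "measured_genes do not overlap")
  }
  m <- vapply(collection, function(g) as.integer(universe %in% g),
              integer(length(universe)))
  if (length(universe) == 1L) m <- matrix(m, nrow = 1L,
                                          dimnames = list(universe, names(collection)))
  else rownames(m) <- universe
  empty <- colSums(m) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " pathway(s) with no measured genes: ",
            paste(colnames(m)[empty], collapse = ", "), call. = FALSE)
    m <- m[, !empty, drop = FALSE]
    if (ncol(m) == 0L) stop("no pathway retains a measured gene")
    keep <- rowSums(m) > 0L
    m <- m[keep, , drop = FALSE]
  }
  new_membership(m)
}

new_membership <- function(m) {
  storage.mode(m) <- "integer"
  stopifnot(all(m %in% c(0L, 1L)),
            all(rowSums(m) >= 1L), all(colSums(m) >= 1L),
            !is.null(rownames(m)), !is.null(colnames(m)))
  class(m) <- c("membership_matrix", "matrix")
  m
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat("Membership matrix:", nrow(x), "genes x", ncol(x), "pathways\n")
  cat("  genes per pathway: ",
      paste(range(colSums(unclass(x))), collapse = "-"),
      "; pathways per gene: ",
      paste(range(rowSums(unclass(x))), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Append an artificial control pathway of randomly sampled genes
#'
#' Adds one column named `"CONTROL"` with `n_genes` ones at genes sampled
#' uniformly without replacement from the matrix's gene universe. The control
#' pathway provides a null baseline for pathway-age correlation ranking:
#' random, unrelated genes processed through an identically shaped
#' sub-network.
#'
#' @param m A `membership_matrix`.
#' @param n_genes Number of control genes (default 150).
#' @param seed Integer seed making the draw reproducible.
#' @param exclude_pathways Optional character vector of pathway names whose
#'   member genes are excluded from the draw.
#' @return The matrix with one appended `CONTROL` column; existing columns are
#'   untouched.
#' @export
add_control_pathway <- function(m, n_genes = 150L, seed = 1L,
                                exclude_pathways = NULL) {
  stopifnot(inherits(m, "membership_matrix"))
  if ("CONTROL" %in% colnames(m)) stop("matrix already has a CONTROL column")
  pool <- rownames(m)
  if (!is.null(exclude_pathways)) {
    bad <- setdiff(exclude_pathways, colnames(m))
    if (length(bad)) stop("unknown pathway(s): ", paste(bad, collapse = ", "))
    excluded <- rowSums(m[, exclude_pathways, drop = FALSE]) > 0L
    pool <- pool[!excluded]
  }
  if (n_genes > length(pool)) {
    stop("n_genes (", n_genes, ") exceeds the available gene pool (",
         length(pool), ")")
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  chosen <- sample(pool, n_genes)
  ctrl <- as.integer(rownames(m) %in% chosen)
  out <- cbind(unclass(m), CONTROL = ctrl)
  new_membership(out)
}

#' Write gene sets to a GMT file
#'
#' Accepts either a `gene_set_collection` or a `membership_matrix` (each
#' pathway column becomes one set). Output round-trips through [read_gmt()].
#'
#' @param x Collection or membership matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(x, path) {
  if (inherits(x, "membership_matrix")) {
    if (ncol(x) == 0L || nrow(x) == 0L) stop("empty membership matrix")
    sets <- lapply(seq_len(ncol(x)),
                   function(j) rownames(x)[x[, j] == 1L])
    names(sets) <- colnames(x)
    desc <- stats::setNames(rep("na", length(sets)), names(sets))
  } else if (is.list(x) && length(x) > 0L) {
    sets <- x
    desc <- attr(x, "description")
    if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  } else {
    stop("x must be a gene_set_collection or membership_matrix")
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
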