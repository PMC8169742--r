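# Architectural blueprints: from a membership matrix (or a dense layer stack)
# to a deterministic layer/mask plan with closed-form parameter counts.

#' Network hyperparameters
#'
#' Bundles the architectural hyperparameters of the clock. Defaults are the
#' published configuration: neuron scaling factor `f = 2`, four hidden layers,
#' unit dropout probability 0.1 between hidden layers, global L2 weight decay
#' 0.01, elu activations, He (fan-in) initialization.
#'
#' @param f Neuron scaling factor: each pathway's hidden-layer width is
#'   `5 + floor(n_genes / f)`.
#' @param n_hidden Number of hidden pathway layers.
#' @param dropout Drop probability between hidden layers (`0 <= p < 1`).
#' @param l2 L2 weight-decay coefficient applied to all unmasked weights
#'   (biases are not penalized).
#' @param activation Hidden activation; only `"elu"` is supported.
#' @param init Weight initialization; only `"he"` is supported.
#' @return An object of class `clock_hyper`.
#' @export
clock_hyper <- function(f = 2, n_hidden = 4L, dropout = 0.1, l2 = 0.01,
                        activation = "elu", init = "he") {
  stopifnot(is.numeric(f), length(f) == 1L, f > 0,
            n_hidden >= 1L, dropout >= 0, dropout < 1, l2 >= 0)
  activation <- match.arg(activation, "elu")
  init <- match.arg(init, "he")
  structure(list(f = as.numeric(f), n_hidden = as.integer(n_hidden),
                 dropout = as.numeric(dropout), l2 = as.numeric(l2),
                 activation = activation, init = init),
            class = "clock_hyper")
}

#' Hidden-layer width for a pathway
#'
#' The neuron-scaling rule sizing each pathway's hidden layers:
#' `width = 5 + floor(n_genes / f)`. Every pathway receives a base width of 5
#' neurons, with additional neurons awarded as the gene count grows to
#' accommodate increasing regulatory complexity.
#'
#' @param n_genes Number of genes annotated to the pathway (vectorized).
#' @param f Positive neuron scaling factor (default 2).
#' @return Integer vector of layer widths.
#' @examples
#' neurons_for_pathway(0, 2)    # 5
#' neurons_for_pathway(200, 2)  # 105
#' @export
neurons_for_pathway <- function(n_genes, f = 2) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0) stop("f must be > 0")
  if (any(n_genes < 0)) stop("n_genes must be >= 0")
  as.integer(5L + floor(n_genes / f))
}

#' Build the pathway-masked network blueprint
#'
#' Converts a membership matrix into a full architectural plan: per-pathway
#' hidden-layer widths via [neurons_for_pathway()], the first-layer
#' gene-to-pathway mask, pathway-internal dense hidden layers (no connections
#' across pathways), a linear aggregation neuron per pathway (the auxiliary
#' "pathway age" output), and a single main output neuron fed by all pathway
#' neurons. The blueprint is pure data; [pathclock()] and [train_member()]
#' realize it as trained weights.
#'
#' @param membership A `membership_matrix` (see [build_membership()]).
#' @param hyper A [clock_hyper()] object.
#' @return An object of class `clock_spec` with `kind = "pathway_masked"`.
#' @export
masked_spec <- function(membership, hyper = clock_hyper()) {
  stopifnot(inherits(membership, "membership_matrix"),
            inherits(hyper, "clock_hyper"))
  n_genes <- colSums(unclass(membership))
  plans <- data.frame(pathway = colnames(membership),
                      n_genes = as.integer(n_genes),
                      width = neurons_for_pathway(n_genes, hyper$f),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(kind = "pathway_masked",
                 input_genes = rownames(membership),
                 pathways = colnames(membership),
                 plans = plans,
                 membership = membership,
                 hyper = hyper,
                 has_aux = TRUE),
            class = "clock_spec")
}

#' Build a fully connected baseline blueprint
#'
#' The dense "black box" counterpart used to benchmark the pathway-masked
#' clock: the same depth, a comparable parameter count, one main output and no
#' auxiliary output. The published baseline uses hidden sizes
#' `c(350, 350, 350, 50)` on 4359 input genes (1,789,301 parameters).
#'
#' @param input_genes Character vector of input gene symbols, or a single
#'   count (symbols are then generated).
#' @param hidden_sizes Positive integer vector of hidden-layer widths.
#' @param hyper A [clock_hyper()] object.
#' @return An object of class `clock_spec` with `kind = "fully_connected"`.
#' @export
fcn_spec <- function(input_genes, hidden_sizes = c(350L, 350L, 350L, 50L),
                     hyper = clock_hyper()) {
  if (is.numeric(input_genes) && length(input_genes) == 1L) {
    input_genes <- sprintf("gene%05d", seq_len(input_genes))
  }
  stopifnot(is.character(input_genes), length(input_genes) > 0L,
            inherits(hyper, "clock_hyper"))
  if (length(hidden_sizes) == 0L) stop("hidden_sizes must be non-empty")
  if (any(hidden_sizes <= 0)) stop("hidden_sizes must be positive")
  structure(list(kind = "fully_connected",
                 input_genes = input_genes,
                 hidden_sizes = as.integer(hidden_sizes),
                 hyper = hyper,
                 has_aux = FALSE),
            class = "clock_spec")
}

#' @export
print.clock_spec <- function(x, ...) {
  if (x$kind == "pathway_masked") {
    cat("Pathway-masked network spec:", length(x$input_genes), "genes,",
        length(x$pathways), "pathways,", x$hyper$n_hidden, "hidden layers\n")
    cat("  widths:", paste(range(x$plans$width), collapse = "-"),
        " total hidden width:", sum(x$plans$width), "\n")
  } else {
    cat("Fully connected network spec:", length(x$input_genes), "inputs,",
        "hidden [", paste(x$hidden_sizes, collapse = ","), "]\n")
  }
  cat("  trainable parameters:", format(count_parameters(x), big.mark = ","),
      "\n")
  invisible(x)
}

# Internal: materialize the layer plan. Each layer is a list with
#   n_in, n_out, mask (binary matrix or NULL for dense), activation
#   ("elu"/"linear"), dropout (apply unit dropout after this layer in
#   training), role ("hidden", "aux", "output").
# Dropout sits between hidden layers only: after hidden layers 1..n_hidden-1.
spec_layers <- function(spec) {
  hp <- spec$hyper
  if (spec$kind == "fully_connected") {
    sizes <- c(length(spec$input_genes), spec$hidden_sizes, 1L)
    n_l <- length(sizes) - 1L
    layers <- vector("list", n_l)
    for (i in seq_len(n_l)) {
      is_out <- i == n_l
      layers[[i]] <- list(n_in = sizes[i], n_out = sizes[i + 1L], mask = NULL,
                          activation = if (is_out) "linear" else hp$activation,
                          dropout = !is_out && i < n_l - 1L,
                          role = if (is_out) "output" else "hidden")
    }
    return(layers)
  }
  m <- unclass(spec$membership)
  widths <- spec$plans$width
  P <- ncol(m)
  H <- sum(widths)
  blk <- rep(seq_len(P), widths)          # pathway owning each hidden neuron
  # layer 1: gene -> pathway neurons, masked by membership
  mask1 <- m[, blk, drop = FALSE]
  storage.mode(mask1) <- "double"
  layers <- list(list(n_in = nrow(m), n_out = H, mask = mask1,
                      activation = hp$activation,
                      dropout = hp$n_hidden > 1L, role = "hidden"))
  # layers 2..n_hidden: block-diagonal within pathway
  if (hp$n_hidden > 1L) {
    maskh <- matrix(0, H, H)
    for (p in seq_len(P)) maskh[blk == p, blk == p] <- 1
    for (i in 2:hp$n_hidden) {
      layers[[i]] <- list(n_in = H, n_out = H, mask = maskh,
                          activation = hp$activation,
                          dropout = i < hp$n_hidden, role = "hidden")
    }
  }
  # aggregation: one linear neuron per pathway (auxiliary output)
  maska <- matrix(0, H, P, dimnames = list(NULL, spec$pathways))
  maska[cbind(seq_len(H), blk)] <- 1
  layers[[hp$n_hidden + 1L]] <- list(n_in = H, n_out = P, mask = maska,
                                     activation = "linear", dropout = FALSE,
                                     role = "aux")
  # main output neuron fed by all pathway neurons
  layers[[hp$n_hidden + 2L]] <- list(n_in = P, n_out = 1L, mask = NULL,
                                     activation = "linear", dropout = FALSE,
                                     role = "output")
  layers
}

#' Count trainable parameters of a blueprint
#'
#' Exact closed-form count: for every layer, the number of unmasked incoming
#' edges plus one bias per neuron. For the masked kind this includes the
#' per-pathway aggregation neurons and the final output neuron fed by all
#' pathway neurons.
#'
#' @param spec A `clock_spec`.
#' @return Integer parameter count.
#' @examples
#' count_parameters(fcn_spec(4359))  # 1789301
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "clock_spec"))
  layers <- spec_layers(spec)
  total <- 0
  for (l in layers) {
    w <- if (is.null(l$mask)) l$n_in * l$n_out else sum(l$mask)
    total <- total + w + l$n_out
  }
  as.integer(total)
}

#' Serialize a blueprint to JSON
#'
#' Writes everything needed to rebuild the spec bit-identically: kind, gene
#' order, pathway gene sets (masked kind) or hidden sizes (dense kind), and
#' hyperparameters.
#'
#' @param spec A `clock_spec`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_spec()]
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "clock_spec"))
  doc <- list(format = "pathclock_spec", version = 1L, kind = spec$kind,
              input_genes = spec$input_genes,
              hyper = unclass(spec$hyper))
  if (spec$kind == "pathway_masked") {
    m <- spec$membership
    doc$sets <- lapply(stats::setNames(seq_len(ncol(m)), colnames(m)),
                       function(j) rownames(m)[m[, j] == 1L])
  } else {
    doc$hidden_sizes <- spec$hidden_sizes
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a blueprint written by [write_spec()]
#'
#' @param path Path to the JSON document.
#' @return A `clock_spec`.
#' @export
read_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pathclock_spec")) {
    stop("not a pathclock spec document: ", path)
  }
  hyper <- do.call(clock_hyper, doc$hyper)
  if (doc$kind == "pathway_masked") {
    sets <- doc$sets
    if (is.data.frame(sets)) sets <- as.list(sets)
    m <- vapply(sets, function(g) as.integer(doc$input_genes %in% g),
                integer(length(doc$input_genes)))
    rownames(m) <- doc$input_genes
    masked_spec(new_membership(m), hyper)
  } else {
    fcn_spec(doc$input_genes, doc$hidden_sizes, hyper)
  }
}
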