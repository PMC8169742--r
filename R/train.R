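# Fitting the ensemble clock: preprocessing, train/test split, per-member
# training with the combined main + auxiliary loss, and ensemble stacking.

#' Training control parameters
#'
#' Defaults are the published training protocol: loss balance `alpha = 0.4`,
#' Adam with learning rate 0.001, mini-batches of 16 samples, 200 epochs, and
#' a random 70/30 train/test split.
#'
#' @param alpha Balancing hyperparameter in `[0, 1]` mixing the main-output
#'   MSE (weight `1 - alpha`) with the auxiliary pathway-output MSE (weight
#'   `alpha`).
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Number of training epochs (no early stopping).
#' @param train_fraction Fraction of samples assigned to the training fold.
#' @return An object of class `clock_control`.
#' @export
clock_control <- function(alpha = 0.4, learning_rate = 0.001,
                          batch_size = 16L, epochs = 200L,
                          train_fraction = 0.7) {
  stopifnot(alpha >= 0, alpha <= 1, learning_rate > 0, batch_size >= 1L,
            epochs >= 0L, train_fraction > 0, train_fraction < 1)
  structure(list(alpha = alpha, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 train_fraction = train_fraction),
            class = "clock_control")
}

#' Combined main + auxiliary loss
#'
#' `total = (1 - alpha) * mse_main + alpha * mse_aux`. The auxiliary term
#' forces every pathway sub-network to produce its own age estimate, which is
#' what makes the pathway-neuron activations interpretable as "pathway ages".
#'
#' @param mse_main Mean squared error of the main age output.
#' @param mse_aux Mean squared error of the auxiliary pathway outputs, pooled
#'   over all pathway neurons and samples.
#' @param alpha Balancing hyperparameter in `[0, 1]`.
#' @return A list with components `mse_main`, `mse_aux`, `total`.
#' @examples
#' combined_loss(1, 2, 0.4)$total  # 1.4
#' @export
combined_loss <- function(mse_main, mse_aux, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  stopifnot(mse_main >= 0, mse_aux >= 0)
  list(mse_main = mse_main, mse_aux = mse_aux,
       total = (1 - alpha) * mse_main + alpha * mse_aux)
}

#' Random train/test split
#'
#' Disjoint, exhaustive and reproducible split of sample IDs; the training
#' fold has `round(train_fraction * n)` samples.
#'
#' @param sample_ids Character or integer vector of sample identifiers.
#' @param train_fraction Fraction assigned to training (strictly in (0, 1)).
#' @param seed Integer seed.
#' @return A list with components `train` and `test`.
#' @export
split_train_test <- function(sample_ids, train_fraction = 0.7, seed = 1L) {
  n <- length(sample_ids)
  if (n < 2L) stop("need at least 2 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  n_train <- round(train_fraction * n)
  if (n_train == 0L || n_train == n) stop("split would leave a fold empty")
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  idx <- sample.int(n, n_train)
  list(train = sample_ids[sort(idx)], test = sample_ids[-sort(idx)])
}

#' Fit the input preprocessor
#'
#' Learns the input transform from the training fold: `log2(x + 1)` if the
#' expression is on linear TPM scale (identity if already log-scale), then a
#' per-gene z-score using training-fold mean and standard deviation.
#' Constant genes (sd 0) are scaled to zero with a warning; spec genes absent
#' from the expression matrix are imputed as constant 0 after scaling.
#'
#' @param expr Samples x genes numeric matrix (training fold only), with
#'   sample IDs as row names and gene symbols as column names.
#' @param spec A `clock_spec` giving the required gene universe and order.
#' @param scale `"linear"` for TPM-like input, `"log2"` if already
#'   log-transformed.
#' @return An object of class `clock_preprocessor`.
#' @export
fit_preprocessor <- function(expr, spec, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(expr), !is.null(colnames(expr)),
            inherits(spec, "clock_spec"))
  if (anyNA(expr)) stop("expression matrix contains missing values")
  genes <- spec$input_genes
  present <- genes[genes %in% colnames(expr)]
  if (length(present) == 0L) stop("no spec gene present in the expression matrix")
  missing <- setdiff(genes, present)
  if (length(missing)) {
    warning(length(missing), " spec gene(s) absent from expression data; ",
            "imputed as 0 after scaling", call. = FALSE)
  }
  x <- expr[, present, drop = FALSE]
  if (scale == "linear") {
    if (any(x < 0)) stop("linear-scale expression must be non-negative")
    x <- log2(x + 1)
  }
  center <- colMeans(x)
  # population sd, so a two-point gene {1, 3} scales to exactly {-1, +1}
  sds <- sqrt(colMeans(sweep(x, 2L, center)^2))
  n_const <- sum(sds == 0)
  if (n_const > 0) {
    warning(n_const, " constant gene(s) (sd = 0) scaled to zero",
            call. = FALSE)
    sds[sds == 0] <- 1
  }
  structure(list(genes = genes, present = present, missing = missing,
                 scale = scale, center = center, sd = sds),
            class = "clock_preprocessor")
}

# Transform a log2-scale samples x genes matrix into the network input
# (z-scored, spec gene order, absent genes imputed 0).
apply_preprocessor <- function(prep, expr_log) {
  stopifnot(inherits(prep, "clock_preprocessor"), is.matrix(expr_log))
  if (nrow(expr_log) == 0L) stop("empty sample set")
  out <- matrix(0, nrow(expr_log), length(prep$genes),
                dimnames = list(rownames(expr_log), prep$genes))
  use <- intersect(prep$present, colnames(expr_log))
  if (length(use) == 0L) stop("no spec gene present in the expression matrix")
  x <- expr_log[, use, drop = FALSE]
  x <- sweep(x, 2L, prep$center[use], `-`)
  x <- sweep(x, 2L, prep$sd[use], `/`)
  out[, use] <- x
  out
}

# Convert raw input to log2 scale according to the preprocessor convention.
to_log2 <- function(expr, scale) {
  if (scale == "linear") {
    if (any(expr < 0)) stop("linear-scale expression must be non-negative")
    log2(expr + 1)
  } else expr
}

#' Train a single ensemble member
#'
#' Trains one masked (or dense) network on preprocessed inputs with Adam,
#' mini-batches, unit dropout between hidden layers, L2 weight decay on
#' unmasked weights, and the combined loss of [combined_loss()]. The auxiliary
#' target is the chronological age broadcast to every pathway neuron. Masked
#' weight positions stay exactly zero throughout training.
#'
#' @param spec A `clock_spec`.
#' @param x Preprocessed input matrix (samples x spec genes), as produced by
#'   the fitted preprocessor.
#' @param y Ages in years, aligned to the rows of `x`.
#' @param control A [clock_control()] object.
#' @param seed Integer seed; fixes initialization, shuffling and dropout, so
#'   identical seeds give identical training histories.
#' @param monitor Optional list with components `x`, `y`: a held-out set on
#'   which the per-epoch history loss is computed (defaults to the training
#'   data). The monitor set is never used to update weights or stop training
#'   (the protocol trains a fixed number of epochs).
#' @param layers Optional precomputed `spec_layers(spec)` (internal reuse).
#' @param engine `"cpp"` (compiled training loop, default) or `"R"` (pure-R
#'   reference implementation of the identical algorithm).
#' @return An object of class `clock_member`: trained weights plus a
#'   per-epoch history data frame (`epoch`, `mse_main`, `mse_aux`, `loss`).
#' @export
train_member <- function(spec, x, y, control = clock_control(), seed = 1L,
                         monitor = NULL, layers = NULL,
                         engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "clock_spec"), is.matrix(x),
            nrow(x) == length(y), inherits(control, "clock_control"))
  if (is.null(layers)) layers <- spec_layers(spec)
  hp <- spec$hyper
  alpha <- if (spec$has_aux) control$alpha else 0
  mon_x <- if (is.null(monitor)) x else monitor$x
  mon_y <- if (is.null(monitor)) y else monitor$y
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  net <- init_network(layers)
  history <- data.frame(epoch = integer(0), mse_main = numeric(0),
                        mse_aux = numeric(0), loss = numeric(0))
  if (control$epochs > 0L && engine == "cpp") {
    if (spec$kind == "pathway_masked") {
      # block-structured loop: dense per-pathway blocks, no structural zeros
      m <- unclass(spec$membership)
      gene_idx <- lapply(seq_len(ncol(m)),
                         function(p) which(m[, p] == 1L) - 1L)
      res <- .train_loop_blk_cpp(
        net$W, net$b, gene_idx, spec$plans$width, hp$n_hidden,
        x, y, mon_x, mon_y,
        alpha, control$learning_rate, control$batch_size, control$epochs,
        hp$dropout, hp$l2)
    } else {
      aux_index <- which(vapply(layers, function(l) l$role == "aux",
                                logical(1)))
      res <- .train_loop_cpp(
        net$W, net$b,
        lapply(layers, `[[`, "mask"),
        vapply(layers, function(l) if (l$activation == "elu") 1L else 0L,
               integer(1)),
        vapply(layers, `[[`, logical(1), "dropout"),
        if (length(aux_index)) aux_index[1L] - 1L else -1L,
        x, y, mon_x, mon_y,
        alpha, control$learning_rate, control$batch_size, control$epochs,
        hp$dropout, hp$l2)
    }
    net <- list(W = res$W, b = lapply(res$b, as.numeric))
    history <- data.frame(epoch = seq_len(control$epochs),
                          mse_main = res$history[, 1L],
                          mse_aux = res$history[, 2L],
                          loss = res$history[, 3L])
  } else if (control$epochs > 0L) {
    state <- adam_init(net)
    n <- nrow(x)
    hist_rows <- vector("list", control$epochs)
    for (epoch in seq_len(control$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = control$batch_size)
      for (s in starts) {
        take <- idx[s:min(s + control$batch_size - 1L, n)]
        xb <- x[take, , drop = FALSE]
        yb <- y[take]
        fw <- forward_net(net, layers, xb, training = TRUE,
                          dropout = hp$dropout)
        if (!all(is.finite(fw$main))) {
          stop("non-finite network output at epoch ", epoch,
               "; try a lower learning rate")
        }
        fw$cache$D <- fw$cache$D  # dropout masks reused in backprop
        grads <- backward_net(net, layers, fw$cache, yb, alpha, hp$l2)
        upd <- adam_step(net, layers, grads, state, control$learning_rate)
        net <- upd$net
        state <- upd$state
      }
      ml <- net_loss(net, layers, mon_x, mon_y, alpha, spec$has_aux)
      if (!is.finite(ml$total)) {
        stop("non-finite monitor loss at epoch ", epoch,
             "; try a lower learning rate")
      }
      hist_rows[[epoch]] <- data.frame(epoch = epoch, mse_main = ml$mse_main,
                                       mse_aux = ml$mse_aux, loss = ml$total)
    }
    history <- do.call(rbind, hist_rows)
  }
  structure(list(net = net, history = history, seed = seed,
                 epochs = control$epochs),
            class = "clock_member")
}

#' Stack trained members into an ensemble clock
#'
#' Joins independently trained networks that share one blueprint and one
#' preprocessor into an ensemble whose main prediction is the arithmetic mean
#' of the member main outputs, and whose pathway activations are the
#' per-pathway mean of the member auxiliary outputs.
#'
#' @param members List of `clock_member` objects (all trained from the same
#'   spec).
#' @param spec The shared `clock_spec`.
#' @param preprocessor The shared fitted `clock_preprocessor`.
#' @return A `pathclock` object (without attached training data; use
#'   `predict(clock, newdata = ...)`).
#' @export
stack_ensemble <- function(members, spec, preprocessor) {
  stopifnot(length(members) >= 1L,
            all(vapply(members, inherits, logical(1), "clock_member")),
            inherits(spec, "clock_spec"),
            inherits(preprocessor, "clock_preprocessor"))
  layers <- spec_layers(spec)
  shapes <- lapply(layers, function(l) c(l$n_in, l$n_out))
  for (m in members) {
    ms <- lapply(m$net$W, dim)
    if (!identical(lapply(shapes, as.integer), lapply(ms, as.integer))) {
      stop("member network shape does not match the spec")
    }
  }
  structure(list(spec = spec, layers = layers, members = members,
                 preprocessor = preprocessor, data = NULL, control = NULL,
                 seed = NULL, call = sys.call()),
            class = "pathclock")
}

#' Fit a pathway-guided neural-network age clock
#'
#' The main fitting function. Splits samples into training and test folds,
#' fits the input preprocessor on the training fold, trains `n_members`
#' networks independently (member `m` uses seed `seed + m`) on the combined
#' main + auxiliary loss, and stacks them into an ensemble whose outputs are
#' the member means. The per-epoch history of each member records the loss on
#' the held-out test fold; it is never used to tune or stop training.
#'
#' @param expr Samples x genes numeric matrix; row names are sample IDs,
#'   column names gene symbols.
#' @param ages Numeric vector of chronological ages in years, either named by
#'   sample ID or aligned to the rows of `expr`.
#' @param membership A `membership_matrix` defining the architecture
#'   (ignored if `spec` is given).
#' @param spec Optional prebuilt `clock_spec` (e.g. [fcn_spec()] for the
#'   dense baseline).
#' @param hyper A [clock_hyper()] object.
#' @param control A [clock_control()] object.
#' @param n_members Number of ensemble members (published model: 10).
#' @param scale `"linear"` for TPM-like input, `"log2"` if already
#'   log-transformed.
#' @param seed Base seed governing the split and member training.
#' @param test_ids Optional explicit test-fold sample IDs (overrides the
#'   random split).
#' @return An object of class `pathclock`, with methods `predict`, `print`,
#'   `summary`, `plot`, `residuals` and `fitted`.
#' @examples
#' sim <- simulate_aging_dataset(n_samples = 60, n_pathways = 2,
#'                               genes_per_pathway = 8, seed = 1)
#' fit <- pathclock(sim$expr, sim$ages, sim$membership, n_members = 1,
#'                  control = clock_control(epochs = 3), seed = 1)
#' predict(fit)[1:3]
#' @export
pathclock <- function(expr, ages, membership = NULL, spec = NULL,
                      hyper = clock_hyper(), control = clock_control(),
                      n_members = 10L, scale = c("log2", "linear"),
                      seed = 1L, test_ids = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("sample%04d", seq_len(nrow(expr)))
  }
  if (!is.null(names(ages))) {
    if (!all(rownames(expr) %in% names(ages))) {
      stop("ages is missing entries for some samples")
    }
    ages <- ages[rownames(expr)]
  } else if (length(ages) != nrow(expr)) {
    stop("length(ages) must match nrow(expr)")
  } else {
    names(ages) <- rownames(expr)
  }
  if (anyNA(ages)) stop("ages contain missing values")
  if (is.null(spec)) {
    if (is.null(membership)) stop("supply either membership or spec")
    spec <- masked_spec(membership, hyper)
  }
  ids <- rownames(expr)
  if (is.null(test_ids)) {
    sp <- split_train_test(ids, control$train_fraction, seed)
  } else {
    if (!all(test_ids %in% ids)) stop("unknown test_ids")
    sp <- list(train = setdiff(ids, test_ids), test = test_ids)
  }
  expr_log <- to_log2(expr, scale)
  prep <- fit_preprocessor(expr_log[sp$train, , drop = FALSE], spec,
                           scale = "log2")
  layers <- spec_layers(spec)
  x_train <- apply_preprocessor(prep, expr_log[sp$train, , drop = FALSE])
  x_test <- apply_preprocessor(prep, expr_log[sp$test, , drop = FALSE])
  monitor <- list(x = x_test, y = ages[sp$test])
  members <- lapply(seq_len(n_members), function(m) {
    train_member(spec, x_train, ages[sp$train], control,
                 seed = seed + m, monitor = monitor, layers = layers)
  })
  clock <- stack_ensemble(members, spec, prep)
  clock$control <- control
  clock$seed <- seed
  clock$input_scale <- scale
  clock$data <- list(expr_log = expr_log, ages = ages,
                     train = sp$train, test = sp$test)
  clock$call <- match.call()
  clock
}

# Ensemble forward on an already log2-scale matrix.
clock_predict_log <- function(clock, expr_log) {
  x <- apply_preprocessor(clock$preprocessor, expr_log)
  n <- nrow(x)
  P <- if (clock$spec$has_aux) length(clock$spec$pathways) else 0L
  main <- matrix(0, n, length(clock$members))
  aux <- if (P > 0L) array(0, c(n, P, length(clock$members))) else NULL
  for (m in seq_along(clock$members)) {
    fw <- forward_net(clock$members[[m]]$net, clock$layers, x,
                      training = FALSE)
    main[, m] <- fw$main
    if (P > 0L) aux[, , m] <- fw$aux
  }
  age <- rowMeans(main)
  names(age) <- rownames(expr_log)
  pathways <- NULL
  if (P > 0L) {
    pathways <- apply(aux, c(1L, 2L), mean)
    dimnames(pathways) <- list(rownames(expr_log), clock$spec$pathways)
  }
  list(age = age, pathways = pathways)
}

#' Predict age and pathway activations
#'
#' Deterministic inference (dropout off). The main prediction is the mean of
#' the member main outputs; pathway activations ("pathway ages") are the
#' per-pathway mean of the member auxiliary outputs.
#'
#' @param object A fitted `pathclock`.
#' @param newdata Samples x genes matrix; defaults to the held-out test fold
#'   stored in the object.
#' @param type `"age"` (numeric vector), `"pathways"` (samples x pathways
#'   matrix) or `"both"` (list with both).
#' @param scale Input scale of `newdata`; defaults to the scale used at fit
#'   time.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.pathclock <- function(object, newdata = NULL,
                              type = c("age", "pathways", "both"),
                              scale = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$data)) stop("clock carries no data; supply newdata")
    expr_log <- object$data$expr_log[object$data$test, , drop = FALSE]
  } else {
    stopifnot(is.matrix(newdata), !is.null(colnames(newdata)))
    if (nrow(newdata) == 0L) stop("empty sample set")
    scale <- scale %||% object$input_scale %||% "log2"
    expr_log <- to_log2(newdata, scale)
  }
  out <- clock_predict_log(object, expr_log)
  if (type == "pathways" && is.null(out$pathways)) {
    stop("this clock has no auxiliary pathway output")
  }
  switch(type, age = out$age, pathways = out$pathways, both = out)
}

#' Accuracy metrics for an age clock
#'
#' @param predicted Predicted ages.
#' @param actual Chronological ages.
#' @return Named vector with `mae` (median absolute error, years) and `r`
#'   (Pearson correlation).
#' @export
clock_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  r <- if (stats::sd(actual) > 0 && stats::sd(predicted) > 0) {
    stats::cor(predicted, actual)
  } else NA_real_
  c(mae = stats::median(abs(predicted - actual)), r = r)
}

#' @export
print.pathclock <- function(x, ...) {
  cat("Pathway neural-network age clock\n")
  print(x$spec)
  cat("  members:", length(x$members), "\n")
  if (!is.null(x$data)) {
    m <- clock_metrics(predict(x), x$data$ages[x$data$test])
    cat(sprintf("  test fold: n = %d, MAE = %.2f years, r = %.3f\n",
                length(x$data$test), m["mae"], m["r"]))
  }
  invisible(x)
}

#' @export
summary.pathclock <- function(object, ...) {
  out <- list(spec = object$spec, n_members = length(object$members))
  if (!is.null(object$data)) {
    d <- object$data
    pr_tr <- clock_predict_log(object,
                               d$expr_log[d$train, , drop = FALSE])$age
    pr_te <- clock_predict_log(object,
                               d$expr_log[d$test, , drop = FALSE])$age
    out$train <- clock_metrics(pr_tr, d$ages[d$train])
    out$test <- clock_metrics(pr_te, d$ages[d$test])
    out$n_train <- length(d$train)
    out$n_test <- length(d$test)
  }
  class(out) <- "summary.pathclock"
  out
}

#' @export
print.summary.pathclock <- function(x, ...) {
  cat("Ensemble age clock:", x$n_members, "members,",
      format(count_parameters(x$spec), big.mark = ","),
      "parameters per member\n")
  if (!is.null(x$train)) {
    cat(sprintf("  training fold (n = %d): MAE %.2f years, r = %.3f\n",
                x$n_train, x$train["mae"], x$train["r"]))
    cat(sprintf("  test fold     (n = %d): MAE %.2f years, r = %.3f\n",
                x$n_test, x$test["mae"], x$test["r"]))
  }
  invisible(x)
}

#' @export
fitted.pathclock <- function(object, ...) {
  if (is.null(object$data)) stop("clock carries no data")
  d <- object$data
  clock_predict_log(object, d$expr_log[d$train, , drop = FALSE])$age
}

#' @export
residuals.pathclock <- function(object, fold = c("test", "train"), ...) {
  fold <- match.arg(fold)
  if (is.null(object$data)) stop("clock carries no data")
  d <- object$data
  ids <- d[[fold]]
  pred <- clock_predict_log(object, d$expr_log[ids, , drop = FALSE])$age
  pred - d$ages[ids]
}

#' Plot a fitted clock
#'
#' `which = "history"` shows the per-member monitor loss across epochs (the
#' training history); `which = "prediction"` shows predicted against actual
#' age on the test fold.
#'
#' @param x A fitted `pathclock`.
#' @param which `"history"` or `"prediction"`.
#' @param ... Passed to the underlying plotting function.
#' @return Invisibly, `x`.
#' @export
plot.pathclock <- function(x, which = c("history", "prediction"), ...) {
  which <- match.arg(which)
  if (which == "history") {
    hs <- lapply(x$members, function(m) m$history$loss)
    if (!length(hs[[1]])) stop("no training history (0 epochs)")
    H <- do.call(cbind, hs)
    graphics::matplot(H, type = "l", lty = 1, xlab = "epoch",
                      ylab = "monitor loss", main = "Training history", ...)
  } else {
    if (is.null(x$data)) stop("clock carries no data")
    actual <- x$data$ages[x$data$test]
    pred <- predict(x)
    graphics::plot(actual, pred, xlab = "chronological age (years)",
                   ylab = "predicted age (years)",
                   main = "Test-fold predictions", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Save / load a fitted clock
#'
#' The archive holds the blueprint, member weight tensors, preprocessor state
#' and training configuration; reloading reproduces predictions
#' bit-identically.
#'
#' @param clock A `pathclock`.
#' @param path Archive path (RDS).
#' @return `write_clock` invisibly returns `path`; `read_clock` returns the
#'   clock.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "pathclock"))
  saveRDS(list(format = "pathclock_archive", version = 1L, clock = clock),
          path)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "pathclock_archive")) {
    stop("not a pathclock archive: ", path)
  }
  if (obj$version > 1L) stop("archive version ", obj$version,
                             " is newer than this package supports")
  obj$clock
}

#' Read an expression matrix / age table from TSV
#'
#' `read_expression` expects a header row of gene symbols with the first
#' column holding sample IDs; `read_ages` expects two columns
#' (sample ID, age in years).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A samples x genes matrix, or a named numeric vector of ages.
#' @export
read_expression <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @export
read_ages <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d[[2L]]), as.character(d[[1L]]))
}
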