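# Internal neural-network engine for the masked clock: He initialization,
# forward pass with unit dropout, backpropagation of the combined
# main + auxiliary MSE loss, Adam updates, and hard mask enforcement.
# Masked weight positions are exactly zero at initialization, contribute zero
# to every forward pass, and receive zero update (gradients are multiplied by
# the binary mask and weights re-masked after every Adam step).

# He (fan-in) initialization; fan-in of a masked neuron is its number of
# unmasked incoming edges. Consumes the current RNG stream.
init_network <- function(layers) {
  W <- vector("list", length(layers))
  b <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    fan_in <- if (is.null(l$mask)) rep(l$n_in, l$n_out) else colSums(l$mask)
    sd <- sqrt(2 / pmax(fan_in, 1))
    Wi <- matrix(stats::rnorm(l$n_in * l$n_out), l$n_in, l$n_out)
    Wi <- sweep(Wi, 2L, sd, `*`)
    if (!is.null(l$mask)) Wi <- Wi * l$mask
    W[[i]] <- Wi
    b[[i]] <- numeric(l$n_out)
  }
  list(W = W, b = b)
}

# Forward pass. Returns main output (n-vector), aux activations (n x P or
# NULL), and, when keep_cache, the per-layer pre-activations/outputs needed
# for backprop. Dropout (inverted scaling) is applied only when training.
forward_net <- function(net, layers, X, training = FALSE, dropout = 0) {
  n_l <- length(layers)
  A <- vector("list", n_l + 1L)
  Z <- vector("list", n_l)
  D <- vector("list", n_l)
  A[[1L]] <- X
  aux <- NULL
  for (i in seq_len(n_l)) {
    l <- layers[[i]]
    Zi <- A[[i]] %*% net$W[[i]]
    Zi <- Zi + rep(net$b[[i]], each = nrow(Zi))
    Ai <- if (l$activation == "elu") elu(Zi) else Zi
    if (l$role == "aux") aux <- Ai
    if (training && l$dropout && dropout > 0) {
      keep <- 1 - dropout
      Di <- matrix((stats::runif(length(Ai)) < keep) / keep,
                   nrow(Ai), ncol(Ai))
      Ai <- Ai * Di
      D[[i]] <- Di
    }
    Z[[i]] <- Zi
    A[[i + 1L]] <- Ai
  }
  list(main = as.numeric(A[[n_l + 1L]]), aux = aux,
       cache = list(A = A, Z = Z, D = D))
}

# One backprop pass for a mini-batch; returns per-layer gradients of the
# combined loss (1-alpha)*MSE_main + alpha*MSE_aux plus the L2 penalty
# l2 * sum(W^2) on unmasked weights (biases unpenalized). The auxiliary MSE
# pools squared errors over all pathway neurons and samples; its gradient is
# injected at the aggregation layer, which both emits the aux output and
# feeds the main output neuron.
backward_net <- function(net, layers, cache, y, alpha, l2) {
  n_l <- length(layers)
  nb <- length(y)
  gW <- vector("list", n_l)
  gb <- vector("list", n_l)
  has_aux <- any(vapply(layers, function(l) l$role == "aux", logical(1)))
  yhat <- as.numeric(cache$A[[n_l + 1L]])
  w_main <- if (has_aux) (1 - alpha) else 1
  dA <- matrix(w_main * 2 * (yhat - y) / nb, nb, 1L)
  for (i in rev(seq_len(n_l))) {
    l <- layers[[i]]
    if (l$role == "aux") {
      S <- cache$A[[i + 1L]]               # aux layer has no dropout
      P <- ncol(S)
      dA <- dA + alpha * 2 * (S - y) / (nb * P)
    }
    if (!is.null(cache$D[[i]])) dA <- dA * cache$D[[i]]
    dZ <- if (l$activation == "elu") dA * elu_grad_z(cache$Z[[i]]) else dA
    gWi <- crossprod(cache$A[[i]], dZ)
    if (l2 > 0) gWi <- gWi + 2 * l2 * net$W[[i]]
    if (!is.null(l$mask)) gWi <- gWi * l$mask
    gW[[i]] <- gWi
    gb[[i]] <- colSums(dZ)
    if (i > 1L) dA <- tcrossprod(dZ, net$W[[i]])
  }
  list(gW = gW, gb = gb)
}

# Adam keeps its first/second-moment state as single flat vectors (all weight
# tensors, then all biases, column-major) so each step is a handful of
# vectorized operations rather than many small per-layer ones.
adam_init <- function(net) {
  n <- sum(vapply(net$W, length, integer(1))) +
    sum(vapply(net$b, length, integer(1)))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(net, layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  g <- c(unlist(grads$gW, use.names = FALSE),
         unlist(grads$gb, use.names = FALSE))
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  upd <- (lr / (1 - beta1^state$t)) * state$m /
    (sqrt(state$v / (1 - beta2^state$t)) + eps)
  pos <- 0L
  for (i in seq_along(net$W)) {
    len <- length(net$W[[i]])
    net$W[[i]] <- net$W[[i]] - upd[(pos + 1L):(pos + len)]
    if (!is.null(layers[[i]]$mask)) net$W[[i]] <- net$W[[i]] * layers[[i]]$mask
    pos <- pos + len
  }
  for (i in seq_along(net$b)) {
    len <- length(net$b[[i]])
    net$b[[i]] <- net$b[[i]] - upd[(pos + 1L):(pos + len)]
    pos <- pos + len
  }
  list(net = net, state = state)
}

# Combined loss of a network on a dataset (no dropout).
net_loss <- function(net, layers, X, y, alpha, has_aux) {
  fw <- forward_net(net, layers, X, training = FALSE)
  mse_main <- mean((fw$main - y)^2)
  mse_aux <- if (has_aux) mean((fw$aux - y)^2) else 0
  a <- if (has_aux) alpha else 0
  combined_loss(mse_main, mse_aux, a)
}
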