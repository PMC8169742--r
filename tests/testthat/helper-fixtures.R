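# Shared fixtures. Trained clocks are expensive, so they are built once per
# test run and memoized; all fixtures are generated in code from the
# synthetic benchmark generator.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# The synthetic benchmark: n = 500 samples, 4 pathways x 40 genes, one
# planted pathway with slope 0.05 / year, sigma = 1, ages 30-89.
bench_sim <- function(seed = 1L) {
  memo(paste0("sim", seed), simulate_aging_dataset(seed = seed))
}

# 3-member ensemble trained on the benchmark at the full 200-epoch protocol.
bench_clock <- function(seed = 1L) {
  memo(paste0("clock", seed), {
    sim <- bench_sim(seed)
    pathclock(sim$expr, sim$ages, sim$membership, n_members = 3L,
              seed = seed)
  })
}

# Small overlapping-pathway dataset (crossroads genes shared between
# consecutive pathways; every pathway planted so all genes are informative)
# and a quick 2-member clock for perturbation tests.
toy_sim <- function() {
  memo("toysim", simulate_aging_dataset(
    n_samples = 240L, n_pathways = 4L, genes_per_pathway = 30L,
    n_overlap = 6L, n_planted = 4L, slope = 0.05, seed = 42L))
}

# Genome-wide knockdown scan of the benchmark clock (shared across files).
bench_scan <- function() {
  memo("scan1", genome_wide_knockdown(bench_clock(1L)))
}

toy_clock <- function() {
  memo("toyclock", {
    sim <- toy_sim()
    pathclock(sim$expr, sim$ages, sim$membership, n_members = 2L,
              control = clock_control(epochs = 120L), seed = 42L)
  })
}

# Clock trained on a planted *negative*-slope pathway (expression declines
# with age, the classic pro-youth marker situation): knocking such genes
# down must increase predicted age.
neg_sim <- function() {
  memo("negsim", simulate_aging_dataset(
    n_samples = 240L, n_pathways = 3L, genes_per_pathway = 25L,
    n_planted = 1L, slope = -0.05, seed = 7L))
}

neg_clock <- function() {
  memo("negclock", {
    sim <- neg_sim()
    pathclock(sim$expr, sim$ages, sim$membership, n_members = 2L,
              control = clock_control(epochs = 120L), seed = 7L)
  })
}

# Independent oracle: brute-force edge enumeration of the trainable
# parameters of a masked architecture, straight from its definition --
# gene->first-layer edges where membership allows, dense within-pathway
# hidden edges, one aggregation neuron per pathway, one output neuron fed by
# all pathway neurons, one bias per neuron.
count_params_oracle <- function(membership, f = 2, n_hidden = 4L) {
  total <- 0L
  P <- ncol(membership)
  widths <- integer(P)
  for (p in seq_len(P)) {
    genes_p <- which(membership[, p] == 1L)
    w <- 5L + as.integer(floor(length(genes_p) / f))
    widths[p] <- w
    for (g in genes_p) for (j in seq_len(w)) total <- total + 1L   # layer 1
    total <- total + w                                             # biases 1
    for (l in seq_len(n_hidden - 1L)) {
      for (i in seq_len(w)) for (j in seq_len(w)) total <- total + 1L
      total <- total + w
    }
    total <- total + w + 1L            # aggregation neuron edges + bias
  }
  total + P + 1L                       # output neuron edges + bias
}

# Exhaustive enumeration oracle for the two-sided exact Wilcoxon signed-rank
# p-value (no ties, no zeros, n <= 12): enumerate all 2^n sign assignments.
signed_rank_p_oracle <- function(x) {
  n <- length(x)
  stopifnot(n <= 12L, all(x != 0), !anyDuplicated(abs(x)))
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Step-down Holm reference, written independently of stats::p.adjust.
holm_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

random_membership <- function(n_genes, n_pathways, seed) {
  set.seed(seed)
  m <- matrix(rbinom(n_genes * n_pathways, 1L, 0.35), n_genes, n_pathways,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("P%02d", seq_len(n_pathways))))
  # repair empty rows/columns so the matrix is always a valid membership
  for (i in which(rowSums(m) == 0L)) m[i, sample.int(n_pathways, 1L)] <- 1L
  for (j in which(colSums(m) == 0L)) m[sample.int(n_genes, 1L), j] <- 1L
  m
}

new_membership_fixture <- function(ng, np, seed) {
  pathclock:::new_membership(random_membership(ng, np, seed))
}
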