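test_that("combined loss follows the alpha-balanced algebra", {
  expect_equal(combined_loss(1, 2, 0.4)$total, 1.4)
  expect_equal(combined_loss(3.3, 9.9, 0)$total, 3.3)
  expect_equal(combined_loss(3.3, 9.9, 1)$total, 9.9)
  set.seed(1)
  for (i in 1:1000) {
    a <- runif(1); x <- rexp(1); y <- rexp(1)
    expect_equal(combined_loss(x, y, a)$total, (1 - a) * x + a * y)
  }
  expect_error(combined_loss(1, 1, -0.1), "alpha")
  expect_error(combined_loss(1, 1, 1.1), "alpha")
})

test_that("train/test split is disjoint, exhaustive and seed-reproducible", {
  ids <- sprintf("s%03d", 1:887)
  sp <- split_train_test(ids, 0.7, seed = 3)
  expect_length(sp$train, round(0.7 * 887))  # 621
  expect_length(sp$test, 887 - 621)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_train_test(ids, 0.7, seed = 3))
  expect_false(identical(sp, split_train_test(ids, 0.7, seed = 4)))

  sp10 <- split_train_test(letters[1:10], 0.7, seed = 1)
  expect_length(sp10$train, 7)
  expect_error(split_train_test("a", 0.7, 1), "at least 2")
  expect_error(split_train_test(letters[1:5], 1.2, 1), "between 0 and 1")
})

test_that("preprocessor z-scales on the log2 scale and handles degenerate genes", {
  spec <- masked_spec(pathclock:::new_membership(
    matrix(1L, 3, 1, dimnames = list(c("gA", "gB", "gC"), "P"))))
  # two-point gene on log scale scales to -1 / +1
  expr <- cbind(gA = c(1, 3), gB = c(2, 2), gC = c(0, 4))
  rownames(expr) <- c("s1", "s2")
  expect_warning(prep <- fit_preprocessor(expr, spec, scale = "log2"),
                 "constant gene")
  x <- pathclock:::apply_preprocessor(prep, expr)
  expect_equal(unname(x[, "gA"]), c(-1, 1))   # two-point z-scale
  expect_equal(unname(x[, "gB"]), c(0, 0))    # constant gene -> zeros

  # linear TPM input is log2(x + 1) transformed: TPM 3 -> 2 before scaling
  expr_lin <- cbind(gA = c(3, 3), gB = c(1, 7), gC = c(0, 1))
  rownames(expr_lin) <- c("s1", "s2")
  expect_warning(prep_lin <- fit_preprocessor(expr_lin, spec, "linear"))
  expect_equal(unname(prep_lin$center["gA"]), 2)  # mean of log2(3+1)

  # spec genes absent from the data are imputed as 0 after scaling
  expr_mis <- cbind(gA = c(1, 3, 5))
  rownames(expr_mis) <- c("s1", "s2", "s3")
  expect_warning(prep_m <- fit_preprocessor(expr_mis, spec, "log2"),
                 "absent")
  xm <- pathclock:::apply_preprocessor(prep_m, expr_mis)
  expect_equal(unname(xm[, "gB"]), rep(0, 3))
  expect_error(fit_preprocessor(cbind(zz = 1:3), spec, "log2"),
               "no spec gene")
})

test_that("backpropagated gradients match finite differences", {
  sim <- simulate_aging_dataset(n_samples = 12, n_pathways = 2,
                                genes_per_pathway = 5, seed = 9)
  spec <- masked_spec(sim$membership, clock_hyper(dropout = 0, n_hidden = 2))
  layers <- pathclock:::spec_layers(spec)
  prep <- suppressWarnings(fit_preprocessor(sim$expr, spec, "log2"))
  x <- pathclock:::apply_preprocessor(prep, sim$expr)
  y <- sim$ages / 50  # keep the objective well-scaled for differencing
  set.seed(4)
  net <- pathclock:::init_network(layers)
  alpha <- 0.4; l2 <- 0.01
  objective <- function(net) {
    l <- pathclock:::net_loss(net, layers, x, y, alpha, TRUE)
    pen <- sum(vapply(net$W, function(w) sum(w^2), numeric(1)))
    l$total + l2 * pen
  }
  fw <- pathclock:::forward_net(net, layers, x, training = FALSE)
  grads <- pathclock:::backward_net(net, layers, fw$cache, y, alpha, l2)
  h <- 1e-6
  set.seed(11)
  for (li in seq_along(layers)) {
    live <- if (is.null(layers[[li]]$mask)) {
      seq_along(net$W[[li]])
    } else which(layers[[li]]$mask == 1)
    for (k in sample(live, min(4, length(live)))) {
      np <- net; np$W[[li]][k] <- np$W[[li]][k] + h
      nm <- net; nm$W[[li]][k] <- nm$W[[li]][k] - h
      num <- (objective(np) - objective(nm)) / (2 * h)
      expect_equal(grads$gW[[li]][k], num, tolerance = 1e-4)
    }
    kb <- sample(seq_along(net$b[[li]]), 1)
    np <- net; np$b[[li]][kb] <- np$b[[li]][kb] + h
    nm <- net; nm$b[[li]][kb] <- nm$b[[li]][kb] - h
    expect_equal(unname(grads$gb[[li]][kb]),
                 (objective(np) - objective(nm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("compiled and pure-R training engines agree", {
  sim <- simulate_aging_dataset(n_samples = 40, n_pathways = 2,
                                genes_per_pathway = 6, seed = 3)
  spec <- masked_spec(sim$membership, clock_hyper(dropout = 0))
  prep <- fit_preprocessor(sim$expr, spec, "log2")
  x <- pathclock:::apply_preprocessor(prep, sim$expr)
  # full-batch training makes the two engines see identical batches
  ctl <- clock_control(epochs = 15, batch_size = 40)
  mR <- train_member(spec, x, sim$ages, ctl, seed = 5, engine = "R")
  mC <- train_member(spec, x, sim$ages, ctl, seed = 5, engine = "cpp")
  expect_equal(mR$history$loss, mC$history$loss, tolerance = 1e-10)
  for (i in seq_along(mR$net$W)) {
    expect_equal(mR$net$W[[i]], mC$net$W[[i]], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(mR$net$b[[i]], mC$net$b[[i]], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("training is seed-reproducible and makes progress", {
  sim <- toy_sim()
  spec <- masked_spec(sim$membership)
  prep <- fit_preprocessor(sim$expr, spec, "log2")
  x <- pathclock:::apply_preprocessor(prep, sim$expr)
  ctl <- clock_control(epochs = 25)
  m1 <- train_member(spec, x, sim$ages, ctl, seed = 8)
  m2 <- train_member(spec, x, sim$ages, ctl, seed = 8)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$net$W, m2$net$W)
  m3 <- train_member(spec, x, sim$ages, ctl, seed = 9)
  expect_false(identical(m1$net$W, m3$net$W))
  # training-progress property on planted data
  expect_lt(m1$history$loss[25], m1$history$loss[1])

  # 0 epochs returns the freshly initialized, untrained network
  m0 <- train_member(spec, x, sim$ages, clock_control(epochs = 0), seed = 8)
  expect_identical(nrow(m0$history), 0L)
  set.seed(8)
  ref <- pathclock:::init_network(pathclock:::spec_layers(spec))
  expect_equal(m0$net$W, ref$W, ignore_attr = TRUE)
})

test_that("loss history honours the alpha boundaries", {
  sim <- simulate_aging_dataset(n_samples = 60, n_pathways = 2,
                                genes_per_pathway = 8, seed = 5)
  spec <- masked_spec(sim$membership)
  prep <- fit_preprocessor(sim$expr, spec, "log2")
  x <- pathclock:::apply_preprocessor(prep, sim$expr)
  h0 <- train_member(spec, x, sim$ages,
                     clock_control(epochs = 3, alpha = 0), seed = 1)$history
  expect_equal(h0$loss, h0$mse_main)
  h1 <- train_member(spec, x, sim$ages,
                     clock_control(epochs = 3, alpha = 1), seed = 1)$history
  expect_equal(h1$loss, h1$mse_aux)
})

test_that("stacked predictions equal the member mean and are deterministic", {
  clock <- toy_clock()
  sim <- toy_sim()
  # member-mean contract on fresh random inputs
  set.seed(31)
  newx <- matrix(rnorm(100 * ncol(sim$expr), mean = 5), 100,
                 dimnames = list(sprintf("n%03d", 1:100),
                                 colnames(sim$expr)))
  ens <- predict(clock, newx, type = "both")
  xs <- pathclock:::apply_preprocessor(clock$preprocessor, newx)
  per_member <- vapply(clock$members, function(m) {
    pathclock:::forward_net(m$net, clock$layers, xs)$main
  }, numeric(100))
  expect_equal(ens$age, rowMeans(per_member), tolerance = 1e-12,
               ignore_attr = TRUE)

  # two members predicting a and b average to (a+b)/2 -- direct check
  expect_equal(unname(ens$age[1]), mean(per_member[1, ]))

  # single-member ensemble is identical to that member
  solo <- stack_ensemble(clock$members[1], clock$spec, clock$preprocessor)
  expect_equal(predict(solo, newx), per_member[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)

  # duplicated input row gives identical outputs (inference determinism)
  dup <- newx[c(1, 1), , drop = FALSE]
  pd <- predict(clock, dup)
  expect_identical(pd[[1]], pd[[2]])

  expect_error(stack_ensemble(list(), clock$spec, clock$preprocessor))
  expect_error(predict(clock, newx[0, , drop = FALSE]), "empty sample")
})

test_that("a clock with a zeroed output layer predicts its output bias", {
  clock <- toy_clock()
  zeroed <- clock
  n_l <- length(zeroed$layers)
  for (m in seq_along(zeroed$members)) {
    zeroed$members[[m]]$net$W[[n_l]][] <- 0
    zeroed$members[[m]]$net$b[[n_l]][] <- 7.5
  }
  sim <- toy_sim()
  p <- predict(zeroed, sim$expr[1:5, ])
  expect_equal(unname(p), rep(7.5, 5))
})

test_that("clock metrics and residuals behave", {
  expect_equal(unname(clock_metrics(c(1, 2, 3), c(1, 2, 3))),
               c(0, 1))
  expect_equal(unname(clock_metrics(c(3, 4, 5), c(1, 2, 3))[1]), 2)
  expect_error(clock_metrics(1:3, 1:4), "length mismatch")

  clock <- toy_clock()
  res <- residuals(clock)
  pred <- predict(clock)
  ages <- toy_clock()$data$ages[toy_clock()$data$test]
  expect_equal(res, pred - ages)
})

test_that("clock archives reload with bit-identical predictions", {
  clock <- toy_clock()
  path <- withr::local_tempfile(fileext = ".rds")
  write_clock(clock, path)
  back <- read_clock(path)
  expect_identical(predict(back), predict(clock))
  expect_error(suppressWarnings(
    read_clock(withr::local_tempfile(fileext = ".rds"))))
  saveRDS(list(format = "other"), path)
  expect_error(read_clock(path), "not a pathclock archive")
})

test_that("expression and age tables round-trip through TSV", {
  sim <- simulate_aging_dataset(n_samples = 8, n_pathways = 2,
                                genes_per_pathway = 4, seed = 13)
  ef <- withr::local_tempfile(fileext = ".tsv")
  af <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = rownames(sim$expr), sim$expr,
                         check.names = FALSE),
              ef, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(sample_id = names(sim$ages), age = sim$ages),
              af, sep = "\t", row.names = FALSE, quote = FALSE)
  e2 <- read_expression(ef)
  a2 <- read_ages(af)
  expect_equal(e2, sim$expr, tolerance = 1e-12)
  expect_equal(a2, sim$ages, tolerance = 1e-12)
})
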