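test_that("expression perturbation is an additive log2 shift", {
  expr <- matrix(10, 3, 2, dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  out <- perturb_expression(expr, c(gA = -2))
  expect_equal(unname(out[, "gA"]), rep(8, 3))
  expect_equal(unname(out[, "gB"]), rep(10, 3))
  expect_equal(unname(expr[, "gA"]), rep(10, 3))  # input untouched

  ident <- perturb_expression(expr, c(gA = 0, gB = 0))
  expect_equal(unclass(ident), unclass(expr), ignore_attr = TRUE)

  skipped <- perturb_expression(expr, c(gZ = -2, gA = 1))
  expect_identical(attr(skipped, "n_skipped"), 1L)
  expect_identical(attr(skipped, "n_applied"), 1L)
  expect_error(perturb_expression(expr, numeric(0)), "empty change")
})

test_that("knockdown effects are local to the pathways containing the gene", {
  clock <- toy_clock()
  sim <- toy_sim()
  m <- sim$membership
  # a gene belonging to exactly one pathway
  solo <- rownames(m)[rowSums(m) == 1L][1]
  eff <- knockdown_effect(clock, solo)
  inside <- colnames(m)[m[solo, ] == 1L]
  outside <- setdiff(colnames(m), inside)
  expect_true(all(eff$delta_activation[, outside] == 0))
  expect_true(any(eff$delta_activation[, inside] != 0))

  expect_error(knockdown_effect(clock, "not-a-gene"), "not in the clock")
})

test_that("perturb-then-revert restores baseline predictions", {
  clock <- toy_clock()
  sim <- toy_sim()
  expr <- sim$expr[clock$data$test, ]
  g <- sim$truth$planted_genes[1]
  base <- predict(clock, expr, type = "both")
  forth <- perturb_expression(expr, setNames(-2, g))
  back <- perturb_expression(forth, setNames(+2, g))
  rest <- predict(clock, back, type = "both")
  expect_equal(rest$age, base$age, tolerance = 1e-6)
  expect_equal(rest$pathways, base$pathways, tolerance = 1e-6)
})

test_that("a one-gene signature reduces exactly to the single-gene knockdown", {
  clock <- toy_clock()
  g <- toy_sim()$truth$planted_genes[1]
  kd <- knockdown_effect(clock, g, log2fc = -2)
  sig <- signature_table(g, -2, 0.001, label = "one")
  sg <- apply_signature(clock, sig)
  expect_identical(sg$delta_age, kd$delta_age)
  expect_identical(sg$delta_activation, kd$delta_activation)
})

test_that("dose response passes through zero and is linear for a linear clock", {
  clock <- toy_clock()
  g <- toy_sim()$truth$planted_genes[1]
  dr <- dose_response(clock, g, c(-2, 0, 2))
  expect_identical(dr$median_delta_age[dr$log2fc == 0], 0)

  # linear-network oracle: strip the elu activations from an untrained clock
  # and compare with the closed-form mask-weighted linear response
  sim <- simulate_aging_dataset(n_samples = 30, n_pathways = 2,
                                genes_per_pathway = 6, seed = 21)
  spec <- masked_spec(sim$membership, clock_hyper(dropout = 0))
  prep <- fit_preprocessor(sim$expr, spec, "log2")
  x0 <- pathclock:::apply_preprocessor(prep, sim$expr)
  member <- train_member(spec, x0, sim$ages, clock_control(epochs = 0),
                         seed = 2)
  lin <- stack_ensemble(list(member), spec, prep)
  for (i in seq_along(lin$layers)) lin$layers[[i]]$activation <- "linear"
  gene <- spec$input_genes[1]
  W <- member$net$W
  path_gain <- W[[1]][1, , drop = FALSE]
  for (i in 2:length(W)) path_gain <- path_gain %*% W[[i]]
  gain <- drop(path_gain) / prep$sd[gene]
  dr_lin <- dose_response(lin, gene, c(-2, -1, 0, 1, 2), expr = sim$expr,
                          scale = "log2")
  expect_equal(dr_lin$median_delta_age, c(-2, -1, 0, 1, 2) * gain,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(dose_response(clock, g, numeric(0)), "empty")
})

test_that("genome-wide scan covers every gene and recovers planted effects", {
  clock <- bench_clock(1)
  sim <- bench_sim(1)
  scan <- bench_scan()
  expect_identical(sort(scan$gene), sort(clock$spec$input_genes))
  expect_identical(order(scan$delta_age, decreasing = TRUE),
                   seq_len(nrow(scan)))
  expect_true(all(colnames(sim$membership) %in% names(scan)))
  # direction recovery: knocking down positive-slope planted genes
  # rejuvenates; null-gene effects are centred on zero
  pl <- scan$gene %in% sim$truth$planted_genes
  expect_gte(mean(scan$delta_age[pl] < 0), 0.9)
  expect_lt(wilcox.test(scan$delta_age[pl], scan$delta_age[!pl],
                        alternative = "less")$p.value, 1e-6)
  # the rejuvenating extreme of the scan is dominated by planted genes
  neg10 <- scan$gene[order(scan$delta_age)][1:10]
  expect_gte(sum(neg10 %in% sim$truth$planted_genes), 7L)

  # all-zero weights produce exactly zero deltas everywhere
  zeroed <- clock
  for (m in seq_along(zeroed$members)) {
    for (i in seq_along(zeroed$members[[m]]$net$W)) {
      zeroed$members[[m]]$net$W[[i]][] <- 0
    }
  }
  scan0 <- genome_wide_knockdown(zeroed, genes = sim$truth$planted_genes[1:3])
  expect_true(all(scan0$delta_age == 0))
})

test_that("homolog mapping re-keys, drops unmapped and resolves collisions", {
  sig <- signature_table(c("rGene1", "rGene2", "rGene3"), c(-2, 1, 0.5),
                         c(0.01, 0.04, 0.2), label = "rat",
                         species = "Rattus norvegicus")
  map <- data.frame(rat = c("rGene1", "rGene2"),
                    human = c("HGENE1", "HGENE2"))
  expect_message(out <- map_homologs(sig, map), "1 record")
  expect_setequal(out$gene, c("HGENE1", "HGENE2"))
  expect_identical(attr(out, "n_unmapped"), 1L)

  # two sources collapsing to one target keep the smaller FDR
  map2 <- data.frame(rat = c("rGene1", "rGene2"), human = c("H", "H"))
  expect_message(coll <- map_homologs(sig, map2), "collision")
  expect_identical(nrow(coll), 1L)
  expect_identical(coll$fdr, 0.01)

  expect_error(map_homologs(sig, map[0, ]), "empty mapping")
  expect_error(map_homologs(sig, data.frame(rat = c("a", "a"),
                                            human = c("x", "y"))),
               "unique")
})

test_that("signature application honours the FDR filter", {
  clock <- toy_clock()
  truth <- toy_sim()$truth
  weak <- signature_table(truth$planted_genes[1:3], rep(-2, 3),
                          rep(0.5, 3))
  expect_error(apply_signature(clock, weak), "no signature record")

  mixed <- signature_table(truth$planted_genes[1:4], rep(-2, 4),
                           c(0.01, 0.2, 0.01, 0.9))
  eff <- apply_signature(clock, mixed)
  expect_identical(eff$n_applied, 2L)
})

test_that("synthetic aging and rejuvenating signatures shift age as constructed", {
  clock <- toy_clock()
  truth <- toy_sim()$truth
  up <- apply_signature(clock, simulate_signature(truth, "aging"))
  down <- apply_signature(clock, simulate_signature(truth, "rejuvenating"))
  expect_gt(median(up$delta_age), 0)
  expect_lt(median(down$delta_age), 0)
})

test_that("knocking down an age-declining gene increases predicted age", {
  clock <- neg_clock()
  g <- neg_sim()$truth$planted_genes[1]
  eff <- knockdown_effect(clock, g, log2fc = -2)
  expect_gt(median(eff$delta_age), 0)
  # and a zero-effect gene moves predictions less than the planted one
  null_gene <- setdiff(neg_clock()$spec$input_genes,
                       neg_sim()$truth$planted_genes)[1]
  null_eff <- knockdown_effect(clock, null_gene, log2fc = -2)
  expect_lt(abs(median(null_eff$delta_age)), abs(median(eff$delta_age)))
})
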