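test_that("identical groups give zero log fold-change everywhere", {
  set.seed(61)
  half <- matrix(rnorm(60), nrow = 10)
  values <- cbind(half, half)
  rownames(values) <- sprintf("g%02d", 1:10)
  dge <- differential_expression(values,
                                 rep(c("test", "control"), each = 6))
  expect_equal(dge$logfc, rep(0, 10))
  expect_equal(dge$p_value, rep(1, 10))
})

test_that("swapping group labels negates logFC and preserves p-values", {
  sim <- simulate_expression(40, planted_logfc = c(gene0003 = 1.5),
                             seed = 62)
  d1 <- differential_expression(sim$values, sim$groups)
  d2 <- differential_expression(
    sim$values, ifelse(sim$groups == "test", "control", "test"))
  expect_equal(d2$logfc, -d1$logfc)
  expect_equal(d2$p_value, d1$p_value)
})

test_that("a planted 2.62 logFC is recovered without bias", {
  est <- vapply(1:50, function(s) {
    sim <- simulate_expression(60, planted_logfc = c(gene0001 = 2.62),
                               noise_sd = 0.2, seed = s)
    differential_expression(sim)$logfc[1]
  }, numeric(1))
  expect_lt(abs(mean(est) - 2.62), 0.1)
})

test_that("Welch p-values agree in rank with a moderated-t cross-check", {
  skip_if_not_installed("limma")
  sim <- simulate_expression(100,
                             planted_logfc = c(gene0001 = 2, gene0002 = -2),
                             seed = 63)
  dge <- differential_expression(sim)
  design <- cbind(1, sim$groups == "test")
  fit <- limma::eBayes(limma::lmFit(sim$values, design))
  # identical logFC estimators; the two smallest p-values pick the same genes
  expect_equal(dge$logfc, unname(fit$coefficients[, 2]), tolerance = 1e-9)
  expect_setequal(order(dge$p_value)[1:2], order(fit$p.value[, 2])[1:2])
})

test_that("type-I error stays at or below nominal on null data", {
  frac <- vapply(1:20, function(s) {
    sim <- simulate_expression(150, noise_sd = 0.3, seed = 1000 + s)
    mean(differential_expression(sim)$adj_p < 0.05)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / (20 * 150))
  expect_lte(mean(frac), 0.05 + 2 * se)
})

test_that("zero-variance genes with equal means get p = 1 by convention", {
  values <- matrix(5, nrow = 2, ncol = 6)
  values[2, 1:3] <- 7
  rownames(values) <- c("flat", "shifted")
  dge <- differential_expression(values,
                                 rep(c("test", "control"), each = 3))
  expect_equal(dge$p_value[1], 1)
  expect_lt(dge$p_value[2], 1e-10)
  expect_equal(dge$logfc[2], 2)
})

test_that("operon summaries aggregate members correctly", {
  rows <- data.frame(
    gene_id = sprintf("g%02d", 1:17),
    logfc = c(rep(1.3, 14), 0.4, -0.6, 2.0),
    p_value = 0.001, adj_p = c(rep(0.01, 14), 0.5, 0.01, 0.01),
    operon_id = NA_character_)
  op_map <- c(stats::setNames(rep("nadh", 14), sprintf("g%02d", 1:14)),
              g15 = "mixed", g16 = "mixed", g17 = "solo")
  sm <- operon_summarize(rows, op_map)
  nadh <- sm[sm$operon_id == "nadh", ]
  expect_equal(nadh$n_members, 14)
  expect_equal(nadh$median_logfc, 1.3)
  expect_equal(nadh$direction, "up")
  expect_equal(nadh$frac_significant, 1)
  # single-gene operon equals its row
  solo <- sm[sm$operon_id == "solo", ]
  expect_equal(solo$median_logfc, 2.0)
  expect_equal(solo$n_members, 1)
  # mixed-sign operon median agrees with the sorting oracle
  mixed <- sm[sm$operon_id == "mixed", ]
  expect_equal(mixed$median_logfc,
               sort(c(0.4, -0.6))[1] / 2 + sort(c(0.4, -0.6))[2] / 2)
  # unmapped genes are collected
  rows2 <- rbind(rows, data.frame(gene_id = "g99", logfc = 1,
                                  p_value = 0.1, adj_p = 0.1,
                                  operon_id = NA_character_))
  expect_true("unmapped" %in% operon_summarize(rows2, op_map)$operon_id)
})

test_that("affected-gene report partitions and reports fractions", {
  # 50 up, 17 down, 33 null: the up/down split is 75%/25% of affected
  planted <- c(stats::setNames(rep(2, 50), sprintf("gene%04d", 1:50)),
               stats::setNames(rep(-2, 17), sprintf("gene%04d", 51:67)))
  sim <- simulate_expression(100, planted_logfc = planted,
                             noise_sd = 0.1, seed = 64)
  rep_ <- affected_gene_report(differential_expression(sim),
                               logfc_threshold = 1,
                               adjp_threshold = 0.05)
  expect_equal(unname(rep_$counts["up"]), 50)
  expect_equal(unname(rep_$counts["down"]), 17)
  expect_equal(unname(rep_$fractions["up"]), 50 / 67, tolerance = 1e-9)
  expect_equal(unname(rep_$fractions["down"]), 17 / 67, tolerance = 1e-9)
  # an unreachable threshold leaves everything unchanged
  rep2 <- affected_gene_report(differential_expression(sim),
                               logfc_threshold = 1e6)
  expect_equal(unname(rep2$counts["unchanged"]), 100)
  expect_error(affected_gene_report(data.frame(), logfc_threshold = 0),
               "positive")
})

test_that("group structure is validated", {
  sim <- simulate_expression(10, seed = 65)
  expect_error(differential_expression(sim$values, c("test", "control")),
               "every sample")
  expect_error(differential_expression(sim$values,
                                       rep(c("a", "b"), each = 3)),
               "test")
  v <- sim$values; rownames(v) <- rep("dup", 10)
  expect_error(differential_expression(v, sim$groups), "duplicate")
})
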