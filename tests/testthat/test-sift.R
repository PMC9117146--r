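test_that("normalization scales cells to the target library and log-transforms", {
  em <- make_expr(cbind(c(2, 0, 2), c(1, 1, 2)))
  nm <- normalize_counts(em, scale = 4)
  expect_equal(nm$norm[, 1], c(log(3), 0, log(3)), ignore_attr = TRUE)
  # equal library sizes: normalization is a global scaling
  expect_equal(nm$norm[, 2], log1p(c(1, 1, 2)), ignore_attr = TRUE)
  expect_equal(sum(nm$norm == 0), sum(em$counts == 0))  # sparsity preserved
  em0 <- make_expr(cbind(c(1, 1, 0), c(0, 0, 0)))
  expect_error(normalize_counts(em0), "zero-total")
})

resp_fixture <- function(mut_counts, wt_counts, gene = "IFNG") {
  n1 <- length(mut_counts)
  n2 <- length(wt_counts)
  # large constant filler gene keeps library sizes near-constant so the
  # designed fold change survives library normalization
  counts <- rbind(c(mut_counts, wt_counts), rep(1000, n1 + n2))
  em <- make_expr(counts, genes = c(gene, "FILL"),
                  condition = rep(c("MUT", "WT"), c(n1, n2)))
  vdj <- make_vdj(em$barcodes, "cl1")
  list(norm = normalize_counts(em, scale = 1000), vdj = vdj)
}

test_that("log2 ratio identities: equality gives 0, 4-fold gives ~2, swap negates", {
  f <- resp_fixture(c(4, 4, 4), c(4, 4, 4))
  r <- clonotype_response_table(f$norm, f$vdj)
  expect_equal(r$log2_ratio, 0)
  f4 <- resp_fixture(c(40, 40, 40), c(10, 10, 10))
  r4 <- clonotype_response_table(f4$norm, f4$vdj)
  expect_equal(r4$log2_ratio, 2, tolerance = 0.05)  # means >> eps
  # swapping condition labels negates the ratio exactly
  f_swap <- resp_fixture(c(10, 10, 10), c(40, 40, 40))
  r_swap <- clonotype_response_table(f_swap$norm, f_swap$vdj)
  expect_equal(r_swap$log2_ratio, -r4$log2_ratio)
})

test_that("non-evaluable clonotypes are kept with undefined ratio", {
  f <- resp_fixture(c(5, 5), c(5, 5, 5))  # only 2 MUT cells
  r <- clonotype_response_table(f$norm, f$vdj, min_cells = 3)
  expect_false(r$evaluable)
  expect_true(is.na(r$log2_ratio))
  expect_error(clonotype_response_table(f$norm, f$vdj, target_gene = "NOPE"),
               "not in matrix")
})

test_that("clonotype cell counts conserve the assigned-cell total", {
  sim <- simulate_sc_experiment(sim_config(seed = 8))
  fit <- sift(sim$matrix, sim$vdj)
  r <- fit$responses
  expect_equal(sum(r$n_cells_mut + r$n_cells_wt),
               length(unique(fit$vdj$barcode)))
  expect_equal(sum(r$frequency), 1)
})

test_that("the Welch candidate test reproduces the textbook example", {
  responses <- structure(
    data.frame(clonotype_id = "cl1", n_cells_mut = 4, n_cells_wt = 4,
               frequency = 1, mean_target_mut = 3.5, mean_target_wt = 0.5,
               log2_ratio = log2(3.6 / 0.6), evaluable = TRUE,
               stringsAsFactors = FALSE),
    class = c("clonotype_response", "data.frame"))
  expr <- list(cl1 = list(MUT = c(3, 3, 4, 4), WT = c(0, 0, 1, 1)))
  out <- test_candidates(responses, expr)
  o <- oracle_welch(expr$cl1$MUT, expr$cl1$WT)
  # equal group variances of 1/3: t = 3 / sqrt(1/6), Welch-Satterthwaite df 6
  expect_equal(o$t, 3 / sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(o$df, 6, tolerance = 1e-12)
  expect_equal(out$p_value, o$p, tolerance = 1e-12)
  expect_equal(out$p_value, 0.000325, tolerance = 1e-3)
  expect_true(out$is_candidate)
})

test_that("tie handling and the ratio gate behave as specified", {
  responses <- structure(
    data.frame(clonotype_id = c("tie", "gated"),
               n_cells_mut = 4, n_cells_wt = 4, frequency = 0.5,
               mean_target_mut = c(2, 1.5), mean_target_wt = c(2, 1),
               log2_ratio = c(0, log2(1.5)), evaluable = TRUE,
               stringsAsFactors = FALSE),
    class = c("clonotype_response", "data.frame"))
  # force the tie clonotype through the gate to exercise tie handling
  expr <- list(tie = list(MUT = c(2, 2, 2), WT = c(2, 2, 2)),
               gated = list(MUT = c(9, 9, 9), WT = c(0, 0, 0)))
  out <- test_candidates(responses, expr, ratio_threshold = 1)
  expect_equal(out$p_value[out$clonotype_id == "tie"], 1)
  expect_false(out$is_candidate[out$clonotype_id == "tie"])
  # below the default gate: untested regardless of separation
  out2 <- test_candidates(responses, expr, ratio_threshold = 2)
  expect_false(out2$tested[out2$clonotype_id == "gated"])
  expect_true(is.na(out2$p_value[out2$clonotype_id == "gated"]))
})

test_that("Welch statistics match the textbook oracle on random inputs", {
  set.seed(99)
  for (i in 1:50) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    o <- oracle_welch(a, b)
    ht <- t.test(a, b)
    expect_equal(unname(ht$statistic), o$t, tolerance = 1e-10)
    expect_equal(ht$p.value, o$p, tolerance = 1e-10)
  }
})

test_that("row-wise Welch p-values match the scalar textbook oracle", {
  set.seed(7)
  counts <- matrix(rpois(20 * 12, 5) + 1, 20, 12)
  em <- make_expr(counts, condition = rep(c("MUT", "WT"), each = 6))
  vdj <- make_vdj(em$barcodes, "cl1")
  nm <- normalize_counts(em)
  de <- clonotype_de(nm, vdj, clonotype_id = "cl1")
  for (g in sample(20, 5)) {
    o <- oracle_welch(nm$norm[g, 1:6], nm$norm[g, 7:12])
    expect_equal(de$p_value[g], o$p, tolerance = 1e-10)
  }
})

test_that("lineage prediction follows the CD3E gate and CD8A/CD4 comparison", {
  mk_norm <- function(cd8, cd4, cd3) {
    counts <- rbind(cd8, cd4, cd3, rep(20, length(cd8)))
    make_expr(counts, genes = c("CD8A", "CD4", "CD3E", "FILL"))
  }
  nm <- normalize_counts(mk_norm(c(2, 2, 3), c(0, 0, 0), c(1, 1, 1)),
                         scale = 1)
  out <- predict_hla_class(nm, nm$barcodes)
  expect_equal(out$call, "CLASS_I")
  expect_lt(out$p, 0.05)
  # CD4-dominant clonotype
  nm2 <- normalize_counts(mk_norm(c(0, 0, 0), c(3, 2, 3), c(1, 1, 1)),
                          scale = 1)
  expect_equal(predict_hla_class(nm2, nm2$barcodes)$call, "CLASS_II")
  # identical markers: indeterminate
  nm3 <- normalize_counts(mk_norm(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
                          scale = 1)
  expect_equal(predict_hla_class(nm3, nm3$barcodes)$call, "INDETERMINATE")
  # CD3E undetected: gated to indeterminate regardless of separation
  nm4 <- normalize_counts(mk_norm(c(5, 5, 5), c(0, 0, 0), c(0, 0, 0)),
                          scale = 1)
  expect_equal(predict_hla_class(nm4, nm4$barcodes)$call, "INDETERMINATE")
  expect_true(is.na(predict_hla_class(nm4, nm4$barcodes)$p))
})

test_that("planted activation genes are recovered by the per-clonotype volcano", {
  # 150 cells/condition gives the reactive clonotype ~60 cells per aliquot,
  # enough power for every activation gene to clear the BH threshold
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_sc_experiment(sim_config(seed = s * 7,
                                             n_cells_per_condition = 150))
    fit <- sift(sim$matrix, sim$vdj)
    de <- clonotype_de(fit, clonotype_id = "clonotype1")
    up <- de$gene[de$direction == "up"]
    if (all(c("IFNG", "TNF", "IL2", "XCL1") %in% up)) hits <- hits + 1
    expect_false(any(de$direction[de$gene %in%
                                    c("IFNG", "TNF", "IL2", "XCL1")] ==
                       "down"))
  }
  expect_gte(hits, 9)
})

test_that("permuted condition labels produce at most alpha-level flags", {
  sim <- simulate_sc_experiment(sim_config(seed = 44))
  set.seed(1)
  perm <- sim$matrix
  perm$condition <- sample(perm$condition)
  fit <- sift(perm, sim$vdj)
  de <- clonotype_de(fit, clonotype_id = "clonotype1")
  expect_lte(sum(de$direction != "none"), 3)
})

test_that("degenerate DE inputs: identical groups give adjusted p of 1", {
  counts <- rbind(rep(3, 8), rep(10, 8))
  em <- make_expr(counts, genes = c("GENE", "FILL"),
                  condition = rep(c("MUT", "WT"), each = 4))
  vdj <- make_vdj(em$barcodes, "cl1")
  nm <- normalize_counts(em, scale = 1)
  de <- clonotype_de(nm, vdj, clonotype_id = "cl1")
  expect_equal(de$adjusted_p, c(1, 1))
  expect_true(all(de$direction == "none"))
})

test_that("TCR retrieval returns the majority pair and flags ambiguity", {
  sim <- simulate_sc_experiment(sim_config(seed = 14))
  chains <- sim$truth$clonotype_chains
  rep1 <- retrieve_tcr(sim$vdj, "clonotype1")
  truth <- chains[chains$clonotype_id == "clonotype1", ]
  expect_equal(rep1$TRA$cdr3_aa, truth$tra_cdr3)
  expect_equal(rep1$TRB$cdr3_aa, truth$trb_cdr3)
  expect_false(rep1$missing_chain)
  # 7:3 split between two TRA variants sharing one TRB
  vdj <- rbind(
    make_vdj(sprintf("B%d", 1:10), "clx", chain = "TRB", cdr3_aa = "CASSB"),
    make_vdj(sprintf("B%d", 1:7), "clx", chain = "TRA", cdr3_aa = "CAMAJ"),
    make_vdj(sprintf("B%d", 8:10), "clx", chain = "TRA", cdr3_aa = "CAMIN"))
  class(vdj) <- c("vdj_table", "data.frame")
  repx <- retrieve_tcr(vdj, "clx")
  expect_equal(repx$TRA$cdr3_aa, "CAMAJ")
  expect_true(repx$ambiguous_tra)
  # missing TRB flagged; unknown clonotype errors
  vdj_a <- make_vdj("B1", "cly", chain = "TRA")
  expect_true(retrieve_tcr(vdj_a, "cly")$missing_chain)
  expect_error(retrieve_tcr(vdj_a, "nope"), "not found")
})

test_that("sift fit methods print, summarize and plot without error", {
  sim <- simulate_sc_experiment(sim_config(seed = 2))
  fit <- sift(sim$matrix, sim$vdj)
  expect_s3_class(fit, "sift")
  expect_output(print(fit), "SIFT-seq fit")
  s <- summary(fit)
  expect_output(print(s), "candidates")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("log2 ratio is invariant to cell order", {
  sim <- simulate_sc_experiment(sim_config(seed = 23))
  q <- run_qc(sim$matrix, sim$vdj)
  nm <- normalize_counts(q$matrix)
  r1 <- clonotype_response_table(nm, q$vdj)
  perm <- sample(ncol(q$matrix$counts))
  em2 <- expr_matrix(q$matrix$counts[, perm], q$matrix$condition[perm])
  r2 <- clonotype_response_table(normalize_counts(em2), q$vdj)
  r2 <- r2[match(r1$clonotype_id, r2$clonotype_id), ]
  expect_equal(r1$log2_ratio, r2$log2_ratio)
})
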