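test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulate_sc_experiment(sim_config(seed = 7))
  b <- simulate_sc_experiment(sim_config(seed = 7))
  expect_identical(a, b)
  qa <- simulate_qpcr_plate(12, hit_wells = 3, seed = 5)
  qb <- simulate_qpcr_plate(12, hit_wells = 3, seed = 5)
  expect_identical(qa, qb)
  ma <- simulate_mutation_cohort(n = 30, seed = 2)
  mb <- simulate_mutation_cohort(n = 30, seed = 2)
  expect_identical(ma, mb)
  ha <- simulate_hla_sites(seed = 4)
  hb <- simulate_hla_sites(seed = 4)
  expect_identical(ha, hb)
})

test_that("planted violation counts are forced exactly and disjoint", {
  cfg <- sim_config(seed = 21, n_cells_per_condition = 1000,
                    doublet_rate = 0.05, high_mito_rate = 0.02,
                    low_gene_rate = 0.03, multi_chain_rate = 0.01,
                    no_vdj_rate = 0.02)
  sim <- simulate_sc_experiment(cfg)
  tc <- sim$truth$cells
  expect_equal(sum(tc$is_doublet), round(0.05 * 2000))
  expect_equal(sum(tc$is_high_mito), round(0.02 * 2000))
  expect_equal(sum(tc$is_low_gene), round(0.03 * 2000))
  expect_equal(sum(tc$is_multi_chain), round(0.01 * 2000))
  expect_equal(sum(!tc$has_vdj), round(0.02 * 2000))
  flags <- tc$is_doublet + tc$is_high_mito + tc$is_low_gene +
    tc$is_multi_chain + (!tc$has_vdj)
  expect_true(all(flags <= 1))
  # planted violations have the promised phenotypes
  mt <- grepl("^MT-", sim$matrix$gene_names)
  mito_frac <- colSums(sim$matrix$counts[mt, ]) / colSums(sim$matrix$counts)
  expect_true(all(mito_frac[tc$is_high_mito] > 0.15))
  detected <- colSums(sim$matrix$counts > 0)
  expect_true(all(detected[tc$is_low_gene] < 200))
  n_tra <- table(factor(sim$vdj$barcode[sim$vdj$chain == "TRA"],
                        levels = tc$barcode))
  expect_true(all(as.vector(n_tra)[tc$is_multi_chain] == 3))
  expect_false(any(tc$barcode[!tc$has_vdj] %in% sim$vdj$barcode))
})

test_that("clonotype structure is shared between conditions and labels cover all cells", {
  sim <- simulate_sc_experiment(sim_config(seed = 3))
  tc <- sim$truth$cells
  expect_equal(nrow(tc), 100)
  expect_setequal(tc$barcode, sim$matrix$barcodes)
  expect_equal(sort(unique(tc$condition)), c("MUT", "WT"))
  # the dominant clonotype is large in both aliquots (shared Zipf law)
  tab <- table(tc$clonotype_id, tc$condition)
  expect_true(all(tab["clonotype1", ] >= 5))
})

test_that("the planted reactive effect lands near the configured fold", {
  ratios <- vapply(1:100, function(s) {
    sim <- simulate_sc_experiment(sim_config(seed = s))
    tc <- sim$truth$cells
    cnt <- sim$matrix$counts["IFNG", ]
    mean(cnt[tc$clonotype_id == "clonotype1" & tc$condition == "MUT"]) /
      mean(cnt[tc$clonotype_id == "clonotype1" & tc$condition == "WT"])
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  expect_gte(median(ratios), 4)
  expect_lte(median(ratios), 16)
  # concentration consistent with ~20 cells/condition of NB(0.5) noise
  expect_gte(mean(ratios >= 4 & ratios <= 16), 0.85)
})

test_that("with effect_fold 1 the MUT and WT IFNG means differ only by noise", {
  cfg <- sim_config(seed = 13, reactive_clonotypes = list(
    list(clonotype_id = "clonotype1", effect_fold = 1,
         activation_genes = "TNF")))
  sims <- lapply(1:40, function(s) { cfg$seed <- s; simulate_sc_experiment(cfg) })
  lr <- vapply(sims, function(sim) {
    tc <- sim$truth$cells
    cnt <- sim$matrix$counts["IFNG", ]
    log(mean(cnt[tc$condition == "MUT"]) / mean(cnt[tc$condition == "WT"]))
  }, numeric(1))
  expect_lt(abs(mean(lr)), 0.1)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(doublet_rate = 1.2), "rates")
  expect_error(sim_config(reactive_clonotypes = list(
    list(clonotype_id = "clonotype1", effect_fold = 0.5,
         activation_genes = "TNF"))), "effect_fold")
  expect_error(sim_config(n_clonotypes = 500, n_cells_per_condition = 10),
               "clonotypes")
  expect_error(simulate_qpcr_plate(hit_delta = 0), "positive")
  expect_error(simulate_mutation_cohort(depth_mean = 0), "positive")
  expect_error(simulate_hla_sites(n_sites = 3), "at least 5")
})

test_that("qPCR plate emits Ct pairs whose difference is the drawn delta", {
  qp <- simulate_qpcr_plate(24, hit_wells = "W07", hit_delta = 4,
                            noise_sd = 0.3, seed = 9)
  expect_equal(qp$plate$ct_wt - qp$plate$ct_mut, qp$truth$delta_ct)
  expect_true(qp$truth$is_hit[qp$truth$well_id == "W07"])
  expect_equal(sum(qp$truth$is_hit), 1)
})

test_that("mutation cohort expected VAF follows the CCF model closed form", {
  # purity 1, CN 2, m 1, clonal CCF 1 => expected VAF 0.5
  mc <- simulate_mutation_cohort(n = 400, clonal_fraction = 1,
                                 depth_mean = 2000,
                                 purity_range = c(1, 1), seed = 31)
  sub <- mc$mutations[mc$mutations$cn_tumor == 2 & mc$mutations$m == 1, ]
  vaf <- sub$alt_reads / (sub$alt_reads + sub$ref_reads)
  expect_equal(mean(vaf), 0.5, tolerance = 0.01)
})

test_that("HLA site simulator matches its closed forms", {
  # loh with purity 1: lost allele receives zero tumor reads
  h <- simulate_hla_sites(n_sites = 10, loh = TRUE, purity = 1,
                          coverage_mean = 100, seed = 5)
  lost <- h$sites[h$sites$allele == h$truth$lost_allele, ]
  expect_true(all(lost$reads_tumor == 0))
  # balanced: tumor VAF centred at 0.5
  h2 <- simulate_hla_sites(n_sites = 200, loh = FALSE, purity = 0.6,
                           coverage_mean = 300, seed = 6)
  v <- site_vaf(h2$sites)
  expect_equal(mean(v$vaf_tumor[v$allele == "A1"]), 0.5, tolerance = 0.02)
  # loh at purity 0.6: lost-allele tumor VAF near (1-p)/((1-p)*2+p) = 0.2857
  h3 <- simulate_hla_sites(n_sites = 200, loh = TRUE, purity = 0.6,
                           coverage_mean = 300, seed = 7)
  v3 <- site_vaf(h3$sites)
  expect_equal(mean(v3$vaf_tumor[v3$allele == h3$truth$lost_allele]),
               0.4 / 1.4, tolerance = 0.02)
})
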