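test_that("reference panel generators are deterministic and pass validation", {
  a <- generate_reference_panel(n_blocks = 2, n_background_genes = 50,
                                n_samples = 40, seed = 5)
  b <- generate_reference_panel(n_blocks = 2, n_background_genes = 50,
                                n_samples = 40, seed = 5)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth$marker_of_block, b$truth$marker_of_block)
  expect_true(all(a$expr >= 0))
  expect_silent(validate_matrix(a$expr))
  c2 <- generate_reference_panel(n_blocks = 2, n_background_genes = 50,
                                 n_samples = 40, seed = 6)
  expect_false(identical(a$expr, c2$expr))
})

test_that("within-block correlation approaches 1 in the low-noise limit", {
  pan <- generate_reference_panel(n_blocks = 1, genes_per_block = 100,
                                  n_background_genes = 0, n_samples = 60,
                                  within_block_corr = 0.99, noise_sd = 0.01,
                                  seed = 2)
  g <- pan$expr[c("B1G001", "B1G002"), ]
  expect_gt(cor(g[1, ], g[2, ]), 0.99)
})

test_that("cross-block genes are uncorrelated and blocks carry their markers", {
  pan <- generate_reference_panel(n_blocks = 2, genes_per_block = 100,
                                  n_background_genes = 0, n_samples = 300,
                                  seed = 3)
  cross <- cor(pan$expr["B1G001", ], pan$expr["B2G001", ])
  expect_lt(abs(cross), 0.2)
  expect_true(all(pan$markers %in% rownames(pan$expr)))
  for (b in names(pan$truth$marker_of_block)) {
    mk <- pan$truth$marker_of_block[[b]]
    expect_identical(unname(pan$truth$cell_type_of_gene[mk]), b)
  }
})

test_that("small blocks trigger the module-exhaustion warning", {
  expect_warning(
    generate_reference_panel(n_blocks = 1, genes_per_block = 20,
                             n_background_genes = 10, n_samples = 20,
                             seed = 1, module_size = 100),
    "recruit background")
})

test_that("tumor cohorts obey the censoring contract", {
  ref <- generate_reference_panel(n_blocks = 1, n_background_genes = 20,
                                  n_samples = 20, seed = 1)
  all_events <- generate_tumor_cohort(50, ref$truth, beta = 0,
                                      censor_rate = 0,
                                      admin_censor_days = 1e9, seed = 2)
  expect_true(all(all_events$clinical$event == 1))
  adm <- generate_tumor_cohort(50, ref$truth, beta = 0, censor_rate = 0,
                               admin_censor_days = 100, seed = 2)
  expect_true(all(adm$clinical$time <= 100))
  expect_true(all(adm$clinical$event[adm$clinical$time == 100] == 0))
  expect_error(generate_tumor_cohort(50, ref$truth, baseline_hazard = 0),
               "hazard")
})

test_that("null cohorts give uniform log-rank p-values for the true split", {
  ref <- generate_reference_panel(n_blocks = 1, n_background_genes = 10,
                                  n_samples = 20, seed = 1)
  ps <- vapply(1:200, function(i) {
    coh <- generate_tumor_cohort(60, ref$truth, beta = 0, seed = 1000 + i)
    part <- make_partition(coh$clinical$sample,
                           coh$clinical$sample[coh$truth$true_hi])
    logrank_test(coh$clinical, part)$p_value
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("infiltrate raises block-gene expression and drives the hazard", {
  ref <- generate_reference_panel(n_blocks = 1, n_background_genes = 100,
                                  n_samples = 20, seed = 1)
  coh <- generate_tumor_cohort(200, ref$truth, beta = -1, seed = 9)
  f <- coh$truth$infiltrate_fraction
  blk <- names(which(coh$truth$cell_type_of_gene == "BLK1"))
  blk_mean <- colMeans(coh$expr[blk, ])
  expect_gt(cor(f, blk_mean), 0.5)
  bg <- setdiff(rownames(coh$expr), blk)
  expect_lt(abs(cor(f, colMeans(coh$expr[bg, ]))), 0.3)
})

test_that("CNV generator plants a contiguous loss in the declared carriers", {
  ref <- generate_reference_panel(n_blocks = 1, n_background_genes = 10,
                                  n_samples = 20, seed = 1)
  coh <- generate_tumor_cohort(100, ref$truth, beta = -1, seed = 2)
  cn <- generate_cnv_profiles(coh$truth, n_genes = 200, region_span = 20,
                              loss_depth = 2, noise_sd = 0.1, seed = 3)
  reg <- cn$truth$deleted_region$index
  expect_equal(length(reg), 20)
  expect_equal(reg, seq(min(reg), max(reg)))
  carriers <- cn$truth$loss_carriers
  others <- setdiff(colnames(cn$cnv), carriers)
  expect_lt(mean(cn$cnv[reg, carriers]), -1.5)
  expect_lt(abs(mean(cn$cnv[reg, others])), 0.2)
  # carriers are mostly low-infiltrate samples
  expect_gt(mean(!coh$truth$true_hi[carriers]), 0.6)
  expect_error(generate_cnv_profiles(coh$truth, n_genes = 10,
                                     region_span = 10), "region_span")
})

test_that("a zero-depth loss leaves the genome scan at the nominal rate", {
  ref <- generate_reference_panel(n_blocks = 1, n_background_genes = 10,
                                  n_samples = 20, seed = 1)
  coh <- generate_tumor_cohort(100, ref$truth, beta = 0, seed = 4)
  cn <- generate_cnv_profiles(coh$truth, n_genes = 300, region_span = 20,
                              loss_depth = 0, seed = 5)
  part <- make_partition(names(coh$truth$true_hi),
                         names(which(coh$truth$true_hi)))
  sc <- scan_partition(cn$cnv, part, cn$positions)
  expect_lt(sum(sc$p < 0.05), qbinom(0.999, 300, 0.05) + 1)
})
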