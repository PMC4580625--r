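test_that("random sample partitions split floor/ceiling with hi taking the extra", {
  even <- random_sample_partitions(sprintf("S%d", 1:6), 50, seed = 1)
  expect_true(all(colSums(even) == 3))
  odd <- random_sample_partitions(sprintf("S%d", 1:7), 50, seed = 1)
  expect_true(all(colSums(odd) == 4))
  again <- random_sample_partitions(sprintf("S%d", 1:7), 50, seed = 1)
  expect_identical(odd, again)
  expect_false(identical(odd,
                         random_sample_partitions(sprintf("S%d", 1:7), 50, 2)))
  pl <- as_partition_list(even[, 1:3, drop = FALSE])
  expect_length(pl, 3)
  expect_equal(sum(pl[[1]]$labels == "hi"), 3)
  expect_error(random_sample_partitions(sprintf("S%d", 1:3), 5), "at least 4")
})

test_that("null count tallies match thresholds and expected-by-chance arithmetic", {
  expect_equal(null_counts(rep(1, 100))$count, c(0, 0))
  nc <- null_counts(c(rep(0.5, 520), rep(2e-3, 3), rep(4e-4, 3)),
                    thresholds = c(1e-3, 5e-3))
  expect_equal(nc$count[1], 3)
  expect_equal(nc$count[2], 6)
  expect_equal(nc$n_tests, c(526, 526))
  expect_equal(nc$expected[2], 2.63)
  expect_error(null_counts(numeric(0)), "no p-values")
})

test_that("random-partition p-values on a null cohort hit the nominal rate", {
  ref <- generate_reference_panel(n_blocks = 1, n_background_genes = 10,
                                  n_samples = 20, seed = 1)
  coh <- generate_tumor_cohort(150, ref$truth, beta = 0, seed = 51)
  p <- null_partition_pvalues(coh$clinical, n_perm = 2000, seed = 52)
  expect_length(p, 2000)
  # 5% level: comfortably inside exact binomial 99.9% bounds
  expect_gte(sum(p < 0.05), qbinom(5e-4, 2000, 0.05))
  expect_lte(sum(p < 0.05), qbinom(1 - 5e-4, 2000, 0.05))
})

test_that("cluster counting equals connected components of the overlap graph", {
  mods <- c("A", "B", "C", "D", "E")
  ov <- diag(5); dimnames(ov) <- list(mods, mods)
  expect_equal(count_significant_clusters(mods, ov), 5)
  ov2 <- matrix(1, 5, 5, dimnames = list(mods, mods))
  expect_equal(count_significant_clusters(mods, ov2), 1)
  # chain A-B (0.3), B-C (0.3), A-C (0.0), D isolated -> 2 components
  ov3 <- diag(4); dimnames(ov3) <- list(mods[1:4], mods[1:4])
  ov3["A", "B"] <- ov3["B", "A"] <- 0.3
  ov3["B", "C"] <- ov3["C", "B"] <- 0.3
  expect_equal(count_significant_clusters(c("A", "B", "C", "D"), ov3), 2)
  # boundary: overlap exactly 0.25 is NOT an edge (rule is strictly greater)
  ov4 <- diag(2); dimnames(ov4) <- list(mods[1:2], mods[1:2])
  ov4["A", "B"] <- ov4["B", "A"] <- 0.25
  expect_equal(count_significant_clusters(c("A", "B"), ov4), 2)
  expect_equal(count_significant_clusters(character(0), ov4), 0L)
  expect_error(count_significant_clusters("ZZ", ov4), "not in overlap")
})

test_that("theme filter keeps multiply-supported themes and drops singletons", {
  cl <- structure(list(cluster = c(m1 = 1L, m2 = 1L, m3 = 2L, m4 = 3L,
                                   m5 = 4L),
                       n_clusters = 4L, hclust = NULL, silhouette = NULL),
                  class = "module_clusters")
  ann <- structure(list(cluster_terms = data.frame(
    cluster = 1:4,
    summary_term = c("T cells", "T cells", "myeloid", "NS"),
    stringsAsFactors = FALSE)), class = "annotation_result")
  # same cluster
  tf <- theme_filter(c("m1", "m2"), cl, ann)
  expect_true(all(tf$supported))
  expect_true(all(tf$support == "cluster"))
  # different clusters, shared summary term
  tf2 <- theme_filter(c("m1", "m3"), cl, ann)
  expect_true(all(tf2$supported))
  expect_true(all(tf2$support == "annotation"))
  # singleton
  tf3 <- theme_filter("m4", cl, ann)
  expect_false(tf3$supported)
  # NS terms never support a theme
  tf4 <- theme_filter(c("m4", "m5"), cl, ann)
  expect_false(any(tf4$supported))
  expect_equal(nrow(theme_filter(character(0), cl, ann)), 0)
})

test_that("per-cohort BH FDR reproduces the step-up formula", {
  scr <- data.frame(cohort = rep(c("c1", "c2"), c(3, 1)),
                    p_value = c(0.01, 0.02, 0.03, 0.2))
  fd <- bh_fdr_per_cohort(scr, cutoffs = c(0.05, 0.5))
  expect_equal(fd$per_cohort$fdr_at_0.05[1], 0.03)
  expect_equal(fd$per_cohort$fdr_at_0.5[2], 0.2)   # single test: FDR = p
  expect_equal(unname(fd$median_fdr["0.5"]), median(c(0.03, 0.2)))
  # order invariance within a cohort
  scr2 <- scr[c(3, 1, 2, 4), ]
  fd2 <- bh_fdr_per_cohort(scr2, cutoffs = c(0.05, 0.5))
  expect_equal(fd$per_cohort, fd2$per_cohort)
})

test_that("cohort summaries tally modules, nulls and clusters per threshold", {
  pan <- generate_reference_panel(n_blocks = 2, n_background_genes = 200,
                                  n_samples = 60, seed = 61)
  col <- build_all_modules(pan$expr, pan$markers)
  rand <- random_gene_sets(rownames(pan$expr), n_sets = 2, seed = 62)
  coh <- generate_tumor_cohort(150, pan$truth, beta = -1.5, seed = 63)
  ms <- suppressMessages(screen(coh$expr, coh$clinical, col,
                                cohort = "melanoma_like"))
  rs <- suppressMessages(screen(coh$expr, coh$clinical, rand,
                                cohort = "melanoma_like"))
  np <- null_partition_pvalues(coh$clinical, 200, seed = 64)
  ov <- overlap_matrix(col)
  cl <- cluster_modules(ov, k = 2)
  tab <- cohort_summary_table(ms, rs, list(melanoma_like = np), ov, cl)
  expect_equal(nrow(tab), 1)
  expect_true(tab$modules_5em03 >= tab$modules_1em03)
  expect_true(tab$clusters_5em03 <= tab$modules_5em03)
  expect_true(tab$top_module %in% names(col))
})
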