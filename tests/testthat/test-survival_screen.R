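test_that("module scores are per-sample medians of present module genes", {
  m <- toy_expr(6, 4)
  s1 <- module_score(m, "G2")
  expect_equal(as.numeric(s1), unname(m["G2", ]))
  s3 <- module_score(m, c("G1", "G3", "G5"))
  expect_equal(as.numeric(s3),
               unname(apply(m[c("G1", "G3", "G5"), ], 2, median)))
  const <- matrix(7, 3, 4, dimnames = list(c("A", "B", "C"),
                                           sprintf("S%d", 1:4)))
  expect_true(all(module_score(const, c("A", "B", "C")) == 7))
})

test_that("module coverage below half triggers a skip, not an error", {
  m <- toy_expr(4, 4)
  sk <- module_score(m, c("G1", "X1", "X2", "X3"))
  expect_s3_class(sk, "screen_skip")
  expect_identical(sk$reason, "coverage")
  ok <- module_score(m, c("G1", "G2", "X1", "X2"), min_coverage = 0.5)
  expect_false(inherits(ok, "screen_skip"))
  expect_identical(attr(ok, "genes_used"), c("G1", "G2"))
})

test_that("median partition sends ties to lo and flags degenerate scores", {
  s <- setNames(c(1, 2, 3, 4), sprintf("S%d", 1:4))
  p <- median_partition(s)
  expect_identical(unname(p$labels), c("lo", "lo", "hi", "hi"))
  s2 <- setNames(c(1, 2, 2, 3), sprintf("S%d", 1:4))
  p2 <- median_partition(s2)
  expect_identical(names(which(p2$labels == "hi")), "S4")
  expect_equal(sum(p2$labels == "lo"), 3)
  s3 <- setNames(rep(5, 6), sprintf("S%d", 1:6))
  expect_s3_class(median_partition(s3), "screen_skip")
  expect_error(median_partition(s[1:3]), "at least 4")
})

test_that("KM estimate matches the hand product-limit oracle", {
  cl <- toy_clinical(sprintf("S%d", 1:4), c(10, 20, 30, 40), c(1, 0, 0, 0))
  km <- km_estimate(cl)
  expect_equal(km_surv_at(km, 10), 0.75)
  expect_equal(km_surv_at(km, 5), 1)
  none <- toy_clinical(sprintf("S%d", 1:3), c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km_surv_at(km_estimate(none), c(1, 10, 100)) == 1))
  mixed <- toy_clinical(sprintf("S%d", 1:6),
                        c(5, 8, 8, 12, 15, 20), c(1, 1, 0, 1, 0, 1))
  km2 <- km_estimate(mixed)
  ora <- oracle_km(mixed$time, mixed$event)
  expect_equal(km_surv_at(km2, ora$time), ora$surv)
  # property: starts at 1, non-increasing
  expect_true(all(diff(km2$surv) <= 0))
  expect_lte(km2$surv[1], 1)
})

test_that("log-rank agrees with the direct O-E oracle and survdiff", {
  cl <- toy_clinical(sprintf("S%d", 1:4), c(1, 2, 3, 4), c(1, 1, 1, 1))
  p <- make_partition(cl$sample, c("S1", "S2"))
  lr <- logrank_test(cl, p)
  ora <- oracle_logrank(cl$time, cl$event, cl$sample %in% c("S1", "S2"))
  expect_equal(lr$chi_square, ora$chisq)
  expect_equal(lr$p_value, ora$p)
  set.seed(31)
  for (i in 1:15) {
    n <- sample(8:40, 1)
    cl2 <- toy_clinical(sprintf("S%d", 1:n),
                        sample(1:15, n, replace = TRUE),  # forces tied times
                        rbinom(n, 1, 0.7))
    hi <- sample(cl2$sample, sample(2:(n - 2), 1))
    p2 <- make_partition(cl2$sample, hi)
    lr2 <- logrank_test(cl2, p2)
    if (inherits(lr2, "screen_skip")) next
    ora2 <- oracle_logrank(cl2$time, cl2$event, cl2$sample %in% hi)
    expect_equal(lr2$chi_square, ora2$chisq, tolerance = 1e-10)
    sd_fit <- survival::survdiff(
      survival::Surv(time, event) ~ I(sample %in% hi), data = cl2)
    expect_equal(lr2$chi_square, sd_fit$chisq, tolerance = 1e-10)
  }
})

test_that("log-rank is label-symmetric and null on identical groups", {
  cl <- toy_clinical(sprintf("S%d", 1:8),
                     rep(c(3, 7, 11, 13), 2), rep(c(1, 1, 0, 1), 2))
  hi <- sprintf("S%d", 1:4)
  lr_a <- logrank_test(cl, make_partition(cl$sample, hi))
  expect_equal(lr_a$chi_square, 0)
  expect_equal(lr_a$p_value, 1)
  set.seed(13)
  cl2 <- toy_clinical(sprintf("S%d", 1:20), rexp(20, 1 / 100),
                      rbinom(20, 1, 0.8))
  hi2 <- sample(cl2$sample, 9)
  a <- logrank_test(cl2, make_partition(cl2$sample, hi2))
  b <- logrank_test(cl2, make_partition(cl2$sample, setdiff(cl2$sample, hi2)))
  expect_equal(a$chi_square, b$chi_square)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$direction, -b$direction)
})

test_that("log-rank skips when untestable", {
  cl <- toy_clinical(sprintf("S%d", 1:4), c(1, 2, 3, 4), c(0, 0, 0, 0))
  sk <- logrank_test(cl, make_partition(cl$sample, c("S1", "S2")))
  expect_s3_class(sk, "screen_skip")
  expect_identical(sk$reason, "no_events")
  cl2 <- toy_clinical(sprintf("S%d", 1:4), c(1, 2, 3, 4), c(1, 1, 1, 1))
  one_sided <- make_partition(cl2$sample, cl2$sample)
  expect_s3_class(logrank_test(cl2, one_sided), "screen_skip")
})

test_that("vectorized log-rank over many partitions equals per-partition tests", {
  set.seed(77)
  n <- 30
  cl <- toy_clinical(sprintf("S%d", 1:n), sample(1:20, n, TRUE),
                     rbinom(n, 1, 0.7))
  hi <- random_sample_partitions(cl$sample, 25, seed = 3)
  many <- logrank_many(cl$time, cl$event, hi)
  for (j in seq(1, 25, by = 6)) {
    single <- logrank_test(cl, as_partition_list(hi[, j, drop = FALSE])[[1]])
    expect_equal(many$chisq[j], single$chi_square, tolerance = 1e-12)
  }
})

test_that("concordance matches pair enumeration, with ties and orientation", {
  cl <- toy_clinical(sprintf("S%d", 1:5), c(3, 9, 6, 14, 2), c(1, 0, 1, 1, 1))
  sc <- setNames(c(2.5, 1.0, 2.5, 0.5, 3.0), cl$sample)
  ci <- concordance_index(sc, cl)
  expect_equal(ci$raw, oracle_cindex(sc, cl$time, cl$event))
  expect_equal(ci$oriented, max(ci$raw, 1 - ci$raw))
  # perfect risk ranking: score inversely ordered with death times
  cl2 <- toy_clinical(sprintf("S%d", 1:5), c(10, 20, 30, 40, 50), rep(1, 5))
  perfect <- setNames(5:1, cl2$sample)
  expect_equal(concordance_index(perfect, cl2)$raw, 1)
  # constant score is exactly uninformative
  expect_equal(concordance_index(setNames(rep(1, 5), cl2$sample), cl2)$raw,
               0.5)
  # C(s) = 1 - C(-s) without score ties
  set.seed(4)
  cl3 <- toy_clinical(sprintf("S%d", 1:12), rexp(12, 0.01), rbinom(12, 1, 0.7))
  s3 <- setNames(rnorm(12), cl3$sample)
  expect_equal(concordance_index(s3, cl3)$raw,
               1 - concordance_index(-s3, cl3)$raw)
  # with no tied times the value agrees with the survival package
  cf <- survival::concordance(
    survival::Surv(cl3$time, cl3$event) ~ s3)
  expect_equal(concordance_index(s3, cl3)$raw, 1 - cf$concordance,
               tolerance = 1e-12)
  # no comparable pairs
  cl4 <- toy_clinical(sprintf("S%d", 1:3), c(1, 2, 3), c(0, 0, 0))
  expect_s3_class(concordance_index(setNames(1:3, cl4$sample), cl4),
                  "screen_skip")
})

test_that("follow-up truncation censors at the horizon and keeps the boundary", {
  cl <- toy_clinical(sprintf("S%d", 1:3), c(2000, 1825, 100), c(1, 1, 1))
  tr <- truncate_followup(cl, 1825)
  expect_equal(tr$time, c(1825, 1825, 100))
  expect_equal(tr$event, c(0, 1, 1))
  under <- toy_clinical(sprintf("S%d", 1:3), c(10, 20, 30), c(1, 0, 1))
  expect_identical(truncate_followup(under), under)
})

test_that("the screen covers every module with results or skip reasons", {
  pan <- generate_reference_panel(n_blocks = 2, n_background_genes = 200,
                                  n_samples = 60, seed = 41)
  col <- build_all_modules(pan$expr, pan$markers)
  coh <- generate_tumor_cohort(120, pan$truth, beta = -1.5, seed = 42)
  res <- suppressMessages(screen(coh$expr, coh$clinical, col))
  expect_s3_class(res, "screen_matrix")
  expect_equal(nrow(res), length(col))
  expect_true(all(!res$skipped))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # planted modules track infiltrate, which is protective here
  expect_true(all(res$direction == 1))
  expect_true(all(res$concordance_oriented >= 0.5 &
                    res$concordance_oriented <= 1))
  # a module of absent genes is skipped with reason
  col2 <- module_collection(list(ghost.mod = sprintf("NO%d", 1:100)),
                            provenance = "random")
  res2 <- suppressMessages(screen(coh$expr, coh$clinical, col2))
  expect_true(res2$skipped)
  expect_identical(res2$reason, "coverage")
  # truncation runs end to end
  res3 <- suppressMessages(screen(coh$expr, coh$clinical, col,
                                  truncate = TRUE))
  expect_equal(nrow(res3), length(col))
  s <- summary(res)
  expect_true(all(c("sig_1e3", "sig_5e3") %in% names(s)))
  nm <- neglog10_matrix(res)
  expect_equal(dim(nm), c(length(col), 1L))
  expect_equal(unname(nm[res$module[1], 1]), -log10(res$p_value[1]))
})
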