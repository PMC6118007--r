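make_genes <- function(ids, chrom) {
  data.frame(gene_id = ids, chrom = chrom, stringsAsFactors = FALSE)
}

test_that("normalization equalizes autosomal totals and ignores the X", {
  genes <- make_genes(c("a1", "a2", "x1"), c("autosome_1", "autosome_1", "X"))
  m <- cbind(s1 = c(100L, 100L, 10L), s2 = c(100L, 100L, 10L), s3 = c(200L, 200L, 10L))
  rownames(m) <- genes$gene_id
  cm <- counts_from_matrix(m, c("Cre+", "Cre-", "Cre-"))
  norm <- normalize_libraries(cm, genes)
  auto_totals <- colSums(norm$norm[c("a1", "a2"), ])
  expect_equal(max(auto_totals) - min(auto_totals), 0, tolerance = 1e-9)
  # the doubled sample gets half the factor of the equal ones
  expect_equal(unname(norm$scale_factors["s3"] / norm$scale_factors["s1"]), 0.5)
  # equal autosomal totals -> all factors 1, even with X inflated in Cre+
  m2 <- cbind(s1 = c(100L, 100L, 90L), s2 = c(100L, 100L, 10L), s3 = c(100L, 100L, 10L))
  rownames(m2) <- genes$gene_id
  cm2 <- counts_from_matrix(m2, c("Cre+", "Cre-", "Cre-"))
  expect_equal(unname(normalize_libraries(cm2, genes)$scale_factors), rep(1, 3))
  # zero autosomal reads is an error
  m3 <- m
  m3[c("a1", "a2"), "s1"] <- 0L
  expect_error(normalize_libraries(counts_from_matrix(m3, c("Cre+", "Cre-", "Cre-")),
                                   genes), "zero autosomal")
})

test_that("the low-coverage filter uses the strict fewer-than boundary on raw totals", {
  m <- cbind(s1 = c(10L, 10L, 0L), s2 = c(9L, 10L, 0L))
  rownames(m) <- c("g19", "g20", "g0")
  cm <- counts_from_matrix(m, c("Cre+", "Cre-"))
  kept <- filter_low_coverage(cm, 20)
  expect_identical(kept, "g20")
  expect_setequal(filter_low_coverage(cm, 0), c("g19", "g20", "g0"))
})

test_that("reactivation ratios follow the closed form and flag zero totals", {
  genes <- make_genes(c("a1", "x1", "x2", "x3"),
                      c("autosome_1", "X", "X", "X"))
  m <- cbind(p1 = c(1000L, 100L, 103L, 0L), n1 = c(1000L, 100L, 100L, 50L))
  rownames(m) <- genes$gene_id
  cm <- counts_from_matrix(m, c("Cre+", "Cre-"))
  rr <- reactivation_ratio(normalize_libraries(cm, genes),
                           c("x1", "x2", "x3"))
  expect_equal(rr$ratio, c(0.5, 103 / 203, 0))
  # zero in both conditions -> NA ratio
  m2 <- cbind(p1 = c(1000L, 0L), n1 = c(1000L, 0L))
  rownames(m2) <- c("a1", "x1")
  rr2 <- reactivation_ratio(normalize_libraries(
    counts_from_matrix(m2, c("Cre+", "Cre-")), genes[1:2, ]), "x1")
  expect_true(is.na(rr2$ratio))
})

test_that("stratification yields equal bins with remainders in the lowest bins", {
  ids <- sprintf("g%03d", 1:540)
  expr <- seq_along(ids)
  b3 <- stratify_by_expression(ids, expr, 3)
  expect_identical(as.integer(table(b3$bin)), rep(180L, 3))
  b4 <- stratify_by_expression(ids, expr, 4)
  expect_identical(as.integer(table(b4$bin)), rep(135L, 4))
  b7 <- stratify_by_expression(sprintf("g%d", 1:7), 7:1, 3)
  expect_identical(as.integer(table(b7$bin)), c(3L, 2L, 2L))
  # bin index is nondecreasing in expression
  expect_true(all(diff(b3$bin[order(expr[match(b3$gene_id, ids)])]) >= 0))
  # ties broken by lexicographic gene id
  bt <- stratify_by_expression(c("b", "a", "c", "d"), c(1, 1, 1, 1), 2)
  expect_identical(bt$gene_id, c("a", "b", "c", "d"))
  expect_identical(bt$bin, c(1L, 1L, 2L, 2L))
  expect_error(stratify_by_expression(c("a", "b"), 1:2, 3), "exceeds")
})

test_that("between-bin t test handles identity, degenerate groups, and has the MC power of its summaries", {
  ids <- sprintf("g%03d", 1:60)
  rr <- data.frame(gene_id = ids, ratio = rep(c(0.4, 0.5, 0.6), 20),
                   stringsAsFactors = FALSE)
  bins <- data.frame(gene_id = ids, bin = rep(1:2, each = 30))
  rr$ratio[31:60] <- rr$ratio[1:30]  # identical groups
  cmp <- compare_bins(rr, bins, 1, 2)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  # group of size 1 errors
  bins1 <- data.frame(gene_id = ids, bin = c(1L, rep(2L, 59)))
  expect_error(compare_bins(rr, bins1, 1, 2), ">= 2")
  # Monte-Carlo power oracle at the printed tercile summaries
  # (0.509 +/- 0.047, n=180 vs 0.495 +/- 0.096, n=180): closed-form power
  # of the two-sided t at alpha = 0.05 is ~0.44, and the MC agrees
  set.seed(424)
  hits <- 0L
  n_mc <- 600
  ids180 <- sprintf("g%03d", 1:360)
  bins180 <- data.frame(gene_id = ids180, bin = rep(1:2, each = 180))
  for (i in seq_len(n_mc)) {
    rrk <- data.frame(gene_id = ids180,
                      ratio = c(stats::rnorm(180, 0.509, 0.047),
                                stats::rnorm(180, 0.495, 0.096)))
    if (compare_bins(rrk, bins180, 1, 2)$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / n_mc, 0.35)
  expect_lt(hits / n_mc, 0.55)
})

test_that("the ratio inverts to the per-cell reactivation fraction", {
  expect_equal(estimate_reactivation_fraction(0.5), 0)
  expect_equal(estimate_reactivation_fraction(103 / 203), 0.03)
  expect_lt(estimate_reactivation_fraction(0.49), 0)
  # round trip through the forward map r = (1+f)/(2+f)
  for (f in c(0.001, 0.04, 0.3, 0.9)) {
    expect_equal(estimate_reactivation_fraction((1 + f) / (2 + f)), f)
  }
  expect_error(estimate_reactivation_fraction(1), "r must")
})

test_that("delta-delta-Ct returns 2^-ddCt", {
  expect_equal(delta_delta_ct(20, 18, 20, 18), 1)
  expect_equal(delta_delta_ct(25, 18, 20, 18), 0.03125)
  expect_equal(delta_delta_ct(23, 18, 20, 18), 0.125)
  expect_error(delta_delta_ct(Inf, 18, 20, 18), "finite")
})

test_that("with zero reactivation the X ratio centers on 0.5; reactivation raises it", {
  # the mean ratio carries shared noise from the normalization factors, so
  # the null check uses the MC standard error across cohorts, and the
  # alternative is checked as a seed-paired contrast (identical autosomal
  # RNG stream -> identical scale factors, so the shared noise cancels)
  fx <- small_fixture(seed = 81, n_auto = 300, n_x = 120)
  cohort_mean <- function(fraction, seed) {
    pops <- c(lapply(1:3, function(i) make_fixed_population(fx, fraction, "Cre+")),
              lapply(1:3, function(i) make_fixed_population(fx, 0, "Cre-")))
    cm <- simulate_bulk_counts(fx, pops, seed = seed)
    norm <- normalize_libraries(cm, fx)
    x_ret <- intersect(filter_low_coverage(cm),
                       fx$genes$gene_id[fx$genes$chrom == "X"])
    rr <- reactivation_ratio(norm, x_ret)
    mean(rr$ratio, na.rm = TRUE)
  }
  seeds <- 500 + 1:4
  r0 <- vapply(seeds, function(s) cohort_mean(0, s), numeric(1))
  r5 <- vapply(seeds, function(s) cohort_mean(0.05, s), numeric(1))
  mc_se <- stats::sd(r0) / sqrt(length(r0))
  expect_lt(abs(mean(r0) - 0.5), 4 * mc_se + 0.002)
  expect_true(all(r5 > r0))
  # expected ratio under f = 0.05 is (1 + f)/(2 + f)
  expect_lt(abs(mean(r5 - r0) - (1.05 / 2.05 - 0.5)), 0.005)
})
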