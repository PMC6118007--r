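make_icm <- function(m, conditions) {
  storage.mode(m) <- "integer"
  structure(list(counts = m,
                 samples = data.frame(sample_id = colnames(m),
                                      condition = conditions,
                                      replicate = stats::ave(seq_along(conditions),
                                                             conditions, FUN = seq_along),
                                      stringsAsFactors = FALSE),
                 background = NULL, params = list()),
            class = "island_count_matrix")
}

test_that("TSS linkage respects the inclusive 4 kb window and tie rules", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "X",
                      tss = c(10000L, 30000L), stringsAsFactors = FALSE)
  islands <- data.frame(island_id = c("near", "far"),
                        chrom = "X",
                        # midpoints: 10000+3999 (inside window), 10000+4001
                        start = c(13949L, 13951L),
                        end = c(14050L, 14052L),
                        stringsAsFactors = FALSE)
  link <- link_islands_to_tss(islands, genes, max_distance = 4000)
  expect_identical(link$gene_id[link$island_id == "near"], "gA")
  expect_identical(link$tss_distance[link$island_id == "near"], 3999L)
  expect_true(is.na(link$gene_id[link$island_id == "far"]))
  # exactly equidistant between two TSSs -> lower gene id wins
  genes_eq <- data.frame(gene_id = c("gB", "gA"), chrom = "X",
                         tss = c(22000L, 18000L), stringsAsFactors = FALSE)
  mid_isl <- data.frame(island_id = "mid", chrom = "X",
                        start = 19950L, end = 20051L, stringsAsFactors = FALSE)
  link_eq <- link_islands_to_tss(mid_isl, genes_eq, max_distance = 4000)
  expect_identical(link_eq$midpoint, 20000L)
  expect_identical(link_eq$gene_id, "gA")
  # idempotent, and a function (one gene per island)
  link2 <- link_islands_to_tss(islands, genes, max_distance = 4000)
  expect_identical(link, link2)
  expect_identical(nrow(link), nrow(islands))
  # genes sharing a TSS coordinate: lexicographically smallest id wins
  genes_dup <- data.frame(gene_id = c("gz", "ga"), chrom = "X",
                          tss = c(10000L, 10000L), stringsAsFactors = FALSE)
  link3 <- link_islands_to_tss(islands[1, ], genes_dup)
  expect_identical(link3$gene_id, "ga")
})

test_that("island methylation ratios follow the closed form and drop zero islands", {
  islands <- data.frame(island_id = c("auto1", "x1", "x2"),
                        chrom = c("autosome_1", "X", "X"),
                        start = c(0L, 0L, 1000L), end = c(100L, 100L, 1100L),
                        stringsAsFactors = FALSE)
  m <- cbind(p1 = c(1000L, 90L, 0L), n1 = c(1000L, 100L, 0L))
  rownames(m) <- islands$island_id
  icm <- make_icm(m, c("Cre+", "Cre-"))
  linkage <- data.frame(island_id = islands$island_id, chrom = islands$chrom,
                        midpoint = c(49L, 49L, 1049L),
                        gene_id = c(NA, "gx", NA), tss_distance = c(NA, 100L, NA),
                        stringsAsFactors = FALSE)
  expect_message(rec <- island_methylation_ratio(icm, islands, linkage),
                 "zero abundance")
  expect_identical(rec$island_id, c("auto1", "x1"))
  expect_equal(rec$ratio, c(0.5, 0.9 / 1.9))
  expect_identical(rec$gene_id, c(NA, "gx"))
})

test_that("minority hypermethylated islands show fc > 1 while the aggregate X shift is negative", {
  n_auto <- 60
  n_x <- 40
  islands <- data.frame(
    island_id = sprintf("i%03d", seq_len(n_auto + n_x)),
    chrom = rep(c("autosome_1", "X"), c(n_auto, n_x)),
    start = as.integer(seq(0, by = 1000, length.out = n_auto + n_x)),
    end = as.integer(seq(0, by = 1000, length.out = n_auto + n_x)) + 500L,
    stringsAsFactors = FALSE)
  base <- 400L
  cre_neg <- rep(base, n_auto + n_x)
  cre_pos <- cre_neg
  x_idx <- which(islands$chrom == "X")
  hypo <- x_idx[1:36]
  hyper <- x_idx[37:40]
  cre_pos[hypo] <- 320L   # demethylated majority
  cre_pos[hyper] <- 480L  # hypermethylated minority
  m <- cbind(p1 = cre_pos, p2 = cre_pos, n1 = cre_neg, n2 = cre_neg)
  rownames(m) <- islands$island_id
  res <- island_fold_change(make_icm(m, c("Cre+", "Cre+", "Cre-", "Cre-")),
                            islands, pseudocount = 0)
  expect_true(all(res$fc$fc[match(islands$island_id[hyper], res$fc$island_id)] > 1))
  expect_lt(res$shift$mean_shift, 0)
  expect_lt(res$shift$p, 0.01)
})

test_that("Xi demethylation in simulation produces the hypomethylation shift", {
  fx <- small_fixture(seed = 105, n_auto = 200, n_x = 60)
  fxp <- perturb_methylome(fx, reactivation_model(p_max = 1, e50 = 0),
                           d_max = 0.1, hyper_fraction = 0, seed = 3)
  icm <- simulate_medseq_samples(fxp, 2, n_cells = 40, seed = 7)
  res <- island_fold_change(icm, fxp$islands)
  expect_lt(res$shift$mean_shift, 0)
  expect_lt(res$shift$p, 0.01)
  # unperturbed fixture: no systematic X shift (|shift| below 4 MC SE)
  icm0 <- simulate_medseq_samples(fx, 2, n_cells = 40, seed = 7)
  res0 <- island_fold_change(icm0, fx$islands)
  se0 <- sqrt(stats::var(res0$shift$values_test) / res0$shift$n_test +
                stats::var(res0$shift$values_ref) / res0$shift$n_ref)
  expect_lt(abs(res0$shift$mean_shift), 4 * se0)
})

test_that("expression-group contrast detects expression-coupled demethylation", {
  # demethylation increasing with linked-gene expression -> group B
  # (terciles 2+3) has lower methylation ratio than group A (tercile 1)
  n_x <- 90
  islands <- data.frame(island_id = sprintf("x%03d", 1:n_x), chrom = "X",
                        start = as.integer(seq(0, by = 1000, length.out = n_x)),
                        end = as.integer(seq(0, by = 1000, length.out = n_x)) + 500L,
                        stringsAsFactors = FALSE)
  auto <- data.frame(island_id = "a1", chrom = "autosome_1",
                     start = 0L, end = 500L, stringsAsFactors = FALSE)
  islands_all <- rbind(auto, islands)
  expr <- exp(seq(log(0.5), log(50), length.out = n_x))
  d <- 0.2 * expr / max(expr)  # demethylation proportional to expression
  cre_neg <- rep(1000L, n_x)
  cre_pos <- as.integer(round(1000 * (1 - d)))
  m <- cbind(p1 = c(1000L, cre_pos), n1 = c(1000L, cre_neg))
  rownames(m) <- islands_all$island_id
  icm <- make_icm(m, c("Cre+", "Cre-"))
  linkage <- data.frame(island_id = islands_all$island_id,
                        chrom = islands_all$chrom,
                        midpoint = islands_all$start + 249L,
                        gene_id = c(NA, sprintf("g%03d", 1:n_x)),
                        tss_distance = c(NA, rep(100L, n_x)),
                        stringsAsFactors = FALSE)
  rec <- island_methylation_ratio(icm, islands_all, linkage)
  bins <- stratify_by_expression(sprintf("g%03d", 1:n_x), expr, 3)
  cmp <- compare_methylation_groups(rec, bins)
  expect_lt(cmp$mean_b, cmp$mean_a)
  # per-island closed form: ratio = (1-d)/(2-d); group means match the
  # average of the closed form over each group's islands
  r_exp <- (1 - d) / (2 - d)
  expect_equal(cmp$mean_a, mean(r_exp[1:30]), tolerance = 1e-3)
  expect_equal(cmp$mean_b, mean(r_exp[31:90]), tolerance = 1e-3)
  # identical groups -> t = 0, p = 1
  rec_flat <- rec
  rec_flat$ratio[rec_flat$chrom == "X"] <- 0.5
  cmp_flat <- compare_methylation_groups(rec_flat, bins)
  expect_equal(cmp_flat$t, 0)
  expect_equal(cmp_flat$p, 1)
  # no linked X islands -> error
  linkage_none <- linkage
  linkage_none$gene_id <- NA_character_
  rec_none <- island_methylation_ratio(icm, islands_all, linkage_none)
  expect_error(compare_methylation_groups(rec_none, bins), "linked X islands")
})
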