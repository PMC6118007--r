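test_that("a single symmetric CpG releases exactly one fragment of 2*offset bp", {
  fx <- one_island_fixture(pos = 500L)
  fr <- digest_methylome(fx, TRUE)
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$length, 32L)
  expect_identical(fr$start, 500L - 16L + 1L)
  expect_identical(fr$end, 500L + 16L + 1L)
  # custom offset scales the fragment length as 2*offset
  fr20 <- digest_methylome(fx, TRUE, digestion_model(cut_offset = 20))
  expect_identical(fr20$length, 40L)
})

test_that("unmethylated, hemimethylated and non-assayable CpGs emit nothing", {
  fx <- one_island_fixture(pos = 500L)
  expect_identical(nrow(digest_methylome(fx, FALSE)), 0L)
  expect_identical(nrow(digest_methylome(fx, list(plus = TRUE, minus = FALSE))), 0L)
  expect_identical(nrow(digest_methylome(fx, list(plus = FALSE, minus = TRUE))), 0L)
  fx_na <- one_island_fixture(pos = 500L, assayable = FALSE)
  expect_identical(nrow(digest_methylome(fx_na, TRUE)), 0L)
})

test_that("well-separated CpGs give disjoint centered fragments; close CpGs interfere", {
  fx <- one_island_fixture(pos = c(450L, 550L))
  fr <- digest_methylome(fx, c(TRUE, TRUE))
  expect_identical(nrow(fr), 2L)
  expect_identical(fr$length, c(32L, 32L))
  # each fragment is centered on its CpG (midpoint == site position)
  mid <- fr$start + (fr$length - 1L) %/% 2L
  expect_identical(mid, c(450L, 550L))
  expect_true(fr$end[1] <= fr$start[2])
  # CpGs closer than 2*offset: inter-cut pieces are short and fall out of
  # the size window (no special casing)
  fx_close <- one_island_fixture(pos = c(450L, 464L))
  frc <- size_select(digest_methylome(fx_close, c(TRUE, TRUE)))
  expect_identical(nrow(frc), 0L)
})

test_that("fragments that would extend beyond the chromosome are dropped with a warning", {
  fx <- one_island_fixture(pos = c(10L, 500L), island = c(0L, 600L))
  expect_warning(fr <- digest_methylome(fx, c(TRUE, TRUE)), "beyond the chromosome")
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$start, 485L)
})

test_that("size selection keeps exactly the in-window lengths, preserving order", {
  fr <- data.frame(chrom = "c", start = c(0L, 100L, 200L, 300L),
                   end = c(32L, 200L, 227L, 337L))
  fr$length <- fr$end - fr$start
  kept <- size_select(fr, c(27, 37))
  expect_identical(kept$length, c(32L, 27L, 37L))  # closed interval, order kept
  expect_identical(nrow(size_select(fr[0, ], c(27, 37))), 0L)
})

test_that("fragments are assigned to islands by midpoint with background tally", {
  islands <- data.frame(island_id = c("a", "b"), chrom = "c",
                        start = c(100L, 300L), end = c(200L, 400L))
  frags <- data.frame(chrom = "c",
                      start = c(150L, 195L, 250L, 90L),
                      end = c(182L, 227L, 282L, 122L))
  # midpoints: 165 (in a), 210 (outside: straddles a's edge), 265 (none), 105 (in a)
  res <- count_island_fragments(frags, islands)
  expect_identical(res$counts$n, c(2L, 0L))
  expect_identical(res$background, 2L)
  # overlapping islands are rejected
  bad <- data.frame(island_id = c("a", "b"), chrom = "c",
                    start = c(100L, 150L), end = c(200L, 250L))
  expect_error(count_island_fragments(frags, bad), "overlap")
})

test_that("an all-unmethylated methylome yields an all-zero count matrix", {
  fx <- small_fixture(seed = 52, n_auto = 40, n_x = 10)
  fx$methylome[!is.na(fx$methylome)] <- 0
  icm <- simulate_medseq_samples(fx, 2, n_cells = 5, seed = 1)
  expect_true(all(icm$counts == 0))
})

test_that("fully methylated X with 10% Cre+ Xi demethylation hits the closed-form ratio", {
  # Xa and Xi fully methylated; Cre+ Xi demethylated by d = 0.1:
  # expected Cre+/(Cre+ + Cre-) island ratio = 1.9 / 3.9
  pos <- seq(100L, 1000L, by = 40L)
  fx <- one_island_fixture(pos = pos, chrom = "X", island = c(50L, 1050L))
  fx$methylome$p_xi_pos <- 0.9
  icm <- simulate_medseq_samples(fx, 2, n_cells = 400, seed = 13)
  cond <- icm$samples$condition
  cre_pos <- mean(icm$counts[1, cond == "Cre+"])
  cre_neg <- mean(icm$counts[1, cond == "Cre-"])
  r <- cre_pos / (cre_pos + cre_neg)
  expect_lt(abs(r - 1.9 / 3.9), 0.02)  # ~4 MC SDs at these counts
})

test_that("expected island counts match per-site enumeration on small fixtures", {
  # <= 5 islands; expected per-sample island count = depth_scale * n_cells *
  # sum over assayable sites of the summed per-allele methylation probability
  fx <- small_fixture(seed = 61, n_auto = 4, n_x = 2, n_bg = 1)
  keep <- fx$islands$island_id[1:min(5, nrow(fx$islands))]
  fx$islands <- fx$islands[fx$islands$island_id %in% keep, , drop = FALSE]
  sel <- fx$cpg_sites$island_id %in% keep
  fx$cpg_sites <- fx$cpg_sites[sel, , drop = FALSE]
  fx$methylome <- fx$methylome[sel, , drop = FALSE]
  n_cells <- 60
  n_rep <- 10   # 10 replicates per condition to average MC noise
  icm <- simulate_medseq_samples(fx, n_rep, n_cells = n_cells, seed = 29)
  cs <- fx$cpg_sites
  m <- fx$methylome
  on_x <- cs$chrom == "X"
  p_sum_neg <- ifelse(on_x, m$p_xa_neg + m$p_xi_neg, 2 * m$p_auto_neg)
  expected <- n_cells * tapply(p_sum_neg * cs$assayable, cs$island_id, sum)
  obs <- rowMeans(icm$counts[, icm$samples$condition == "Cre-", drop = FALSE])
  for (id in names(expected)) {
    mc_se <- sqrt(expected[[id]] / n_rep) + 1e-9   # Poisson-scale MC error
    expect_lt(abs(obs[[id]] - expected[[id]]), 4 * mc_se)
  }
})

test_that("halving the assayable fraction halves expected counts", {
  pos <- seq(100L, 2000L, by = 40L)
  fx_full <- one_island_fixture(pos = pos, island = c(50L, 2050L), p_meth = 0.5)
  fx_half <- fx_full
  fx_half$cpg_sites$assayable <- seq_along(pos) %% 2 == 0
  i1 <- simulate_medseq_samples(fx_full, 4, n_cells = 100, seed = 5)
  i2 <- simulate_medseq_samples(fx_half, 4, n_cells = 100, seed = 5)
  m1 <- mean(i1$counts)
  m2 <- mean(i2$counts)
  expect_lt(abs(m2 / m1 - 0.5), 0.05)
})

test_that("MeD-seq simulation is deterministic under a fixed seed", {
  fx <- small_fixture(seed = 71, n_auto = 30, n_x = 10)
  a <- simulate_medseq_samples(fx, 2, n_cells = 5, seed = 17)
  b <- simulate_medseq_samples(fx, 2, n_cells = 5, seed = 17)
  expect_identical(a$counts, b$counts)
})
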