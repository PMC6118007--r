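# Shared test fixtures, built in code.

# Minimal hand-built fixture: one chromosome, one gene, one island whose
# CpG sites are given explicitly. Used for digestion-geometry tests.
one_island_fixture <- function(pos, assayable = TRUE, chrom = "autosome_1",
                               chrom_len = 100000L, island = c(min(pos) - 50L, max(pos) + 50L),
                               p_meth = 1) {
  n <- length(pos)
  on_x <- chrom == "X"
  genome_fixture(
    chrom_lengths = stats::setNames(as.integer(chrom_len), chrom),
    genes = data.frame(gene_id = "g1", chrom = chrom, strand = "+",
                       start = 10L, end = 500L, tss = 10L, expr_rate = 1,
                       stringsAsFactors = FALSE),
    islands = data.frame(island_id = "i1", chrom = chrom,
                         start = as.integer(max(0L, island[1])),
                         end = as.integer(island[2]), stringsAsFactors = FALSE),
    cpg_sites = data.frame(island_id = "i1", chrom = chrom, pos = as.integer(pos),
                           assayable = rep_len(assayable, n), stringsAsFactors = FALSE),
    methylome = data.frame(
      p_auto_neg = if (on_x) rep(NA_real_, n) else rep(p_meth, n),
      p_auto_pos = if (on_x) rep(NA_real_, n) else rep(p_meth, n),
      p_xa_neg = if (on_x) rep(p_meth, n) else rep(NA_real_, n),
      p_xa_pos = if (on_x) rep(p_meth, n) else rep(NA_real_, n),
      p_xi_neg = if (on_x) rep(p_meth, n) else rep(NA_real_, n),
      p_xi_pos = if (on_x) rep(p_meth, n) else rep(NA_real_, n)))
}

# Small random fixture for analysis tests.
small_fixture <- function(seed = 11, n_auto = 400, n_x = 100, n_bg = 5, ...) {
  make_genome_fixture(n_autosomal_genes = n_auto, n_x_genes = n_x,
                      n_islands_per_chrom = n_bg, seed = seed, ...)
}

# Build a count_matrix directly from a matrix (for analysis unit tests).
counts_from_matrix <- function(m, conditions) {
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  }
  storage.mode(m) <- "integer"
  rep_idx <- stats::ave(seq_along(conditions), conditions, FUN = seq_along)
  structure(list(counts = m,
                 samples = data.frame(sample_id = colnames(m),
                                      condition = conditions,
                                      replicate = as.integer(rep_idx),
                                      library_size = unname(colSums(m)),
                                      stringsAsFactors = FALSE)),
            class = "count_matrix")
}

# Simulate one RNA cohort (3 + 3 replicates) on a fixture and return the
# per-gene ratio table of retained X genes.
simulate_ratio_cohort <- function(fixture, model, seed, n_cells = 10000,
                                  depth = 10, dispersion = 0.05, n_rep = 3) {
  pops <- c(
    lapply(seq_len(n_rep), function(i)
      sample_reactivation_states(fixture, model, n_cells, "Cre+",
                                 seed = stage_seed(seed, "pos", i))),
    lapply(seq_len(n_rep), function(i)
      sample_reactivation_states(fixture, model, n_cells, "Cre-",
                                 seed = stage_seed(seed, "neg", i))))
  cm <- simulate_bulk_counts(fixture, pops, depth = depth,
                             dispersion = dispersion,
                             seed = stage_seed(seed, "counts"))
  norm <- normalize_libraries(cm, fixture)
  x_ret <- intersect(filter_low_coverage(cm),
                     fixture$genes$gene_id[fixture$genes$chrom == "X"])
  rr <- reactivation_ratio(norm, x_ret)
  rr[!is.na(rr$ratio), , drop = FALSE]
}
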