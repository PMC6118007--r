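#' Library-size normalization on autosomal totals
#'
#' Scales each sample so that its autosomal read total equals the
#' across-sample geometric mean of autosomal totals. X-linked counts
#' share their sample's factor but are excluded from computing it, so an
#' X-wide dosage change cannot distort the scale factors. After scaling,
#' autosomal per-sample totals are equal (to numerical precision).
#'
#' @param counts a `count_matrix` (see [simulate_bulk_counts()] /
#'   [read_count_matrix()]).
#' @param genes gene annotation: a [genome_fixture()] or a data.frame
#'   with `gene_id` and `chrom` covering the count matrix rows.
#' @return object of class `normalized_counts`: `norm` (real matrix),
#'   `raw` (the input counts), `samples`, `scale_factors`, `genes`.
#' @export
normalize_libraries <- function(counts, genes) {
  if (inherits(genes, "genome_fixture")) genes <- genes$genes
  .assert(all(rownames(counts$counts) %in% genes$gene_id),
          "count matrix contains genes absent from the annotation")
  chrom <- genes$chrom[match(rownames(counts$counts), genes$gene_id)]
  auto <- chrom != "X"
  .assert(any(auto), "need at least one autosomal gene to normalize")
  totals <- colSums(counts$counts[auto, , drop = FALSE])
  .assert(all(totals > 0), "sample(s) with zero autosomal reads: %s",
          paste(colnames(counts$counts)[totals == 0], collapse = ", "))
  factors <- .geo_mean(totals) / totals
  norm <- sweep(counts$counts, 2, factors, `*`)
  structure(list(norm = norm, raw = counts$counts, samples = counts$samples,
                 scale_factors = factors,
                 genes = data.frame(gene_id = rownames(counts$counts),
                                    chrom = chrom, stringsAsFactors = FALSE)),
            class = "normalized_counts")
}

#' Low-coverage gene filter
#'
#' A gene is retained iff its raw read total summed over all samples is
#' at least `min_reads`; genes covered by fewer reads have expression too
#' low for an accurate allelic ratio. The boundary follows the strict
#' "fewer than" reading: a total of exactly `min_reads` is retained.
#'
#' @param counts a `count_matrix`.
#' @param min_reads non-negative integer threshold (default 20).
#' @return character vector of retained gene ids.
#' @export
filter_low_coverage <- function(counts, min_reads = 20) {
  .assert(length(min_reads) == 1 && min_reads >= 0, "min_reads must be >= 0")
  rn <- rownames(counts$counts)
  rn[rowSums(counts$counts) >= min_reads]
}

#' Per-gene Cre+/(Cre+ plus Cre-) reactivation ratio
#'
#' The reactivation-ratio statistic: for each gene,
#' `r = cre_pos / (cre_pos + cre_neg)` where `cre_pos`/`cre_neg` are the
#' per-condition means of library-normalized counts. Under intact Xi
#' silencing the conditions are exchangeable and `r` centers on 0.5; Xi
#' derepression in a fraction of cells pushes X-linked ratios above 0.5.
#' Genes whose denominator is zero get `ratio = NA` and are excluded
#' downstream.
#'
#' @param norm a `normalized_counts` object.
#' @param retained optional character vector restricting the genes
#'   (e.g. X-linked genes passing [filter_low_coverage()]); default all.
#' @param min_reads threshold used to set the `pass_filter` flag.
#' @param pooled if `TRUE`, use pooled raw read sums per condition
#'   instead of means of normalized counts.
#' @return data.frame with `gene_id`, `chrom`, `cre_pos`, `cre_neg`,
#'   `total_raw_reads`, `ratio`, `pass_filter`.
#' @export
reactivation_ratio <- function(norm, retained = NULL, min_reads = 20,
                               pooled = FALSE) {
  .assert(inherits(norm, "normalized_counts"), "norm must be a normalized_counts")
  cond <- norm$samples$condition
  .assert(all(c("Cre+", "Cre-") %in% cond), "need >= 1 sample per condition")
  sel <- if (is.null(retained)) rownames(norm$norm) else retained
  .assert(all(sel %in% rownames(norm$norm)), "unknown gene id in 'retained'")
  m <- if (pooled) norm$raw[sel, , drop = FALSE] else norm$norm[sel, , drop = FALSE]
  agg <- if (pooled) rowSums else rowMeans
  cre_pos <- agg(m[, cond == "Cre+", drop = FALSE])
  cre_neg <- agg(m[, cond == "Cre-", drop = FALSE])
  total <- cre_pos + cre_neg
  ratio <- ifelse(total > 0, cre_pos / total, NA_real_)
  raw_total <- rowSums(norm$raw[sel, , drop = FALSE])
  data.frame(gene_id = sel,
             chrom = norm$genes$chrom[match(sel, norm$genes$gene_id)],
             cre_pos = unname(cre_pos), cre_neg = unname(cre_neg),
             total_raw_reads = unname(raw_total),
             ratio = unname(ratio),
             pass_filter = unname(raw_total >= min_reads),
             stringsAsFactors = FALSE)
}

#' Stratify genes into expression bins (terciles/quartiles)
#'
#' Ranks genes by an expression measure (ascending; ties broken by
#' lexicographic gene id) and splits them into `k` contiguous rank
#' blocks whose sizes differ by at most one, with remainders assigned to
#' the lowest bins. Bin 1 is the lowest-expression bin.
#'
#' @param gene_id character vector of gene ids.
#' @param expression numeric expression measure parallel to `gene_id`.
#'   The pipeline uses the mean normalized count over all samples
#'   (`cre_pos + cre_neg`): ranking genes by a single condition's counts
#'   couples the bin assignment to the noise in the ratio's own numerator
#'   or denominator and systematically biases the extreme bins.
#' @param k number of bins (>= 2; 3 for terciles, 4 for quartiles).
#' @return data.frame `gene_id`, `bin` (integer 1..k), ordered by rank,
#'   with attribute `"boundaries"`: the expression values at the upper
#'   edge of each bin.
#' @export
stratify_by_expression <- function(gene_id, expression, k) {
  .assert(.is_count(k, min = 2), "k must be an integer >= 2")
  n <- length(gene_id)
  .assert(n >= k, "k exceeds the number of genes")
  .assert(length(expression) == n, "expression must parallel gene_id")
  o <- order(expression, gene_id)
  base <- n %/% k
  sizes <- rep(base, k) + (seq_len(k) <= n %% k)
  bin <- rep(seq_len(k), times = sizes)
  out <- data.frame(gene_id = gene_id[o], bin = bin, stringsAsFactors = FALSE)
  attr(out, "boundaries") <- tapply(expression[o], bin, max)
  out
}

#' Compare reactivation ratios between expression bins
#'
#' Two-sample Student's t test (pooled variance, two-sided) on the ratio
#' values of two gene groups, each given as one bin index or an
#' aggregate of several (e.g. `bin_b = c(2, 3)` for the combined upper
#' terciles). Also reports per-group mean, SD and size. A Welch variant
#' is available via `var_equal = FALSE`.
#'
#' @param ratios data.frame from [reactivation_ratio()] (or any frame
#'   with `gene_id` and `ratio`).
#' @param bins data.frame from [stratify_by_expression()].
#' @param bin_a,bin_b integer bin indices (vectors aggregate bins).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return object of class `bin_comparison`: list with `n_a`, `mean_a`,
#'   `sd_a`, `n_b`, `mean_b`, `sd_b`, `t`, `df`, `p`.
#' @export
compare_bins <- function(ratios, bins, bin_a, bin_b, var_equal = TRUE) {
  grab <- function(b) {
    ids <- bins$gene_id[bins$bin %in% b]
    v <- ratios$ratio[match(ids, ratios$gene_id)]
    v[!is.na(v)]
  }
  a <- grab(bin_a)
  b <- grab(bin_b)
  .assert(length(a) >= 2 && length(b) >= 2, "each group needs >= 2 genes")
  if (stats::sd(c(a, b)) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  structure(list(n_a = length(a), mean_a = mean(a), sd_a = stats::sd(a),
                 n_b = length(b), mean_b = mean(b), sd_b = stats::sd(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "bin_comparison")
}

#' @export
print.bin_comparison <- function(x, ...) {
  cat(sprintf("%.3f +/- %.3f (n=%d) vs %.3f +/- %.3f (n=%d), t=%.3f, p=%.4g\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b, x$t, x$p))
  invisible(x)
}

#' Invert the mean ratio into a per-cell reactivation fraction
#'
#' If a fraction `f` of cells carries a fully reactivated Xi allele, the
#' expected Cre+/(Cre+ plus Cre-) ratio is `(1 + f) / (2 + f)`; this
#' inverts that relation: `f = (2 r - 1) / (1 - r)`. Negative estimates
#' (from `r < 0.5`) are reported as-is.
#'
#' @param r ratio values in `[0, 1)`.
#' @return implied reactivation fraction(s).
#' @examples
#' estimate_reactivation_fraction(103 / 203)  # 0.03
#' @export
estimate_reactivation_fraction <- function(r) {
  .assert(all(r >= 0 & r < 1), "r must lie in [0, 1)")
  (2 * r - 1) / (1 - r)
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR quantification normalized to a reference gene (e.g. GAPDH) and a
#' calibrator sample: returns `2^-ddCt` with
#' `ddCt = (Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator`.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the
#'   calibrator.
#' @return relative expression (1 when ddCt is 0).
#' @export
delta_delta_ct <- function(ct_target_sample, ct_ref_sample,
                           ct_target_calibrator, ct_ref_calibrator) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator, ct_ref_calibrator)
  .assert(all(is.finite(vals)), "Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
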