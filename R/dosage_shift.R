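#' Per-gene mutant/control fold changes
#'
#' `fc = (mean_mutant + c) / (mean_control + c)` on per-condition means
#' of library-normalized counts, with pseudocount `c` keeping
#' zero-control genes finite. Genes with both means zero are dropped
#' with a message. Cre+ is the mutant (Xist-deleted) condition.
#'
#' @param norm a `normalized_counts` object.
#' @param retained optional character vector of gene ids (gene universe,
#'   typically from [filter_low_coverage()]); default all genes.
#' @param pseudocount non-negative real added to both means.
#' @return data.frame `gene_id`, `chrom`, `mean_mutant`, `mean_control`,
#'   `fc`, `log2fc`.
#' @export
per_gene_fold_change <- function(norm, retained = NULL, pseudocount = 0.5) {
  .assert(inherits(norm, "normalized_counts"), "norm must be a normalized_counts")
  .assert(length(pseudocount) == 1 && pseudocount >= 0, "pseudocount must be >= 0")
  cond <- norm$samples$condition
  .assert(all(c("Cre+", "Cre-") %in% cond), "need >= 1 sample per condition")
  sel <- if (is.null(retained)) rownames(norm$norm) else retained
  .assert(all(sel %in% rownames(norm$norm)), "unknown gene id in 'retained'")
  m <- norm$norm[sel, , drop = FALSE]
  mean_mut <- rowMeans(m[, cond == "Cre+", drop = FALSE])
  mean_ctl <- rowMeans(m[, cond == "Cre-", drop = FALSE])
  both_zero <- mean_mut == 0 & mean_ctl == 0
  if (any(both_zero)) {
    message(sprintf("dropping %d gene(s) with zero means in both conditions",
                    sum(both_zero)))
  }
  fc <- (mean_mut + pseudocount) / (mean_ctl + pseudocount)
  out <- data.frame(gene_id = sel,
                    chrom = norm$genes$chrom[match(sel, norm$genes$gene_id)],
                    mean_mutant = unname(mean_mut),
                    mean_control = unname(mean_ctl),
                    fc = unname(fc), log2fc = unname(log2(fc)),
                    stringsAsFactors = FALSE)
  out[!both_zero, , drop = FALSE]
}

# Wilcoxon rank-sum with an exact-tie guard: when every value in both
# groups is identical the normal approximation degenerates (sd 0); the
# distributions are then trivially equal and p is 1 by construction.
.wilcox_shift <- function(x, y) {
  if (length(unique(c(x, y))) == 1) {
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  w <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(w$statistic), p.value = w$p.value)
}

#' X-versus-reference cumulative fold-change shift test
#'
#' Two-sided Wilcoxon rank-sum test comparing the fold-change
#' distribution of genes on a test chromosome (X) against a reference
#' set (all autosomes pooled by default, or a single autosome for
#' per-autosome comparisons). Returns the empirical CDFs for plotting
#' and the mean shift (difference of group mean fold changes, computed
#' on the fc scale; positive = rightward shift of the test chromosome).
#'
#' @param fcs data.frame from [per_gene_fold_change()] (columns `chrom`,
#'   `fc`).
#' @param test_chrom chromosome label under test (default `"X"`).
#' @param reference character vector of reference chromosome labels;
#'   `NULL` pools every chromosome other than `test_chrom`.
#' @return object of class `shift_result`: `n_test`, `n_ref`,
#'   `statistic` (Mann-Whitney W), `p`, `mean_shift`, `values_test`,
#'   `values_ref`, `ecdf_test`, `ecdf_ref`, labels.
#' @export
cumulative_shift_test <- function(fcs, test_chrom = "X", reference = NULL) {
  x <- fcs$fc[fcs$chrom == test_chrom]
  ref_set <- reference %||% setdiff(unique(fcs$chrom), test_chrom)
  y <- fcs$fc[fcs$chrom %in% ref_set]
  .assert(length(x) >= 2, "empty/degenerate test group (%s)", test_chrom)
  .assert(length(y) >= 2, "empty/degenerate reference group")
  w <- .wilcox_shift(x, y)
  structure(list(test_chrom = test_chrom, reference = ref_set,
                 n_test = length(x), n_ref = length(y),
                 statistic = w$statistic, p = w$p.value,
                 mean_shift = mean(x) - mean(y),
                 values_test = x, values_ref = y,
                 ecdf_test = stats::ecdf(x), ecdf_ref = stats::ecdf(y)),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("shift test: %s (n=%d) vs %s (n=%d): W=%.4g, p=%.4g, mean shift=%+.4f\n",
              x$test_chrom, x$n_test, paste(x$reference, collapse = "+"),
              x$n_ref, x$statistic, x$p, x$mean_shift))
  invisible(x)
}

#' Binned fold-change distributions and mean shift
#'
#' Histograms the test-chromosome and reference fold changes on shared
#' bin edges and reports the mean shift (mean test fc minus mean
#' reference fc). Per-group bin frequencies sum to 1.
#'
#' @param fcs data.frame from [per_gene_fold_change()].
#' @param test_chrom chromosome label under test.
#' @param bin_width positive bin width on the fc scale.
#' @param reference reference chromosome labels (`NULL` = all others).
#' @return list with `bins` (data.frame `bin_lo`, `bin_hi`, `freq_test`,
#'   `freq_ref`) and `mean_shift`.
#' @export
binned_fold_change <- function(fcs, test_chrom = "X", bin_width = 0.1,
                               reference = NULL) {
  .assert(length(bin_width) == 1 && bin_width > 0, "bin_width must be positive")
  x <- fcs$fc[fcs$chrom == test_chrom]
  ref_set <- reference %||% setdiff(unique(fcs$chrom), test_chrom)
  y <- fcs$fc[fcs$chrom %in% ref_set]
  .assert(length(x) >= 1 && length(y) >= 1, "need >= 1 gene per group")
  lo <- floor(min(x, y) / bin_width) * bin_width
  hi <- ceiling(max(x, y) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + bin_width)
  hx <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  hy <- graphics::hist(y, breaks = edges, plot = FALSE)$counts
  list(bins = data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                         freq_test = hx / length(x), freq_ref = hy / length(y)),
       mean_shift = mean(x) - mean(y))
}

#' Control-versus-control consistency check
#'
#' Null control for the shift analysis: fold change of the first named
#' control sample over the mean of the remaining controls, followed by
#' the X-versus-autosome cumulative shift test. With biological controls
#' only, the X and autosomal distributions should overlap (no shift).
#'
#' @param norm a `normalized_counts` object.
#' @param control_samples character vector of at least 3 control sample
#'   ids; the first is compared against the mean of the rest.
#' @param retained optional gene universe.
#' @param pseudocount pseudocount added to both terms.
#' @return a `shift_result` (see [cumulative_shift_test()]).
#' @export
control_consistency <- function(norm, control_samples, retained = NULL,
                                pseudocount = 0.5) {
  .assert(length(control_samples) >= 3, "need >= 3 control samples")
  .assert(all(control_samples %in% colnames(norm$norm)), "unknown control sample id")
  sel <- if (is.null(retained)) rownames(norm$norm) else retained
  first <- norm$norm[sel, control_samples[1]]
  rest <- rowMeans(norm$norm[sel, control_samples[-1], drop = FALSE])
  fc <- (first + pseudocount) / (rest + pseudocount)
  fcs <- data.frame(gene_id = sel,
                    chrom = norm$genes$chrom[match(sel, norm$genes$gene_id)],
                    fc = unname(fc), stringsAsFactors = FALSE)
  cumulative_shift_test(fcs, test_chrom = "X")
}
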