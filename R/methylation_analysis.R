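# CpG-island methylation analyses: island normalization mirrors the RNA
# side (per-sample scaling on autosomal island totals) so that X-wide
# demethylation cannot distort the scale factors.

.normalize_islands <- function(icm, islands) {
  .assert(all(rownames(icm$counts) %in% islands$island_id),
          "island counts contain islands absent from the annotation")
  chrom <- islands$chrom[match(rownames(icm$counts), islands$island_id)]
  auto <- chrom != "X"
  .assert(any(auto), "need >= 1 autosomal island to normalize")
  totals <- colSums(icm$counts[auto, , drop = FALSE])
  .assert(all(totals > 0), "sample(s) with zero autosomal island counts")
  factors <- .geo_mean(totals) / totals
  list(norm = sweep(icm$counts, 2, factors, `*`), chrom = chrom,
       factors = factors)
}

#' CpG-island methylation fold changes and X-vs-autosome shift
#'
#' Per-island fold methylation abundance change
#' `fc = (Cre+ mean + c) / (Cre- mean + c)` on normalized island counts,
#' followed by the two-sided Wilcoxon rank-sum shift test of X islands
#' against autosomal islands. Under Xi demethylation the X distribution
#' shifts left (hypomethylation, mean shift < 0) even when a minority of
#' islands gains methylation.
#'
#' @param icm an `island_count_matrix`.
#' @param islands island annotation data.frame (`island_id`, `chrom`).
#' @param pseudocount non-negative real added to both means.
#' @return list with `fc` (data.frame `island_id`, `chrom`,
#'   `mean_mutant`, `mean_control`, `fc`, `log2fc`) and `shift`
#'   (a `shift_result`).
#' @export
island_fold_change <- function(icm, islands, pseudocount = 0.5) {
  .assert(length(pseudocount) == 1 && pseudocount >= 0, "pseudocount must be >= 0")
  cond <- icm$samples$condition
  .assert(all(c("Cre+", "Cre-") %in% cond), "need >= 1 sample per condition")
  nn <- .normalize_islands(icm, islands)
  mean_mut <- rowMeans(nn$norm[, cond == "Cre+", drop = FALSE])
  mean_ctl <- rowMeans(nn$norm[, cond == "Cre-", drop = FALSE])
  fc <- (mean_mut + pseudocount) / (mean_ctl + pseudocount)
  fcdf <- data.frame(island_id = rownames(icm$counts), chrom = nn$chrom,
                     mean_mutant = unname(mean_mut),
                     mean_control = unname(mean_ctl),
                     fc = unname(fc), log2fc = unname(log2(fc)),
                     stringsAsFactors = FALSE)
  shift <- cumulative_shift_test(fcdf, test_chrom = "X")
  list(fc = fcdf, shift = shift)
}

#' Link CpG islands to the nearest TSS
#'
#' Each island is linked to the gene (same chromosome) whose TSS is
#' nearest to the island midpoint, provided that distance is at most
#' `max_distance` (inclusive); otherwise the island is unlinked. Ties
#' are broken by lexicographic gene id. The linkage is a function:
#' every island maps to at most one gene, and re-running is idempotent.
#'
#' @param islands data.frame `island_id`, `chrom`, `start`, `end`.
#' @param genes data.frame `gene_id`, `chrom`, `tss`.
#' @param max_distance inclusive linkage window in bp (default 4000,
#'   i.e. islands within 4 kb of a TSS).
#' @return data.frame `island_id`, `chrom`, `midpoint`, `gene_id`
#'   (`NA` when unlinked), `tss_distance` (`NA` when unlinked).
#' @export
link_islands_to_tss <- function(islands, genes, max_distance = 4000) {
  .assert(max_distance >= 0, "max_distance must be >= 0")
  mid <- islands$start + (islands$end - islands$start - 1L) %/% 2L
  gene_id <- rep(NA_character_, nrow(islands))
  dist <- rep(NA_integer_, nrow(islands))
  for (ch in unique(islands$chrom)) {
    isel <- which(islands$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    # sort TSS; candidate neighbours of each midpoint are the flanking
    # entries; ties resolved by lexicographic gene id
    o <- order(g$tss, g$gene_id)
    tss <- g$tss[o]
    gid <- g$gene_id[o]
    idx <- findInterval(mid[isel], tss)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(tss))
    d_lo <- abs(mid[isel] - tss[lo])
    d_hi <- abs(mid[isel] - tss[hi])
    # prefer the closer; on exact distance ties take the lower gene id
    use_hi <- d_hi < d_lo | (d_hi == d_lo & gid[hi] < gid[lo])
    best <- ifelse(use_hi, hi, lo)
    # genes sharing the same TSS coordinate: the first occurrence in the
    # (tss, gene_id) order is the lexicographically smallest id
    best <- match(tss[best], tss)
    best_d <- pmin(d_lo, d_hi)
    linked <- best_d <= max_distance
    gene_id[isel[linked]] <- gid[best[linked]]
    dist[isel[linked]] <- as.integer(best_d[linked])
  }
  data.frame(island_id = islands$island_id, chrom = islands$chrom,
             midpoint = as.integer(mid), gene_id = gene_id,
             tss_distance = dist, stringsAsFactors = FALSE)
}

#' Per-island Cre+/(Cre+ plus Cre-) methylation ratio
#'
#' The methylation analogue of the reactivation ratio: per-condition
#' means of normalized island counts and
#' `ratio = cre_pos / (cre_pos + cre_neg)`. A ratio below 0.5 indicates
#' loss of methylation in the Cre+ (Xist-deleted) animals. Islands with
#' zero total abundance are excluded with a message.
#'
#' @param icm an `island_count_matrix`.
#' @param islands island annotation (`island_id`, `chrom`, `start`, `end`).
#' @param linkage data.frame from [link_islands_to_tss()].
#' @return data.frame `island_id`, `chrom`, `gene_id`, `tss_distance`,
#'   `cre_pos`, `cre_neg`, `ratio`.
#' @export
island_methylation_ratio <- function(icm, islands, linkage) {
  cond <- icm$samples$condition
  .assert(all(c("Cre+", "Cre-") %in% cond), "need >= 1 sample per condition")
  nn <- .normalize_islands(icm, islands)
  cre_pos <- rowMeans(nn$norm[, cond == "Cre+", drop = FALSE])
  cre_neg <- rowMeans(nn$norm[, cond == "Cre-", drop = FALSE])
  total <- cre_pos + cre_neg
  zero <- total == 0
  if (any(zero)) {
    message(sprintf("excluding %d island(s) with zero abundance in both conditions",
                    sum(zero)))
  }
  li <- match(rownames(icm$counts), linkage$island_id)
  out <- data.frame(island_id = rownames(icm$counts), chrom = nn$chrom,
                    gene_id = linkage$gene_id[li],
                    tss_distance = linkage$tss_distance[li],
                    cre_pos = unname(cre_pos), cre_neg = unname(cre_neg),
                    ratio = unname(ifelse(zero, NA_real_, cre_pos / total)),
                    stringsAsFactors = FALSE)
  out[!zero, , drop = FALSE]
}

#' Compare methylation ratios across expression groups
#'
#' Groups X-linked islands by the expression tercile of their linked
#' gene and contrasts tercile 1 (lowest expression, no derepression)
#' against the aggregate of terciles 2 and 3 (derepressed) with a
#' two-sided pooled-variance Student's t test on the island methylation
#' ratios.
#'
#' @param records data.frame from [island_methylation_ratio()].
#' @param bins data.frame from [stratify_by_expression()] with `k = 3`,
#'   computed on the same gene universe as the expression analysis.
#' @param group_a,group_b bin indices contrasted (defaults 1 vs 2+3).
#' @return a `bin_comparison` (group A first), plus elements
#'   `records` with an `expression_group` label per island.
#' @export
compare_methylation_groups <- function(records, bins, group_a = 1,
                                       group_b = c(2, 3)) {
  on_x <- records$chrom == "X" & !is.na(records$gene_id) & !is.na(records$ratio)
  bin_of <- bins$bin[match(records$gene_id, bins$gene_id)]
  grp <- rep(NA_character_, nrow(records))
  grp[on_x & bin_of %in% group_a] <- "tercile1"
  grp[on_x & bin_of %in% group_b] <- "terciles2+3"
  a <- records$ratio[!is.na(grp) & grp == "tercile1"]
  b <- records$ratio[!is.na(grp) & grp == "terciles2+3"]
  .assert(length(a) >= 2 && length(b) >= 2,
          "need >= 2 linked X islands in each expression group")
  if (stats::sd(c(a, b)) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
  }
  res <- structure(list(n_a = length(a), mean_a = mean(a), sd_a = stats::sd(a),
                        n_b = length(b), mean_b = mean(b), sd_b = stats::sd(b),
                        t = unname(tt$statistic), df = unname(tt$parameter),
                        p = tt$p.value),
                   class = "bin_comparison")
  res$records <- cbind(records, expression_group = ifelse(is.na(grp), "unlinked", grp))
  res
}
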