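#' Methylation-dependent digestion model
#'
#' Geometry of the in-silico methylation-dependent restriction digestion.
#' The enzyme cuts at a fixed offset downstream of a methylated cytosine
#' on its own strand; we model a single blunt double-strand break, so a
#' CpG whose plus-strand C sits at `c` (minus-strand partner at `c + 1`)
#' that is methylated on both strands releases the fragment
#' `[c - cut_offset + 1, c + cut_offset + 1)` of length exactly
#' `2 * cut_offset` (32 bp at the default offset of 16). Hemimethylated
#' CpGs cut only one strand and release no sized fragment. After
#' digestion, fragments are gel size-selected into `size_window` and
#' captured with probability `capture_efficiency`.
#'
#' @param cut_offset positive integer, nt downstream of a methylated C at
#'   which the break is placed.
#' @param size_window closed integer interval `c(min, max)` of retained
#'   fragment lengths in bp.
#' @param capture_efficiency per-fragment capture probability.
#' @return an object of class `digestion_model`.
#' @export
digestion_model <- function(cut_offset = 16, size_window = c(27, 37),
                            capture_efficiency = 1) {
  .assert(.is_count(cut_offset), "cut_offset must be a positive integer")
  .assert(length(size_window) == 2 && size_window[1] <= size_window[2],
          "size_window must be c(min, max) with min <= max")
  .assert(.is_prob(capture_efficiency), "capture_efficiency must be a probability")
  structure(list(cut_offset = as.integer(cut_offset),
                 size_window = as.integer(size_window),
                 capture_efficiency = capture_efficiency),
            class = "digestion_model")
}

# Core cut geometry for one molecule of one chromosome.
# pos_cut: sorted 0-based plus-strand C coordinates of symmetrically
# methylated, assayable CpGs. Returns data.frame(start, end) of the
# inter-break pieces that contain at least one cutting CpG (the
# methylation-bearing fragments; CpG-free inter-fragment gaps are not
# sequenced). Cuts whose fragment would extend beyond the chromosome are
# dropped (caller warns).
.digest_positions <- function(pos_cut, cut_offset) {
  if (!length(pos_cut)) {
    return(data.frame(start = integer(), end = integer()))
  }
  b <- sort(unique(c(pos_cut - cut_offset + 1L, pos_cut + cut_offset + 1L)))
  piece <- findInterval(pos_cut, b)          # piece i spans [b[i], b[i+1])
  keep <- sort(unique(piece[piece >= 1 & piece < length(b)]))
  data.frame(start = b[keep], end = b[keep + 1L])
}

#' In-silico digestion of a realized methylome
#'
#' Applies the methylation-dependent cut geometry to one DNA molecule
#' (one allele copy): every assayable CpG methylated on both strands
#' places a double-strand break `cut_offset` nt downstream of each of its
#' two cytosines; the emitted fragments are the inter-break pieces that
#' carry at least one methylated CpG. Unmethylated, hemimethylated and
#' non-assayable sites emit nothing. Sites whose fragment would extend
#' beyond the chromosome are dropped with a warning.
#'
#' @param fixture a [genome_fixture()] supplying CpG site coordinates and
#'   assayable flags.
#' @param methylated either a logical vector parallel to
#'   `fixture$cpg_sites` giving the symmetric methylation state of each
#'   site, or a list `list(plus = , minus = )` of per-strand states (a
#'   fragment requires both).
#' @param model a [digestion_model()].
#' @return data.frame of fragments: `chrom`, `start`, `end` (0-based
#'   half-open), `length`.
#' @examples
#' # one island, one symmetric CpG -> one 32 bp fragment
#' fx <- genome_fixture(
#'   chrom_lengths = c(autosome_1 = 1000L),
#'   genes = data.frame(gene_id = "g1", chrom = "autosome_1", strand = "+",
#'                      start = 10L, end = 200L, tss = 10L, expr_rate = 1),
#'   islands = data.frame(island_id = "i1", chrom = "autosome_1",
#'                        start = 400L, end = 600L),
#'   cpg_sites = data.frame(island_id = "i1", chrom = "autosome_1",
#'                          pos = 500L, assayable = TRUE),
#'   methylome = data.frame(p_auto_neg = 1, p_auto_pos = 1, p_xa_neg = NA,
#'                          p_xa_pos = NA, p_xi_neg = NA, p_xi_pos = NA))
#' digest_methylome(fx, TRUE)
#' @export
digest_methylome <- function(fixture, methylated, model = digestion_model()) {
  .assert(inherits(model, "digestion_model"), "model must be a digestion_model")
  cs <- fixture$cpg_sites
  if (is.list(methylated) && !is.data.frame(methylated)) {
    .assert(all(c("plus", "minus") %in% names(methylated)),
            "per-strand states need elements 'plus' and 'minus'")
    symmetric <- methylated$plus & methylated$minus
  } else {
    symmetric <- as.logical(methylated)
  }
  .assert(length(symmetric) == nrow(cs),
          "methylation states must be defined for every CpG site")
  cut <- symmetric & cs$assayable
  off <- model$cut_offset
  cl <- fixture$chrom_lengths
  in_bounds <- cs$pos - off + 1L >= 0L & cs$pos + off + 1L <= cl[cs$chrom]
  n_clip <- sum(cut & !in_bounds)
  if (n_clip > 0) {
    warning(sprintf("%d methylated site(s) dropped: fragment would extend beyond the chromosome", n_clip))
  }
  cut <- cut & in_bounds
  out <- lapply(unique(cs$chrom[cut]), function(ch) {
    fr <- .digest_positions(sort(cs$pos[cut & cs$chrom == ch]), off)
    if (nrow(fr)) cbind(chrom = ch, fr) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
  }
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Size-select fragments
#'
#' Keeps exactly the fragments whose length lies in the closed window,
#' preserving input order (in-silico analogue of gel size selection).
#'
#' @param fragments data.frame with a `length` column (as produced by
#'   [digest_methylome()]).
#' @param window closed integer interval `c(min, max)`.
#' @return the retained rows of `fragments`.
#' @export
size_select <- function(fragments, window = c(27, 37)) {
  .assert(length(window) == 2 && window[1] <= window[2],
          "window must be c(min, max) with min <= max")
  fragments[fragments$length >= window[1] & fragments$length <= window[2], ,
            drop = FALSE]
}

#' Count fragments per CpG island
#'
#' Assigns each fragment to the island containing its midpoint (the
#' lower-median position for even lengths); fragments whose midpoint lies
#' in no island are tallied as background. Islands must be
#' non-overlapping within a chromosome.
#'
#' @param fragments data.frame `chrom`, `start`, `end`.
#' @param islands data.frame `island_id`, `chrom`, `start`, `end`.
#' @return list with `counts` (data.frame `island_id`, `n`, one row per
#'   island in input order) and `background` (count of unassigned
#'   fragments).
#' @export
count_island_fragments <- function(fragments, islands) {
  for (ch in unique(islands$chrom)) {
    sub <- islands[islands$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1) {
      .assert(all(sub$start[-1] >= sub$end[-nrow(sub)]),
              "islands overlap on chromosome %s", ch)
    }
  }
  n <- stats::setNames(integer(nrow(islands)), islands$island_id)
  background <- 0L
  if (nrow(fragments)) {
    mid <- fragments$start + (fragments$end - fragments$start - 1L) %/% 2L
    for (ch in unique(fragments$chrom)) {
      fsel <- fragments$chrom == ch
      sub <- islands[islands$chrom == ch, , drop = FALSE]
      if (!nrow(sub)) {
        background <- background + sum(fsel)
        next
      }
      sub <- sub[order(sub$start), , drop = FALSE]
      idx <- findInterval(mid[fsel], sub$start)
      hit <- idx >= 1 & mid[fsel] < sub$end[pmax(idx, 1L)]
      background <- background + sum(!hit)
      tab <- tabulate(idx[hit], nbins = nrow(sub))
      n[sub$island_id] <- n[sub$island_id] + tab
    }
  }
  list(counts = data.frame(island_id = islands$island_id, n = unname(n[islands$island_id]),
                           stringsAsFactors = FALSE),
       background = background)
}

#' Simulate MeD-seq style island count matrices
#'
#' Per sample, per cell and per allele copy (two copies of each autosome;
#' Xa and Xi for the X) realizes binary CpG methylation from the
#' fixture's methylome (Cre+ samples use the perturbed Xi probabilities),
#' digests, size-selects, thins fragments by
#' `capture_efficiency * depth_scale`, and counts fragments per island.
#' The expected count of an island is proportional to the sum over its
#' assayable sites of the per-allele methylation probabilities.
#'
#' @param fixture a [genome_fixture()] (typically after
#'   [perturb_methylome()]).
#' @param n_replicates_per_condition samples per condition (study design: 2
#'   animals per genotype).
#' @param n_cells cells (genome copies) realized per sample.
#' @param model a [digestion_model()].
#' @param depth_scale fragment retention multiplier;
#'   `capture_efficiency * depth_scale` must be in (0, 1].
#' @param seed integer seed.
#' @return object of class `island_count_matrix`: `counts` (integer
#'   islands x samples matrix), `samples` (data.frame `sample_id`,
#'   `condition`, `replicate`), `background` (per-sample background
#'   fragment tallies).
#' @export
simulate_medseq_samples <- function(fixture, n_replicates_per_condition = 2,
                                    n_cells = 20, model = digestion_model(),
                                    depth_scale = 1, seed) {
  .assert(.is_count(n_replicates_per_condition), "n_replicates_per_condition must be >= 1")
  .assert(.is_count(n_cells), "n_cells must be >= 1")
  keep_prob <- model$capture_efficiency * depth_scale
  .assert(keep_prob > 0 && keep_prob <= 1,
          "capture_efficiency * depth_scale must be in (0, 1]")
  cs <- fixture$cpg_sites
  meth <- fixture$methylome
  isl <- fixture$islands
  off <- model$cut_offset
  cl <- fixture$chrom_lengths
  win <- model$size_window

  # precompute per-chromosome site tables (assayable, in-bounds sites only)
  ok <- cs$assayable & cs$pos - off + 1L >= 0L & cs$pos + off + 1L <= cl[cs$chrom]
  chrom_tab <- lapply(names(cl), function(ch) {
    sel <- ok & cs$chrom == ch
    o <- order(cs$pos[sel])
    sub_isl <- isl[isl$chrom == ch, , drop = FALSE]
    sub_isl <- sub_isl[order(sub_isl$start), , drop = FALSE]
    list(chrom = ch,
         pos = cs$pos[sel][o],
         p = meth[sel, , drop = FALSE][o, , drop = FALSE],
         isl_start = sub_isl$start, isl_end = sub_isl$end,
         isl_row = match(sub_isl$island_id, isl$island_id))
  })
  names(chrom_tab) <- names(cl)

  conds <- rep(c("Cre+", "Cre-"), each = n_replicates_per_condition)
  tag <- ifelse(conds == "Cre+", "CrePos", "CreNeg")
  sample_id <- sprintf("%s_md%d", tag, rep(seq_len(n_replicates_per_condition), 2))

  counts <- matrix(0L, nrow = nrow(isl), ncol = length(conds),
                   dimnames = list(isl$island_id, sample_id))
  background <- stats::setNames(integer(length(conds)), sample_id)

  # one molecule: realize methylation at probabilities p, digest, select,
  # thin, return per-island count increments for this chromosome
  run_molecule <- function(tab, p) {
    ns <- length(tab$pos)
    if (!ns || all(p == 0)) return(NULL)
    m <- stats::runif(ns) < p
    if (!any(m)) return(NULL)
    fr <- .digest_positions(tab$pos[m], off)
    len <- fr$end - fr$start
    sel <- len >= win[1] & len <= win[2]
    if (keep_prob < 1) sel <- sel & (stats::runif(nrow(fr)) < keep_prob)
    if (!any(sel)) return(NULL)
    mid <- fr$start[sel] + (len[sel] - 1L) %/% 2L
    if (!length(tab$isl_row)) {
      return(list(tab = integer(0), bg = length(mid)))
    }
    idx <- findInterval(mid, tab$isl_start)
    hit <- idx >= 1 & mid < tab$isl_end[pmax(idx, 1L)]
    list(tab = tabulate(idx[hit], nbins = length(tab$isl_row)), bg = sum(!hit))
  }

  withr::with_seed(as.integer(seed), {
    for (s in seq_along(conds)) {
      suffix <- if (conds[s] == "Cre+") "pos" else "neg"
      for (cell in seq_len(n_cells)) {
        for (tab in chrom_tab) {
          if (tab$chrom == "X") {
            molecules <- list(tab$p[[paste0("p_xa_", suffix)]],
                              tab$p[[paste0("p_xi_", suffix)]])
          } else {
            pa <- tab$p[[paste0("p_auto_", suffix)]]
            molecules <- list(pa, pa)
          }
          for (p in molecules) {
            res <- run_molecule(tab, p)
            if (!is.null(res)) {
              if (length(res$tab)) {
                counts[tab$isl_row, s] <- counts[tab$isl_row, s] + res$tab
              }
              background[s] <- background[s] + res$bg
            }
          }
        }
      }
    }
    NULL
  })

  structure(list(
    counts = counts,
    samples = data.frame(sample_id = sample_id, condition = conds,
                         replicate = rep(seq_len(n_replicates_per_condition), 2),
                         stringsAsFactors = FALSE),
    background = background,
    params = list(n_cells = n_cells, depth_scale = depth_scale,
                  cut_offset = off, size_window = win,
                  capture_efficiency = model$capture_efficiency)),
    class = "island_count_matrix")
}

#' @export
print.island_count_matrix <- function(x, ...) {
  cat(sprintf("island_count_matrix: %d islands x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write / read an island count matrix as TSV plus sample sheet
#'
#' @param icm an `island_count_matrix`.
#' @param counts_path,samples_path file paths.
#' @param provenance optional named list written as `#` comment headers.
#' @return paths, invisibly.
#' @export
write_island_counts <- function(icm, counts_path, samples_path, provenance = NULL) {
  df <- data.frame(island_id = rownames(icm$counts), icm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, counts_path, provenance)
  .write_tsv(icm$samples, samples_path, provenance)
  invisible(c(counts_path, samples_path))
}

#' @rdname write_island_counts
#' @export
read_island_counts <- function(counts_path, samples_path) {
  df <- .read_tsv(counts_path)
  samples <- .read_tsv(samples_path)
  samples$condition <- .canon_condition(samples$condition)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  .assert(setequal(colnames(m), samples$sample_id),
          "island counts columns and sample sheet disagree")
  m <- m[, samples$sample_id, drop = FALSE]
  structure(list(counts = m, samples = samples, background = NULL,
                 params = list()),
            class = "island_count_matrix")
}

#' Export fragments as BED3
#'
#' @param fragments data.frame `chrom`, `start`, `end`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  .export_bed(data.frame(chrom = fragments$chrom, start = fragments$start,
                         end = fragments$end,
                         name = rep(NA_character_, nrow(fragments)),
                         stringsAsFactors = FALSE), path)
}
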