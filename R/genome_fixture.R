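#' Construct a genome fixture from its components
#'
#' Low-level constructor with validation. Most users will call
#' [make_genome_fixture()]; this constructor exists so that hand-built
#' fixtures (e.g. a single CpG island with known coordinates, or real
#' annotation read from BED files) can flow through the same simulators
#' and analyses.
#'
#' Coordinates are 0-based half-open throughout. The transcription start
#' site (TSS) follows the strand convention: `tss == start` for `+` genes
#' and `tss == end - 1` for `-` genes.
#'
#' @param chrom_lengths named integer vector of chromosome lengths. Names
#'   are the chromosome labels; the X chromosome must be called `"X"`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`, `tss`, `expr_rate` (expected reads per
#'   active allele at unit sequencing depth, strictly positive).
#' @param islands data.frame with columns `island_id`, `chrom`, `start`,
#'   `end` (0-based half-open CpG island intervals, non-overlapping within
#'   a chromosome).
#' @param cpg_sites data.frame with columns `island_id`, `chrom`, `pos`
#'   (0-based coordinate of the plus-strand C of each CpG, strictly
#'   increasing within an island and contained in the island interval),
#'   `assayable` (logical: whether the site is interrogatable by the
#'   digestion assay).
#' @param methylome data.frame parallel to `cpg_sites` with per-site
#'   methylation probabilities by allele class and condition:
#'   `p_auto_neg`, `p_auto_pos` (autosomal alleles, Cre- / Cre+),
#'   `p_xa_neg`, `p_xa_pos` (active X), `p_xi_neg`, `p_xi_pos`
#'   (inactive X). Columns that do not apply to a site's chromosome are
#'   `NA`. In an unperturbed fixture `p_xi_pos == p_xi_neg`.
#' @param params list of generator parameters (recorded for provenance).
#' @param seed integer seed recorded for provenance (`NA` for hand-built
#'   fixtures).
#' @return an object of class `genome_fixture`.
#' @seealso [make_genome_fixture()], [write_fixture()], [read_fixture()]
#' @export
genome_fixture <- function(chrom_lengths, genes, islands, cpg_sites,
                           methylome = NULL, params = list(), seed = NA_integer_) {
  fx <- structure(
    list(chrom_lengths = chrom_lengths, genes = genes, islands = islands,
         cpg_sites = cpg_sites, methylome = methylome, params = params,
         seed = seed),
    class = "genome_fixture")
  validate_genome_fixture(fx)
  fx
}

#' Validate the invariants of a genome fixture
#'
#' Checks id uniqueness, coordinate sanity (0-based half-open, inside the
#' declared chromosome lengths), strictly increasing CpG site coordinates
#' within islands, island non-overlap within chromosomes, positive
#' expression rates and methylation probabilities in \[0, 1\].
#'
#' @param fx a `genome_fixture`.
#' @return `fx`, invisibly; errors describe the first violated invariant.
#' @export
validate_genome_fixture <- function(fx) {
  .assert(inherits(fx, "genome_fixture"), "not a genome_fixture")
  cl <- fx$chrom_lengths
  .assert(!is.null(names(cl)) && all(nzchar(names(cl))), "chrom_lengths must be named")
  .assert(all(cl > 0), "chromosome lengths must be positive")
  g <- fx$genes
  .assert(!anyDuplicated(g$gene_id), "gene_ids must be unique")
  .assert(all(g$chrom %in% names(cl)), "gene chrom not in chrom_lengths")
  .assert(all(g$expr_rate > 0), "expr_rate must be > 0")
  .assert(all(g$strand %in% c("+", "-")), "strand must be '+' or '-'")
  .assert(all(g$start >= 0 & g$start < g$end), "gene intervals must satisfy 0 <= start < end")
  .assert(all(g$end <= cl[g$chrom]), "gene end beyond chromosome length")
  .assert(all(g$tss >= 0 & g$tss < cl[g$chrom]), "tss outside chromosome")
  tss_exp <- ifelse(g$strand == "+", g$start, g$end - 1L)
  .assert(all(g$tss == tss_exp), "tss violates the strand convention")
  isl <- fx$islands
  if (nrow(isl)) {
    .assert(!anyDuplicated(isl$island_id), "island_ids must be unique")
    .assert(all(isl$start >= 0 & isl$start < isl$end), "island intervals must satisfy 0 <= start < end")
    .assert(all(isl$chrom %in% names(cl)), "island chrom not in chrom_lengths")
    .assert(all(isl$end <= cl[isl$chrom]), "island end beyond chromosome length")
    for (ch in unique(isl$chrom)) {
      sub <- isl[isl$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1) {
        .assert(all(sub$start[-1] >= sub$end[-nrow(sub)]),
                "islands overlap on chromosome %s", ch)
      }
    }
  }
  cs <- fx$cpg_sites
  if (!is.null(cs) && nrow(cs)) {
    .assert(all(cs$island_id %in% isl$island_id), "cpg site island_id unknown")
    idx <- match(cs$island_id, isl$island_id)
    .assert(all(cs$pos >= isl$start[idx] & cs$pos < isl$end[idx]),
            "cpg site outside its island interval")
    ord_ok <- tapply(cs$pos, cs$island_id, function(p) all(diff(p) > 0))
    .assert(all(unlist(ord_ok)), "cpg sites must be strictly increasing within an island")
    .assert(is.logical(cs$assayable), "assayable must be logical")
  }
  m <- fx$methylome
  if (!is.null(m)) {
    .assert(nrow(m) == nrow(cs), "methylome must parallel cpg_sites")
    for (col in c("p_auto_neg", "p_auto_pos", "p_xa_neg", "p_xa_pos",
                  "p_xi_neg", "p_xi_pos")) {
      v <- m[[col]]
      .assert(!is.null(v), "methylome missing column %s", col)
      .assert(all(is.na(v) | (v >= 0 & v <= 1)), "%s outside [0,1]", col)
    }
  }
  invisible(fx)
}

#' Generate a seeded synthetic genome fixture
#'
#' Builds a small genome with the statistical structure the downstream
#' analyses assume: `n_autosomes` synthetic autosomes plus one X
#' chromosome; genes laid on a regular grid with random strands and
#' log-normally distributed per-allele expression rates; a CpG island near
#' each TSS with probability `p_tss_island` plus `n_islands_per_chrom`
#' TSS-distal background islands per chromosome; CpG sites within islands
#' with a seeded Bernoulli assayable flag; and a baseline methylome in
#' which CpG islands are moderately methylated on active alleles and
#' hypermethylated on the inactive X (Xi), identical between conditions
#' until [perturb_methylome()] is applied.
#'
#' The default log-normal spread (`sdlog = log(100) / (2 * qnorm(5/6))`)
#' makes the median expression of the top tercile of genes about 10-fold
#' higher than the middle tercile and about 100-fold higher than the
#' bottom tercile, the spread reported for X-linked genes in adult mouse
#' brain. CpG sites are spaced at least twice the digestion cut offset
#' apart so each symmetrically methylated CpG releases its own fragment
#' (see the methods vignette for why).
#'
#' @param n_autosomal_genes,n_x_genes gene counts (>= 1).
#' @param n_islands_per_chrom number of background (TSS-distal) CpG
#'   islands per chromosome.
#' @param expr_lognormal_params numeric `c(meanlog, sdlog)` of the
#'   expression-rate distribution.
#' @param assayable_fraction probability that a CpG site is
#'   interrogatable by the digestion assay (default 0.5, the fraction of
#'   CpG sites the enzymatic assay can interrogate genome-wide).
#' @param seed integer seed; regeneration with the same arguments is
#'   bit-identical.
#' @param n_autosomes number of synthetic autosomes the autosomal genes
#'   are split across.
#' @param p_tss_island probability that a gene has a CpG island whose
#'   midpoint lies within 4 kb of its TSS.
#' @param gene_spacing distance in bp between consecutive gene starts.
#' @param meth_active,meth_xi baseline methylation probabilities of
#'   island CpG sites on active alleles (autosomal and Xa) and on the Xi.
#' @return a [genome_fixture()].
#' @examples
#' fx <- make_genome_fixture(n_autosomal_genes = 40, n_x_genes = 12,
#'                           n_islands_per_chrom = 3, seed = 1)
#' table(fx$genes$chrom)
#' @export
make_genome_fixture <- function(n_autosomal_genes = 15000,
                                n_x_genes = 600,
                                n_islands_per_chrom = 50,
                                expr_lognormal_params = c(meanlog = log(5),
                                                          sdlog = log(100) / (2 * stats::qnorm(5 / 6))),
                                assayable_fraction = 0.5,
                                seed,
                                n_autosomes = 4,
                                p_tss_island = 0.9,
                                gene_spacing = 10000,
                                meth_active = 0.3,
                                meth_xi = 0.8) {
  .assert(.is_count(n_autosomal_genes), "n_autosomal_genes must be a positive count")
  .assert(.is_count(n_x_genes), "n_x_genes must be a positive count")
  .assert(.is_count(n_islands_per_chrom, min = 0), "n_islands_per_chrom must be a non-negative count")
  .assert(.is_count(n_autosomes), "n_autosomes must be a positive count")
  .assert(length(expr_lognormal_params) == 2 && all(is.finite(expr_lognormal_params)),
          "expr_lognormal_params must be c(meanlog, sdlog)")
  .assert(.is_prob(assayable_fraction) && assayable_fraction > 0,
          "assayable_fraction must be in (0, 1]")
  .assert(.is_prob(p_tss_island), "p_tss_island must be a probability")
  .assert(!missing(seed), "seed is required")

  meanlog <- expr_lognormal_params[[1]]
  sdlog <- expr_lognormal_params[[2]]

  # split autosomal genes across autosomes; remainder on the first ones
  base <- n_autosomal_genes %/% n_autosomes
  sizes <- rep(base, n_autosomes) + (seq_len(n_autosomes) <= n_autosomal_genes %% n_autosomes)
  chroms <- c(paste0("autosome_", seq_len(n_autosomes)), "X")
  chrom_ngenes <- c(sizes, n_x_genes)
  names(chrom_ngenes) <- chroms

  withr::with_seed(as.integer(seed), {
    n_genes <- sum(chrom_ngenes)
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    gene_chrom <- rep(chroms, chrom_ngenes)
    idx_in_chrom <- unlist(lapply(chrom_ngenes, seq_len), use.names = FALSE)
    glen <- sample(500:5000, n_genes, replace = TRUE)
    gstart <- idx_in_chrom * gene_spacing
    gend <- gstart + glen
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss <- ifelse(strand == "+", gstart, gend - 1L)
    expr_rate <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)

    genes <- data.frame(gene_id = gene_id, chrom = gene_chrom, strand = strand,
                        start = as.integer(gstart), end = as.integer(gend),
                        tss = as.integer(tss), expr_rate = expr_rate,
                        stringsAsFactors = FALSE)

    # TSS-proximal islands: one per gene with probability p_tss_island,
    # midpoint jittered within 1 kb of the TSS (well inside the 4 kb
    # linkage window). Gene spacing guarantees non-overlap.
    has_isl <- stats::runif(n_genes) < p_tss_island
    ti_gene <- which(has_isl)
    ti_w <- sample(400:900, length(ti_gene), replace = TRUE)
    ti_jit <- sample(-1000:1000, length(ti_gene), replace = TRUE)
    ti_start <- pmax(0L, as.integer(tss[ti_gene] + ti_jit - ti_w %/% 2))
    ti_end <- ti_start + ti_w
    ti <- data.frame(chrom = gene_chrom[ti_gene], start = ti_start, end = ti_end,
                     stringsAsFactors = FALSE)

    # background islands: in the tail region beyond the last gene of each
    # chromosome, one per spacing slot -> non-overlapping, > 4 kb from any TSS
    bg <- NULL
    if (n_islands_per_chrom > 0) {
      bg_chrom <- rep(chroms, each = n_islands_per_chrom)
      bg_slot <- rep(seq_len(n_islands_per_chrom), times = length(chroms))
      bg_w <- sample(400:900, length(bg_chrom), replace = TRUE)
      bg_start <- as.integer((chrom_ngenes[bg_chrom] + 1L + bg_slot) * gene_spacing)
      bg <- data.frame(chrom = bg_chrom, start = bg_start, end = bg_start + bg_w,
                       stringsAsFactors = FALSE)
    }
    islands <- rbind(ti, bg)
    islands <- islands[order(match(islands$chrom, chroms), islands$start), , drop = FALSE]
    islands <- data.frame(island_id = sprintf("cgi%05d", seq_len(nrow(islands))),
                          islands, stringsAsFactors = FALSE)
    rownames(islands) <- NULL

    chrom_lengths <- as.integer((chrom_ngenes + n_islands_per_chrom + 2L) * gene_spacing)
    names(chrom_lengths) <- chroms

    # CpG sites: regular-ish spacing >= 2 * default cut offset (32 bp) so
    # neighbouring methylated CpGs release non-interfering fragments
    w <- islands$end - islands$start
    step <- sample(34:46, nrow(islands), replace = TRUE)
    n_sites <- pmax(1L, (w - 4L) %/% step + 1L)
    pos <- sequence(n_sites, from = islands$start + 2L, by = step)
    cpg_sites <- data.frame(
      island_id = rep(islands$island_id, n_sites),
      chrom = rep(islands$chrom, n_sites),
      pos = as.integer(pos),
      assayable = stats::runif(length(pos)) < assayable_fraction,
      stringsAsFactors = FALSE)

    on_x <- cpg_sites$chrom == "X"
    methylome <- data.frame(
      p_auto_neg = ifelse(on_x, NA_real_, meth_active),
      p_auto_pos = ifelse(on_x, NA_real_, meth_active),
      p_xa_neg = ifelse(on_x, meth_active, NA_real_),
      p_xa_pos = ifelse(on_x, meth_active, NA_real_),
      p_xi_neg = ifelse(on_x, meth_xi, NA_real_),
      p_xi_pos = ifelse(on_x, meth_xi, NA_real_))

    genome_fixture(
      chrom_lengths = chrom_lengths, genes = genes, islands = islands,
      cpg_sites = cpg_sites, methylome = methylome,
      params = list(n_autosomal_genes = n_autosomal_genes, n_x_genes = n_x_genes,
                    n_islands_per_chrom = n_islands_per_chrom,
                    expr_lognormal_params = c(meanlog = meanlog, sdlog = sdlog),
                    assayable_fraction = assayable_fraction,
                    n_autosomes = n_autosomes, p_tss_island = p_tss_island,
                    gene_spacing = gene_spacing, meth_active = meth_active,
                    meth_xi = meth_xi),
      seed = as.integer(seed))
  })
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf("genome_fixture: %d chromosomes, %d genes (%d on X), %d islands, %d CpG sites (seed %s)\n",
              length(x$chrom_lengths), nrow(x$genes),
              sum(x$genes$chrom == "X"), nrow(x$islands),
              nrow(x$cpg_sites), format(x$seed)))
  invisible(x)
}
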