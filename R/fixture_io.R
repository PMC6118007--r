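# On-disk representation of a fixture: genes as BED6 + expression TSV,
# islands as BED4 + CpG-site TSV (with methylome columns), chromosome
# lengths TSV and a JSON manifest recording seed and parameters. BED files
# are written/read through rtracklayer; all internal coordinates stay
# 0-based half-open (BED native).

.export_bed <- function(df, path, strand = NULL, score = NULL) {
  if (!nrow(df)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(strand)) "*" else strand)
  if (!all(is.na(df$name))) names(gr) <- df$name
  if (!is.null(score)) gr$score <- score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

.import_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a genome fixture to a directory
#'
#' Emits `genes.bed` (BED6), `gene_expression.tsv`, `islands.bed` (BED4),
#' `cpg_sites.tsv` (site coordinates, assayable flags and methylome
#' probabilities), `chromosomes.tsv` and `manifest.json`. The file set
#' round-trips losslessly through [read_fixture()].
#'
#' @param fixture a [genome_fixture()].
#' @param out_dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(fixture, out_dir) {
  validate_genome_fixture(fixture)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .assert(dir.exists(out_dir), "cannot create directory %s", out_dir)
  g <- fixture$genes
  .export_bed(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                         name = g$gene_id, stringsAsFactors = FALSE),
              file.path(out_dir, "genes.bed"),
              strand = g$strand, score = rep(0L, nrow(g)))
  .write_tsv(g[, c("gene_id", "expr_rate")],
             file.path(out_dir, "gene_expression.tsv"))
  isl <- fixture$islands
  .export_bed(data.frame(chrom = isl$chrom, start = isl$start, end = isl$end,
                         name = isl$island_id, stringsAsFactors = FALSE),
              file.path(out_dir, "islands.bed"))
  cs <- cbind(fixture$cpg_sites, fixture$methylome)
  .write_tsv(cs, file.path(out_dir, "cpg_sites.tsv"))
  .write_tsv(data.frame(chrom = names(fixture$chrom_lengths),
                        length = unname(fixture$chrom_lengths),
                        stringsAsFactors = FALSE),
             file.path(out_dir, "chromosomes.tsv"))
  jsonlite::write_json(list(seed = fixture$seed, params = fixture$params),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a genome fixture written by [write_fixture()]
#'
#' @param dir directory containing the fixture file set.
#' @return a [genome_fixture()] equal to the one written.
#' @export
read_fixture <- function(dir) {
  .assert(dir.exists(dir), "no such directory: %s", dir)
  gb <- .import_bed(file.path(dir, "genes.bed"))
  expr <- .read_tsv(file.path(dir, "gene_expression.tsv"))
  genes <- data.frame(gene_id = gb$name, chrom = gb$chrom, strand = gb$strand,
                      start = gb$start, end = gb$end,
                      tss = ifelse(gb$strand == "+", gb$start, gb$end - 1L),
                      expr_rate = expr$expr_rate[match(gb$name, expr$gene_id)],
                      stringsAsFactors = FALSE)
  ib <- .import_bed(file.path(dir, "islands.bed"))
  islands <- data.frame(island_id = ib$name, chrom = ib$chrom,
                        start = ib$start, end = ib$end, stringsAsFactors = FALSE)
  if (!nrow(islands)) {
    islands <- data.frame(island_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  }
  cs_all <- .read_tsv(file.path(dir, "cpg_sites.tsv"))
  meth_cols <- c("p_auto_neg", "p_auto_pos", "p_xa_neg", "p_xa_pos",
                 "p_xi_neg", "p_xi_pos")
  cpg_sites <- cs_all[, c("island_id", "chrom", "pos", "assayable"), drop = FALSE]
  cpg_sites$assayable <- as.logical(cpg_sites$assayable)
  methylome <- cs_all[, meth_cols, drop = FALSE]
  chroms <- .read_tsv(file.path(dir, "chromosomes.tsv"))
  cl <- as.integer(chroms$length)
  names(cl) <- chroms$chrom
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  genome_fixture(chrom_lengths = cl, genes = genes, islands = islands,
                 cpg_sites = cpg_sites, methylome = methylome,
                 params = manifest$params,
                 seed = if (is.null(manifest$seed)) NA_integer_ else as.integer(manifest$seed))
}
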