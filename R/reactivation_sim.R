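#' Expression-dependent Xi reactivation model
#'
#' Hill-type model for the probability that a given X-linked gene is
#' reactivated (loses Xi silencing) in a given cell after Xist deletion:
#' `p(e) = p_max * e^h / (e^h + e50^h)` where `e` is the gene's
#' per-allele expression rate. The probability increases with expression
#' level, capturing the observation that highly expressed genes (neuronal
#' MeCP2-like, reactivated in a few percent of cells) lose silencing an
#' order of magnitude more often than lowly expressed ones.
#'
#' Defaults are calibrated so that the probability at the top-tercile
#' median expression of the default fixture (~50 reads/allele) is ~0.043,
#' inside the 2.3-4.8% range measured for neurons, and the probability at
#' 100-fold lower expression is ~0.0017, inside the 0.1-0.2% astrocyte
#' range.
#'
#' @param p_max ceiling reactivation fraction in \[0, 1\].
#' @param e50 expression rate at half-ceiling; `e50 = 0` is the
#'   expression-independent limit where every gene reactivates with
#'   probability `p_max` (used for uniform-fraction simulations).
#' @param h Hill steepness (> 0).
#' @return an object of class `reactivation_model`.
#' @export
reactivation_model <- function(p_max = 0.045, e50 = 5, h = 1.4) {
  .assert(.is_prob(p_max), "p_max must be in [0, 1]")
  .assert(length(e50) == 1 && is.finite(e50) && e50 >= 0, "e50 must be >= 0")
  .assert(length(h) == 1 && is.finite(h) && h > 0, "h must be > 0")
  structure(list(p_max = p_max, e50 = e50, h = h), class = "reactivation_model")
}

#' Per-gene per-cell reactivation probability
#'
#' @param expr_rate vector of strictly positive expression rates.
#' @param model a [reactivation_model()].
#' @return probabilities in `[0, model$p_max]`, nondecreasing in
#'   `expr_rate`.
#' @examples
#' m <- reactivation_model()
#' reactivation_probability(c(0.5, 5, 50), m)
#' @export
reactivation_probability <- function(expr_rate, model) {
  .assert(inherits(model, "reactivation_model"), "model must be a reactivation_model")
  .assert(all(expr_rate > 0), "expr_rate must be > 0")
  if (model$e50 == 0) return(rep(model$p_max, length(expr_rate)))
  eh <- expr_rate^model$h
  model$p_max * eh / (eh + model$e50^model$h)
}

#' Sample per-cell Xi reactivation states
#'
#' Realizes the mosaic cell population: for a Cre+ sample each
#' (X-linked gene, cell) pair carries an all-or-none reactivation
#' indicator; in Cre- samples Xist is intact and every indicator is 0.
#' Two coupling modes are available. `"locus"` (default) draws
#' indicators independently across genes within a cell, i.e. silencing is
#' lost locus-by-locus. `"chromosome"` draws a single latent uniform per
#' cell and reactivates gene `g` in cell `c` iff `u_c < p(e_g)`, i.e.
#' derepression is nested along a per-cell severity axis; both modes have
#' identical marginals `P(indicator) = p(e_g)`.
#'
#' @param fixture a [genome_fixture()].
#' @param model a [reactivation_model()].
#' @param n_cells number of cells in the sample (>= 1).
#' @param condition `"Cre+"` or `"Cre-"`.
#' @param seed integer seed.
#' @param coupling `"locus"` or `"chromosome"`.
#' @return an object of class `cell_population` with elements
#'   `condition`, `n_cells`, `gene_id` (X genes), `indicators` (logical
#'   genes x cells matrix) and `mean_reactivated` (per-gene fraction of
#'   reactivated cells).
#' @export
sample_reactivation_states <- function(fixture, model, n_cells, condition,
                                       seed, coupling = c("locus", "chromosome")) {
  .assert(.is_count(n_cells), "n_cells must be >= 1")
  condition <- .canon_condition(condition)
  coupling <- match.arg(coupling)
  xg <- fixture$genes[fixture$genes$chrom == "X", , drop = FALSE]
  ng <- nrow(xg)
  if (condition == "Cre-") {
    ind <- matrix(FALSE, nrow = ng, ncol = n_cells, dimnames = list(xg$gene_id, NULL))
  } else {
    p <- reactivation_probability(xg$expr_rate, model)
    ind <- withr::with_seed(as.integer(seed), {
      if (coupling == "locus") {
        matrix(stats::runif(ng * n_cells) < p, nrow = ng,
               dimnames = list(xg$gene_id, NULL))
      } else {
        u <- stats::runif(n_cells)
        outer(p, u, FUN = ">")
      }
    })
    dimnames(ind) <- list(xg$gene_id, NULL)
  }
  structure(list(condition = condition, n_cells = n_cells, gene_id = xg$gene_id,
                 indicators = ind, mean_reactivated = rowMeans(ind)),
            class = "cell_population")
}

#' Deterministic large-population limit of a cell population
#'
#' Returns a `cell_population` whose per-gene mean reactivation fraction
#' equals `fraction` exactly, without per-cell sampling. This is the
#' injected-shift mode used for power analyses (e.g. a uniform 4% X-wide
#' dosage upshift): expected bulk counts are the infinite-cell limit of
#' the mosaic model.
#'
#' @param fixture a [genome_fixture()].
#' @param fraction reactivated fraction in \[0, 1\] (recycled per gene).
#' @param condition `"Cre+"` or `"Cre-"` (the latter forces 0).
#' @return a `cell_population` with `indicators = NULL`.
#' @export
make_fixed_population <- function(fixture, fraction, condition = "Cre+") {
  condition <- .canon_condition(condition)
  .assert(all(fraction >= 0 & fraction <= 1), "fraction must be in [0, 1]")
  xg <- fixture$genes[fixture$genes$chrom == "X", , drop = FALSE]
  fr <- if (condition == "Cre-") rep(0, nrow(xg)) else rep_len(fraction, nrow(xg))
  structure(list(condition = condition, n_cells = NA_integer_, gene_id = xg$gene_id,
                 indicators = NULL, mean_reactivated = stats::setNames(fr, xg$gene_id)),
            class = "cell_population")
}

#' Expected bulk counts for one sample
#'
#' Closed-form expectation of the bulk count of each gene given the
#' sample's cell population: an autosomal gene has two active alleles and
#' expects `2 * expr_rate * depth`; an X-linked gene expects
#' `(1 + mean reactivation fraction) * expr_rate * depth` (the Xa
#' contributes one allele's worth, the Xi contributes a full allele in
#' the reactivated fraction of cells and nothing elsewhere).
#'
#' @param fixture a [genome_fixture()].
#' @param population a `cell_population`.
#' @param depth positive sequencing-depth scalar.
#' @return named numeric vector of expected counts, one per gene.
#' @export
expected_bulk_counts <- function(fixture, population, depth) {
  .assert(inherits(population, "cell_population"), "population must be a cell_population")
  .assert(length(depth) == 1 && depth > 0, "depth must be positive")
  g <- fixture$genes
  alleles <- rep(2, nrow(g))
  on_x <- g$chrom == "X"
  .assert(identical(population$gene_id, g$gene_id[on_x]),
          "population X genes do not match the fixture")
  alleles[on_x] <- 1 + population$mean_reactivated
  stats::setNames(alleles * g$expr_rate * depth, g$gene_id)
}

#' Simulate bulk RNA-seq count matrices from cell populations
#'
#' Aggregates each cell population (one per animal/sample) into a bulk
#' count vector: expected counts from [expected_bulk_counts()], with
#' negative-binomial noise at a single gene-shared dispersion
#' (`Var = mu + dispersion * mu^2`; Poisson when `dispersion = 0`).
#'
#' @param fixture a [genome_fixture()].
#' @param populations list of `cell_population` objects, one sample each.
#' @param depth positive sequencing-depth scalar.
#' @param dispersion non-negative NB dispersion shared across genes.
#' @param seed integer seed.
#' @return an object of class `count_matrix`: list with `counts`
#'   (integer genes x samples matrix), `samples` (data.frame `sample_id`,
#'   `condition`, `replicate`, `library_size`).
#' @export
simulate_bulk_counts <- function(fixture, populations, depth = 10,
                                 dispersion = 0.05, seed) {
  .assert(length(populations) >= 1, "populations must be nonempty")
  .assert(length(depth) == 1 && depth > 0, "depth must be positive")
  .assert(length(dispersion) == 1 && dispersion >= 0, "dispersion must be >= 0")
  g <- fixture$genes
  conds <- vapply(populations, function(p) p$condition, character(1))
  rep_idx <- stats::ave(seq_along(conds), conds, FUN = seq_along)
  tag <- ifelse(conds == "Cre+", "CrePos", "CreNeg")
  sample_id <- sprintf("%s_r%d", tag, rep_idx)
  counts <- withr::with_seed(as.integer(seed), {
    vapply(populations, function(pop) {
      mu <- expected_bulk_counts(fixture, pop, depth)
      as.integer(if (dispersion == 0) stats::rpois(length(mu), mu)
                 else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
    }, integer(nrow(g)))
  })
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = nrow(g))
  dimnames(counts) <- list(g$gene_id, sample_id)
  structure(list(
    counts = counts,
    samples = data.frame(sample_id = sample_id, condition = conds,
                         replicate = as.integer(rep_idx),
                         library_size = unname(colSums(counts)),
                         stringsAsFactors = FALSE)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$samples$condition)),
                            table(x$samples$condition)), collapse = ", ")))
  invisible(x)
}

#' Write / read a count matrix as TSV plus sample sheet
#'
#' `counts.tsv` has `gene_id` as the first column and one column per
#' sample; `samples.tsv` has `sample_id`, `condition`, `replicate`.
#'
#' @param cm a `count_matrix`.
#' @param counts_path,samples_path file paths.
#' @param provenance optional named list written as `#` comment headers.
#' @return paths, invisibly.
#' @export
write_count_matrix <- function(cm, counts_path, samples_path, provenance = NULL) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, counts_path, provenance)
  .write_tsv(cm$samples, samples_path, provenance)
  invisible(c(counts_path, samples_path))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  df <- .read_tsv(counts_path)
  samples <- .read_tsv(samples_path)
  samples$condition <- .canon_condition(samples$condition)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  .assert(setequal(colnames(m), samples$sample_id),
          "counts columns and sample sheet disagree")
  m <- m[, samples$sample_id, drop = FALSE]
  if (is.null(samples$library_size)) samples$library_size <- unname(colSums(m))
  structure(list(counts = m, samples = samples), class = "count_matrix")
}
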