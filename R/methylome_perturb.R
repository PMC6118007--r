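#' Apply the Xist-loss methylome perturbation to a fixture
#'
#' Models the DNA-methylation consequence of deleting Xist after X
#' inactivation is established: CpG islands on the Xi lose methylation in
#' proportion to how often their gene reactivates, while a small minority
#' of X islands instead gain methylation. Concretely, for an X island
#' linked to a gene with expression rate `e` (nearest TSS within
#' `max_distance` of the island midpoint), the Cre+ Xi site
#' probabilities become `p_xi_neg * (1 - d)` with
#' `d = d_max * p(e) / p_max` — demethylation coupled to the
#' reactivation propensity of [reactivation_model()]. Unlinked X islands
#' are left at baseline. Independently, a seeded Bernoulli
#' `hyper_fraction` of X islands gains `hyper_delta` on the Cre+ Xi
#' probability (capped at 1), producing the observed minority of
#' hypermethylated islands. Cre- probabilities and all autosomal/Xa
#' probabilities are untouched.
#'
#' @param fixture a [genome_fixture()].
#' @param model a [reactivation_model()] supplying the coupling shape.
#' @param d_max maximal Xi demethylation fraction (at genes whose
#'   reactivation probability reaches `p_max`).
#' @param hyper_fraction fraction of X islands gaining methylation.
#' @param hyper_delta additive gain on Cre+ Xi methylation probability.
#' @param max_distance TSS linkage window in bp.
#' @param seed integer seed (hyper-island selection).
#' @return the fixture with updated `p_xi_pos` and a `perturbation`
#'   element recording per-island demethylation and hyper flags.
#' @export
perturb_methylome <- function(fixture, model = reactivation_model(),
                              d_max = 0.25, hyper_fraction = 0.05,
                              hyper_delta = 0.15, max_distance = 4000, seed) {
  .assert(.is_prob(d_max), "d_max must be in [0, 1]")
  .assert(.is_prob(hyper_fraction), "hyper_fraction must be in [0, 1]")
  .assert(hyper_delta >= 0, "hyper_delta must be >= 0")
  linkage <- link_islands_to_tss(fixture$islands, fixture$genes,
                                 max_distance = max_distance)
  on_x <- fixture$islands$chrom == "X"
  e <- fixture$genes$expr_rate[match(linkage$gene_id, fixture$genes$gene_id)]
  d <- rep(0, nrow(fixture$islands))
  linked <- on_x & !is.na(linkage$gene_id)
  if (model$p_max > 0 && any(linked)) {
    d[linked] <- d_max * reactivation_probability(e[linked], model) / model$p_max
  }
  hyper <- rep(FALSE, nrow(fixture$islands))
  if (hyper_fraction > 0 && any(on_x)) {
    hyper[on_x] <- withr::with_seed(as.integer(seed),
                                    stats::runif(sum(on_x)) < hyper_fraction)
  }
  site_isl <- match(fixture$cpg_sites$island_id, fixture$islands$island_id)
  p_new <- fixture$methylome$p_xi_neg * (1 - d[site_isl]) +
    hyper[site_isl] * hyper_delta
  fixture$methylome$p_xi_pos <- pmin(1, p_new)
  fixture$perturbation <- data.frame(
    island_id = fixture$islands$island_id,
    demethylation = d, hyper = hyper, stringsAsFactors = FALSE)
  fixture
}
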