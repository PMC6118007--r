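---
title: "Methods: simulating and detecting mosaic Xi reactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting mosaic Xi reactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(XiMosaic)
```

## The model

XiMosaic models a female mouse brain in which Xist has been deleted from the
inactive X (Xi) after X inactivation was established. The biological picture
it encodes is mosaic, all-or-none reactivation: in each cell, each X-linked
gene either stays fully silenced on the Xi (contributing zero Xi reads) or
reactivates completely (contributing a full allele's worth). Bulk sequencing
then sees the *population average*: an X gene whose reactivated cell
fraction is $f$ has expected expression $(1+f)\,e\,d$ against the autosomal
baseline $2\,e\,d$, where $e$ is the per-allele expression rate and $d$ the
sequencing depth scalar.

Reactivation propensity increases with expression level through a Hill
curve,

$$p(e) \;=\; p_{\max}\,\frac{e^{h}}{e^{h} + e_{50}^{h}},$$

which encodes the observation that strongly transcribed genes (neuronal
MeCP2-like) lose silencing roughly an order of magnitude more often than
weakly transcribed ones. Setting $e_{50}=0$ collapses the curve to an
expression-independent fraction $p_{\max}$; this uniform limit is what the
recovery and power analyses use.

The central statistic is the per-gene **reactivation ratio**

$$r \;=\; \frac{\text{Cre+}}{\text{Cre+} + \text{Cre\textminus}}$$

on per-condition means of library-normalized counts. Under intact silencing
the two conditions are exchangeable and $E[r] = 1/2$ exactly; a uniform
reactivated fraction $f$ gives $E[r] \approx (1+f)/(2+f)$, inverted by the
estimator $\hat f = (2\bar r - 1)/(1-\bar r)$.

On the methylation side, the Xi's CpG islands are hypermethylated at
baseline and lose methylation where genes reactivate. The in-silico MeD-seq
digest emulates a methylation-dependent restriction enzyme that cuts at a
fixed offset (default 16 nt) downstream of each methylated cytosine on its
own strand: a CpG methylated on both strands releases a fragment of exactly
$2 \times 16 = 32$ bp, hemimethylated and unmethylated CpGs release nothing,
and gel size selection (window 27–37 bp) keeps the CpG-sized fragments.
Island fragment counts are then analysed with the same normalization,
fold-change shift, and ratio machinery as the RNA side.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| expression rates | log-normal, meanlog $\log 5$, sdlog $\log(100)/(2\,\Phi^{-1}(5/6)) \approx 2.38$ | tercile medians span ~10× (top/middle) and ~100× (top/bottom), the spread reported for X-linked genes in adult brain |
| `p_max`, `e50`, `h` | 0.045, 5, 1.4 | $p$ at the top-tercile median (~50 reads/allele) is ~0.043, inside the 2.3–4.8% neuronal band; $p$ at 100-fold lower expression is ~0.0017, inside the 0.1–0.2% astrocyte band |
| replicates | 3 RNA + 3 RNA, 2 MeD + 2 MeD | the study design (n = 3 RNA-seq, n = 2 MeD-seq animals per genotype) |
| cells per RNA sample | 10,000 | large enough that per-sample binomial noise in the realized reactivated fraction (~0.2% SD at $f=0.05$) is negligible against count noise |
| depth | 10 | a median X gene totals ~60 raw reads over six samples, so ~90% of 600 X genes clear the 20-read filter, reproducing the ~540-gene filtered universe |
| NB dispersion | 0.05 | simplest shared overdispersion adequate for rank-based tests; it sets a per-gene ratio SD floor of ~0.046, matching the observed top-tercile SD |
| baseline methylation | 0.3 active alleles / 0.8 Xi | CpG islands moderately methylated on active chromosomes, hypermethylated on the Xi |
| Xi demethylation | $d(e) = d_{\max}\, p(e)/p_{\max}$, $d_{\max}=0.25$ | demethylation coupled to reactivation propensity; $d_{\max}$ chosen so the tercile-2+3 vs tercile-1 island-ratio gap is ~0.02–0.03, the size of the reported contrast (0.487 vs 0.512) |
| hypermethylated islands | 5% of X islands, +0.15 | a small minority of X islands gains methylation, so individual fold changes above 1 coexist with an aggregate hypomethylation shift |
| 20-read filter | ≥ 20 raw reads summed over all samples | strict "fewer than 20 excluded" boundary: exactly 20 is retained |
| TSS linkage | island midpoint within 4,000 bp (inclusive) of the nearest TSS | the anchor point (midpoint) is a package choice; ties go to the lexicographically smaller gene id |
| pseudocount | 0.5 on both fold-change means | keeps zero-control genes finite without materially moving high-count genes |

## What the generator emulates — and what it does not

The fixture is an abstraction, not a genome. Genes sit on a regular grid
(10 kb spacing) across four synthetic autosomes plus an X; there are no
exons, sequences, or overlapping transcripts. CpG islands appear near each
TSS with probability 0.9 (plus a configurable number of TSS-distal
background islands per chromosome), and island CpG sites are spaced 34–46 bp
apart — **at least twice the cut offset** — so that every symmetrically
methylated CpG releases its own full-length fragment. Real CpG islands are
far denser; with realistic spacing, cuts at neighbouring methylated CpGs
would truncate each other's fragments below the size window and island
counts would no longer be linear in methylation probability. We chose
linearity (expected island abundance proportional to the sum of per-site
methylation probabilities) as the contract the analyses rely on, and
document the density abstraction as a known deviation from real MeD-seq,
where fragment recovery saturates in dense, highly methylated regions.

Other simplifications: silencing escape genes are absent by default (the
Cre− Xi contributes exactly zero reads); the enzyme's sequence-context
specificity is summarized by a single per-site "assayable" Bernoulli flag
(~50% of sites); the cut is modelled as one blunt double-strand break rather
than the enzyme's staggered cut; and cell-type structure (neurons vs
astrocytes) is represented only through the expression dependence of
$p(e)$, not as discrete mixtures. Passing tests therefore show that the
*analysis chain* behaves correctly under the stated generative model — they
do not validate the model against real brain data, which this package does
not ship.

Reactivation coupling across genes is configurable. The default
(`coupling = "locus"`) draws each (gene, cell) indicator independently; the
alternative (`coupling = "chromosome"`) draws one latent uniform per cell so
that derepression is nested along a per-cell severity axis. Both have the
same marginals, hence the same bulk expectations; bulk data of this design
cannot distinguish them.

## Numerical and design choices

**Stratification measure.** Genes are ranked for tercile/quartile binning by
their mean normalized count over *all six samples*. Ranking by one
condition alone is biased: the Cre− mean is the denominator of $r$, so
conditioning the lowest bin on low observed Cre− counts enriches it for
genes whose Cre− counts fluctuated downward and inflates that bin's mean
ratio by about +0.01 at default scale — enough to invert the expected
ordering. The symmetric total-expression measure makes the bin assignment
nearly independent of the ratio's noise. (A measure that overweights Cre+
reads has the opposite artifact, depressing the lowest bin below 0.5, which
is worth keeping in mind when comparing to published bin means.)

**Normalization.** Each sample is scaled so its autosomal read total equals
the across-sample geometric mean of autosomal totals; X-linked (and X
island) counts share the factor but are excluded from computing it, so an
X-wide dosage or methylation change cannot distort the scale factors.
Because library totals carry overdispersed noise, the scale factors
contribute a *shared* error component to cohort-level summaries (SD ≈ 0.004
on the mean X ratio at default scale, about double the naive per-gene
standard error); Monte-Carlo checks in the test suite therefore estimate
their error bars across replicate cohorts rather than from per-gene spread.

**Ratios and fold changes.** Per-condition means of normalized counts by
default; a `pooled` switch uses raw read sums instead. Fold changes are
reported on the fc scale (mutant/control), matching the additive shift
statistic (difference of group mean fold changes); a log2 column is provided
for plotting. Genes or islands with zero totals in both conditions are
dropped with a logged count; zero-denominator ratios are `NA` and excluded
downstream.

**Tests.** Student's pooled-variance t (two-sided) for bin contrasts, as
named in the study, with a Welch option; two-sided Wilcoxon rank-sum
(normal approximation) for distribution shifts, with an exact-tie guard
returning $p = 1$ when every value in both groups is identical; no
multiple-testing correction, since only a handful of planned comparisons is
reported. Stratification breaks expression ties lexicographically by gene
id and assigns remainder genes to the lowest bins (540 genes give terciles
of 180 and quartiles of 135; 7 genes with $k=3$ give sizes 3/2/2).

**Digestion edge cases.** Cut sites whose fragment would extend beyond the
chromosome are dropped with a warning; fragments are assigned to islands by
midpoint (lower median for even lengths), fragments whose midpoint lies in
no island count as background; islands must be non-overlapping within a
chromosome, which the generator guarantees and the counter validates. The
digest emits only inter-cut pieces containing at least one methylated CpG —
CpG-free spacer pieces between distant cuts are not sequenced fragments.

**Determinism.** Every stochastic stage takes an explicit seed; the pipeline
derives per-stage seeds from the master seed by a stable polynomial hash of
the stage name plus replicate index (`stage_seed()`), keeps all seeds below
$2^{31}$, and writes doubles at full precision (`%.17g`), so a repeated run
is byte-identical and fixtures round-trip losslessly through their BED/TSV
representation.

## Problem sizes used by the test suite

The default fixture (15,000 autosomal + 600 X genes, ~14,000 islands) runs
end to end in seconds, so the acceptance-level checks use it directly:
8 null cohorts for the null-centering check, 16 cohorts per reactivation
fraction for estimator recovery (with common random numbers across the
fraction grid, which makes the recovered estimates provably nested),
200 seeds each for the type-I and power properties of the shift test,
48 cohorts for the quartile-ordering signature, and 2 in-silico MeD-seq
cohorts for the methylation contrast. Oracle-equivalence checks use
deliberately tiny fixtures (≤ 10 genes × ≤ 100 cells; ≤ 5 islands) where
brute-force per-cell summation and per-site enumeration are exact.

## Known limitations

* The generator's noise model is a single shared NB dispersion; real
  RNA-seq has gene-specific dispersion and GC/length effects.
* CpG site spacing is widened to keep island counts linear in methylation
  (see above); absolute MeD-seq fragment yields are therefore not
  comparable to real libraries.
* The reactivation ratio is a bulk statistic: it cannot distinguish many
  genes reactivating weakly from few cells reactivating fully — that
  identification comes from the all-or-none model assumption, which in the
  motivating system is established by single-cell imaging, not by this
  package.
* With two MeD-seq replicates per condition, island-level inference leans
  on the large number of islands, not on biological replication; the
  per-island ratio SDs from simulation are accordingly much smaller than
  those of real between-animal comparisons.
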