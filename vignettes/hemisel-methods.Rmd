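---
title: "Detecting purifying selection in hemizygous tumor genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting purifying selection in hemizygous tumor genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Cancer cells depend on essential genes, yet purifying selection against
damaging somatic mutations is rarely visible in tumor sequencing data. The
reason is zygosity: most essential genes are haplosufficient, so a damaging
mutation on one allele is masked by the healthy second copy and carries
little fitness cost. In hemizygously deleted (HeZD) regions that backup is
gone. hemisel operationalises this as a contrast: for each gene, compare the
functional-impact distribution of somatic mutations observed in HeZD samples
with that in copy-number-neutral (CNN) samples. Purifying selection removes
high-impact mutations specifically from the HeZD group, shifting its impact
distribution downwards; positive selection on the remaining allele (the
hemizygous tumor-suppressor situation) shifts it upwards.

The screen's per-gene statistic is a one-sided Wilcoxon rank-sum test of
HeZD impact scores against CNN impact scores (`alternative = "less"` for
purifying selection), over genes with at least `min_mut = 10` mutations in
each group, with Benjamini-Hochberg FDR control across the screened genes
and ranks assigned by ascending p-value.

Impact scores are phred-like on a 0-40 scale with hard conventions: silent
mutations score exactly 0, truncating mutations (nonsense substitutions,
stop-loss substitutions and frameshift indels) exactly 40, and missense
substitutions take a precomputed per-substitution score. In-frame indels,
which are non-silent but rarely truncating, receive a midpoint score of 20
unless stated otherwise; they are rare and do not drive the statistics.

## Mutational signatures and the neutral expectation

Mutation probabilities are strongly context-dependent, and the context
spectrum (the 96 trinucleotide substitution classes: 6 pyrimidine-referenced
substitution types x 4 upstream x 4 downstream bases) differs between cancer
types. Two statistics use a per-cancer 96-class signature as the neutral
model:

* **Signature-weighted dN/dS.** Each of a gene's `3L` possible
  substitutions receives the signature weight of its class; with normalised
  per-substitution probabilities `p_j`, the expected silent site count is
  `S = 3L * sum(p_j over silent j)` and `N = 3L - S`. dN/dS is
  `(n/N)/(s/S)` for observed non-silent and silent counts `n` and `s`;
  values below 1 indicate purifying selection. A one-sided Fisher's exact
  test on `[[n, s], [round(N), round(S)]]` (deficit of non-silent) tests
  dN/dS < 1. The analytic expectation is the default; a sampling mode
  (default 10^6 multinomial draws) reproduces the simulation approach and
  cross-validates the closed form.
* **Normalized impact scores.** The no-selection score distribution of a
  gene in a cancer is the score vector of all `3L` substitutions weighted by
  the signature probabilities; its weighted median is the simulated-null
  median. An observed score is normalised to
  `(obs - med) / (40 - med)` when above the median and
  `(obs - med) / (med - 0)` below it, giving values in `[-1, 1]` where
  negative means purifying and positive means positive selection, with a
  deterministic denominator fixed by the score bounds.

Within the full screen, per-cancer signatures (estimated from the pooled,
deduplicated substitutions of each cancer) drive the normalized scores,
while the per-gene dN/dS columns estimate the class proportions from each
gene-and-state stratum's own substitutions, matching how the site
expectation is defined for that comparison. `dnds()` accepts any signature,
so either policy can be applied explicitly.

## The filter cascade

1. **Deduplication** removes repeated (sample, gene, position, allele)
   records, keeping first occurrences.
2. **Cluster filter.** Positional mutation clusters signal positive
   selection or artefacts and would contaminate a purifying-selection
   screen. For a gene with `m` pooled mutations and CDS length `L`, a
   position carrying `k >= 2` mutations is removed (all mutations at it)
   when the binomial tail `P(X >= k)`, `X ~ Binomial(m, 1/L)`, is at most
   `alpha = 0.01`. This is a single pass: flags are computed once from the
   input counts. (A fixpoint iteration would remove slightly more in
   borderline cases; the single pass is the procedure the screen is built
   on, and the audit flags make the removals fully reproducible.)
3. **Expression filter.** Purifying selection requires the gene to be
   expressed; a gene is expressed in a cancer when its median expression
   exceeds 200 (strictly) in RSEM-like units. Filtering is per
   (gene, cancer) pair: a gene expressed in one cancer contributes only its
   mutations from that cancer.
4. **State assignment.** Mutations take the GISTIC-style call of their
   (gene, sample): -1 HeZD, 0 CNN, +1/+2 amplified. Homozygously deleted
   cells are excluded (no allele left to select on).
5. **Group-size filter.** Only genes with >= 10 mutations in both the HeZD
   and the CNN group are screened; below that the rank-sum test has no
   useful resolution.

## Statistical machinery and numerical choices

* **Rank-sum test.** `rank_sum_test()` enumerates all `choose(n1+n2, n1)`
  group assignments with midranks when that count is at most 10^5 — exact
  even under ties, which matter here because silent mutations tie at score
  0 — and otherwise uses the normal approximation with tie correction and
  continuity correction (numerically identical to `wilcox.test`'s
  approximate path).
* **One-sample deviation test.** Normalized-score deviations from 0 use the
  Wilcoxon signed-rank test; zeros are dropped first. Up to 15 non-zero
  scores, all 2^n sign assignments are enumerated with midranks (exact under
  ties); beyond that the normal approximation is used. An all-zero input is
  degenerate and returns p = 1 with a warning.
* **Weighted median.** The simulated-null median is the lower weighted
  median: the smallest score whose cumulative weight reaches 1/2. With
  atoms at 0 (silent) and 40 (truncating) a smoothed definition would be
  arbitrary; the lower median is deterministic and matches the enumeration
  oracle used in the tests.
* **Fisher table rounding.** Expected site counts are real numbers; the
  Fisher comparison row uses `round()` (half-to-even), documented and
  deterministic.
* **Ranks and ties.** Screen ranks follow ascending p with lexicographic
  gene-id tie-breaks, so output ordering is reproducible byte for byte.
* **Degenerate inputs.** dN/dS with `s == 0` or `S == 0` is undefined and
  reported as `NA` with a note rather than an infinity; a signature putting
  zero weight on every substitution of a gene is an error; a normalization
  span of zero (observed score equal to a median sitting on a bound)
  yields 0 with a warning.

ROC/AUC benchmarking uses the rank-sum identity with midranks (ties count
half), which equals explicit pair counting; gene-set enrichment uses
one-sided Fisher's exact tests against the screened-gene background — using
the whole genome as background would confound enrichment with the elevated
mutation rates of screenable loci.

## The synthetic cohort generator

`generate_cohort()` creates cohorts with the statistical structure the
analysis assumes, plus ground-truth labels, so that calibration and recovery
are measurable. Per cancer, a 96-class signature is drawn from a
Dirichlet(0.5) (or supplied explicitly). Per gene and sample, a copy-number
state is drawn (per-gene HeZD probability uniform in [0.2, 0.4]; HoZD
0.005; amplification 0.10). Candidate substitutions are drawn with
per-site hazards proportional to the class weight divided by the genome-wide
opportunity count of that class — the configured signature is a target
observed spectrum, and without opportunity normalisation the codon-driven
trinucleotide composition of coding sequences would distort the realised
spectrum. Per-gene candidate rates scale with each gene's total hazard
(mutation-prone genes collect proportionally more mutations), with a mean of
0.4 expected mutations per gene per sample.

Selection acts only in HeZD samples: a candidate mutation in an essential
gene is rejected with probability `sigma * impact/40` (default
`sigma = 0.8`), the simplest model in which rejection scales linearly with
functional impact; candidates in tumor-suppressor genes are drawn with
weights tilted by `1 + beta * impact/40` (default `beta = 2`), enriching
high-impact mutations without altering counts. (An acceptance-probability
variant of the TSG rule was rejected because it halves TSG mutation counts,
which the intended weighting does not.) All CNN candidates follow the plain
signature, so neutral expectations are analytically known. Expression
(log-normal around 1000 for the ~90% expressed gene-cancer pairs, uniform
below 150 otherwise) and methylation (Beta-distributed probe values with
rare hypermethylated states) layers, plus noisy essential-gene benchmark
lists (80% sensitivity, 8% false positives), complete the cohort.

The default dimensions — 2 cancers x 200 samples, 300 genes of 250-500
codons — are the package's study conditions for its calibration and
recovery tests; the mutation rate is deliberately far above per-gene rates
in real exome cohorts, because a few hundred samples must reach the
>= 10/>= 10 group occupancy that tens of thousands of samples provide in
practice. What the generator does not emulate: genomic coordinates and
linkage (copy-number calls are independent across genes by default),
subclonal evolution, tumor purity, sequencing error, and indels. Passing
tests therefore demonstrate internal statistical correctness and
recoverability under the stated model, not robustness to those real-data
complications.

## Calibration and recovery (what the test suite computes)

With selection switched off (`sigma = 0`), the pooled dN/dS over the
deduplicated cohort must sit inside its 95% counting CI of 1, per-state
median normalized scores must lie within 0.05 of 0, and the fraction of
screened genes at p <= 0.05 must be near the nominal level. The pooled
dN/dS is evaluated before the cluster filter: the filter removes whole
multi-hit positions, which both biases the spectrum relative to a
pre-filter signature and overdisperses the remaining counts, so the
post-filter ratio is not the right quantity for a counting CI. With
selection on (`sigma = 0.8`, 15% essential genes), the screen's ranking is
scored against the ground-truth labels by ROC AUC, and the reverse
(`alternative = "greater"`) screen against the simulated tumor suppressors.

## Design choices left open by the method

* Cancer-type labels are opaque; any harmonisation (e.g. merging colon and
  rectal cohorts) happens upstream.
* Signatures default to estimation from all deduplicated substitutions;
  `signature_scope = "cluster_filtered"` restricts them to the
  cluster-filtered set for analyses that must be internally consistent with
  the filtered data.
* The simulated-null median is computed per gene and cancer (not pooled
  over genes), matching how the normalization is defined gene by gene.
* The normalization denominator uses the score bounds [0, 40], which
  guarantees values in [-1, 1] deterministically; a per-cancer maximal
  observed difference would make the scale data-dependent.
* "Hypermethylated in a sample" means any probe of the region exceeds
  beta 0.7 (strictly); mean-probe aggregation is available via
  `aggregate = "mean"`.
* The GSEA background defaults to the screened-gene universe; report
  thresholds (p <= 0.05, FDR <= 0.50 for hit lists, FDR <= 0.25 for
  enrichment) are reporting conventions, not computation parameters.

## Known limitations

Screen power is bounded by the group-size filter: genes under the strongest
purifying selection lose HeZD mutations and can fall below the >= 10
threshold, so the screened set under-represents exactly the strongest
targets. Per-cancer conclusions are out of reach at desk-scale cohort sizes;
all screens are pan-cohort. The single-impact-channel convention (one 0-40
score per substitution) does not model disagreement between impact
predictors.
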