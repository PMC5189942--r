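# hemisel

Hemizygosity-stratified detection of purifying selection in tumor genomes.

## The problem

Tumors depend on many essential genes, but purifying (negative) selection
against damaging somatic mutations is hard to observe: most essential genes
are haplosufficient, so a healthy second allele masks the fitness cost of a
damaging mutation. In hemizygously deleted (HeZD) regions no backup allele
exists, so damaging mutations in essential genes should be depleted there
relative to copy-number-neutral (CNN) samples. hemisel turns this idea into
a genome-wide screen for cancer genomics: it is aimed at researchers with a
somatic mutation table (MAF-reduced), gene-level copy-number calls
(GISTIC-thresholded), expression medians and per-substitution
functional-impact scores, who want per-gene evidence of purifying (or
positive) selection stratified by copy-number state.

## The statistics at its core

For each gene with at least 10 mutations in both groups, the screen compares
HeZD and CNN impact-score distributions with a one-sided Wilcoxon rank-sum
test (HeZD stochastically smaller = purifying selection), applies
Benjamini–Hochberg FDR control and ranks genes by ascending p. Impact
scores are phred-like on a 0–40 scale with silent = 0 and truncating = 40.
Two signature-aware statistics support the screen, both built on the
per-cancer 96-class trinucleotide mutational signature:

* signature-weighted dN/dS: with per-substitution prior probabilities
  `p_j` over a gene's `3L` possible substitutions,
  `S = 3L * Σ_{j silent} p_j`, `N = 3L − S`, and
  `dN/dS = (n/N)/(s/S)` for observed non-silent/silent counts `n`, `s`;
  values below 1 indicate purifying selection (one-sided Fisher's exact
  test on `[[n, s], [round(N), round(S)]]`);
* normalized impact scores: each observed score is centered on the
  signature-weighted null median of its gene and cancer and scaled to the
  maximal attainable difference, giving values in `[−1, 1]` where negative
  indicates purifying and positive indicates positive selection.

Mutations are deduplicated, positionally clustered mutations are removed by
a binomial test (`P(X ≥ k) ≤ 0.01`, `X ~ Binomial(m, 1/L)`), and only
expressed (gene, cancer) pairs (median expression strictly above 200) enter
the screen. Downstream modules provide Fisher-based gene-set enrichment,
ROC/AUC benchmarking against essential-gene lists, and secondary-event
analysis (homozygous deletions, promoter hypermethylation at beta > 0.7).
A synthetic-cohort generator with known ground truth supports calibration
and power analysis end to end. See `vignettes/hemisel-methods.Rmd` for the
full model description.

## Worked example

The deterministic worked fixture is a 2-cancer, 20-gene, 60-sample cohort
whose counts are hand-checkable (gene G001 carries exactly 10 HeZD and 10
CNN mutations):

```r
library(hemisel)
f <- worked_fixture()
fit <- hemisel(f$mutations, f$genome$models, f$genome$impacts,
               f$cn, f$expression)
print(fit)
#> Hemizygosity-stratified purifying-selection screen
#>   2 gene(s) screened (>= 10 mutations in HeZD and CNN), alternative = 'less'
#>   0 gene(s) at P <= 0.05; 1 at FDR <= 0.50
#>   Top-ranked genes:
#>  rank gene_id      p   fdr dnds_hezd dnds_cnn
#>     1    G001 0.0533 0.107     0.245    0.469
#>     2    G005 0.7108 0.711     0.188    0.190
```

Only G001 (10/10 mutations) and G005 (11/11) pass the group-size filter;
G002 (9 HeZD mutations) and the unexpressed G004 are excluded, and the
12-fold mutation cluster in G003 is removed by the binomial filter. G001's
HeZD mutations score lower than its CNN mutations (one-sided Wilcoxon
p = 0.053), and its HeZD dN/dS of 0.245 sits well below 1 — the pattern
expected under purifying selection. The co-mutation stratification shows the
comparison within samples lacking a non-silent mutation of the partner gene
G006:

```r
comutation_stratify(fit$groups, "G001", "G006", annotated = fit$annotated)
#>           stratum n_hezd n_cnn          p                                  note
#> 1 without_partner      5    10 0.04195804                                  <NA>
#> 2    with_partner      5     0         NA empty group within stratum; p omitted
```

`run_pipeline(f, "out/")` writes every stage table (screen, signatures,
normalized scores, qq data, benchmark AUCs, secondary events) plus a JSON
manifest with row counts and output checksums.

For cohort-scale use, `generate_cohort(simulation_config(seed = 1))` builds
a 400-sample synthetic cohort with known essential and tumor-suppressor
genes, and `hemisel()` on it recovers the simulated essential genes near the
top of the ranking.

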