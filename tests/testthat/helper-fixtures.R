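# Shared fixtures (memoised: the larger cohorts are generated once per run)
# and independent oracles used across test files.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, make) {
  if (is.null(.fixture_env[[key]])) assign(key, make(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# sigma = 0 cohort at the default study conditions (neutrality calibration)
neutral_cohort <- function() memo_fixture("neutral", function() {
  cfg <- simulation_config(seed = 11L, selection_strength = 0,
                           fraction_essential = 0, fraction_tsg = 0)
  generate_cohort(cfg, generate_genome(cfg))
})

# sigma = 0.8 cohort with essential and tsg genes (parameter recovery)
selection_cohort <- function() memo_fixture("selection", function() {
  cfg <- simulation_config(seed = 11L)
  generate_cohort(cfg, generate_genome(cfg))
})

fixture <- function() memo_fixture("worked", worked_fixture)

uniform_signature <- function()
  stats::setNames(rep(1 / 96, 96), context_class_labels())

# small fixed gene models used in unit tests
toy_gene <- function()
  gene_model("TOY", "GCTTACGGAGATTGCACC", "A", "G")

# oracle: classify a substitution through Biostrings' genetic code,
# independently of the package's classification path
oracle_classify <- function(cds, pos, alt) {
  gc <- Biostrings::GENETIC_CODE
  ci <- (pos - 1) %/% 3
  codon <- substr(cds, 3 * ci + 1, 3 * ci + 3)
  new <- codon
  substr(new, (pos - 1) %% 3 + 1, (pos - 1) %% 3 + 1) <- alt
  a1 <- gc[[codon]]; a2 <- gc[[new]]
  if (a1 == "*") { if (a2 == "*") "silent" else "truncating" }
  else if (a2 == "*") "truncating"
  else if (a1 == a2) "silent"
  else "missense"
}

# oracle: one-sided (enrichment) hypergeometric tail by explicit summation
# over a 2x2 table [[a, b], [c, d]] with rows query/rest, cols in/out
hyper_tail_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c       # in-set genes
  q <- a + b       # query size
  i <- seq(a, min(K, q))
  sum(choose(K, i) * choose(N - K, q - i)) / choose(N, q)
}

# oracle: AUC by explicit pair counting (ties between scores count 1/2)
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# oracle: exact binomial upper tail by explicit combinatorial summation
binom_tail_oracle <- function(k, m, pr) {
  j <- seq(k, m)
  sum(choose(m, j) * pr^j * (1 - pr)^(m - j))
}

# build an annotated-style mutation data.frame from vectors (unit tests)
make_annotated <- function(context_class, mclass = NULL, impact = NULL,
                           cancer_type = "CA", gene_id = "G1",
                           sample_id = NULL) {
  n <- length(context_class)
  data.frame(sample_id = if (is.null(sample_id)) sprintf("S%03d", seq_len(n))
             else sample_id,
             cancer_type = rep_len(cancer_type, n),
             gene_id = rep_len(gene_id, n),
             cds_pos = seq_len(n), ref = "C", alt = "A",
             variant_kind = "substitution",
             mclass = if (is.null(mclass)) rep("missense", n) else mclass,
             context_class = context_class,
             impact = if (is.null(impact)) rep(10, n) else impact)
}
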