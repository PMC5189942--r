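test_that("substitutions are classified by the genetic code", {
  g <- toy_gene()  # GCT TAC GGA GAT TGC ACC
  expect_equal(classify_substitution(g, 3, "C"), "silent")      # GCT->GCC Ala
  expect_equal(classify_substitution(g, 5, "T"), "missense")    # TAC->TTC Phe
  expect_equal(classify_substitution(g, 6, "A"), "truncating")  # TAC->TAA stop
  # vectorised call
  expect_equal(classify_substitution(g, c(3, 6), c("C", "A")),
               c("silent", "truncating"))
  expect_error(classify_substitution(g, 0, "A"), "out of range")
  expect_error(classify_substitution(g, 19, "A"), "out of range")
  expect_error(classify_substitution(g, 3, "T"), "equals the reference")
})

test_that("reference stop codons: stop-loss is truncating, stop-retaining silent", {
  g <- gene_model("ST", "ATGTAAGGC", "A", "C")
  expect_equal(classify_substitution(g, 4, "G"), "truncating")  # TAA->GAA
  expect_equal(classify_substitution(g, 6, "G"), "silent")      # TAA->TAG stop
})

test_that("indels are truncating when out of frame, missense-like otherwise", {
  expect_equal(classify_indel("deletion", 2), "truncating")
  expect_equal(classify_indel("insertion", 3), "missense")
  expect_equal(classify_indel("deletion", 6), "missense")
  expect_error(classify_indel("deletion", 0), "positive")
  expect_error(classify_indel("inversion", 2), "variant_kind")
})

test_that("trinucleotide context classes follow the pyrimidine convention", {
  g <- gene_model("CTX", "ACGACG", "A", "T")
  # 5'-A C G-3' with C>A  ->  "A[C>A]G"
  k <- context_class(g, 2, "A")
  expect_equal(context_class_labels()[k + 1], "A[C>A]G")
  # purine reference: 5'-T G C-3' with G>A reverse-complements to "G[C>T]A"
  g2 <- gene_model("CTX2", "ATGCAT", "C", "C")
  k2 <- context_class(g2, 3, "A")
  expect_equal(context_class_labels()[k2 + 1], "G[C>T]A")
  # flanks supply context at the CDS ends
  kend <- context_class(g, 1, "C")  # flank5 A, ref A -> purine, revcomp
  expect_true(kend %in% 0:95)
})

test_that("all (ref, alt, flank) combinations map onto exactly 96 classes, twice each", {
  combos <- expand.grid(ref = BASES <- c("A", "C", "G", "T"), alt = BASES,
                        up = BASES, down = BASES,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  cls <- hemisel:::.context_class_vec(combos$ref, combos$alt, combos$up,
                                      combos$down)
  expect_equal(sort(unique(cls)), 0:95)
  expect_true(all(table(cls) == 2))  # each class = one pyrimidine + one purine strand
})

test_that("context class is invariant under reverse-complement of the substitution", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(42)
  b <- c("A", "C", "G", "T")
  for (i in 1:50) {
    ref <- sample(b, 1); alt <- sample(setdiff(b, ref), 1)
    up <- sample(b, 1); down <- sample(b, 1)
    k1 <- hemisel:::.context_class_vec(ref, alt, up, down)
    k2 <- hemisel:::.context_class_vec(comp[[ref]], comp[[alt]],
                                       comp[[down]], comp[[up]])
    expect_identical(k1, k2)
  }
})

test_that("enumerating a gene yields 3L substitutions partitioned into classes", {
  set.seed(7)
  for (i in 1:3) {
    cfg <- simulation_config(seed = 30L + i, n_genes = 1L,
                             cds_codons = c(20L, 40L))
    gm <- generate_genome(cfg)$models[[1]]
    en <- enumerate_substitutions(gm)
    expect_equal(nrow(en), 3L * cds_length(gm))
    expect_equal(sum(table(en$mclass)), 3L * cds_length(gm))
    # independent classification oracle on a random subset
    idx <- sample(nrow(en), 40)
    orc <- mapply(oracle_classify, pos = en$cds_pos[idx], alt = en$alt[idx],
                  MoreArgs = list(cds = gm$cds))
    expect_equal(en$mclass[idx], unname(orc))
  }
})

test_that("annotation attaches class, context and conventional impact scores", {
  f <- fixture()
  g <- f$genome$models
  ann <- annotate_mutations(f$mutations, g, f$genome$impacts)
  expect_equal(nrow(ann), nrow(f$mutations))  # fixture has no droppable rows
  expect_true(all(ann$impact[ann$mclass == "silent"] == 0))
  expect_true(all(ann$impact[ann$mclass == "truncating"] == 40))
  mis <- which(ann$mclass == "missense" & ann$variant_kind == "substitution")
  i <- mis[1]
  mat <- f$genome$impacts[[ann$gene_id[i]]]
  expect_equal(ann$impact[i],
               unname(mat[match(ann$alt[i], c("A", "C", "G", "T")),
                          ann$cds_pos[i]]))

  # dropped + kept == input, with diagnostics
  muts <- f$mutations
  muts$gene_id[1] <- "UNKNOWN"
  muts$cds_pos[2] <- NA
  muts$ref[3] <- setdiff(c("A", "C", "G", "T"),
                         c(muts$ref[3], muts$alt[3]))[1]
  expect_message(ann2 <- annotate_mutations(muts, g, f$genome$impacts),
                 "dropped")
  expect_equal(nrow(ann2) + length(attr(ann2, "diagnostics")), nrow(muts))
  expect_length(attr(ann2, "diagnostics"), 3)

  # in-frame and frameshift indels
  ind <- data.frame(sample_id = "S1", cancer_type = "CA", gene_id = "G001",
                    cds_pos = c(5L, 8L),
                    ref = c("ACT", "AC"), alt = c("-", "-"),
                    variant_kind = "deletion")
  anni <- annotate_mutations(ind, g, f$genome$impacts)
  expect_equal(anni$mclass, c("missense", "truncating"))
  expect_equal(anni$impact, c(20, 40))
  expect_true(all(is.na(anni$context_class)))
})
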