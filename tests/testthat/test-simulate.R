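test_that("the generator is deterministic and obeys the 3L and 0/40 laws", {
  cfg <- simulation_config(seed = 51L, n_genes = 10L, n_cancers = 2L,
                           samples_per_cancer = 20L,
                           cds_codons = c(100L, 100L), mutation_rate = 0.3)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$models, g2$models)
  expect_identical(g1$impacts, g2$impacts)

  # 3L law: exactly 3 * 300 scored substitutions per 100-codon gene
  expect_true(all(vapply(unclass(g1$impacts),
                         function(m) sum(!is.na(m)), numeric(1)) == 900))
  for (g in names(g1$models)) {
    en <- g1$enum[[g]]
    sc <- g1$impacts[[g]][cbind(match(en$alt, c("A", "C", "G", "T")),
                                en$cds_pos)]
    expect_true(all(sc[en$mclass == "silent"] == 0))
    expect_true(all(sc[en$mclass == "truncating"] == 40))
    expect_true(all(sc >= 0 & sc <= 40))
  }

  c1 <- generate_cohort(cfg, g1)
  c2 <- generate_cohort(cfg, g1)
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$cn, c2$cn)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$methylation, c2$methylation)
  expect_true(all(c1$cn %in% -2:2))
  expect_true(all(c1$expression >= 0))
  expect_true(all(c1$methylation$beta >= 0 & c1$methylation$beta <= 1))
  # generated alleles agree with the gene models
  ann <- annotate_mutations(c1$mutations, g1$models, g1$impacts)
  expect_equal(nrow(ann), nrow(c1$mutations))
})

test_that("with no selection the mutation spectrum matches the signature", {
  cfg <- simulation_config(seed = 5L, n_genes = 300L, n_cancers = 1L,
                           mutation_rate = 0.9, selection_strength = 0,
                           fraction_essential = 0, fraction_tsg = 0)
  g <- generate_genome(cfg)
  coh <- generate_cohort(cfg, g)
  ann <- annotate_mutations(coh$mutations, g$models, g$impacts)
  expect_gt(nrow(ann), 50000)
  emp <- tabulate(ann$context_class + 1L, 96)
  emp <- emp / sum(emp)
  tv <- sum(abs(emp - coh$signatures[[1]])) / 2
  expect_lt(tv, 0.02)
})

test_that("purifying selection strength produces a monotone dose-response", {
  med_ess_hezd <- vapply(c(0, 0.4, 0.8), function(sigma) {
    cfg <- simulation_config(seed = 61L, n_genes = 80L,
                             samples_per_cancer = 150L,
                             fraction_essential = 0.3, fraction_tsg = 0,
                             selection_strength = sigma)
    g <- generate_genome(cfg)
    coh <- generate_cohort(cfg, g)
    fit <- suppressWarnings(
      hemisel(coh$mutations, g$models, g$impacts, coh$cn, coh$expression))
    ess <- coh$truth$gene_id[coh$truth$role == "essential"]
    rows <- fit$groups$gene_id %in% ess & fit$groups$cn_state == "HeZD"
    stats::median(fit$groups$normalized[rows])
  }, numeric(1))
  expect_true(all(diff(med_ess_hezd) < 0))
  expect_lt(med_ess_hezd[3], med_ess_hezd[1] - 0.1)
})

test_that("at sigma = 1 no truncating mutation survives in essential HeZD cells", {
  cfg <- simulation_config(seed = 71L, n_genes = 40L,
                           samples_per_cancer = 100L,
                           fraction_essential = 0.5, fraction_tsg = 0,
                           selection_strength = 1)
  g <- generate_genome(cfg)
  coh <- generate_cohort(cfg, g)
  ann <- annotate_mutations(coh$mutations, g$models, g$impacts)
  st <- coh$cn[cbind(match(ann$gene_id, rownames(coh$cn)),
                     match(ann$sample_id, colnames(coh$cn)))]
  ess <- coh$truth$gene_id[coh$truth$role == "essential"]
  hezd_ess <- ann$gene_id %in% ess & st == -1L
  expect_gt(sum(hezd_ess), 50)
  expect_equal(sum(ann$mclass[hezd_ess] == "truncating"), 0L)
  # neutral genes in the same cohort still carry truncating HeZD mutations
  neut <- ann$gene_id %in% coh$truth$gene_id[coh$truth$role == "neutral"]
  expect_gt(sum(ann$mclass[neut & st == -1L] == "truncating"), 0L)
})

test_that("the worked fixture has its documented hand-checkable structure", {
  f <- fixture()
  m <- f$mutations
  st <- f$cn[cbind(match(m$gene_id, rownames(f$cn)),
                   match(m$sample_id, colnames(f$cn)))]
  expect_equal(sum(m$gene_id == "G001" & st == -1L), 10L)
  expect_equal(sum(m$gene_id == "G001" & st == 0L), 10L)
  expect_equal(sum(m$gene_id == "G002" & st == -1L), 9L)
  expect_equal(sum(m$gene_id == "G005" & st == -1L), 11L)
  expect_equal(sum(m$gene_id == "G003" & m$cds_pos == 9L), 12L)
  expect_equal(f$expression["G004", "CA"], 100)
  expect_equal(unname(f$expression["G007", ]), c(200, 200))
  expect_identical(worked_fixture()$mutations, m)  # deterministic
})
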