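test_that("rank-sum test matches wilcox.test where the latter is exact", {
  set.seed(1)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:8, 1))
    y <- stats::rnorm(sample(3:8, 1))
    for (alt in c("less", "greater", "two.sided")) {
      ours <- rank_sum_test(x, y, alt)
      ref <- stats::wilcox.test(x, y, alternative = alt, exact = TRUE)
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
      expect_true(ours$exact)
    }
  }
})

test_that("rank-sum normal approximation matches wilcox.test with tie correction", {
  set.seed(2)
  for (i in 1:10) {
    x <- sample(0:5, 40, replace = TRUE)   # heavy ties
    y <- sample(0:5, 60, replace = TRUE)
    for (alt in c("less", "greater", "two.sided")) {
      ours <- rank_sum_test(x, y, alt)
      ref <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = alt, correct = TRUE))
      expect_false(ours$exact)
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("rank-sum test stays exact under ties via permutation enumeration", {
  r <- rank_sum_test(c(0, 0, 5), c(30, 35, 40), "less")
  expect_true(r$exact)
  expect_identical(r$p.value, 1 / choose(6, 3))
  # identical multisets: p >= 0.5 (16 of the 20 assignments are <= observed)
  expect_equal(rank_sum_test(c(1, 1, 2), c(1, 1, 2), "less")$p.value, 0.8,
               tolerance = 1e-12)
})

test_that("clustered positions are flagged by the binomial tail and removed", {
  cfg <- simulation_config(seed = 91L, n_genes = 1L,
                           cds_codons = c(1000L, 1000L))
  gnm <- generate_genome(cfg)
  g <- gnm$models[[1]]
  # 30 mutations, one position hit 4 times, the rest distinct
  pos <- c(rep(9L, 4L), seq(12L, by = 3L, length.out = 26L))
  ann <- make_annotated(context_class = rep(0L, 30), gene_id = g$gene_id)
  ann$cds_pos <- pos
  res <- remove_clustered(ann, stats::setNames(list(g), g$gene_id))
  expect_equal(nrow(res$flags), 1L)
  expect_equal(res$flags$k, 4L)
  expect_true(res$flags$flagged)
  expect_equal(res$flags$p, binom_tail_oracle(4, 30, 1 / 3000),
               tolerance = 1e-12)
  expect_lt(res$flags$p, 1e-9)
  expect_equal(nrow(res$mutations), 26L)
  expect_false(9L %in% res$mutations$cds_pos)

  # all positions distinct: nothing removed; a single mutation: nothing removed
  ann2 <- ann[-(1:3), ]
  res2 <- remove_clustered(ann2, stats::setNames(list(g), g$gene_id))
  expect_equal(nrow(res2$mutations), nrow(ann2))
  expect_equal(nrow(res2$flags), 0L)
  res3 <- remove_clustered(ann[1, ], stats::setNames(list(g), g$gene_id))
  expect_equal(nrow(res3$mutations), 1L)
})

test_that("cluster removal is a single pass fully determined by its flags", {
  coh <- neutral_cohort()
  g <- coh$genome
  ann <- suppressMessages(
    annotate_mutations(deduplicate_mutations(coh$mutations[1:4000, ]),
                       g$models, g$impacts))
  r1 <- remove_clustered(ann, g$models)
  # removals are exactly the mutations at flagged positions
  fl <- r1$flags[r1$flags$flagged, ]
  key <- paste(ann$gene_id, ann$cds_pos)
  expect_equal(nrow(r1$mutations),
               nrow(ann) - sum(key %in% paste(fl$gene_id, fl$cds_pos)))
  expect_false(any(paste(r1$mutations$gene_id, r1$mutations$cds_pos) %in%
                     paste(fl$gene_id, fl$cds_pos)))
  # flags are reproducible and every flagged position obeys the threshold
  r1b <- remove_clustered(ann, g$models)
  expect_identical(r1$flags, r1b$flags)
  expect_true(all(fl$p <= 0.01))
  expect_true(all(r1$flags$p[!r1$flags$flagged] > 0.01))
})

test_that("expected site counts conserve N + S == 3L and match enumeration", {
  g <- toy_gene()
  en <- enumerate_substitutions(g)
  L3 <- nrow(en)

  # uniform signature: N/S equals the non-silent/silent enumeration ratio
  es <- expected_sites_analytic(g, uniform_signature(), enum = en)
  n_sil <- sum(vapply(seq_len(L3), function(j)
    oracle_classify(g$cds, en$cds_pos[j], en$alt[j]), character(1)) == "silent")
  expect_equal(es$S, L3 * n_sil / L3)
  expect_equal(es$N / es$S, (L3 - n_sil) / n_sil)
  expect_identical(es$N + es$S, as.numeric(L3))

  # exact conservation for arbitrary signatures
  set.seed(5)
  for (i in 1:10) {
    sig <- stats::rgamma(96, 0.3); sig <- sig / sum(sig)
    es <- expected_sites_analytic(g, sig, enum = en)
    expect_identical(es$N + es$S, as.numeric(L3))
  }

  # a gene with no silent substitution forces S == 0
  gw <- gene_model("W", "TGGTGGTGG", "A", "A")
  expect_equal(expected_sites_analytic(gw, uniform_signature())$S, 0)

  # a signature confined to silent-only contexts forces N == 0
  ga <- gene_model("SIL", "GCTGCTGCT", "A", "G")
  ena <- enumerate_substitutions(ga)
  sil_only <- setdiff(ena$context_class[ena$mclass == "silent"],
                      ena$context_class[ena$mclass != "silent"])
  expect_gt(length(sil_only), 0)
  sig <- rep(0, 96); sig[sil_only[1] + 1L] <- 1
  expect_equal(expected_sites_analytic(ga, sig)$N, 0)

  expect_error(expected_sites_analytic(g, rep(0, 96)), "zero weight")
})

test_that("sampled site counts are reproducible and converge to analytic", {
  g <- toy_gene()
  sig <- uniform_signature()
  s1 <- expected_sites_sampled(g, sig, n_draws = 1e4, seed = 7L)
  s2 <- expected_sites_sampled(g, sig, n_draws = 1e4, seed = 7L)
  expect_identical(s1, s2)
  an <- expected_sites_analytic(g, sig)
  s3 <- expected_sites_sampled(g, sig, n_draws = 2e5, seed = 8L)
  expect_lt(abs(s3$N - an$N) / an$N, 0.02)
  expect_identical(s3$N + s3$S, an$N + an$S)
})

test_that("dN/dS is the per-site non-silent/silent ratio with a one-sided Fisher test", {
  g <- toy_gene()
  en <- enumerate_substitutions(g)
  sig <- uniform_signature()
  es <- expected_sites_analytic(g, sig, enum = en)

  # observed counts proportional to expected sites give dN/dS == 1
  sil <- en[en$mclass == "silent", ][1, ]
  non <- en[en$mclass != "silent", ][1, ]
  mk <- function(n, s) {
    idx <- c(rep(1, n), rep(2, s))
    src <- rbind(non, sil)[idx, ]
    a <- make_annotated(context_class = src$context_class,
                        mclass = src$mclass, gene_id = g$gene_id)
    a$cds_pos <- src$cds_pos
    a
  }
  ratio <- es$N / es$S
  r <- dnds(mk(round(4 * ratio), 4), g, sig, enum = en)
  expect_equal(r$dnds, (round(4 * ratio) / es$N) / (4 / es$S))
  expect_equal(r$dnds, 1, tolerance = 0.05)  # rounding of 4*ratio only

  # boundary: no non-silent mutations
  r0 <- dnds(mk(0, 10), g, sig, enum = en)
  expect_equal(r0$dnds, 0)
  expect_lt(r0$fisher_p, 1)
  expect_equal(r0$fisher_p,
               stats::fisher.test(matrix(c(0, 10, round(es$N), round(es$S)),
                                         2, byrow = TRUE),
                                  alternative = "less")$p.value)

  # undefined ratio when s == 0
  ru <- dnds(mk(5, 0), g, sig, enum = en)
  expect_true(is.na(ru$dnds))
  expect_match(ru$note, "undefined")
})

test_that("the null score distribution has the signature-weighted median", {
  f <- fixture()
  g <- f$genome$models[["G001"]]
  imp <- f$genome$impacts

  nd <- null_score_distribution(g, uniform_signature(), imp)
  # uniform weights: lower weighted median equals the order-statistic median
  sc <- sort(nd$scores)
  expect_equal(nd$median_sim, sc[ceiling(length(sc) / 2)])

  set.seed(9)
  sig <- stats::rgamma(96, 0.5); sig <- sig / sum(sig)
  nda <- null_score_distribution(g, sig, imp)
  # brute-force weighted median oracle on the enumerated scores
  en <- enumerate_substitutions(g)
  w <- sig[en$context_class + 1L]; w <- w / sum(w)
  o <- order(nda$scores)
  oracle <- nda$scores[o][which(cumsum(w[o]) >= 0.5)[1]]
  expect_equal(nda$median_sim, oracle)

  nds <- null_score_distribution(g, sig, imp, mode = "sampled",
                                 n_draws = 2e5, seed = 10L)
  expect_lt(abs(nds$median_sim - nda$median_sim), 0.5)
})

test_that("score normalization is bounded, linear and strictly increasing", {
  expect_identical(normalize_score(20, 20), 0)
  expect_identical(normalize_score(40, 20), 1)
  expect_identical(normalize_score(0, 20), -1)
  expect_equal(normalize_score(c(30, 10), 20), c(0.5, -0.5))
  # strictly increasing in the observed score
  v <- normalize_score(seq(0, 40, by = 0.5), 13.7)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= -1 & v <= 1))
  # degenerate span collapses to 0
  expect_identical(suppressWarnings(normalize_score(40, 40)), 0)
  expect_error(normalize_score(41, 20), "impact_obs")
  expect_error(normalize_score(10, 45), "median_sim")
})

test_that("one-sample deviation test is a signed-rank test against zero", {
  expect_lt(test_normalized_deviation(c(-0.5, -0.4, -0.3, -0.2, -0.1, -0.6),
                                      "less"), 0.02)
  p <- test_normalized_deviation(c(-0.3, 0.3, -0.2, 0.2, -0.1, 0.1), "less")
  expect_gt(p, 0.3)

  # exact enumeration oracle over all 2^4 sign assignments
  x <- c(-0.3, -0.2, -0.1, 0.1)
  v_obs <- sum(rank(abs(x))[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 4))
  v_all <- as.matrix(signs) %*% rank(abs(x))
  expect_equal(test_normalized_deviation(x, "less"), mean(v_all <= v_obs))

  expect_warning(p0 <- test_normalized_deviation(c(0, 0, 0), "less"),
                 "degenerate")
  expect_equal(p0, 1)
})
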