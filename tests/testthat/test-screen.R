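test_that("expression filter is strict at the threshold", {
  m <- matrix(c(201, 200, 0, 1000), nrow = 2,
              dimnames = list(c("G1", "G2"), c("CA", "CB")))
  e <- expression_filter(m)
  expect_true(e["G1", "CA"])
  expect_false(e["G2", "CA"])   # exactly 200 is not expressed
  expect_false(e["G1", "CB"])
  expect_true(expression_filter(m, threshold = 199)["G2", "CA"])
})

test_that("group assembly assigns states and applies the filters", {
  ann <- make_annotated(context_class = rep(0L, 6),
                        gene_id = rep(c("G1", "G2"), each = 3),
                        sample_id = rep(c("S1", "S2", "S3"), 2))
  cn <- matrix(c(-1L, 0L, -2L,    # G1 across S1..S3
                 1L, 2L, 0L),     # G2
               nrow = 2, byrow = TRUE,
               dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
  expressed <- matrix(TRUE, nrow = 2, ncol = 1,
                      dimnames = list(c("G1", "G2"), "CA"))
  g <- assemble_groups(ann, cn, expressed)
  expect_equal(nrow(g), 5L)  # the HoZD (G1, S3) mutation is excluded
  expect_equal(as.character(g$cn_state[g$gene_id == "G1"]), c("HeZD", "CNN"))
  expect_equal(as.character(g$cn_state[g$gene_id == "G2"]),
               c("Amp", "Amp", "CNN"))

  # unexpressed (gene, cancer) pairs are excluded
  expressed["G2", "CA"] <- FALSE
  g2 <- assemble_groups(ann, cn, expressed)
  expect_false("G2" %in% g2$gene_id)

  # missing expression entry counts as unexpressed, with a warning
  expect_warning(g3 <- assemble_groups(ann, cn,
                                       expressed["G1", , drop = FALSE]),
                 "unexpressed")
  expect_false("G2" %in% g3$gene_id)

  # sample absent from the copy-number matrix -> diagnostic, excluded
  g4 <- assemble_groups(ann, cn[, 1:2], expressed)
  expect_match(attr(g4, "diagnostics"), "absent", all = FALSE)
})

test_that("the screen tests HeZD < CNN with BH FDR and deterministic ranks", {
  mk <- function(gene, state, impact)
    data.frame(sample_id = paste0("S", seq_along(impact)),
               cancer_type = "CA", gene_id = gene,
               cds_pos = seq_along(impact), ref = "C", alt = "A",
               variant_kind = "substitution", mclass = "missense",
               context_class = 0L, impact = impact,
               cn_state = factor(state, levels = c("HeZD", "CNN", "Amp")))
  groups <- rbind(mk("GA", "HeZD", c(0, 0, 5)), mk("GA", "CNN", c(30, 35, 40)),
                  mk("GB", "HeZD", c(1, 2, 3)), mk("GB", "CNN", c(1, 2, 3)))
  s <- run_screen(groups, min_mut = 3)
  expect_equal(s$p[s$gene_id == "GA"], 0.05)
  expect_gte(s$p[s$gene_id == "GB"], 0.5)
  expect_equal(sort(s$rank), 1:2)
  expect_equal(s$gene_id[s$rank == 1], "GA")
  expect_equal(s$fdr, stats::p.adjust(s$p, "BH"))
  expect_true(all(s$fdr >= s$p))

  # min_mut boundary
  expect_error(run_screen(groups, min_mut = 4), "no gene passes")

  # BH equals its brute-force definition on the screen output
  set.seed(13)
  pvec <- sort(s$p)
  m <- length(pvec)
  brute <- vapply(seq_len(m), function(i)
    min(1, min(pvec[i:m] * m / (i:m))), numeric(1))
  expect_equal(sort(s$fdr), brute)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(21)
  for (i in 1:10) {
    p <- stats::runif(sample(3:30, 1))
    o <- order(p)
    m <- length(p)
    brute <- numeric(m)
    for (k in seq_len(m))
      brute[o[k]] <- min(1, min(p[o[k:m]] * m / (k:m)))
    expect_equal(stats::p.adjust(p, "BH"), brute)
  }
})

test_that("qq data pairs sorted p-values with uniform quantiles", {
  q <- qq_data(c(0.3, 0.1, 0.4, 0.2))
  expect_equal(q$expected, c(0.2, 0.4, 0.6, 0.8))
  expect_equal(q$observed, c(0.1, 0.2, 0.3, 0.4))
  q1 <- qq_data(0.7)
  expect_equal(q1$expected, 0.5)
  qg <- qq_data(c(0.5, 0.1, 0.9), group = c("a", "b", "a"))
  expect_equal(qg$expected[qg$group == "a"], c(1, 2) / 3)
})

test_that("rank/dN-dS correlation reproduces Spearman's coefficient", {
  s <- data.frame(gene_id = paste0("G", 1:5), rank = 1:5,
                  dnds_hezd = c(0.2, 0.5, 0.6, 1.0, 1.3),
                  dnds_cnn = c(1.3, 1.0, 0.6, 0.5, 0.2))
  r <- rank_dnds_correlation(s)
  expect_equal(r$rho[r$state == "HeZD"], 1)
  expect_equal(r$rho[r$state == "CNN"], -1)

  s2 <- s
  s2$dnds_hezd <- c(0.9, 0.3, 1.4, 0.7, 1.1)
  rho <- rank_dnds_correlation(s2)$rho[1]
  d <- rank(s2$rank) - rank(s2$dnds_hezd)
  expect_equal(rho, 1 - 6 * sum(d^2) / (5 * 24))  # direct Spearman formula

  s3 <- s
  s3$dnds_hezd <- rep(1, 5)
  expect_error(rank_dnds_correlation(s3), "all-tied")
})

test_that("co-mutation stratification labels samples by partner status", {
  f <- fixture()
  fit <- suppressWarnings(
    hemisel(f$mutations, f$genome$models, f$genome$impacts, f$cn,
            f$expression))
  cs <- comutation_stratify(fit$groups, "G001", "G006",
                            annotated = fit$annotated)
  # partner G006 has non-silent mutations in CA_S001..005, all HeZD for G001
  expect_equal(cs$n_hezd[cs$stratum == "with_partner"], 5L)
  expect_equal(cs$n_cnn[cs$stratum == "with_partner"], 0L)
  expect_equal(cs$n_hezd[cs$stratum == "without_partner"], 5L)
  expect_equal(cs$n_cnn[cs$stratum == "without_partner"], 10L)
  expect_true(is.na(cs$p[cs$stratum == "with_partner"]))
  expect_match(cs$note[cs$stratum == "with_partner"], "empty")

  # no sample carries partner mutations -> "+" stratum empty
  cs2 <- comutation_stratify(fit$groups, "G001", "G019",
                             annotated = fit$annotated)
  expect_equal(cs2$n_hezd[cs2$stratum == "with_partner"], 0L)
})

test_that("the fitted screen object carries methods and consistent fields", {
  f <- fixture()
  fit <- suppressWarnings(
    hemisel(f$mutations, f$genome$models, f$genome$impacts, f$cn,
            f$expression))
  expect_s3_class(fit, "hemisel")
  s <- as.data.frame(fit)
  expect_true(all(c("gene_id", "p", "fdr", "rank", "dnds_hezd",
                    "prop_hezd_samples") %in% names(s)))
  expect_equal(sort(s$rank), seq_len(nrow(s)))
  expect_true(all(s$n_hezd_mut >= 10 & s$n_cnn_mut >= 10))
  expect_equal(s$prop_hezd_samples,
               unname(rowMeans(f$cn == -1L)[s$gene_id]))
  expect_output(print(fit), "purifying-selection screen")
  expect_output(print(summary(fit)), "Screened genes")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
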