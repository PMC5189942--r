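# The genome-wide copy-number-stratified screen: expression filter, group
# assembly, per-gene one-sided Wilcoxon tests with BH FDR, and the hemisel()
# fitting function tying all stages together.

#' Expression filter (strictly greater than the threshold)
#'
#' A gene counts as expressed in a cancer type when its median expression
#' value is strictly greater than `threshold` (default 200, RSEM-like
#' units).
#'
#' @param expression Gene-by-cancer matrix of median expression values.
#' @param threshold Strict lower bound (default 200).
#' @return Logical gene-by-cancer matrix of expressed flags.
#' @export
expression_filter <- function(expression, threshold = 200) {
  expression > threshold
}

#' Assign copy-number states to mutations and apply the expression filter
#'
#' Each mutation receives the copy-number state of its (gene, sample) cell:
#' -1 = HeZD, 0 = CNN, +1/+2 = Amp. Mutations in unexpressed (gene, cancer)
#' pairs are excluded (missing expression entries count as unexpressed, with
#' a warning), as are mutations in homozygously deleted cells (no allele
#' left to select on) and mutations whose gene or sample is absent from the
#' copy-number matrix (with diagnostics).
#'
#' @param annotated Annotated (and typically cluster-filtered) mutation
#'   table.
#' @param cn Gene-by-sample copy-number call matrix.
#' @param expressed Logical gene-by-cancer matrix (see
#'   [expression_filter()]).
#' @return The annotated table restricted to screenable mutations, with an
#'   added `cn_state` factor (`HeZD`/`CNN`/`Amp`); diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
assemble_groups <- function(annotated, cn, expressed) {
  x <- annotated
  diags <- character(0)
  in_gene <- x$gene_id %in% rownames(cn)
  in_samp <- x$sample_id %in% colnames(cn)
  if (any(!in_gene))
    diags <- c(diags, sprintf("row %d: gene '%s' absent from copy-number matrix",
                              which(!in_gene), x$gene_id[!in_gene]))
  if (any(!in_samp))
    diags <- c(diags, sprintf("row %d: sample '%s' absent from copy-number matrix",
                              which(!in_samp), x$sample_id[!in_samp]))
  keep <- in_gene & in_samp
  x <- x[keep, , drop = FALSE]
  state <- cn[cbind(match(x$gene_id, rownames(cn)),
                    match(x$sample_id, colnames(cn)))]
  eg <- match(x$gene_id, rownames(expressed))
  ec <- match(x$cancer_type, colnames(expressed))
  ok <- rep(FALSE, nrow(x))
  have <- !is.na(eg) & !is.na(ec)
  ok[have] <- expressed[cbind(eg[have], ec[have])]
  if (any(!have))
    warning(sum(!have),
            " mutation(s) in (gene, cancer) pairs without expression data; treated as unexpressed")
  keep2 <- ok & state != -2L
  x <- x[keep2, , drop = FALSE]
  state <- state[keep2]
  x$cn_state <- factor(ifelse(state == -1L, "HeZD",
                              ifelse(state == 0L, "CNN", "Amp")),
                       levels = c("HeZD", "CNN", "Amp"))
  rownames(x) <- NULL
  attr(x, "diagnostics") <- diags
  x
}

.state_split <- function(groups, gene) {
  g <- groups[groups$gene_id == gene, , drop = FALSE]
  split(g, g$cn_state)
}

#' Run the per-gene purifying-selection screen
#'
#' For every gene with at least `min_mut` mutations in both the HeZD and the
#' CNN group, the impact scores of the two groups are compared with a
#' one-sided Wilcoxon rank-sum test (`alternative = "less"`: lower impact in
#' HeZD indicates purifying selection; `"greater"` targets positive
#' selection of the remaining allele, as in tumor suppressors;
#' `"two.sided"` screens for either). FDR values use Benjamini-Hochberg over
#' all screened genes; ranks follow ascending p-values with lexicographic
#' gene-id tie-breaks (rank 1 = most significant).
#'
#' @param groups Output of [assemble_groups()] (optionally carrying a
#'   `normalized` score column).
#' @param min_mut Minimal mutation count required in each of the HeZD and
#'   CNN groups (default 10).
#' @param alternative Test direction (default `"less"`).
#' @return Data frame with one row per screened gene: group sizes, `p`,
#'   `fdr`, `rank` and per-state median impact (and median normalized score
#'   when available), sorted by rank.
#' @export
run_screen <- function(groups, min_mut = 10, alternative = "less") {
  med <- function(v) if (length(v)) stats::median(v) else NA_real_
  has_norm <- "normalized" %in% names(groups)
  rows <- lapply(split(groups, groups$gene_id), function(g) {
    hz <- g[g$cn_state == "HeZD", , drop = FALSE]
    cnn <- g[g$cn_state == "CNN", , drop = FALSE]
    amp <- g[g$cn_state == "Amp", , drop = FALSE]
    if (nrow(hz) < min_mut || nrow(cnn) < min_mut) return(NULL)
    p <- rank_sum_test(hz$impact, cnn$impact, alternative)$p.value
    out <- data.frame(gene_id = g$gene_id[1],
                      n_hezd_mut = nrow(hz), n_cnn_mut = nrow(cnn),
                      n_amp_mut = nrow(amp), p = p,
                      median_impact_hezd = med(hz$impact),
                      median_impact_cnn = med(cnn$impact),
                      median_impact_amp = med(amp$impact))
    if (has_norm) {
      out$median_norm_hezd <- med(hz$normalized)
      out$median_norm_cnn <- med(cnn$normalized)
      out$median_norm_amp <- med(amp$normalized)
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no gene passes the ", min_mut, "/", min_mut,
                          " mutation filter")
  df <- do.call(rbind, rows)
  df$fdr <- stats::p.adjust(df$p, method = "BH")
  o <- order(df$p, df$gene_id)
  df$rank <- integer(nrow(df))
  df$rank[o] <- seq_len(nrow(df))
  df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Quantile-quantile data for screen p-values
#'
#' For each group, sorted observed p-values are paired with uniform expected
#' quantiles `i / (n + 1)`; plotting `-log10` of both gives the usual
#' qq-plot, e.g. to contrast expressed (screened) genes with the
#' non-expressed negative controls.
#'
#' @param p Numeric vector of p-values.
#' @param group Optional grouping vector (same length as `p`).
#' @return Data frame with columns `group`, `expected`, `observed`.
#' @export
qq_data <- function(p, group = NULL) {
  if (is.null(group)) group <- rep("all", length(p))
  stopifnot(length(group) == length(p))
  out <- lapply(split(p, group), function(v) {
    v <- sort(v)
    data.frame(expected = seq_along(v) / (length(v) + 1), observed = v)
  })
  res <- do.call(rbind, Map(function(g, d) cbind(group = g, d),
                            names(out), out))
  rownames(res) <- NULL
  res
}

#' Spearman correlation of screen rank with dN/dS
#'
#' Highly ranked genes (strong purifying-selection signal) are expected to
#' show HeZD dN/dS below 1; genes at the opposite end, above 1. This
#' correlates the purifying-selection rank with the per-state dN/dS values
#' of the screen table.
#'
#' @param screen Screen table carrying `rank`, `dnds_hezd`, `dnds_cnn`
#'   columns (see [hemisel()]).
#' @return Data frame with columns `state`, `rho`, `p`, `n`.
#' @export
rank_dnds_correlation <- function(screen) {
  one <- function(state, col) {
    ok <- !is.na(screen[[col]])
    if (sum(ok) < 3L)
      stop("fewer than 3 genes with defined dN/dS in state ", state)
    if (length(unique(screen[[col]][ok])) < 2L ||
        length(unique(screen$rank[ok])) < 2L)
      stop("all-tied input: Spearman correlation undefined for state ", state)
    ct <- suppressWarnings(
      stats::cor.test(screen$rank[ok], screen[[col]][ok],
                      method = "spearman", exact = FALSE))
    data.frame(state = state, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  }
  res <- rbind(one("HeZD", "dnds_hezd"), one("CNN", "dnds_cnn"))
  rownames(res) <- NULL
  res
}

#' Stratify a gene's screen comparison by co-mutation of a partner gene
#'
#' Splits the gene's mutations by whether the carrying sample also harbours
#' at least one non-silent mutation of `partner_gene` (e.g. a co-deleted
#' tumor suppressor), then repeats the HeZD-vs-CNN comparison within each
#' stratum. Used to exclude that a purifying-selection signal merely tracks
#' partner loss-of-function.
#'
#' @param groups Output of [assemble_groups()].
#' @param gene_id Gene under study.
#' @param partner_gene Partner gene whose non-silent mutations define the
#'   strata.
#' @param annotated Annotated table used to look up partner mutations
#'   (defaults to `groups`, i.e. the screened universe).
#' @param alternative Test direction (default `"less"`).
#' @return Data frame with one row per stratum (`without_partner`,
#'   `with_partner`): group sizes and the Wilcoxon p (`NA` with a note when
#'   a stratum side is empty).
#' @export
comutation_stratify <- function(groups, gene_id, partner_gene,
                                annotated = groups, alternative = "less") {
  partner_samples <- unique(annotated$sample_id[
    annotated$gene_id == partner_gene & annotated$mclass != "silent"])
  g <- groups[groups$gene_id == gene_id, , drop = FALSE]
  g$with_partner <- g$sample_id %in% partner_samples
  one <- function(d, label) {
    hz <- d$impact[d$cn_state == "HeZD"]
    cnn <- d$impact[d$cn_state == "CNN"]
    p <- NA_real_
    note <- NA_character_
    if (!length(hz) || !length(cnn))
      note <- "empty group within stratum; p omitted"
    else
      p <- rank_sum_test(hz, cnn, alternative)$p.value
    data.frame(stratum = label, n_hezd = length(hz), n_cnn = length(cnn),
               p = p, note = note)
  }
  res <- rbind(one(g[!g$with_partner, , drop = FALSE], "without_partner"),
               one(g[g$with_partner, , drop = FALSE], "with_partner"))
  rownames(res) <- NULL
  res
}

#' Fit the hemizygosity-stratified purifying-selection screen
#'
#' Runs the full analysis on a cohort: deduplication, annotation
#' (class/context/impact), removal of positionally clustered mutations,
#' per-cancer 96-class signature estimation, expression filtering and
#' copy-number state assignment, per-mutation normalized impact scores
#' against the signature-simulated null, the per-gene one-sided Wilcoxon
#' screen with BH FDR and ranks, and per-gene dN/dS in the HeZD and CNN
#' states (signature prior estimated from each gene-state stratum's own
#' substitution spectrum).
#'
#' @param mutations Raw mutation table (see [read_mutations()]).
#' @param genes Named list of [gene_model()] objects.
#' @param impacts An [impact_table()].
#' @param cn Gene-by-sample copy-number call matrix.
#' @param expression Gene-by-cancer median expression matrix.
#' @param min_mut Minimal per-group mutation count (default 10).
#' @param expression_threshold Strict expression cut-off (default 200).
#' @param cluster_alpha Binomial clustering threshold (default 0.01).
#' @param alternative Screen direction: `"less"` (purifying, default),
#'   `"greater"` or `"two.sided"`.
#' @param pseudocount Signature pseudocount (default 0).
#' @param signature_scope Which mutations feed the per-cancer signatures:
#'   all deduplicated substitutions (`"dedup"`, default) or only those
#'   surviving the cluster filter (`"cluster_filtered"`).
#' @return Object of class `"hemisel"`: a list with `screen` (the per-gene
#'   results table, including `dnds_hezd`/`dnds_cnn` and
#'   `prop_hezd_samples`), `signatures`, `groups` (screenable mutations with
#'   `cn_state` and `normalized`), `cluster_flags`, `median_sim` (gene x
#'   cancer matrix of null medians), `annotated`, `params` and `call`.
#'   Methods: `print`, `summary`, `plot` (qq-plot), `as.data.frame`.
#' @seealso [run_screen()], [dnds()], [normalize_score()]
#' @export
hemisel <- function(mutations, genes, impacts, cn, expression,
                    min_mut = 10, expression_threshold = 200,
                    cluster_alpha = 0.01,
                    alternative = c("less", "greater", "two.sided"),
                    pseudocount = 0,
                    signature_scope = c("dedup", "cluster_filtered")) {
  alternative <- match.arg(alternative)
  signature_scope <- match.arg(signature_scope)
  cl <- match.call()

  dedup <- deduplicate_mutations(mutations)
  ann <- annotate_mutations(dedup, genes, impacts)
  cf <- remove_clustered(ann, genes, alpha = cluster_alpha)

  sig_src <- if (signature_scope == "dedup") ann else cf$mutations
  cancers <- sort(unique(ann$cancer_type))
  signatures <- stats::setNames(
    lapply(cancers, function(ct)
      estimate_signature(sig_src, ct, pseudocount = pseudocount)),
    cancers)

  expressed <- expression_filter(expression, expression_threshold)
  groups <- assemble_groups(cf$mutations, cn, expressed)

  used_genes <- unique(groups$gene_id)
  enum_cache <- stats::setNames(
    lapply(used_genes, function(g) enumerate_substitutions(genes[[g]])),
    used_genes)

  med_sim <- matrix(NA_real_, nrow = length(used_genes),
                    ncol = length(cancers),
                    dimnames = list(used_genes, cancers))
  for (g in used_genes)
    for (ct in unique(groups$cancer_type[groups$gene_id == g]))
      med_sim[g, ct] <- null_score_distribution(
        genes[[g]], signatures[[ct]], impacts,
        enum = enum_cache[[g]])$median_sim
  groups$normalized <- normalize_score(
    groups$impact, med_sim[cbind(groups$gene_id, groups$cancer_type)])

  screen <- run_screen(groups, min_mut = min_mut, alternative = alternative)

  state_dnds <- function(g, state) {
    rows <- groups[groups$gene_id == g & groups$cn_state == state &
                     groups$variant_kind == "substitution", , drop = FALSE]
    if (!nrow(rows)) return(list(dnds = NA_real_, fisher_p = NA_real_))
    sig <- estimate_signature(rows, pseudocount = 0)
    r <- dnds(rows, genes[[g]], sig, enum = enum_cache[[g]])
    list(dnds = r$dnds, fisher_p = r$fisher_p)
  }
  hz <- lapply(screen$gene_id, state_dnds, state = "HeZD")
  cnst <- lapply(screen$gene_id, state_dnds, state = "CNN")
  screen$dnds_hezd <- vapply(hz, `[[`, numeric(1), "dnds")
  screen$dnds_hezd_fisher_p <- vapply(hz, `[[`, numeric(1), "fisher_p")
  screen$dnds_cnn <- vapply(cnst, `[[`, numeric(1), "dnds")
  screen$dnds_cnn_fisher_p <- vapply(cnst, `[[`, numeric(1), "fisher_p")
  prop <- rowMeans(cn == -1L)
  screen$prop_hezd_samples <- unname(prop[screen$gene_id])

  structure(list(screen = screen, signatures = signatures, groups = groups,
                 cluster_flags = cf$flags, median_sim = med_sim,
                 annotated = ann,
                 params = list(min_mut = min_mut,
                               expression_threshold = expression_threshold,
                               cluster_alpha = cluster_alpha,
                               alternative = alternative,
                               pseudocount = pseudocount,
                               signature_scope = signature_scope),
                 call = cl),
            class = "hemisel")
}

#' @export
print.hemisel <- function(x, ...) {
  s <- x$screen
  cat("Hemizygosity-stratified purifying-selection screen\n")
  cat(sprintf("  %d gene(s) screened (>= %d mutations in HeZD and CNN), alternative = '%s'\n",
              nrow(s), x$params$min_mut, x$params$alternative))
  cat(sprintf("  %d gene(s) at P <= 0.05; %d at FDR <= 0.50\n",
              sum(s$p <= 0.05), sum(s$fdr <= 0.5)))
  top <- utils::head(s[order(s$rank),
                       c("rank", "gene_id", "p", "fdr", "dnds_hezd",
                         "dnds_cnn")], 5)
  cat("  Top-ranked genes:\n")
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.hemisel <- function(object, ...) {
  s <- object$screen
  out <- list(
    n_screened = nrow(s),
    n_p05 = sum(s$p <= 0.05),
    n_fdr50 = sum(s$fdr <= 0.5),
    median_norm_hezd = stats::median(
      object$groups$normalized[object$groups$cn_state == "HeZD"]),
    median_norm_cnn = stats::median(
      object$groups$normalized[object$groups$cn_state == "CNN"]),
    params = object$params,
    screen = s)
  class(out) <- "summary.hemisel"
  out
}

#' @export
print.summary.hemisel <- function(x, ...) {
  cat(sprintf("Screened genes: %d (P<=0.05: %d, FDR<=0.50: %d)\n",
              x$n_screened, x$n_p05, x$n_fdr50))
  cat(sprintf("Median normalized impact score: HeZD %.3f, CNN %.3f\n",
              x$median_norm_hezd, x$median_norm_cnn))
  invisible(x)
}

#' @export
as.data.frame.hemisel <- function(x, ...) x$screen

#' qq-plot of the screen p-values
#'
#' Observed versus expected `-log10` p-values of the screened genes.
#'
#' @param x A `"hemisel"` object.
#' @param ... Passed on to [graphics::plot()].
#' @export
plot.hemisel <- function(x, ...) {
  q <- qq_data(x$screen$p)
  graphics::plot(-log10(q$expected), -log10(q$observed),
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 main = "Purifying-selection screen", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
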