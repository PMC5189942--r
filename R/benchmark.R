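# Benchmarking of screen rankings against external essentiality calls.

#' ROC analysis of a gene ranking against a benchmark set
#'
#' The ranking (best gene first, or explicit scores with higher = better) is
#' evaluated against a set of benchmark positives, e.g. human homologs of
#' yeast essential genes. The AUC uses the rank-sum (Mann-Whitney) identity
#' with midranks for ties, so tied scores contribute 1/2 per
#' positive-negative pair. The universe can be restricted to genes present
#' in all compared datasets via `universe`.
#'
#' @param genes Character vector of genes, ordered best-first when `scores`
#'   is `NULL`.
#' @param positives Character vector of benchmark-positive genes.
#' @param scores Optional numeric scores aligned with `genes` (higher =
#'   better ranked); defaults to the reverse position index.
#' @param universe Optional character vector restricting the comparison.
#' @return List with `auc`, `roc` (data frame `threshold`, `fpr`, `tpr`),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(genes, positives, scores = NULL, universe = NULL) {
  if (is.null(scores)) scores <- rev(seq_along(genes))
  stopifnot(length(scores) == length(genes))
  if (!is.null(universe)) {
    keep <- genes %in% universe
    genes <- genes[keep]
    scores <- scores[keep]
  }
  if (anyDuplicated(genes)) stop("duplicated genes in ranking")
  lab <- genes %in% positives
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L)
    stop("ranking must contain at least one positive and one negative gene")
  r <- rank(scores)
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  lab_o <- lab[o]; sc_o <- scores[o]
  last <- !duplicated(sc_o, fromLast = TRUE)
  roc <- data.frame(threshold = sc_o[last],
                    fpr = cumsum(!lab_o)[last] / n0,
                    tpr = cumsum(lab_o)[last] / n1)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  rownames(roc) <- NULL
  list(auc = auc, roc = roc, n_pos = n1, n_neg = n0)
}

#' Cumulative enrichment of benchmark positives along a ranking
#'
#' Point `i` of the curve is the proportion of benchmark positives among the
#' `i` best-ranked genes; for an informative ranking the curve starts high
#' and decays towards the base rate.
#'
#' @inheritParams roc_auc
#' @return Data frame with `rank`, `gene_id`, `cumulative_proportion`.
#' @export
cumulative_enrichment <- function(genes, positives) {
  hit <- genes %in% positives
  data.frame(rank = seq_along(genes), gene_id = genes,
             cumulative_proportion = cumsum(hit) / seq_along(genes))
}

#' Overlap test between screen hits and an orthogonal method's positives
#'
#' One-sided Fisher's exact test for enrichment of an orthogonal method's
#' positives (e.g. CRISPR essentials) among the top genes of the screen,
#' with the per-group positive proportions.
#'
#' @param top Character vector: the screen's hit genes.
#' @param rest Character vector: the remaining screened genes (disjoint from
#'   `top`).
#' @param method_positives Character vector of the orthogonal method's
#'   positives.
#' @param alternative Fisher alternative (default `"greater"`).
#' @return List with `p`, `prop_top`, `prop_rest`, `table`.
#' @export
overlap_test <- function(top, rest, method_positives,
                         alternative = "greater") {
  if (!length(top) || !length(rest))
    stop("both sides of the partition must be non-empty")
  if (length(intersect(top, rest)))
    stop("'top' and 'rest' must be disjoint")
  a <- sum(top %in% method_positives)
  b <- length(top) - a
  cc <- sum(rest %in% method_positives)
  d <- length(rest) - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("top", "rest"),
                                c("positive", "negative")))
  list(p = stats::fisher.test(tab, alternative = alternative)$p.value,
       prop_top = a / (a + b), prop_rest = cc / (cc + d), table = tab)
}
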