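# Secondary inactivating events: homozygous deletions and promoter (TSS)
# versus gene-body (CDS) hypermethylation.

#' Per-gene proportions of deletion and hypermethylation events
#'
#' For every gene in the copy-number matrix: the fraction of samples with a
#' homozygous deletion (call -2) and with a hemizygous deletion (call -1);
#' and, when a methylation table is supplied, the fraction of samples whose
#' TSS (or CDS) probes mark the gene hypermethylated. A sample counts as
#' hypermethylated in a region when any of its probes exceeds
#' `beta_threshold` (strict `>`); `aggregate = "mean"` instead compares the
#' mean probe beta. Genes without probes get `NA` methylation fractions.
#'
#' @param cn Gene-by-sample copy-number call matrix.
#' @param meth Optional methylation table (see [read_methylation()]).
#' @param beta_threshold Strict hypermethylation cut-off (default 0.7).
#' @param aggregate Probe aggregation rule per (gene, sample, region):
#'   `"any"` (default) or `"mean"`.
#' @return Data frame with `gene_id`, `prop_hozd`, `prop_hezd`,
#'   `prop_tss_hyper`, `prop_cds_hyper`.
#' @export
event_proportions <- function(cn, meth = NULL, beta_threshold = 0.7,
                              aggregate = c("any", "mean")) {
  aggregate <- match.arg(aggregate)
  genes <- rownames(cn)
  out <- data.frame(gene_id = genes,
                    prop_hozd = unname(rowMeans(cn == -2L)),
                    prop_hezd = unname(rowMeans(cn == -1L)),
                    prop_tss_hyper = NA_real_,
                    prop_cds_hyper = NA_real_)
  if (!is.null(meth)) {
    for (region in c("TSS", "CDS")) {
      d <- meth[meth$region == region, , drop = FALSE]
      if (!nrow(d)) next
      key <- paste(d$gene_id, d$sample_id, sep = "\r")
      hyper <- if (aggregate == "any")
        tapply(d$beta > beta_threshold, key, any)
      else
        tapply(d$beta, key, mean) > beta_threshold
      gene_of <- sub("\r.*$", "", names(hyper))
      prop <- tapply(as.logical(hyper), gene_of, mean)
      col <- if (region == "TSS") "prop_tss_hyper" else "prop_cds_hyper"
      m <- match(genes, names(prop))
      out[[col]] <- unname(prop[m])
    }
  }
  rownames(out) <- NULL
  out
}

.group_sets <- function(groups) {
  if (is.list(groups)) return(groups)
  split(names(groups), unname(groups))
}

#' Compare event proportions between gene groups
#'
#' Two-sided Wilcoxon rank-sum comparisons of the per-gene event proportions
#' between every pair of gene groups (e.g. screen hits at 50% FDR, hits at
#' P <= 0.05, and the other screened genes), one metric at a time. Pairs
#' with an empty group are skipped.
#'
#' @param props Output of [event_proportions()].
#' @param groups Either a named list of gene-id vectors or a named character
#'   vector mapping gene_id to group label.
#' @return Data frame with `group1`, `group2`, `metric`, `n1`, `n2`, `p`.
#' @export
compare_event_groups <- function(props, groups) {
  sets <- .group_sets(groups)
  metrics <- c("prop_hozd", "prop_hezd", "prop_tss_hyper", "prop_cds_hyper")
  nm <- names(sets)
  rows <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    for (metric in metrics) {
      x <- props[[metric]][props$gene_id %in% sets[[nm[i]]]]
      y <- props[[metric]][props$gene_id %in% sets[[nm[j]]]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = nm[i], group2 = nm[j], metric = metric,
        n1 = length(x), n2 = length(y),
        p = rank_sum_test(x, y, "two.sided")$p.value)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group1 = character(0), group2 = character(0),
               metric = character(0), n1 = integer(0), n2 = integer(0),
               p = numeric(0))
  rownames(df) <- NULL
  df
}

#' Fisher test on the proportion of genes with any homozygous deletion
#'
#' For every pair of gene groups, a Fisher's exact test on the 2x2 table of
#' group membership versus "contains at least one homozygous deletion"
#' (per-gene `prop_hozd > 0`).
#'
#' @inheritParams compare_event_groups
#' @param alternative Fisher alternative (default `"two.sided"`).
#' @return Data frame with `group1`, `group2`, `n1_hozd`, `n1`, `n2_hozd`,
#'   `n2`, `p`.
#' @export
any_hozd_fisher <- function(props, groups, alternative = "two.sided") {
  sets <- .group_sets(groups)
  nm <- names(sets)
  rows <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    x <- props$prop_hozd[props$gene_id %in% sets[[nm[i]]]]
    y <- props$prop_hozd[props$gene_id %in% sets[[nm[j]]]]
    if (!length(x) || !length(y)) next
    tab <- matrix(c(sum(x > 0), sum(x == 0), sum(y > 0), sum(y == 0)),
                  nrow = 2, byrow = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = nm[i], group2 = nm[j],
      n1_hozd = sum(x > 0), n1 = length(x),
      n2_hozd = sum(y > 0), n2 = length(y),
      p = stats::fisher.test(tab, alternative = alternative)$p.value)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group1 = character(0), group2 = character(0),
               n1_hozd = integer(0), n1 = integer(0), n2_hozd = integer(0),
               n2 = integer(0), p = numeric(0))
  rownames(df) <- NULL
  df
}
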