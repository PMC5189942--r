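# Fisher-based gene-set enrichment, pooled pathway/complex tests and the
# essential-complex rule.

#' One-sided Fisher gene-set enrichment
#'
#' For every gene set with at least `min_set` members inside the background
#' universe, a one-sided Fisher's exact test (enrichment) is computed on the
#' 2x2 table of query/background-rest versus in-set/out-of-set, followed by
#' Benjamini-Hochberg FDR over the retained sets. The background should be
#' the screened-gene universe (genes passing the mutation-count filter), so
#' that regional mutation-rate differences do not masquerade as enrichment.
#' The same operation serves curated lists (cancer gene census,
#' loss-of-function-intolerant genes, orthogonal essentiality hits) supplied
#' as single-member-set collections.
#'
#' @param query Character vector of hit genes (intersected with the
#'   background; must be non-empty).
#' @param background Character vector: the gene universe.
#' @param sets Named list of character vectors (see [read_gene_sets()]).
#' @param min_set Minimal in-background set size (default 2).
#' @return Data frame with one row per tested set: `set_name`, `k_hit`,
#'   `k_set`, `q_size`, `bg_size`, `p`, `fdr`, sorted by `p`.
#' @export
fisher_gsea <- function(query, background, sets, min_set = 2) {
  background <- unique(background)
  query <- unique(intersect(query, background))
  if (!length(query)) stop("query is empty (after intersecting the background)")
  q <- length(query)
  bg <- length(background)
  rows <- lapply(names(sets), function(nm) {
    sbg <- unique(intersect(sets[[nm]], background))
    k_set <- length(sbg)
    if (k_set < min_set) return(NULL)
    k_hit <- length(intersect(sbg, query))
    tab <- matrix(c(k_hit, q - k_hit,
                    k_set - k_hit, bg - q - (k_set - k_hit)),
                  nrow = 2, byrow = TRUE)
    data.frame(set_name = nm, k_hit = k_hit, k_set = k_set, q_size = q,
               bg_size = bg,
               p = stats::fisher.test(tab, alternative = "greater")$p.value)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set_name = character(0), k_hit = integer(0),
                      k_set = integer(0), q_size = integer(0),
                      bg_size = integer(0), p = numeric(0), fdr = numeric(0)))
  df <- do.call(rbind, rows)
  df$fdr <- stats::p.adjust(df$p, method = "BH")
  df <- df[order(df$p, df$set_name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pooled per-set purifying-selection test
#'
#' Pools the impact scores of all mutations in genes belonging to the same
#' set (pathway or protein complex) and repeats the HeZD-vs-CNN Wilcoxon
#' comparison on the pooled groups, with BH FDR over sets. Sets with an
#' empty group on either side are skipped with a note.
#'
#' @param sets Named list of gene-id vectors.
#' @param groups Output of [assemble_groups()] (screenable mutations with
#'   `cn_state` and `impact`).
#' @param alternative Test direction (default `"less"`).
#' @return Data frame with `set_name`, `n_genes`, `n_hezd`, `n_cnn`, `p`,
#'   `fdr`, `note`.
#' @export
pooled_set_test <- function(sets, groups, alternative = "less") {
  rows <- lapply(names(sets), function(nm) {
    d <- groups[groups$gene_id %in% sets[[nm]], , drop = FALSE]
    hz <- d$impact[d$cn_state == "HeZD"]
    cnn <- d$impact[d$cn_state == "CNN"]
    if (!length(hz) || !length(cnn))
      return(data.frame(set_name = nm,
                        n_genes = length(unique(d$gene_id)),
                        n_hezd = length(hz), n_cnn = length(cnn),
                        p = NA_real_,
                        note = "empty pooled group; set skipped"))
    data.frame(set_name = nm, n_genes = length(unique(d$gene_id)),
               n_hezd = length(hz), n_cnn = length(cnn),
               p = rank_sum_test(hz, cnn, alternative)$p.value,
               note = NA_character_)
  })
  df <- do.call(rbind, rows)
  df$fdr <- NA_real_
  ok <- !is.na(df$p)
  df$fdr[ok] <- stats::p.adjust(df$p[ok], method = "BH")
  df <- df[order(is.na(df$p), df$p, df$set_name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Flag essential protein complexes
#'
#' A complex is called essential when at least `threshold` (default 70%) of
#' its members are essential genes — the modular-essentiality criterion.
#'
#' @param sets Named list of complex-member vectors.
#' @param essential Character vector of essential gene ids.
#' @param threshold Minimal essential fraction (default 0.70).
#' @return Data frame with `set_name`, `n_members`, `n_essential`,
#'   `frac_essential`, `essential_complex`.
#' @export
essential_complexes <- function(sets, essential, threshold = 0.70) {
  rows <- lapply(names(sets), function(nm) {
    members <- unique(sets[[nm]])
    ke <- length(intersect(members, essential))
    data.frame(set_name = nm, n_members = length(members), n_essential = ke,
               frac_essential = ke / length(members),
               essential_complex = ke / length(members) >= threshold)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Fisher test for protein-complex membership of screen hits
#'
#' Tests whether query genes (e.g. the purifying-selection hits) are part of
#' experimentally determined protein complexes more often than the rest of
#' the background.
#'
#' @param query Character vector of hit genes.
#' @param background Gene universe containing the query.
#' @param complex_members Character vector of all complex-member genes.
#' @param alternative Fisher alternative (default `"greater"`, enrichment).
#' @return List with `p`, `prop_query`, `prop_rest` and the 2x2 `table`.
#' @export
complex_membership_test <- function(query, background, complex_members,
                                    alternative = "greater") {
  background <- unique(background)
  query <- unique(intersect(query, background))
  if (!length(query)) stop("query is empty")
  rest <- setdiff(background, query)
  a <- length(intersect(query, complex_members))
  b <- length(query) - a
  cc <- length(intersect(rest, complex_members))
  d <- length(rest) - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("query", "rest"),
                                c("in_complex", "not_in_complex")))
  list(p = stats::fisher.test(tab, alternative = alternative)$p.value,
       prop_query = a / (a + b), prop_rest = cc / (cc + d), table = tab)
}
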