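#' Estimate a per-cancer 96-class mutational signature
#'
#' The signature is the empirical distribution of annotated substitutions
#' over the 96 trinucleotide substitution classes, optionally smoothed with a
#' pseudocount: `w[k] \propto count(class k) + pseudocount`, normalised to
#' sum to 1. Indels carry no context class and are excluded. The estimate is
#' scale-invariant in the counts.
#'
#' @param annotated Annotated mutation table (see [annotate_mutations()]).
#' @param cancer_type If non-`NULL`, restrict to this cancer type.
#' @param pseudocount Non-negative smoothing constant added to every class
#'   count (default 0).
#' @return Named numeric vector of length 96 summing to 1, with attribute
#'   `cancer_type`.
#' @export
estimate_signature <- function(annotated, cancer_type = NULL,
                               pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  x <- annotated
  if (!is.null(cancer_type))
    x <- x[x$cancer_type == cancer_type, , drop = FALSE]
  ctx <- x$context_class[x$variant_kind == "substitution" &
                           !is.na(x$context_class)]
  counts <- tabulate(ctx + 1L, nbins = 96L)
  if (sum(counts) == 0L && pseudocount == 0)
    stop("no substitutions",
         if (!is.null(cancer_type)) paste0(" for cancer type '", cancer_type, "'"),
         " and pseudocount is 0: signature would be degenerate")
  w <- counts + pseudocount
  w <- w / sum(w)
  names(w) <- context_class_labels()
  attr(w, "cancer_type") <- if (is.null(cancer_type)) NA_character_ else cancer_type
  w
}

#' Per-substitution signature weights across a gene
#'
#' Projects a 96-class signature onto the gene's `3L` possible substitutions:
#' substitution `j` receives the signature weight of its context class, and
#' the vector is normalised to sum to 1 (all-zero weight vectors are
#' returned as zeros). These weights are the prior probability of each
#' possible substitution under the mutational process.
#'
#' @param gene A [gene_model()].
#' @param signature 96-class signature vector (see [estimate_signature()]).
#' @param enum Optional precomputed [enumerate_substitutions()] table for the
#'   gene (cache for repeated calls).
#' @return Numeric weight vector of length `3 * cds_length(gene)`, aligned
#'   with the rows of [enumerate_substitutions()].
#' @export
class_weight_per_site <- function(gene, signature, enum = NULL) {
  if (length(signature) != 96L) stop("signature must have length 96")
  if (is.null(enum)) enum <- enumerate_substitutions(gene)
  w <- as.numeric(signature)[enum$context_class + 1L]
  s <- sum(w)
  if (s > 0) w <- w / s
  w
}
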