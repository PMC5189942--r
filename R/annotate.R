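# Base alphabet, complement, and the canonical (COSMIC-ordered) 96-class model:
# substitution major order C>A, C>G, C>T, T>A, T>C, T>G, then 5' base A,C,G,T,
# then 3' base A,C,G,T. Purine-reference substitutions are reverse-complemented
# onto the pyrimidine strand before lookup.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")
SUB_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
STOP_CODONS <- c("TAA", "TAG", "TGA")
MCLASS_LEVELS <- c("silent", "missense", "truncating")

# codon -> amino acid table, built once from the standard genetic code
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                       stringsAsFactors = FALSE)
      codons <- paste0(g$b1, g$b2, g$b3)
      aa <- vapply(codons,
                   function(cd) seqinr::translate(strsplit(cd, "")[[1]]),
                   character(1))
      tab <<- stats::setNames(aa, codons)
    }
    tab
  }
})

#' Labels of the 96 trinucleotide substitution classes
#'
#' Returns the 96 class labels (e.g. `"A[C>A]G"`) in canonical order:
#' substitution type major (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flanking
#' base (A, C, G, T), then 3' flanking base (A, C, G, T). Class index `k`
#' (0-based, as returned by [context_class()]) corresponds to label `k + 1`.
#'
#' @return Character vector of length 96.
#' @export
context_class_labels <- function() {
  labs <- character(96)
  for (si in 1:6)
    for (ui in 1:4)
      for (di in 1:4)
        labs[(si - 1L) * 16L + (ui - 1L) * 4L + di] <-
          paste0(BASES[ui], "[", SUB_TYPES[si], "]", BASES[di])
  labs
}

#' Construct a gene model
#'
#' A gene model is a coding sequence (CDS, coding strand, 5'->3', length a
#' multiple of 3) together with single-base 5' and 3' flanks, which provide
#' trinucleotide context at the CDS ends.
#'
#' @param gene_id Non-empty gene identifier.
#' @param cds CDS string over A/C/G/T, `nchar(cds) >= 3` and a multiple of 3.
#' @param flank5,flank3 Single bases flanking the CDS.
#' @return An object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, cds, flank5, flank3) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  cds <- toupper(cds)
  flank5 <- toupper(flank5)
  flank3 <- toupper(flank3)
  if (nchar(cds) < 3L || nchar(cds) %% 3L != 0L)
    stop("gene ", gene_id, ": CDS length must be a positive multiple of 3")
  if (!grepl("^[ACGT]+$", cds))
    stop("gene ", gene_id, ": CDS contains non-ACGT characters")
  if (!flank5 %in% BASES || !flank3 %in% BASES)
    stop("gene ", gene_id, ": flanks must be single A/C/G/T bases")
  structure(list(gene_id = gene_id, cds = cds,
                 flank5 = flank5, flank3 = flank3),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model", x$gene_id, "- CDS length", nchar(x$cds), "nt, flanks",
      paste0(tolower(x$flank5), "[CDS]", tolower(x$flank3)), "\n")
  invisible(x)
}

#' CDS length of a gene model
#' @param gene A [gene_model()].
#' @return Integer CDS length in nucleotides.
#' @export
cds_length <- function(gene) nchar(gene$cds)

.cds_chars <- function(gene) strsplit(gene$cds, "")[[1]]

# vectorised 96-class index; all arguments character vectors of equal length
.context_class_vec <- function(ref, alt, up, down) {
  ok <- ref %in% BASES & alt %in% BASES & up %in% BASES & down %in% BASES
  if (!all(ok))
    stop("non-ACGT base in substitution context")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, unname(COMP[ref]), ref)
  a <- ifelse(pur, unname(COMP[alt]), alt)
  u <- ifelse(pur, unname(COMP[down]), up)
  d <- ifelse(pur, unname(COMP[up]), down)
  si <- match(paste0(r, ">", a), SUB_TYPES)
  (si - 1L) * 16L + (match(u, BASES) - 1L) * 4L + (match(d, BASES) - 1L)
}

# vectorised substitution classification within a CDS given as char vector
.classify_subs_vec <- function(b, pos, alt) {
  ci <- (pos - 1L) %/% 3L
  cp <- (pos - 1L) %% 3L + 1L
  cod <- paste0(b[3L * ci + 1L], b[3L * ci + 2L], b[3L * ci + 3L])
  newcod <- paste0(substr(cod, 1L, cp - 1L), alt, substr(cod, cp + 1L, 3L))
  aa <- .codon_table()
  aref <- unname(aa[cod])
  aalt <- unname(aa[newcod])
  ifelse(aref == "*",
         ifelse(aalt == "*", "silent", "truncating"),
         ifelse(aalt == "*", "truncating",
                ifelse(aalt == aref, "silent", "missense")))
}

.check_sub_args <- function(gene, cds_pos, alt) {
  b <- .cds_chars(gene)
  cds_pos <- as.integer(cds_pos)
  if (any(is.na(cds_pos)) || any(cds_pos < 1L) || any(cds_pos > length(b)))
    stop("gene ", gene$gene_id, ": cds_pos out of range 1..", length(b))
  alt <- toupper(alt)
  if (!all(alt %in% BASES))
    stop("alt alleles must be single A/C/G/T bases")
  if (any(alt == b[cds_pos]))
    stop("alt allele equals the reference base at the given position")
  list(b = b, pos = cds_pos, alt = alt)
}

#' Classify a coding substitution as silent, missense or truncating
#'
#' A substitution is silent when the mutated codon translates to the same
#' amino acid, truncating when it creates a stop codon (nonsense) or destroys
#' a reference stop codon (stop-loss, treated as truncating-equivalent), and
#' missense otherwise. Vectorised over `cds_pos`/`alt`.
#'
#' @param gene A [gene_model()].
#' @param cds_pos 1-based position(s) within the CDS.
#' @param alt Alternate base(s), different from the reference base.
#' @return Character vector in `c("silent", "missense", "truncating")`.
#' @export
classify_substitution <- function(gene, cds_pos, alt) {
  a <- .check_sub_args(gene, cds_pos, alt)
  .classify_subs_vec(a$b, a$pos, a$alt)
}

#' Classify an insertion or deletion
#'
#' Out-of-frame (length not a multiple of 3) indels are truncating; in-frame
#' indels are folded into the missense class (non-silent, non-truncating).
#'
#' @param variant_kind `"insertion"` or `"deletion"` (vectorised).
#' @param length Positive integer indel length(s) in nucleotides.
#' @return Character vector, `"truncating"` or `"missense"`.
#' @export
classify_indel <- function(variant_kind, length) {
  if (!all(variant_kind %in% c("insertion", "deletion")))
    stop("variant_kind must be 'insertion' or 'deletion'")
  length <- as.numeric(length)
  if (any(is.na(length)) || any(length < 1) || any(length != floor(length)))
    stop("indel length must be a positive integer")
  ifelse(length %% 3 != 0, "truncating", "missense")
}

#' Trinucleotide substitution class of a coding substitution
#'
#' Maps a substitution and its immediate 5'/3' context onto the canonical
#' 96-class index (0-95). Substitutions with a purine reference base are
#' reverse-complemented (alleles and swapped, complemented flanks) onto the
#' pyrimidine strand first. The gene-model flanks supply context at the CDS
#' ends. Vectorised over `cds_pos`/`alt`.
#'
#' @inheritParams classify_substitution
#' @return Integer vector of class indices in 0..95; see
#'   [context_class_labels()] for the corresponding labels.
#' @export
context_class <- function(gene, cds_pos, alt) {
  a <- .check_sub_args(gene, cds_pos, alt)
  flanked <- c(gene$flank5, a$b, gene$flank3)
  .context_class_vec(a$b[a$pos], a$alt, flanked[a$pos], flanked[a$pos + 2L])
}

#' Enumerate all 3L possible substitutions of a gene
#'
#' Every CDS position can mutate into each of the three non-reference bases,
#' giving exactly `3 * cds_length(gene)` substitutions. Each is classified and
#' assigned its 96-class context. This enumeration is the substitution
#' universe used for expected site counts, per-site signature weights and
#' null impact-score distributions.
#'
#' @param gene A [gene_model()].
#' @return A data frame with columns `cds_pos`, `ref`, `alt`, `mclass`,
#'   `context_class`, with `3 * cds_length(gene)` rows.
#' @export
enumerate_substitutions <- function(gene) {
  b <- .cds_chars(gene)
  L <- length(b)
  pos <- rep(seq_len(L), each = 3L)
  altm <- vapply(BASES, function(x) setdiff(BASES, x), character(3))
  alt <- as.vector(altm[, match(b, BASES)])
  ref <- b[pos]
  flanked <- c(gene$flank5, b, gene$flank3)
  data.frame(cds_pos = pos, ref = ref, alt = alt,
             mclass = .classify_subs_vec(b, pos, alt),
             context_class = .context_class_vec(ref, alt, flanked[pos],
                                                flanked[pos + 2L]))
}

#' Annotate a mutation table with class, context and impact score
#'
#' Attaches to every retained mutation its mutation class (`mclass`:
#' silent/missense/truncating), its 96-class substitution context
#' (`context_class`, `NA` for indels), and its phred-like impact score
#' (`impact`, 0-40). Silent mutations score exactly 0 and truncating
#' mutations exactly 40 by convention; missense substitutions take their
#' score from the impact table; in-frame indels take `inframe_impact`.
#'
#' Mutations in genes without a model, mutations without a CDS position, and
#' substitutions whose stated reference allele disagrees with the gene model
#' are dropped, with row-numbered diagnostics attached as
#' `attr(result, "diagnostics")`. A substitution whose score is missing from
#' the impact table is an error.
#'
#' @param muts Mutation table as returned by [read_mutations()].
#' @param genes Named list of [gene_model()] objects.
#' @param impacts An [impact_table()].
#' @param inframe_impact Score assigned to in-frame indels (default 20).
#' @return The annotated mutation table (input columns plus `mclass`,
#'   `context_class`, `impact`), with dropped-row diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
annotate_mutations <- function(muts, genes, impacts, inframe_impact = 20) {
  req <- c("sample_id", "cancer_type", "gene_id", "cds_pos", "ref", "alt",
           "variant_kind")
  if (!all(req %in% names(muts)))
    stop("mutation table lacks required columns: ",
         paste(setdiff(req, names(muts)), collapse = ", "))
  n <- nrow(muts)
  keep <- rep(TRUE, n)
  diags <- character(0)
  mclass <- character(n)
  ctx <- rep(NA_integer_, n)
  impact <- rep(NA_real_, n)

  no_model <- !(muts$gene_id %in% names(genes))
  if (any(no_model)) {
    diags <- c(diags, sprintf("row %d: no gene model for '%s'",
                              which(no_model), muts$gene_id[no_model]))
    keep[no_model] <- FALSE
  }
  na_pos <- keep & is.na(muts$cds_pos)
  if (any(na_pos)) {
    diags <- c(diags, sprintf("row %d: no CDS position (outside CDS)",
                              which(na_pos)))
    keep[na_pos] <- FALSE
  }

  for (g in unique(muts$gene_id[keep])) {
    gm <- genes[[g]]
    b <- .cds_chars(gm)
    L <- length(b)
    idx <- which(keep & muts$gene_id == g)
    pos <- as.integer(muts$cds_pos[idx])
    bad <- pos < 1L | pos > L
    if (any(bad)) {
      diags <- c(diags, sprintf("row %d: cds_pos %d outside CDS of '%s' (L=%d)",
                                idx[bad], pos[bad], g, L))
      keep[idx[bad]] <- FALSE
      idx <- idx[!bad]
      pos <- pos[!bad]
    }
    if (!length(idx)) next
    is_sub <- muts$variant_kind[idx] == "substitution"

    si <- idx[is_sub]
    if (length(si)) {
      sp <- pos[is_sub]
      sref <- toupper(muts$ref[si])
      salt <- toupper(muts$alt[si])
      mism <- sref != b[sp]
      if (any(mism)) {
        diags <- c(diags,
                   sprintf("row %d: ref allele '%s' disagrees with gene model '%s' at cds_pos %d",
                           si[mism], sref[mism], g, sp[mism]))
        keep[si[mism]] <- FALSE
        si <- si[!mism]; sp <- sp[!mism]; salt <- salt[!mism]
      }
      if (length(si)) {
        mclass[si] <- .classify_subs_vec(b, sp, salt)
        flanked <- c(gm$flank5, b, gm$flank3)
        ctx[si] <- .context_class_vec(b[sp], salt, flanked[sp],
                                      flanked[sp + 2L])
        mat <- impacts[[g]]
        if (is.null(mat))
          stop("impact table has no entries for gene '", g, "'")
        val <- mat[cbind(match(salt, BASES), sp)]
        if (anyNA(val)) {
          miss <- which(is.na(val))
          stop("impact score missing for gene '", g, "' at (cds_pos, alt): ",
               paste(sprintf("(%d,%s)", sp[miss], salt[miss]), collapse = " "))
        }
        impact[si] <- ifelse(mclass[si] == "silent", 0,
                             ifelse(mclass[si] == "truncating", 40, val))
      }
    }

    ii <- idx[!is_sub]
    if (length(ii)) {
      kind <- muts$variant_kind[ii]
      len <- ifelse(kind == "insertion",
                    nchar(gsub("-", "", muts$alt[ii], fixed = TRUE)),
                    nchar(gsub("-", "", muts$ref[ii], fixed = TRUE)))
      mclass[ii] <- classify_indel(kind, len)
      impact[ii] <- ifelse(mclass[ii] == "truncating", 40, inframe_impact)
    }
  }

  out <- muts[keep, , drop = FALSE]
  out$mclass <- mclass[keep]
  out$context_class <- ctx[keep]
  out$impact <- impact[keep]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diags
  if (length(diags))
    message(length(diags), " mutation(s) dropped during annotation; see attr(, \"diagnostics\")")
  out
}
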