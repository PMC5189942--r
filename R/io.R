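# Tabular I/O. Every table is TSV with a header line. Writers emit a fixed
# column order and sort rows on a canonical key so that output files are
# byte-identical across runs for identical inputs.

.default_mut_schema <- c(sample_id = "sample_id", cancer_type = "cancer_type",
                         gene_id = "gene_id", cds_pos = "cds_pos",
                         ref = "ref", alt = "alt",
                         variant_kind = "variant_kind")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("schema error in ", path, ": duplicated header column(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a somatic mutation table
#'
#' Reads a MAF-reduced TSV with one row per somatic mutation. Required fields
#' (resolved through `schema`, a named character vector mapping field name to
#' file column name): `sample_id`, `cancer_type`, `gene_id`, `cds_pos`
#' (1-based CDS position; empty for mutations outside the CDS), `ref`, `alt`,
#' `variant_kind` (`substitution`/`insertion`/`deletion`). Indel alleles use
#' `-` for the absent side (e.g. a deletion has `alt = "-"`).
#'
#' Malformed rows (non-ACGT substitution alleles, `ref == alt`, empty ids,
#' `cds_pos < 1`, unknown `variant_kind`) are dropped; row-numbered
#' diagnostics are collected in `attr(result, "diagnostics")` rather than
#' aborting the parse. A missing or duplicated header column is an error.
#' Row order of the file is preserved.
#'
#' @param path Path to the TSV file.
#' @param schema Named character vector mapping required field names to file
#'   column names; defaults to identity.
#' @return A data.frame mutation table.
#' @export
read_mutations <- function(path, schema = NULL) {
  sc <- .default_mut_schema
  if (!is.null(schema)) sc[names(schema)] <- schema
  raw <- .read_tsv(path)
  missing_cols <- sc[!(sc %in% names(raw))]
  if (length(missing_cols))
    stop("schema error in ", path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- data.frame(sample_id = raw[[sc["sample_id"]]],
                  cancer_type = raw[[sc["cancer_type"]]],
                  gene_id = raw[[sc["gene_id"]]],
                  cds_pos = suppressWarnings(as.integer(raw[[sc["cds_pos"]]])),
                  ref = toupper(raw[[sc["ref"]]]),
                  alt = toupper(raw[[sc["alt"]]]),
                  variant_kind = raw[[sc["variant_kind"]]])
  n <- nrow(x)
  diags <- character(0)
  bad <- rep(FALSE, n)
  note <- function(cond, msg_fmt, vals = NULL) {
    hit <- which(cond & !bad)
    if (length(hit)) {
      diags <<- c(diags, if (is.null(vals))
        sprintf(paste0("row %d: ", msg_fmt), hit)
        else sprintf(paste0("row %d: ", msg_fmt), hit, vals[hit]))
      bad[hit] <<- TRUE
    }
  }
  note(!nzchar(x$sample_id), "empty sample_id")
  note(!nzchar(x$gene_id), "empty gene_id")
  note(!(x$variant_kind %in% c("substitution", "insertion", "deletion")),
       "unknown variant_kind '%s'", x$variant_kind)
  is_sub <- x$variant_kind == "substitution"
  note(is_sub & !(x$ref %in% BASES),
       "ref allele '%s' is not a single A/C/G/T base", x$ref)
  note(is_sub & !(x$alt %in% BASES),
       "alt allele '%s' is not a single A/C/G/T base", x$alt)
  note(is_sub & x$ref == x$alt, "ref and alt alleles are identical")
  note(!is.na(x$cds_pos) & x$cds_pos < 1L, "cds_pos < 1")
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diags
  if (length(diags))
    message(length(diags), " malformed row(s) dropped from ", path,
            "; see attr(, \"diagnostics\")")
  out
}

#' Write a mutation table
#'
#' Columns are written in fixed order and rows sorted by
#' (sample_id, gene_id, cds_pos, ref, alt) for byte-stable output.
#'
#' @param muts Mutation table.
#' @param path Output TSV path.
#' @export
write_mutations <- function(muts, path) {
  cols <- names(.default_mut_schema)
  x <- muts[order(muts$sample_id, muts$gene_id, muts$cds_pos, muts$ref,
                  muts$alt, muts$variant_kind), cols, drop = FALSE]
  .write_tsv(x, path)
}

#' Remove duplicate mutation records
#'
#' Keeps the first occurrence of every (sample_id, gene_id, cds_pos, ref,
#' alt) combination; duplicate lines arise from redundant cohort files.
#' Idempotent.
#'
#' @param muts Mutation table.
#' @return Deduplicated mutation table.
#' @export
deduplicate_mutations <- function(muts) {
  key <- paste(muts$sample_id, muts$gene_id, muts$cds_pos, muts$ref, muts$alt,
               sep = "\r")
  out <- muts[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.read_matrix_tsv <- function(path, id_col, value_check, what) {
  raw <- .read_tsv(path)
  if (names(raw)[1] != id_col)
    stop(path, ": first column must be '", id_col, "'")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) stop(path, ": duplicated ", id_col)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  value_check(m, what, path)
  m
}

#' Read a gene-by-sample copy-number call matrix
#'
#' TSV with first column `gene_id` and one column per sample; calls are
#' GISTIC-thresholded integers in -2..2 (-2 homozygous deletion, -1
#' hemizygous deletion, 0 neutral, 1/2 gain/amplification).
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
read_copy_number <- function(path) {
  m <- .read_matrix_tsv(path, "gene_id", function(m, what, p) {
    if (anyNA(m) || !all(m %in% -2:2))
      stop(p, ": copy-number calls must be integers in -2..2")
  }, "copy number")
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_copy_number
#' @param cn Copy-number matrix.
#' @export
write_copy_number <- function(cn, path) {
  cn <- cn[order(rownames(cn)), order(colnames(cn)), drop = FALSE]
  .write_tsv(data.frame(gene_id = rownames(cn), cn, check.names = FALSE),
             path)
}

#' Read a gene-by-cancer median expression matrix
#'
#' TSV with first column `gene_id` and one column per cancer type holding
#' non-negative median expression values (RSEM-like units).
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows, cancer types in columns.
#' @export
read_expression <- function(path) {
  .read_matrix_tsv(path, "gene_id", function(m, what, p) {
    if (anyNA(m) || any(m < 0))
      stop(p, ": expression values must be non-negative numbers")
  }, "expression")
}

#' @rdname read_expression
#' @param expression Expression matrix.
#' @export
write_expression <- function(expression, path) {
  m <- expression[order(rownames(expression)), order(colnames(expression)),
                  drop = FALSE]
  .write_tsv(data.frame(gene_id = rownames(m), m, check.names = FALSE), path)
}

#' Read a methylation beta-value table
#'
#' TSV with columns `probe_id`, `gene_id`, `region` (`TSS` or `CDS`),
#' `sample_id`, `beta` (in `[0, 1]`).
#'
#' @param path Path to the TSV file.
#' @return A data.frame methylation table.
#' @export
read_methylation <- function(path) {
  raw <- .read_tsv(path)
  req <- c("probe_id", "gene_id", "region", "sample_id", "beta")
  if (!all(req %in% names(raw)))
    stop(path, ": missing required column(s): ",
         paste(setdiff(req, names(raw)), collapse = ", "))
  x <- raw[req]
  x$beta <- as.numeric(x$beta)
  if (!all(x$region %in% c("TSS", "CDS")))
    stop(path, ": region must be 'TSS' or 'CDS'")
  if (anyNA(x$beta) || any(x$beta < 0 | x$beta > 1))
    stop(path, ": beta values must lie in [0, 1]")
  x
}

#' @rdname read_methylation
#' @param meth Methylation table.
#' @export
write_methylation <- function(meth, path) {
  x <- meth[order(meth$gene_id, meth$region, meth$probe_id, meth$sample_id),
            c("probe_id", "gene_id", "region", "sample_id", "beta"),
            drop = FALSE]
  .write_tsv(x, path)
}

#' Read a GMT gene-set file
#'
#' Each line is `set_name TAB description TAB gene TAB gene ...`. Genes are
#' de-duplicated within a set; a line with fewer than 3 fields is a parse
#' error naming the line number. An empty file yields an empty collection.
#'
#' @param path Path to the GMT file.
#' @param source Source tag stored as an attribute (e.g. `"GO"`, `"CORUM"`).
#' @return Named list of character vectors with attribute `source`.
#' @export
read_gene_sets <- function(path, source = "custom") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(path, ": line ", i, ": expected at least 3 tab-separated fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(path, ": line ", i, ": gene set '", f[1], "' is empty")
    sets[[f[1]]] <- genes
  }
  attr(sets, "source") <- source
  sets
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @export
write_gene_sets <- function(sets, path) {
  nm <- sort(names(sets))
  lines <- vapply(nm, function(s)
    paste(c(s, "na", unique(sets[[s]])), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a flank-encoded FASTA file
#'
#' Each record holds one CDS on the coding strand with its single-base flanks
#' encoded as the lowercase first and last characters of the sequence; the
#' uppercase middle is the CDS itself.
#'
#' @param path Path to the FASTA file.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  models <- lapply(names(fa), function(id) {
    s <- as.character(fa[[id]])
    n <- nchar(s)
    if (n < 5L)
      stop(path, ": sequence '", id, "' too short for flanks + CDS")
    f5 <- substr(s, 1L, 1L)
    f3 <- substr(s, n, n)
    if (f5 %in% BASES || f3 %in% BASES)
      stop(path, ": sequence '", id,
           "' must encode flanks as lowercase first/last characters")
    body <- substr(s, 2L, n - 1L)
    if (!grepl("^[ACGT]+$", body))
      stop(path, ": CDS of '", id, "' must be uppercase A/C/G/T")
    gene_model(id, body, toupper(f5), toupper(f3))
  })
  stats::setNames(models, names(fa))
}

#' @rdname read_gene_models
#' @param genes Named list of [gene_model()] objects.
#' @export
write_gene_models <- function(genes, path) {
  nm <- sort(names(genes))
  seqs <- lapply(nm, function(g)
    strsplit(paste0(tolower(genes[[g]]$flank5), genes[[g]]$cds,
                    tolower(genes[[g]]$flank3)), "")[[1]])
  seqinr::write.fasta(seqs, nm, path, nbchar = 70)
  invisible(path)
}

#' Construct a validated per-gene substitution impact table
#'
#' The table maps every possible substitution `(gene, cds_pos, alt)` to a
#' phred-like score in `[0, 40]`. For each gene exactly `3 * cds_length`
#' entries are required; silent substitutions must score exactly 0 and
#' truncating substitutions (nonsense and stop-loss) exactly 40, mirroring
#' the score conventions used throughout the screen.
#'
#' @param scores A data.frame with columns `gene_id`, `cds_pos`, `alt`,
#'   `score`.
#' @param genes Named list of [gene_model()] objects covering the table.
#' @return An object of class `"impact_table"`: a named list with one 4 x L
#'   score matrix per gene (rows A, C, G, T; `NA` on the reference base).
#' @export
impact_table <- function(scores, genes) {
  req <- c("gene_id", "cds_pos", "alt", "score")
  if (!all(req %in% names(scores)))
    stop("impact table lacks required columns: ",
         paste(setdiff(req, names(scores)), collapse = ", "))
  out <- list()
  for (g in unique(scores$gene_id)) {
    gm <- genes[[g]]
    if (is.null(gm)) stop("impact table references unknown gene '", g, "'")
    L <- cds_length(gm)
    d <- scores[scores$gene_id == g, , drop = FALSE]
    if (nrow(d) != 3L * L)
      stop("gene '", g, "': expected ", 3L * L, " impact entries, got ",
           nrow(d))
    pos <- as.integer(d$cds_pos)
    alt <- toupper(d$alt)
    val <- as.numeric(d$score)
    if (anyNA(val) || any(val < 0 | val > 40))
      stop("gene '", g, "': impact scores must lie in [0, 40]")
    en <- enumerate_substitutions(gm)
    key <- paste(pos, alt)
    ekey <- paste(en$cds_pos, en$alt)
    if (anyDuplicated(key) || !setequal(key, ekey))
      stop("gene '", g,
           "': impact entries must cover each possible substitution exactly once")
    m <- match(ekey, key)
    sc <- val[m]
    if (any(sc[en$mclass == "silent"] != 0))
      stop("gene '", g, "': silent substitutions must score exactly 0")
    if (any(sc[en$mclass == "truncating"] != 40))
      stop("gene '", g, "': truncating substitutions must score exactly 40")
    mat <- matrix(NA_real_, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
    mat[cbind(match(en$alt, BASES), en$cds_pos)] <- sc
    out[[g]] <- mat
  }
  structure(out, class = "impact_table")
}

#' Read an impact-score table
#'
#' TSV with columns `gene_id`, `cds_pos`, `alt`, `score`; validated against
#' the gene models (see [impact_table()]).
#'
#' @inheritParams impact_table
#' @param path Path to the TSV file.
#' @return An `"impact_table"`.
#' @export
read_impact_table <- function(path, genes) {
  impact_table(.read_tsv(path), genes)
}

#' @rdname read_impact_table
#' @param impacts An `"impact_table"`.
#' @export
write_impact_table <- function(impacts, path) {
  rows <- lapply(sort(names(unclass(impacts))), function(g) {
    mat <- impacts[[g]]
    idx <- which(!is.na(mat), arr.ind = TRUE)
    idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
    data.frame(gene_id = g, cds_pos = idx[, 2], alt = BASES[idx[, 1]],
               score = mat[idx])
  })
  .write_tsv(do.call(rbind, rows), path)
}

#' Read / write a plain gene-id list (one id per line)
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes Character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(sort(unique(genes)), path)
  invisible(path)
}

#' Read / write per-cancer 96-class signature tables
#'
#' TSV with column `cancer_type` followed by the 96 class-label columns in
#' canonical order (see [context_class_labels()]).
#'
#' @param path File path.
#' @return Named list of signature vectors (length 96, summing to 1).
#' @export
read_signatures <- function(path) {
  raw <- .read_tsv(path)
  labs <- context_class_labels()
  if (!all(labs %in% names(raw)))
    stop(path, ": missing 96-class signature column(s)")
  out <- lapply(seq_len(nrow(raw)), function(i) {
    w <- as.numeric(raw[i, labs])
    stats::setNames(w, labs)
  })
  stats::setNames(out, raw$cancer_type)
}

#' @rdname read_signatures
#' @param signatures Named list of 96-class signature vectors.
#' @export
write_signatures <- function(signatures, path) {
  labs <- context_class_labels()
  nm <- sort(names(signatures))
  m <- do.call(rbind, lapply(nm, function(ct) signatures[[ct]][labs]))
  x <- data.frame(cancer_type = nm, m, check.names = FALSE)
  colnames(x) <- c("cancer_type", labs)
  .write_tsv(x, path)
}
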