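# End-to-end orchestration: fit the screen, run the downstream analyses and
# write every stage output plus a manifest to a directory.

.pipeline_inputs <- function(input) {
  if (is.character(input) && length(input) == 1L) {
    need <- function(f) file.path(input, f)
    genes <- read_gene_models(need("genes.fasta"))
    list(mutations = read_mutations(need("mutations.tsv")),
         genes = genes,
         impacts = read_impact_table(need("impacts.tsv"), genes),
         cn = read_copy_number(need("cn_calls.tsv")),
         expression = read_expression(need("expression.tsv")),
         methylation = if (file.exists(need("methylation.tsv")))
           read_methylation(need("methylation.tsv")) else NULL,
         gene_sets = if (file.exists(need("sets.gmt")))
           read_gene_sets(need("sets.gmt")) else NULL,
         benchmarks = if (file.exists(need("benchmark_genes.txt")))
           list(benchmark = read_gene_list(need("benchmark_genes.txt")))
         else NULL)
  } else {
    genes <- if (!is.null(input$genome)) input$genome$models else input$genes
    impacts <- if (!is.null(input$genome)) input$genome$impacts else
      input$impacts
    list(mutations = input$mutations, genes = genes, impacts = impacts,
         cn = input$cn, expression = input$expression,
         methylation = input$methylation, gene_sets = input$gene_sets,
         benchmarks = input$benchmarks)
  }
}

#' Run the full analysis pipeline and write all stage outputs
#'
#' Orchestrates the whole analysis — screen fit ([hemisel()]), qq data,
#' gene-set enrichment and pooled set tests (when gene sets are available),
#' essentiality benchmarking (when benchmark lists are available) and
#' secondary-event analysis (when methylation data are available) — and
#' writes each stage's table to `out_dir` together with a JSON manifest
#' recording parameters, per-stage row counts and output checksums. The
#' default analytic mode contains no randomness, so reruns on identical
#' inputs produce byte-identical outputs.
#'
#' @param input Either a directory containing `mutations.tsv`,
#'   `genes.fasta`, `impacts.tsv`, `cn_calls.tsv`, `expression.tsv` (and
#'   optionally `methylation.tsv`, `sets.gmt`, `benchmark_genes.txt`), or an
#'   in-memory cohort list such as a `"synthetic_cohort"` or the
#'   [worked_fixture()].
#' @param out_dir Output directory (created if missing).
#' @param params Named list overriding [hemisel()] screen parameters
#'   (`min_mut`, `expression_threshold`, `cluster_alpha`, `alternative`,
#'   `pseudocount`, and the report thresholds `report_fdr`, `report_p`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(input, out_dir, params = list()) {
  inp <- .pipeline_inputs(input)
  defaults <- list(min_mut = 10, expression_threshold = 200,
                   cluster_alpha = 0.01, alternative = "less",
                   pseudocount = 0, report_fdr = 0.50, report_p = 0.05,
                   gsea_fdr = 0.25)
  p <- utils::modifyList(defaults, params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fit <- hemisel(inp$mutations, inp$genes, inp$impacts, inp$cn,
                 inp$expression, min_mut = p$min_mut,
                 expression_threshold = p$expression_threshold,
                 cluster_alpha = p$cluster_alpha,
                 alternative = p$alternative, pseudocount = p$pseudocount)
  outputs <- character(0)
  emit <- function(x, f) {
    path <- file.path(out_dir, f)
    .write_tsv(x, path)
    outputs <<- c(outputs, path)
  }
  emit(fit$screen, "screen.tsv")
  emit(fit$cluster_flags, "cluster_flags.tsv")
  write_signatures(fit$signatures, file.path(out_dir, "signatures.tsv"))
  outputs <- c(outputs, file.path(out_dir, "signatures.tsv"))
  emit(qq_data(fit$screen$p), "qq.tsv")
  norm <- fit$groups[order(fit$groups$gene_id, fit$groups$sample_id,
                           fit$groups$cds_pos, fit$groups$alt), ]
  emit(norm, "normalized_scores.tsv")

  screen <- fit$screen
  query <- screen$gene_id[screen$p <= p$report_p]
  background <- screen$gene_id
  counts <- list(input_mutations = nrow(inp$mutations),
                 annotated = nrow(fit$annotated),
                 screenable = nrow(fit$groups),
                 screened_genes = nrow(screen),
                 hits_p = length(query),
                 hits_fdr = sum(screen$fdr <= p$report_fdr))

  if (!is.null(inp$gene_sets) && length(query)) {
    emit(fisher_gsea(query, background, inp$gene_sets), "enrichment.tsv")
    emit(pooled_set_test(inp$gene_sets, fit$groups), "pooled.tsv")
  }
  if (!is.null(inp$benchmarks)) {
    ranking <- screen$gene_id[order(screen$rank)]
    bm <- do.call(rbind, lapply(names(inp$benchmarks), function(nm) {
      pos <- inp$benchmarks[[nm]]
      if (!any(ranking %in% pos) || all(ranking %in% pos))
        return(data.frame(method = nm, auc = NA_real_, n_pos = NA_integer_,
                          n_neg = NA_integer_))
      r <- roc_auc(ranking, pos)
      data.frame(method = nm, auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg)
    }))
    emit(bm, "benchmark.tsv")
    emit(cumulative_enrichment(ranking, inp$benchmarks[[1]]),
         "cumulative.tsv")
  }
  if (!is.null(inp$methylation)) {
    props <- event_proportions(inp$cn[screen$gene_id, , drop = FALSE],
                               inp$methylation)
    emit(props, "secondary.tsv")
  }

  manifest <- list(package = "hemisel",
                   version = as.character(utils::packageVersion("hemisel")),
                   params = p, counts = counts,
                   outputs = lapply(stats::setNames(outputs,
                                                    basename(outputs)),
                                    function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
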