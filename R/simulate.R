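# Synthetic cohorts with known ground truth. The generator draws mutations
# from per-cancer 96-class signatures over each gene's substitution universe,
# then applies copy-number-dependent selection: in hemizygously deleted
# samples, candidate mutations of essential genes are rejected with
# probability sigma * impact/40 (purifying selection), while candidates of
# tumor-suppressor genes are drawn with their signature weights tilted by
# 1 + beta * impact/40 (relative enrichment of high-impact mutations, i.e.
# positive selection). All copy-number-neutral candidates follow the plain
# signature, so the neutral spectrum is analytically known.

#' Configuration of a synthetic tumor cohort
#'
#' Bundles and validates every parameter of the generator. The defaults are
#' the package's desk-scale study conditions: 2 cancer types x 200 samples,
#' 300 genes of 250-500 codons, Dirichlet(0.5) cancer signatures, per-gene
#' hemizygous-deletion probability uniform in \[0.2, 0.4\], homozygous
#' deletion 0.005, amplification 0.10, 0.4 expected mutations per gene per
#' sample (scaled so that screened genes reach per-group mutation counts
#' the screen has stable power at), 15% essential genes, 10% tumor
#' suppressors, selection strength `sigma = 0.8` and TSG boost `beta = 2`.
#'
#' @param seed Integer master seed (genome uses `seed`, gene roles
#'   `seed + 1`, cohort `seed + 2`).
#' @param n_cancers,samples_per_cancer,n_genes Cohort dimensions.
#' @param cds_codons Length-2 integer range of CDS lengths in codons.
#' @param signature_concentration Dirichlet concentration for random
#'   per-cancer signatures.
#' @param signatures Optional named list of explicit 96-class signatures
#'   (overrides the Dirichlet draw).
#' @param hezd_prob Length-2 range of per-gene hemizygous-deletion
#'   probabilities.
#' @param hozd_prob,amp_prob Homozygous-deletion and amplification
#'   probabilities (amplification split evenly between calls +1 and +2).
#' @param mutation_rate Expected candidate mutations per gene per sample.
#' @param fraction_essential,fraction_tsg Gene-role fractions; the rest are
#'   neutral.
#' @param selection_strength Purifying selection strength `sigma` in
#'   \[0, 1\].
#' @param tsg_boost Positive-selection boost `beta >= 0` for tumor
#'   suppressors.
#' @param fraction_expressed Probability that a (gene, cancer) pair is
#'   expressed.
#' @param expressed_meanlog,expressed_sdlog Log-normal parameters of
#'   expressed median expression values.
#' @param unexpressed_max Upper bound of (uniform) unexpressed values.
#' @param meth_baseline_shape,meth_hyper_shape Beta shapes of baseline and
#'   hypermethylated probe values.
#' @param tss_hyper_prob,cds_hyper_prob Per-(gene, sample) hypermethylation
#'   probabilities for TSS and CDS probes.
#' @param missense_beta_shape Beta shapes of missense impact scores (scaled
#'   to \[0, 40\]).
#' @param benchmark_sensitivity,benchmark_false_rate Sensitivity and
#'   false-positive rate of the simulated orthogonal essentiality methods.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L, n_cancers = 2L,
                              samples_per_cancer = 200L, n_genes = 300L,
                              cds_codons = c(250L, 500L),
                              signature_concentration = 0.5,
                              signatures = NULL,
                              hezd_prob = c(0.2, 0.4), hozd_prob = 0.005,
                              amp_prob = 0.10, mutation_rate = 0.4,
                              fraction_essential = 0.15,
                              fraction_tsg = 0.10,
                              selection_strength = 0.8, tsg_boost = 2,
                              fraction_expressed = 0.9,
                              expressed_meanlog = log(1000),
                              expressed_sdlog = 0.6, unexpressed_max = 150,
                              meth_baseline_shape = c(2, 18),
                              meth_hyper_shape = c(18, 2),
                              tss_hyper_prob = 0.05, cds_hyper_prob = 0.02,
                              missense_beta_shape = c(2, 3),
                              benchmark_sensitivity = 0.8,
                              benchmark_false_rate = 0.08) {
  stopifnot(n_cancers >= 1, samples_per_cancer >= 1, n_genes >= 1,
            length(cds_codons) == 2, cds_codons[1] >= 2,
            cds_codons[2] >= cds_codons[1],
            selection_strength >= 0, selection_strength <= 1,
            tsg_boost >= 0, mutation_rate >= 0,
            all(hezd_prob >= 0 & hezd_prob <= 1),
            hozd_prob >= 0, amp_prob >= 0,
            hozd_prob + max(hezd_prob) + amp_prob < 1,
            fraction_essential >= 0, fraction_tsg >= 0,
            fraction_essential + fraction_tsg <= 1,
            fraction_expressed >= 0, fraction_expressed <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic genome: gene models and frozen impact scores
#'
#' Random CDS sequences (sense codons only, lengths drawn from the
#' configured codon range) with random single-base flanks, plus an
#' [impact_table()] covering all `3L` substitutions per gene: silent
#' substitutions score 0, truncating ones 40, and missense scores are drawn
#' once from a Beta distribution scaled to \[0, 40\] and frozen.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return Object of class `"synthetic_genome"`: list with `models`,
#'   `impacts` and the cached substitution enumeration `enum`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  all_codons <- apply(expand.grid(BASES, BASES, BASES,
                                  stringsAsFactors = FALSE), 1, paste0,
                      collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  ids <- sprintf("G%03d", seq_len(config$n_genes))
  models <- list(); impacts <- list(); enum <- list()
  for (id in ids) {
    nc <- config$cds_codons[1] - 1L +
      sample.int(config$cds_codons[2] - config$cds_codons[1] + 1L, 1L)
    cds <- paste0(sample(sense, nc, replace = TRUE), collapse = "")
    gm <- gene_model(id, cds, sample(BASES, 1L), sample(BASES, 1L))
    en <- enumerate_substitutions(gm)
    sc <- numeric(nrow(en))
    mis <- en$mclass == "missense"
    sc[mis] <- stats::rbeta(sum(mis), config$missense_beta_shape[1],
                            config$missense_beta_shape[2]) * 40
    sc[en$mclass == "truncating"] <- 40
    mat <- matrix(NA_real_, nrow = 4L, ncol = cds_length(gm),
                  dimnames = list(BASES, NULL))
    mat[cbind(match(en$alt, BASES), en$cds_pos)] <- sc
    models[[id]] <- gm
    impacts[[id]] <- mat
    enum[[id]] <- en
  }
  structure(list(models = models,
                 impacts = structure(impacts, class = "impact_table"),
                 enum = enum),
            class = "synthetic_genome")
}

#' Assign ground-truth selection roles to genes
#'
#' Partitions the genes into essential / tumor-suppressor (tsg) / neutral
#' roles at the configured fractions (deterministic given `config$seed`).
#'
#' @param config A [simulation_config()].
#' @param genome A [generate_genome()] result.
#' @return Data frame (`"ground_truth"`) with `gene_id`, `role`, and the
#'   selection parameters applied to each gene (`sigma`, `beta`).
#' @export
assign_gene_roles <- function(config, genome) {
  set.seed(config$seed + 1L)
  ids <- names(genome$models)
  n <- length(ids)
  n_ess <- round(config$fraction_essential * n)
  n_tsg <- round(config$fraction_tsg * n)
  shuffled <- sample(ids)
  role <- stats::setNames(rep("neutral", n), ids)
  role[shuffled[seq_len(n_ess)]] <- "essential"
  if (n_tsg > 0) role[shuffled[n_ess + seq_len(n_tsg)]] <- "tsg"
  out <- data.frame(gene_id = ids, role = unname(role[ids]),
                    sigma = ifelse(role[ids] == "essential",
                                   config$selection_strength, 0),
                    beta = ifelse(role[ids] == "tsg", config$tsg_boost, 0))
  class(out) <- c("ground_truth", "data.frame")
  rownames(out) <- NULL
  out
}

.make_samples <- function(config) {
  cancers <- paste0("C", LETTERS[seq_len(config$n_cancers)])
  samples <- unlist(lapply(cancers, function(ct)
    sprintf("%s_S%03d", ct, seq_len(config$samples_per_cancer))))
  list(cancers = cancers,
       samples = samples,
       cancer_of = stats::setNames(rep(cancers,
                                       each = config$samples_per_cancer),
                                   samples))
}

#' Generate a synthetic tumor cohort
#'
#' Draws, per sample and gene, a copy-number state; draws candidate
#' substitutions from the cancer-specific signature projected on each
#' gene's substitution universe; applies the copy-number-dependent selection
#' rule of the configured gene roles (see the module description above);
#' and adds expression, methylation and benchmark-list layers. Deterministic
#' given the config seed.
#'
#' @param config A [simulation_config()].
#' @param genome A [generate_genome()] result.
#' @param truth Optional [assign_gene_roles()] result (generated when
#'   omitted).
#' @return Object of class `"synthetic_cohort"`: list with `mutations`,
#'   `cn`, `expression`, `methylation`, `signatures` (the true generating
#'   signatures), `benchmarks` (yeast_essential / crispr_w / crispr_h / gts
#'   gene lists), `truth`, `genome` and `config`.
#' @export
generate_cohort <- function(config, genome, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genome, "synthetic_genome"))
  if (is.null(truth)) truth <- assign_gene_roles(config, genome)
  set.seed(config$seed + 2L)
  sm <- .make_samples(config)
  genes <- names(genome$models)
  ng <- length(genes); ns <- length(sm$samples)

  signatures <- config$signatures
  if (is.null(signatures)) {
    signatures <- stats::setNames(lapply(sm$cancers, function(ct) {
      w <- stats::rgamma(96, shape = config$signature_concentration)
      stats::setNames(w / sum(w), context_class_labels())
    }), sm$cancers)
  }

  # copy-number states: -2 HoZD | -1 HeZD (per-gene probability) | 0 | 1/2 Amp
  ph <- stats::runif(ng, config$hezd_prob[1], config$hezd_prob[2])
  u <- matrix(stats::runif(ng * ns), nrow = ng)
  cn <- matrix(0L, nrow = ng, ncol = ns, dimnames = list(genes, sm$samples))
  cn[u < config$hozd_prob] <- -2L
  cn[u >= config$hozd_prob & u < config$hozd_prob + ph] <- -1L
  cn[u >= 1 - config$amp_prob / 2] <- 2L
  cn[u >= 1 - config$amp_prob & u < 1 - config$amp_prob / 2] <- 1L

  role <- stats::setNames(truth$role, truth$gene_id)
  # The configured signature is a target observed spectrum, so per-site
  # hazards are the class weight divided by the genome-wide opportunity
  # count of that class (classes absent from the genome cannot mutate).
  # Per-gene candidate rates scale with the gene's total hazard, so that
  # mutation-prone genes collect proportionally more mutations and the
  # cohort-wide spectrum converges to the configured signature.
  Nk <- rep(0L, 96L)
  for (g in genes)
    Nk <- Nk + tabulate(genome$enum[[g]]$context_class + 1L, 96L)
  inv_opp <- ifelse(Nk > 0L, 1 / Nk, 0)
  site_hazard <- function(g, ct) {
    ctx <- genome$enum[[g]]$context_class + 1L
    as.numeric(signatures[[ct]])[ctx] * inv_opp[ctx]
  }
  hazard <- vapply(sm$cancers, function(ct)
    vapply(genes, function(g) sum(site_hazard(g, ct)), numeric(1)),
    numeric(length(genes)))
  dim(hazard) <- c(length(genes), length(sm$cancers))
  dimnames(hazard) <- list(genes, sm$cancers)
  hazard <- sweep(hazard, 2, colMeans(hazard), "/")
  acc <- list(sample_id = list(), cancer_type = list(), gene_id = list(),
              cds_pos = list(), ref = list(), alt = list())
  k <- 0L
  for (g in genes) {
    en <- genome$enum[[g]]
    mat <- genome$impacts[[g]]
    imp_all <- mat[cbind(match(en$alt, BASES), en$cds_pos)]
    for (ct in sm$cancers) {
      w <- site_hazard(g, ct)
      if (sum(w) <= 0) next
      n_cand <- stats::rpois(1L, config$samples_per_cancer *
                               config$mutation_rate * hazard[g, ct])
      if (n_cand == 0L) next
      j <- sample.int(nrow(en), n_cand, replace = TRUE, prob = w)
      smp <- sample(sm$samples[sm$cancer_of == ct], n_cand, replace = TRUE)
      st <- cn[g, smp]
      if (role[g] == "tsg" && config$tsg_boost > 0 && any(st == -1L)) {
        hez <- which(st == -1L)
        wt <- w * (1 + config$tsg_boost * imp_all / 40)
        j[hez] <- sample.int(nrow(en), length(hez), replace = TRUE,
                             prob = wt)
      }
      imp <- imp_all[j]
      p_keep <- rep(1, n_cand)
      if (role[g] == "essential")
        p_keep[st == -1L] <- 1 - config$selection_strength *
          imp[st == -1L] / 40
      keep <- stats::runif(n_cand) < p_keep
      if (!any(keep)) next
      k <- k + 1L
      acc$sample_id[[k]] <- smp[keep]
      acc$cancer_type[[k]] <- rep(ct, sum(keep))
      acc$gene_id[[k]] <- rep(g, sum(keep))
      acc$cds_pos[[k]] <- en$cds_pos[j[keep]]
      acc$ref[[k]] <- en$ref[j[keep]]
      acc$alt[[k]] <- en$alt[j[keep]]
    }
  }
  mutations <- data.frame(sample_id = unlist(acc$sample_id),
                          cancer_type = unlist(acc$cancer_type),
                          gene_id = unlist(acc$gene_id),
                          cds_pos = unlist(acc$cds_pos),
                          ref = unlist(acc$ref), alt = unlist(acc$alt),
                          variant_kind = "substitution")

  expressed <- matrix(stats::runif(ng * config$n_cancers) <
                        config$fraction_expressed, nrow = ng)
  expression <- matrix(stats::runif(ng * config$n_cancers, 0,
                                    config$unexpressed_max),
                       nrow = ng, dimnames = list(genes, sm$cancers))
  nexp <- sum(expressed)
  expression[expressed] <- stats::rlnorm(nexp, config$expressed_meanlog,
                                         config$expressed_sdlog)

  meth <- do.call(rbind, lapply(c("TSS", "CDS"), function(region) {
    hp <- if (region == "TSS") config$tss_hyper_prob else config$cds_hyper_prob
    hyper <- stats::runif(ng * ns) < hp
    beta <- numeric(ng * ns)
    beta[!hyper] <- stats::rbeta(sum(!hyper), config$meth_baseline_shape[1],
                                 config$meth_baseline_shape[2])
    beta[hyper] <- stats::rbeta(sum(hyper), config$meth_hyper_shape[1],
                                config$meth_hyper_shape[2])
    data.frame(probe_id = paste0(rep(genes, times = ns), "_", region),
               gene_id = rep(genes, times = ns), region = region,
               sample_id = rep(sm$samples, each = ng),
               beta = pmin(pmax(beta, 0), 1))
  }))

  essential <- truth$gene_id[truth$role == "essential"]
  rest <- setdiff(genes, essential)
  noisy_list <- function() {
    hits <- essential[stats::runif(length(essential)) <
                        config$benchmark_sensitivity]
    fp <- rest[stats::runif(length(rest)) < config$benchmark_false_rate]
    sort(c(hits, fp))
  }
  benchmarks <- list(yeast_essential = noisy_list(),
                     crispr_w = noisy_list(), crispr_h = noisy_list(),
                     gts = noisy_list())

  structure(list(mutations = mutations, cn = cn, expression = expression,
                 methylation = meth, signatures = signatures,
                 benchmarks = benchmarks, truth = truth, genome = genome,
                 config = config),
            class = "synthetic_cohort")
}

#' Tiny deterministic worked fixture
#'
#' A hand-built 2-cancer, 20-gene, 60-sample cohort whose counts are
#' directly checkable: gene G001 carries exactly 10 HeZD and 10 CNN
#' mutations (enters the screen at the default filter), G002 carries 9
#' HeZD mutations (excluded at the boundary), G005 carries 11/11, G003
#' carries a 12-mutation positional cluster plus 8 dispersed mutations,
#' G004 is unexpressed in cancer CA (its mutations are excluded), and G007
#' has median expression exactly at the 200 threshold (not expressed, the
#' filter being strict). Sequences and impact scores come from the genome
#' generator at a fixed seed; all mutation placements are deterministic.
#'
#' @return A `"synthetic_cohort"`-like list with `genome`, `mutations`,
#'   `cn`, `expression`, `methylation`, `gene_sets`, `benchmarks`, `truth`.
#' @export
worked_fixture <- function() {
  config <- simulation_config(seed = 424242L, n_cancers = 2L,
                              samples_per_cancer = 30L, n_genes = 20L,
                              cds_codons = c(60L, 120L), mutation_rate = 0)
  genome <- generate_genome(config)
  genes <- names(genome$models)
  sm <- .make_samples(config)
  cn <- matrix(0L, nrow = length(genes), ncol = length(sm$samples),
               dimnames = list(genes, sm$samples))

  # first enumerated substitution at a position (rows are position-major)
  sub_at <- function(g, pos, nth = 1L)
    genome$enum[[g]][(pos - 1L) * 3L + nth, , drop = FALSE]
  mut_rows <- function(g, pos, samples, nth = 1L) {
    do.call(rbind, Map(function(p, s, k) {
      e <- sub_at(g, p, k)
      data.frame(sample_id = s, cancer_type = unname(sm$cancer_of[s]),
                 gene_id = g, cds_pos = e$cds_pos, ref = e$ref, alt = e$alt,
                 variant_kind = "substitution")
    }, pos, samples, rep_len(nth, length(pos))))
  }

  muts <- list()
  # G001: exactly 10 HeZD + 10 CNN mutations, distinct positions, cancer CA
  cn["G001", sprintf("CA_S%03d", 1:10)] <- -1L
  muts$g1h <- mut_rows("G001", seq(3, 30, by = 3), sprintf("CA_S%03d", 1:10))
  muts$g1c <- mut_rows("G001", seq(33, 60, by = 3), sprintf("CA_S%03d", 11:20))
  # G002: 9 HeZD + 12 CNN (below the >=10 HeZD bound)
  cn["G002", sprintf("CA_S%03d", 1:9)] <- -1L
  muts$g2h <- mut_rows("G002", seq(3, 27, by = 3), sprintf("CA_S%03d", 1:9))
  muts$g2c <- mut_rows("G002", seq(30, 63, by = 3), sprintf("CA_S%03d", 11:22))
  # G003: positional cluster (12 hits at cds_pos 9) + 8 dispersed, cancer CB
  muts$g3cl <- mut_rows("G003", rep(9L, 12), sprintf("CB_S%03d", 1:12))
  muts$g3bg <- mut_rows("G003", seq(12, 33, by = 3), sprintf("CB_S%03d", 13:20))
  # G004: 10/10 but unexpressed in CA
  cn["G004", sprintf("CA_S%03d", 1:10)] <- -1L
  muts$g4h <- mut_rows("G004", seq(3, 30, by = 3), sprintf("CA_S%03d", 1:10))
  muts$g4c <- mut_rows("G004", seq(33, 60, by = 3), sprintf("CA_S%03d", 11:20))
  # G005: 11 HeZD + 11 CNN, split over both cancers
  cn["G005", c(sprintf("CA_S%03d", 21:30), "CB_S001")] <- -1L
  muts$g5h <- mut_rows("G005", seq(3, 33, by = 3),
                       c(sprintf("CA_S%03d", 21:30), "CB_S001"))
  muts$g5c <- mut_rows("G005", seq(36, 66, by = 3), sprintf("CB_S%03d", 2:12))
  # G006: co-mutation partner; non-silent mutations in samples CA_S001..005
  en6 <- genome$enum[["G006"]]
  en6 <- en6[en6$mclass != "silent", ]
  en6 <- en6[!duplicated(en6$cds_pos), ][1:5, ]
  muts$g6 <- data.frame(sample_id = sprintf("CA_S%03d", 1:5),
                        cancer_type = "CA", gene_id = "G006",
                        cds_pos = en6$cds_pos, ref = en6$ref, alt = en6$alt,
                        variant_kind = "substitution")
  # background mutations for the remaining genes
  for (g in sprintf("G%03d", 8:20))
    muts[[g]] <- mut_rows(g, c(3L, 9L), sprintf("CB_S%03d", 21:22))
  mutations <- do.call(rbind, muts)
  rownames(mutations) <- NULL

  cn["G008", "CB_S020"] <- -2L
  cn["G001", sprintf("CA_S%03d", 26:28)] <- 1L

  expression <- matrix(1000, nrow = length(genes), ncol = 2,
                       dimnames = list(genes, sm$cancers))
  expression["G004", "CA"] <- 100
  expression["G007", ] <- 200

  methylation <- data.frame(
    probe_id = c("p1", "p1", "p1", "p1", "p2", "p2", "p3"),
    gene_id = c("G001", "G001", "G001", "G001", "G001", "G001", "G002"),
    region = c("TSS", "TSS", "TSS", "TSS", "CDS", "CDS", "TSS"),
    sample_id = c("CA_S001", "CA_S002", "CA_S003", "CA_S004", "CA_S001",
                  "CA_S002", "CA_S001"),
    beta = c(0.71, 0.70, 0.50, 0.90, 0.20, 0.80, 0.10))

  truth <- data.frame(gene_id = genes, role = "neutral", sigma = 0, beta = 0)
  truth$role[truth$gene_id %in% c("G001", "G005")] <- "essential"
  truth$role[truth$gene_id == "G010"] <- "tsg"
  class(truth) <- c("ground_truth", "data.frame")

  list(genome = genome, mutations = mutations, cn = cn,
       expression = expression, methylation = methylation,
       gene_sets = list(RNA_COMPLEX = c("G001", "G005", "G003"),
                        OTHER_SET = c("G002", "G008", "G009")),
       benchmarks = list(yeast_essential = c("G001", "G005"),
                         crispr_w = c("G001", "G005", "G012")),
       truth = truth, config = config)
}
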