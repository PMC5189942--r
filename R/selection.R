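# Core selection statistics: clustered-mutation filter, signature-weighted
# dN/dS with one-sided Fisher test, null impact-score distribution and the
# [-1, 1] normalized impact score.

#' Exact/approximate two-sample Wilcoxon rank-sum test
#'
#' One- or two-sided Mann-Whitney/Wilcoxon rank-sum test. When the number of
#' group assignments `choose(n1 + n2, n1)` does not exceed `exact_max`, the
#' p-value is computed by full permutation enumeration with midranks, which
#' stays exact in the presence of ties; otherwise the normal approximation
#' with tie correction and continuity correction is used. `alternative =
#' "less"` tests whether `x` is stochastically smaller than `y`.
#'
#' @param x,y Numeric vectors.
#' @param alternative `"less"`, `"greater"` or `"two.sided"`.
#' @param exact_max Enumeration budget (number of assignments) for the exact
#'   branch.
#' @return List with `statistic` (rank sum of `x`), `p.value` and `exact`
#'   (logical).
#' @export
rank_sum_test <- function(x, y, alternative = c("less", "greater", "two.sided"),
                          exact_max = 100000) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  nc <- choose(N, n1)
  if (nc <= exact_max) {
    cmb <- utils::combn(N, n1)
    sums <- colSums(matrix(r[cmb], nrow = n1))
    eps <- 1e-8
    p_le <- sum(sums <= W + eps) / nc
    p_ge <- sum(sums >= W - eps) / nc
    p <- switch(alternative,
                less = p_le,
                greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    return(list(statistic = W, p.value = p, exact = TRUE))
  }
  mu <- n1 * (N + 1) / 2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(list(statistic = W, p.value = 1, exact = FALSE))
  sd <- sqrt(sig2)
  p <- switch(alternative,
              less = stats::pnorm((W - mu + 0.5) / sd),
              greater = stats::pnorm((W - mu - 0.5) / sd,
                                     lower.tail = FALSE),
              two.sided = {
                z <- (abs(W - mu) - 0.5) / sd
                min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
              })
  list(statistic = W, p.value = p, exact = FALSE)
}

#' Remove positionally clustered mutations
#'
#' Mutation clusters at single CDS positions are a hallmark of positive
#' selection (and of sequencing artefacts) and would bias a screen for
#' purifying selection. For every gene, with `m` total mutations pooled over
#' the cohort and CDS length `L`, each position carrying `k >= 2` mutations
#' gets a binomial tail probability `p = P(X >= k)`, `X ~ Binomial(m, 1/L)`.
#' All mutations at positions with `p <= alpha` are removed in a single pass.
#'
#' @param annotated Annotated mutation table.
#' @param genes Named list of [gene_model()] objects; every mutated gene
#'   needs a model.
#' @param alpha Flagging threshold on the binomial tail (default 0.01).
#' @return List with `mutations` (filtered table) and `flags` (audit table:
#'   one row per multi-hit position with `gene_id`, `cds_pos`, `k`, `m`, `L`,
#'   `p`, `flagged`).
#' @export
remove_clustered <- function(annotated, genes, alpha = 0.01) {
  x <- annotated
  n <- nrow(x)
  drop <- rep(FALSE, n)
  flags <- list()
  for (g in unique(x$gene_id)) {
    gm <- genes[[g]]
    if (is.null(gm)) stop("no gene model for '", g, "'")
    L <- cds_length(gm)
    idx <- which(x$gene_id == g)
    m <- length(idx)
    tab <- table(x$cds_pos[idx])
    multi <- tab[tab >= 2L]
    if (!length(multi)) next
    k <- as.integer(multi)
    p <- stats::pbinom(k - 1L, m, 1 / L, lower.tail = FALSE)
    flagged <- p <= alpha
    flags[[g]] <- data.frame(gene_id = g,
                             cds_pos = as.integer(names(multi)),
                             k = k, m = m, L = L, p = p, flagged = flagged)
    if (any(flagged)) {
      bad_pos <- as.integer(names(multi))[flagged]
      drop[idx[x$cds_pos[idx] %in% bad_pos]] <- TRUE
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(gene_id = character(0), cds_pos = integer(0), k = integer(0),
               m = integer(0), L = integer(0), p = numeric(0),
               flagged = logical(0))
  rownames(flags) <- NULL
  out <- x[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(mutations = out, flags = flags)
}

.site_probs <- function(gene, signature, enum) {
  w <- as.numeric(signature)[enum$context_class + 1L]
  tot <- sum(w)
  if (tot <= 0)
    stop("gene ", gene$gene_id,
         ": signature puts zero weight on every possible substitution")
  w / tot
}

#' Expected silent and non-silent site counts (analytic)
#'
#' Closed-form expectation of the signature-weighted site simulation: with
#' per-substitution probabilities `p_j` over the gene's `3L` substitutions,
#' `S = 3L * sum(p_j, j silent)` and `N = 3L - S`. `N + S == 3L` exactly.
#'
#' @inheritParams class_weight_per_site
#' @return List with expected non-silent sites `N` and silent sites `S`.
#' @export
expected_sites_analytic <- function(gene, signature, enum = NULL) {
  if (is.null(enum)) enum <- enumerate_substitutions(gene)
  p <- .site_probs(gene, signature, enum)
  L3 <- nrow(enum)
  S <- L3 * sum(p[enum$mclass == "silent"])
  list(N = L3 - S, S = S)
}

#' Expected silent and non-silent site counts (sampled)
#'
#' Monte-Carlo counterpart of [expected_sites_analytic()]: `n_draws`
#' substitutions are drawn with the per-substitution probabilities and the
#' silent/non-silent class frequencies are scaled back to `3L` sites. The
#' estimate converges to the analytic value; at 10^6 draws the relative
#' error is well below 1%.
#'
#' @inheritParams expected_sites_analytic
#' @param n_draws Number of draws (default 10^6).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `N`, `S` and `n_draws`.
#' @export
expected_sites_sampled <- function(gene, signature, n_draws = 1e6,
                                   seed = NULL, enum = NULL) {
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(enum)) enum <- enumerate_substitutions(gene)
  p <- .site_probs(gene, signature, enum)
  L3 <- nrow(enum)
  counts <- as.vector(stats::rmultinom(1L, as.integer(n_draws), p))
  S <- L3 * sum(counts[enum$mclass == "silent"]) / n_draws
  list(N = L3 - S, S = S, n_draws = as.integer(n_draws))
}

#' Signature-weighted dN/dS for one gene (and copy-number state)
#'
#' dN/dS is the ratio of non-silent to silent mutations per site:
#' `(n/N) / (s/S)`, with observed counts `n` (non-silent substitutions) and
#' `s` (silent substitutions) and expected site counts `N`, `S` from the
#' signature-weighted substitution universe (analytic by default, or the
#' 10^6-draw sampling procedure). Values below 1 indicate purifying
#' selection. A one-sided Fisher's exact test on the 2x2 table
#' `[[n, s], [round(N), round(S)]]` (alternative: deficit of non-silent
#' mutations) tests dN/dS < 1.
#'
#' @param annotated Annotated mutations of one gene (and typically one
#'   copy-number state); indels are ignored, as dN/dS is substitution-based.
#' @param gene The [gene_model()].
#' @param signature 96-class signature used as the site prior.
#' @param mode `"analytic"` (default) or `"sampled"`.
#' @inheritParams expected_sites_sampled
#' @return Object of class `"dnds_result"`: list with `n`, `s`, `N`, `S`,
#'   `dnds` (`NA` when `s == 0` or `S == 0`), `fisher_p`, `n_draws`, `mode`,
#'   `note`.
#' @export
dnds <- function(annotated, gene, signature,
                 mode = c("analytic", "sampled"), n_draws = 1e6,
                 seed = NULL, enum = NULL) {
  mode <- match.arg(mode)
  if (is.null(enum)) enum <- enumerate_substitutions(gene)
  subs <- annotated[annotated$variant_kind == "substitution", , drop = FALSE]
  n <- sum(subs$mclass != "silent")
  s <- sum(subs$mclass == "silent")
  es <- if (mode == "analytic")
    expected_sites_analytic(gene, signature, enum = enum)
  else
    expected_sites_sampled(gene, signature, n_draws = n_draws, seed = seed,
                           enum = enum)
  note <- NA_character_
  val <- NA_real_
  if (s == 0L || es$S <= 0) {
    note <- "undefined ratio: no silent observations or expected silent sites"
  } else {
    val <- (n / es$N) / (s / es$S)
  }
  Nr <- round(es$N); Sr <- round(es$S)
  fisher_p <- if ((n + s) > 0 && (Nr + Sr) > 0)
    stats::fisher.test(matrix(c(n, s, Nr, Sr), nrow = 2, byrow = TRUE),
                       alternative = "less")$p.value
  else NA_real_
  structure(list(n = n, s = s, N = es$N, S = es$S, dnds = val,
                 fisher_p = fisher_p,
                 n_draws = if (mode == "sampled") as.integer(n_draws) else NA_integer_,
                 mode = mode, note = note),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dN/dS = %s  (n=%d, s=%d, N=%.1f, S=%.1f; one-sided Fisher p = %s; %s)\n",
              format(x$dnds, digits = 3), x$n, x$s, x$N, x$S,
              format(x$fisher_p, digits = 3), x$mode))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# lower weighted median: smallest x with cumulative weight >= 1/2
.weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5 - 1e-12)[1]]
}

#' Null (no-selection) impact-score distribution for a gene
#'
#' Under no selection, the impact score of a random mutation in a gene is
#' distributed as the impact scores of all `3L` possible substitutions
#' weighted by their signature probabilities. The analytic mode returns that
#' exact weighted distribution and its weighted median (`median_sim`, the
#' simulated-null median used for score normalization); the sampled mode
#' reproduces the 10^6-draw sampling procedure.
#'
#' @inheritParams dnds
#' @param impacts An [impact_table()] covering the gene.
#' @return List with `scores` (length `3L`), `weights` (summing to 1),
#'   `median_sim` and `mode`.
#' @export
null_score_distribution <- function(gene, signature, impacts,
                                    mode = c("analytic", "sampled"),
                                    n_draws = 1e6, seed = NULL, enum = NULL) {
  mode <- match.arg(mode)
  if (is.null(enum)) enum <- enumerate_substitutions(gene)
  mat <- impacts[[gene$gene_id]]
  if (is.null(mat))
    stop("impact table has no entries for gene '", gene$gene_id, "'")
  sc <- mat[cbind(match(enum$alt, BASES), enum$cds_pos)]
  if (anyNA(sc))
    stop("impact table does not cover every substitution of gene '",
         gene$gene_id, "'")
  p <- .site_probs(gene, signature, enum)
  if (mode == "sampled") {
    if (!is.null(seed)) set.seed(seed)
    counts <- as.vector(stats::rmultinom(1L, as.integer(n_draws), p))
    w <- counts / n_draws
  } else {
    w <- p
  }
  list(scores = sc, weights = w, median_sim = .weighted_median(sc, w),
       mode = mode)
}

#' Normalize an observed impact score against the simulated-null median
#'
#' The normalized score rescales the difference between the observed score
#' and the simulated-null median to the maximal attainable difference on
#' each side of the median, so that values in `(0, 1]` indicate positive
#' selection and values in `[-1, 0)` purifying selection:
#' `(obs - med) / (score_max - med)` when `obs >= med`, and
#' `(obs - med) / (med - score_min)` otherwise. Strictly increasing in the
#' observed score; vectorised over `impact_obs` (with `median_sim`
#' recycled).
#'
#' @param impact_obs Observed score(s) in `[score_min, score_max]`.
#' @param median_sim Simulated-null median(s), same range.
#' @param score_min,score_max Score bounds (defaults 0 and 40, the phred-like
#'   convention with silent = 0 and truncating = 40).
#' @return Numeric vector of normalized scores in `[-1, 1]`.
#' @export
normalize_score <- function(impact_obs, median_sim, score_min = 0,
                            score_max = 40) {
  if (any(median_sim < score_min | median_sim > score_max, na.rm = TRUE))
    stop("median_sim must lie within [score_min, score_max]")
  if (any(impact_obs < score_min | impact_obs > score_max, na.rm = TRUE))
    stop("impact_obs must lie within [score_min, score_max]")
  k <- pmax(length(impact_obs), length(median_sim))
  obs <- rep_len(impact_obs, k)
  med <- rep_len(median_sim, k)
  up <- score_max - med
  down <- med - score_min
  num <- obs - med
  denom <- ifelse(num >= 0, up, down)
  zero <- !is.na(denom) & denom == 0
  if (any(zero & !is.na(num) & num != 0))
    warning("zero normalization span on the required side; score set to 0")
  ifelse(zero, 0, num / denom)
}

#' One-sample test for deviation of normalized scores from zero
#'
#' One-sided Wilcoxon signed-rank test of the normalized scores against 0.
#' `side = "less"` tests for net purifying selection (scores below zero),
#' `side = "greater"` for net positive selection. Exact zeros carry no sign
#' information and are removed first (standard signed-rank practice); if
#' nothing remains the test is degenerate and p = 1 is returned with a
#' warning. For up to 15 non-zero scores the p-value is exact, by
#' enumerating all sign assignments with midranks on the absolute values
#' (which stays exact under ties); larger samples use the normal
#' approximation of [stats::wilcox.test()].
#'
#' @param scores Numeric vector of normalized scores.
#' @param side `"less"` or `"greater"`.
#' @return The p-value.
#' @export
test_normalized_deviation <- function(scores, side = c("less", "greater")) {
  side <- match.arg(side)
  if (!length(scores)) stop("at least one score is required")
  nz <- scores[scores != 0]
  if (!length(nz)) {
    warning("all scores are exactly 0; degenerate test, p = 1")
    return(1)
  }
  n <- length(nz)
  if (n <= 15L) {
    r <- rank(abs(nz))
    v_obs <- sum(r[nz > 0])
    bits <- outer(0:(2^n - 1), 2^(0:(n - 1)),
                  function(a, b) (a %/% b) %% 2)
    v_all <- as.vector(bits %*% r)
    eps <- 1e-8
    return(if (side == "less") mean(v_all <= v_obs + eps)
           else mean(v_all >= v_obs - eps))
  }
  suppressWarnings(
    stats::wilcox.test(nz, mu = 0, alternative = side)$p.value)
}

#' Pooled dN/dS across genes and cancers
#'
#' Pools observed silent/non-silent substitution counts over all
#' (gene, cancer) strata and compares them with the signature-expected
#' silent/non-silent proportions of each stratum, weighted by its mutation
#' count. Used for cohort-level neutrality checks: under no selection the
#' pooled ratio converges to 1. An approximate 95% CI is derived from the
#' Poisson variability of the observed counts
#' (`exp(log(dnds) +/- 1.96 * sqrt(1/n + 1/s))`).
#'
#' @param annotated Annotated mutation table (substitutions are used).
#' @param genes Named list of [gene_model()] objects.
#' @param signatures Named list of per-cancer signatures (names are cancer
#'   types).
#' @param enum_cache Optional named list of precomputed enumeration tables.
#' @return List with `dnds`, `n`, `s`, `N`, `S`, `ci_low`, `ci_high`.
#' @export
pooled_dnds <- function(annotated, genes, signatures, enum_cache = NULL) {
  subs <- annotated[annotated$variant_kind == "substitution", , drop = FALSE]
  if (!nrow(subs)) stop("no substitutions to pool")
  n <- sum(subs$mclass != "silent")
  s <- sum(subs$mclass == "silent")
  N <- 0; S <- 0
  strata <- unique(subs[c("gene_id", "cancer_type")])
  for (i in seq_len(nrow(strata))) {
    g <- strata$gene_id[i]; ct <- strata$cancer_type[i]
    m <- sum(subs$gene_id == g & subs$cancer_type == ct)
    enum <- if (!is.null(enum_cache)) enum_cache[[g]] else NULL
    es <- expected_sites_analytic(genes[[g]], signatures[[ct]], enum = enum)
    L3 <- es$N + es$S
    N <- N + m * es$N / L3
    S <- S + m * es$S / L3
  }
  val <- (n / N) / (s / S)
  se <- sqrt(1 / n + 1 / s)
  list(dnds = val, n = n, s = s, N = N, S = S,
       ci_low = val * exp(-1.96 * se), ci_high = val * exp(1.96 * se))
}
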