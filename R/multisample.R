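# Replicate-aware weighted DGE across multiple samples per condition,
# replacing pseudo-bulk count aggregation. Each sample s contributes its
# per-gene weighted mean n_bar_{Z,s} and the variance of that mean; samples
# are then combined with inverse-variance weights and compared across
# conditions with a Welch-type t-test.

#' Per-sample, per-gene weighted summaries
#'
#' Computes, via the weighting module, the weighted mean \eqn{\bar n_{Z,s}},
#' its variance, the effective cell count and the aggregate counts for every
#' gene of one sample.
#'
#' @param sample a [cell_group()] (one biological sample).
#' @param genes gene ids or indices (default all).
#' @param rho_mode as in [gene_profiles()].
#' @return `data.frame` of class `SampleSummary` columns: `gene`, `mean_w`,
#'   `var_mean`, `n_eff`, `agg`, `tot`, plus attribute `sample_id`. A
#'   one-cell sample yields `var_mean = NA` (undefined).
#' @export
summarize_sample <- function(sample, genes = NULL, rho_mode = "estimate") {
  gc <- group_counts(sample, drop_zero_totals = TRUE, warn = FALSE)
  ids <- sample$matrix$gene_ids
  gi <- if (is.null(genes)) seq_along(ids)
        else if (is.character(genes)) match(genes, ids) else as.integer(genes)
  if (ncol(gc$counts) == 1L) {
    x1 <- unname(as.numeric(gc$counts[gi, 1]))
    out <- data.frame(gene = ids[gi], mean_w = x1 / unname(gc$totals),
                      var_mean = NA_real_, n_eff = 1, agg = x1,
                      tot = unname(gc$totals), stringsAsFactors = FALSE,
                      row.names = NULL)
  } else {
    out <- gene_profiles(sample, genes = gi, rho_mode = rho_mode)
  }
  attr(out, "sample_id") <- sample$label
  class(out) <- c("SampleSummary", class(out))
  out
}

# Align a list of SampleSummary on a common gene vector; returns matrices
# genes x samples of means, variances, aggregates and totals.
#' @keywords internal
#' @noRd
stack_summaries <- function(summaries, genes) {
  S <- length(summaries)
  M <- V <- A <- TT <- matrix(NA_real_, length(genes), S)
  for (s in seq_len(S)) {
    idx <- match(genes, summaries[[s]]$gene)
    if (anyNA(idx)) stop("sample summaries do not cover the gene universe")
    M[, s] <- summaries[[s]]$mean_w[idx]
    V[, s] <- summaries[[s]]$var_mean[idx]
    A[, s] <- summaries[[s]]$agg[idx]
    TT[, s] <- summaries[[s]]$tot[idx]
  }
  list(mean = M, var = V, agg = A, tot = TT)
}

# Inverse-variance condition mean with reliability-weights variance at the
# sample level. Zero (or missing) per-sample variances are floored at 1e-3
# times the smallest positive variance in the row so weights stay finite;
# rows with no positive variance fall back to equal weights.
#' @keywords internal
#' @noRd
condition_moments <- function(M, V) {
  S <- ncol(M)
  if (S < 2) stop("at least 2 samples per condition required")
  V2 <- V
  V2[!is.finite(V2) | V2 < 0] <- 0
  minpos <- apply(V2, 1, function(v) if (any(v > 0)) min(v[v > 0]) else NA_real_)
  floorv <- minpos * 1e-3
  for (s in seq_len(S)) {
    z <- V2[, s] <= 0
    V2[z, s] <- floorv[z]
  }
  W <- 1 / V2
  W[!is.finite(W)] <- 1          # rows where every variance was zero
  W <- W / rowSums(W)
  m <- rowSums(W * M)
  sw2 <- rowSums(W^2)
  q <- rowSums(W * (M - m)^2)
  list(mean = m, var_mean = q / (S - 1), n_eff = 1 / sw2)
}

#' Weighted t-test across samples
#'
#' Condition means are inverse-variance weighted averages of the per-sample
#' weighted means \eqn{\bar n_{Z,s}}; the between-sample variance of each
#' condition mean uses the same reliability-weights estimator as
#' [weighted_mean_variance()], applied at the sample level; the two
#' conditions are compared by a Welch-type two-tailed t with per-condition
#' degrees of freedom `n_eff(samples) - 1` (equal to S - 1 at equal weights,
#' smaller - hence conservative - when weights concentrate).
#'
#' @param cond_a,cond_b lists of [summarize_sample()] outputs (>= 2 each).
#' @param genes gene universe (default: genes common to all samples).
#' @return `data.frame`: `gene`, `mean_A`, `mean_B`, `log2fc`, `t`, `df`,
#'   `p`.
#' @export
weighted_t_across_samples <- function(cond_a, cond_b, genes = NULL) {
  if (length(cond_a) < 2 || length(cond_b) < 2)
    stop("at least 2 samples per condition required")
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(c(cond_a, cond_b), function(s) s$gene))
    genes <- sort(genes)
  }
  A <- stack_summaries(cond_a, genes)
  B <- stack_summaries(cond_b, genes)
  ca <- condition_moments(A$mean, A$var)
  cb <- condition_moments(B$mean, B$var)
  wt <- welch_from_moments(ca$mean, ca$var_mean, ca$n_eff,
                           cb$mean, cb$var_mean, cb$n_eff)
  data.frame(gene = genes, mean_A = ca$mean, mean_B = cb$mean,
             log2fc = log2_fold_change(ca$mean, cb$mean),
             t = wt$t, df = wt$df, p = wt$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate-count t-tests across samples (comparators)
#'
#' Pseudo-bulk-style comparators: the per-sample statistic is the aggregate
#' ratio \eqn{r_s = \sum_i X_{Z,i}/\sum_i N_i}. `p_aggr_t` is the unweighted
#' Welch t across samples; `p_aggr_wt` is the weighted variant with sample
#' weights proportional to the inverse binomial variance
#' \eqn{r(1-r)/T_s} of the aggregate ratio.
#'
#' @param cond_a,cond_b lists of [summarize_sample()] outputs.
#' @param genes gene universe (default: common genes).
#' @return `data.frame`: `gene`, `p_aggr_t`, `p_aggr_wt`.
#' @export
aggregate_count_tests <- function(cond_a, cond_b, genes = NULL) {
  if (length(cond_a) < 2 || length(cond_b) < 2)
    stop("at least 2 samples per condition required")
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(c(cond_a, cond_b), function(s) s$gene))
    genes <- sort(genes)
  }
  A <- stack_summaries(cond_a, genes)
  B <- stack_summaries(cond_b, genes)
  ra <- A$agg / A$tot
  rb <- B$agg / B$tot
  # unweighted Welch t on sample-level ratios
  Sa <- ncol(ra); Sb <- ncol(rb)
  mu_a <- rowMeans(ra); mu_b <- rowMeans(rb)
  va <- apply(ra, 1, stats::var); vb <- apply(rb, 1, stats::var)
  unw <- welch_from_moments(mu_a, va / Sa, Sa, mu_b, vb / Sb, Sb)
  # weighted on the same ratios, weights ~ inverse binomial variance
  bva <- ra * (1 - ra) / A$tot
  bvb <- rb * (1 - rb) / B$tot
  caw <- condition_moments(ra, bva)
  cbw <- condition_moments(rb, bvb)
  wt <- welch_from_moments(caw$mean, caw$var_mean, caw$n_eff,
                           cbw$mean, cbw$var_mean, cbw$n_eff)
  data.frame(gene = genes, p_aggr_t = unw$p, p_aggr_wt = wt$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-sample weighted DGE
#'
#' Full replicate-aware pipeline: per-sample weighted summaries, weighted
#' t-test across samples, and the aggregate-count comparators.
#'
#' @param samples named list of [cell_group()]s (one per sample).
#' @param conditions named character vector mapping sample id to one of two
#'   condition labels; condition A is the first level encountered.
#' @param config a [dge_config()] (filters and rho mode; comparators flag
#'   controls the aggregate tests).
#' @return `data.frame`: `gene, mean_A, mean_B, log2fc, p_wt_samples,
#'   p_aggr_t, p_aggr_wt, n_samples_A, n_samples_B`.
#' @export
run_dge_multisample <- function(samples, conditions, config = dge_config()) {
  stopifnot(length(samples) >= 4, !is.null(names(samples)))
  conditions <- conditions[names(samples)]
  if (anyNA(conditions)) stop("conditions must name every sample")
  lev <- unique(unname(conditions))
  if (length(lev) != 2) stop("exactly two conditions required")
  if (!is.null(config$genes)) {
    gi_ids <- if (is.character(config$genes)) config$genes
              else samples[[1]]$matrix$gene_ids[config$genes]
  } else {
    gi <- filter_genes_min_total(samples[[1]]$matrix, samples, config$min_total)
    gi_ids <- names(gi)
  }
  gi_ids <- sort(gi_ids)
  summ <- lapply(samples, summarize_sample, genes = gi_ids,
                 rho_mode = config$rho_mode)
  cond_a <- summ[conditions == lev[1]]
  cond_b <- summ[conditions == lev[2]]
  wt <- weighted_t_across_samples(cond_a, cond_b, genes = gi_ids)
  out <- data.frame(gene = wt$gene, mean_A = wt$mean_A, mean_B = wt$mean_B,
                    log2fc = wt$log2fc, p_wt_samples = wt$p,
                    p_aggr_t = NA_real_, p_aggr_wt = NA_real_,
                    n_samples_A = length(cond_a), n_samples_B = length(cond_b),
                    stringsAsFactors = FALSE)
  if (isTRUE(config$comparators)) {
    agg <- aggregate_count_tests(cond_a, cond_b, genes = gi_ids)
    out$p_aggr_t <- agg$p_aggr_t
    out$p_aggr_wt <- agg$p_aggr_wt
  }
  out
}
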