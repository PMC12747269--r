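# Two-group differential expression: weighted t-test, aggregate chi-squared
# test, p-value combination rules, fold changes, and the comparator tests
# (Wilcoxon rank-sum, unweighted Welch t on relative or log-normalized
# counts) used in the benchmarks.

#' Weighted two-sample t-test
#'
#' Welch-type two-tailed test on weighted means. The statistic is
#' \eqn{t = (\bar n_A - \bar n_B)/\sqrt{Var(\bar n_A) + Var(\bar n_B)}} with
#' Welch–Satterthwaite degrees of freedom using the Kish effective sample
#' sizes: \eqn{df = (v_A + v_B)^2 / (v_A^2/(n_{eff,A}-1) + v_B^2/(n_{eff,B}-1))}.
#'
#' Both profiles may be single [gene_profile()] objects or aligned
#' data.frames from [gene_profiles()] (vectorised over rows).
#'
#' @param profile_a,profile_b profiles with `mean_w`, `var_mean`, `n_eff`.
#' @return `data.frame` with columns `t`, `df`, `p`. When both variances are
#'   zero: `p = 1` for equal means, `p = 0` (degenerate) otherwise.
#' @export
weighted_t_test <- function(profile_a, profile_b) {
  ma <- profile_a$mean_w; mb <- profile_b$mean_w
  va <- profile_a$var_mean; vb <- profile_b$var_mean
  na <- profile_a$n_eff; nb <- profile_b$n_eff
  welch_from_moments(ma, va, na, mb, vb, nb)
}

# Shared Welch machinery on (mean, variance-of-mean, effective n) triples.
#' @keywords internal
#' @noRd
welch_from_moments <- function(ma, va, na, mb, vb, nb) {
  vsum <- va + vb
  tt <- ifelse(vsum > 0, (ma - mb) / sqrt(vsum), 0)
  dfa <- pmax(na - 1, .Machine$double.eps)
  dfb <- pmax(nb - 1, .Machine$double.eps)
  df <- vsum^2 / (va^2 / dfa + vb^2 / dfb)
  p <- ifelse(vsum > 0, 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
              ifelse(ma == mb, 1, 0))
  tt[vsum <= 0 & ma != mb] <- ifelse(ma > mb, Inf, -Inf)[vsum <= 0 & ma != mb]
  data.frame(t = tt, df = df, p = p)
}

#' Aggregate-count chi-squared test
#'
#' Pearson chi-squared (df = 1, no continuity correction) on the 2x2 table
#' of gene vs non-gene aggregate counts in the two groups:
#' `[[X_A, T_A - X_A], [X_B, T_B - X_B]]`. This test accounts only for the
#' stochastic transcript-sampling variance in the sequenced cells, not for
#' cell-to-cell expression variance, and should never be used alone.
#'
#' @param agg_a,agg_b aggregate gene counts X per group (vectorised).
#' @param tot_a,tot_b aggregate total counts T per group.
#' @return Two-sided p-values; `NA` where an expected count is zero (gene
#'   absent from, or constituting all of, both groups).
#' @export
chi2_aggregate_test <- function(agg_a, tot_a, agg_b, tot_b) {
  if (any(tot_a <= 0) || any(tot_b <= 0)) stop("totals must be positive")
  if (any(agg_a > tot_a) || any(agg_b > tot_b)) stop("aggregate exceeds total")
  n <- tot_a + tot_b
  x <- agg_a + agg_b
  num <- (agg_a * (tot_b - agg_b) - agg_b * (tot_a - agg_a))^2 * n
  den <- tot_a * tot_b * x * (n - x)
  p <- rep(NA_real_, length(num))
  ok <- den > 0
  p[ok] <- stats::pchisq(num[ok] / den[ok], df = 1, lower.tail = FALSE)
  p
}

#' P-value combination policy
#' @param mode `"proxy"`: substitute the chi-squared p-value for the weighted
#'   t one when the former but not the latter exceeds `alpha_min`
#'   (moderately conservative); `"max"`: the larger of the two p-values
#'   (most conservative).
#' @param alpha_min significance floor in `(0, 1)`.
#' @export
combination_policy <- function(mode = c("proxy", "max"), alpha_min = 0.05) {
  mode <- match.arg(mode)
  stopifnot(alpha_min > 0, alpha_min < 1)
  structure(list(mode = mode, alpha_min = alpha_min), class = "CombinationPolicy")
}

#' Combine weighted-t and chi-squared p-values
#'
#' @param p_wt,p_chi2 p-values (vectorised); `NA` in `p_chi2` falls back to
#'   `p_wt`.
#' @param policy a [combination_policy()].
#' @export
combine_pvalues <- function(p_wt, p_chi2, policy = combination_policy()) {
  stopifnot(inherits(policy, "CombinationPolicy"))
  out <- if (policy$mode == "max") pmax(p_wt, p_chi2) else
    ifelse(p_chi2 >= policy$alpha_min & p_wt < policy$alpha_min, p_chi2, p_wt)
  ifelse(is.na(p_chi2), p_wt, out)
}

#' Log2 fold change of mean expression
#' @param mean_a,mean_b non-negative means (vectorised).
#' @return `log2(mean_a/mean_b)`; `Inf`/`-Inf` when exactly one mean is 0,
#'   `NA` when both are 0.
#' @export
log2_fold_change <- function(mean_a, mean_b) {
  out <- log2(mean_a / mean_b)
  out[mean_a == 0 & mean_b == 0] <- NA_real_
  out
}

# ---- comparator tests (vectorised across genes) ----

# row means and unbiased row variances of a sparse matrix
#' @keywords internal
#' @noRd
row_moments <- function(m) {
  n <- ncol(m)
  s1 <- Matrix::rowSums(m)
  s2 <- Matrix::rowSums(m * m)
  mu <- s1 / n
  v <- pmax(0, (s2 - n * mu^2) / (n - 1))
  list(mean = mu, var = v, n = n)
}

#' @keywords internal
#' @noRd
welch_rows <- function(ma, va, na, mb, vb, nb) {
  welch_from_moments(ma, va / na, na, mb, vb / nb, nb)
}

# Two-sided rank-sum p-values per row. Exact (via stats::pwilcox) when both
# groups are small and the row has no ties; otherwise tie-corrected normal
# approximation with continuity correction (mirrors stats::wilcox.test).
#' @keywords internal
#' @noRd
rank_sum_rows <- function(xa, xb, exact_max = 25L) {
  na <- ncol(xa); nb <- ncol(xb)
  ng <- nrow(xa)
  p <- numeric(ng)
  block <- max(1L, min(ng, as.integer(2^22 / (na + nb))))
  for (s in seq(1L, ng, by = block)) {
    e <- min(s + block - 1L, ng)
    da <- as.matrix(xa[s:e, , drop = FALSE])
    db <- as.matrix(xb[s:e, , drop = FALSE])
    for (r in seq_len(e - s + 1L)) {
      v <- c(da[r, ], db[r, ])
      rk <- rank(v)
      W <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
      ties <- any(duplicated(v))
      if (!ties && na <= exact_max && nb <= exact_max) {
        pl <- stats::pwilcox(W - 1, na, nb, lower.tail = FALSE)
        pr <- stats::pwilcox(W, na, nb)
        p[s + r - 1L] <- min(1, 2 * min(pl, pr))
      } else {
        z <- W - na * nb / 2
        tie_tab <- rle(sort.int(v, method = "radix"))$lengths
        n <- na + nb
        sigma2 <- (na * nb / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
        if (sigma2 <= 0) { p[s + r - 1L] <- 1; next }
        corr <- sign(z) * 0.5
        p[s + r - 1L] <- min(1, 2 * stats::pnorm(-abs((z - corr) / sqrt(sigma2))))
      }
    }
  }
  p
}

#' Comparator tests for a set of genes
#'
#' The standard tests benchmarked against the weighted approach:
#' unweighted Welch t on relative counts (`p_t_rc`), unweighted Welch t on
#' log-normalized counts `log(1 + 10^4 n)` (`p_t_log`, the Seurat
#' convention), and the two-sided Wilcoxon rank-sum test on relative counts
#' (`p_wilcoxon`).
#'
#' @param group_a,group_b [cell_group()]s (zero-total cells dropped).
#' @param genes gene indices or ids (default all).
#' @param scale_factor scale for log normalization (default 10000).
#' @return `data.frame` with `gene`, `mean_rc_a`, `mean_rc_b`, `p_t_rc`,
#'   `p_t_log`, `p_wilcoxon`. Rows constant in both groups get p = 1.
#' @export
comparator_tests <- function(group_a, group_b, genes = NULL,
                             scale_factor = 1e4) {
  ga <- group_counts(group_a, drop_zero_totals = TRUE)
  gb <- group_counts(group_b, drop_zero_totals = TRUE)
  ids <- group_a$matrix$gene_ids
  gi <- if (is.null(genes)) seq_along(ids)
        else if (is.character(genes)) match(genes, ids) else as.integer(genes)
  rel_a <- ga$counts[gi, , drop = FALSE] %*% Matrix::Diagonal(x = 1 / ga$totals)
  rel_b <- gb$counts[gi, , drop = FALSE] %*% Matrix::Diagonal(x = 1 / gb$totals)
  log_a <- rel_a; log_a@x <- log1p(log_a@x * scale_factor)
  log_b <- rel_b; log_b@x <- log1p(log_b@x * scale_factor)

  sa <- row_moments(rel_a); sb <- row_moments(rel_b)
  la <- row_moments(log_a); lb <- row_moments(log_b)
  t_rc <- welch_rows(sa$mean, sa$var, sa$n, sb$mean, sb$var, sb$n)
  t_log <- welch_rows(la$mean, la$var, la$n, lb$mean, lb$var, lb$n)
  p_w <- rank_sum_rows(rel_a, rel_b)
  data.frame(gene = ids[gi],
             mean_rc_a = sa$mean, mean_rc_b = sb$mean,
             p_t_rc = t_rc$p, p_t_log = t_log$p, p_wilcoxon = p_w,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' DGE run configuration
#'
#' @param min_total gene filter: keep genes with total count strictly
#'   greater than this across the compared cells (default 30).
#' @param detect_frac detection filter: keep genes detected in at least this
#'   fraction of each group's cells (default 0, i.e. off; 0.10 for spatial).
#' @param policy a [combination_policy()].
#' @param rho_mode `"estimate"` or `"zero"` (spatial/aggregate mode).
#' @param comparators run the comparator tests as well (default TRUE).
#' @param genes explicit gene universe (ids or indices) overriding the
#'   filters, e.g. a universe computed on the unmodified data in simulation
#'   benchmarks.
#' @export
dge_config <- function(min_total = 30, detect_frac = 0,
                       policy = combination_policy("proxy", 0.05),
                       rho_mode = "estimate", comparators = TRUE,
                       genes = NULL) {
  structure(list(min_total = min_total, detect_frac = detect_frac,
                 policy = policy, rho_mode = rho_mode,
                 comparators = comparators, genes = genes),
            class = "DGEConfig")
}

#' Two-group differential expression
#'
#' Runs the full per-gene pipeline: filters, per-group weight profiles
#' (ICC, weights, weighted means and variances, WDC), weighted t-test,
#' aggregate chi-squared test, combined p-value, log2 fold change, and
#' (optionally) the comparator tests.
#'
#' @param group_a,group_b [cell_group()]s over matrices with identical gene
#'   universes. The groups may come from different matrices (e.g. original
#'   vs thinned copies of the same cells in simulations).
#' @param config a [dge_config()].
#' @return `data.frame`, one row per surviving gene, ordered by gene id,
#'   with columns `gene, mean_w_A, mean_w_B, log2fc_w, rho_A, rho_B, wdc_A,
#'   wdc_B, agg_A, tot_A, agg_B, tot_B, p_wt, p_chi2, p_combined` and, when
#'   comparators are enabled, `mean_rc_A, mean_rc_B, p_t_rc, p_t_log,
#'   p_wilcoxon`.
#' @export
run_dge <- function(group_a, group_b, config = dge_config()) {
  stopifnot(inherits(group_a, "CellGroup"), inherits(group_b, "CellGroup"))
  if (!identical(group_a$matrix$gene_ids, group_b$matrix$gene_ids))
    stop("groups must share an identical gene universe")
  ids <- group_a$matrix$gene_ids
  if (!is.null(config$genes)) {
    gi <- if (is.character(config$genes)) match(config$genes, ids)
          else as.integer(config$genes)
    if (anyNA(gi)) stop("unknown gene in config$genes")
  } else {
    gi <- filter_genes_min_total(group_a$matrix, list(group_a, group_b),
                                 config$min_total)
    if (config$detect_frac > 0) {
      dsel <- detection_fraction_filter(group_a$matrix,
                                        list(group_a, group_b),
                                        config$detect_frac)
      gi <- intersect(gi, dsel)
    }
  }
  gi <- gi[order(ids[gi])]
  if (length(gi) == 0L) {
    warning("zero surviving genes")
    return(data.frame(gene = character(0)))
  }
  pa <- gene_profiles(group_a, genes = gi, rho_mode = config$rho_mode)
  pb <- gene_profiles(group_b, genes = gi, rho_mode = config$rho_mode)
  wt <- weighted_t_test(pa, pb)
  p_chi2 <- chi2_aggregate_test(pa$agg, pa$tot, pb$agg, pb$tot)
  out <- data.frame(
    gene = pa$gene,
    mean_w_A = pa$mean_w, mean_w_B = pb$mean_w,
    log2fc_w = log2_fold_change(pa$mean_w, pb$mean_w),
    rho_A = pa$rho, rho_B = pb$rho,
    wdc_A = pa$wdc, wdc_B = pb$wdc,
    agg_A = pa$agg, tot_A = pa$tot, agg_B = pb$agg, tot_B = pb$tot,
    p_wt = wt$p, p_chi2 = p_chi2,
    p_combined = combine_pvalues(wt$p, p_chi2, config$policy),
    row.names = NULL, stringsAsFactors = FALSE)
  if (isTRUE(config$comparators)) {
    cmp <- comparator_tests(group_a, group_b, genes = gi)
    out$mean_rc_A <- cmp$mean_rc_a
    out$mean_rc_B <- cmp$mean_rc_b
    out$p_t_rc <- cmp$p_t_rc
    out$p_t_log <- cmp$p_t_log
    out$p_wilcoxon <- cmp$p_wilcoxon
  }
  out
}

#' Write a DGE table as TSV
#'
#' Writes the fixed column contract `gene, mean_w_A, mean_w_B, log2fc_w,
#' rho_A, rho_B, wdc_A, wdc_B, agg_A, tot_A, agg_B, tot_B, p_wt, p_chi2,
#' p_combined, p_t_rc, p_t_log, p_wilcoxon` (UTF-8; infinite fold changes as
#' `Inf`/`-Inf`, undefined p-values as `NA`), preceded by `#`-comment header
#' lines recording the package version, a config hash and the seed.
#'
#' @param dge result of [run_dge()].
#' @param path output file.
#' @param seed seed to record in the header (may be NA).
#' @param config_hash config digest to record in the header.
#' @export
write_dge_tsv <- function(dge, path, seed = NA, config_hash = "") {
  cols <- c("gene", "mean_w_A", "mean_w_B", "log2fc_w", "rho_A", "rho_B",
            "wdc_A", "wdc_B", "agg_A", "tot_A", "agg_B", "tot_B",
            "p_wt", "p_chi2", "p_combined", "p_t_rc", "p_t_log", "p_wilcoxon")
  for (cc in setdiff(cols, names(dge))) dge[[cc]] <- NA_real_
  hdr <- c(sprintf("# weightedDGE %s",
                   as.character(utils::packageVersion("weightedDGE"))),
           sprintf("# config: %s", config_hash),
           sprintf("# seed: %s", as.character(seed)))
  writeLines(hdr, path, useBytes = TRUE)
  suppressWarnings(utils::write.table(
    dge[cols], path, append = TRUE, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, na = "NA", fileEncoding = "UTF-8"))
  invisible(path)
}
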