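# Per-gene statistical weights of cells.
#
# Each cell i is treated as an experimental cluster of size N_i (its total
# UMI count). For a gene Z the analyzed quantity is the relative expression
# n_{Z,i} = N_{Z,i}/N_i, and the weight of cell i in the mean is
#   w_{Z,i}  proportional to  N_i / (1 + rho_Z (N_i - 1)),
# where rho_Z in [0,1] is the intracluster correlation coefficient (ICC)
# estimated from the data. rho = 0 recovers aggregate-count weights
# (w ~ N_i, the pseudo-bulk limit); rho = 1 recovers equal weights 1/N
# (the unweighted-average limit).

#' Relative expression per cell
#'
#' \eqn{n_{Z,i} = N_{Z,i}/N_i}: the fraction of each cell's transcripts that
#' belong to the gene.
#'
#' @param counts_z integer gene counts per cell.
#' @param totals positive per-cell total counts.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
relative_expression <- function(counts_z, totals) {
  if (length(counts_z) != length(totals)) stop("length mismatch")
  if (any(totals <= 0)) stop("zero-total cell included; pre-filter cells with N_i = 0")
  counts_z / totals
}

#' Intracluster correlation coefficient (one-way ANOVA moment estimator)
#'
#' Fleiss–Donner estimator for clustered binary outcomes, the standard
#' choice in cluster-randomized trials. With k cells of sizes \eqn{N_i},
#' \eqn{M = \sum N_i}, per-cell proportions \eqn{p_i = N_{Z,i}/N_i} and
#' pooled proportion \eqn{\bar p}:
#' \deqn{MSB = \sum N_i (p_i - \bar p)^2/(k-1), \quad
#'       MSW = \sum N_i p_i (1-p_i)/(M-k),}
#' \deqn{n_0 = (M - \sum N_i^2/M)/(k-1), \quad
#'       \hat\rho = (MSB - MSW)/(MSB + (n_0-1) MSW),}
#' clamped to `[0, 1]`. A zero or non-finite denominator (constant gene)
#' returns 0: no between-cell variance detected, the aggregate-weight limit.
#'
#' @param counts_z integer gene counts per cell (at least 2 cells).
#' @param totals positive per-cell total counts.
#' @return ICC estimate in `[0, 1]`.
#' @export
estimate_icc <- function(counts_z, totals) {
  k <- length(counts_z)
  if (k < 2) stop("at least 2 cells required")
  if (length(totals) != k) stop("length mismatch")
  if (any(totals <= 0)) stop("zero-total cell included")
  M <- sum(totals)
  T_z <- sum(counts_z)
  p <- counts_z / totals
  S2 <- sum(totals * p^2)               # = sum N_i p_i^2
  msb <- (S2 - T_z^2 / M) / (k - 1)
  msw <- (T_z - S2) / (M - k)
  n0 <- (M - sum(totals^2) / M) / (k - 1)
  denom <- msb + (n0 - 1) * msw
  if (!is.finite(denom) || denom <= 0) return(0)
  clamp01((msb - msw) / denom)
}

#' ICC-based cell weights
#'
#' Normalized weights \eqn{w_i \propto N_i/(1 + \rho(N_i - 1))}. At
#' \eqn{\rho = 0} the weights are proportional to the totals (aggregate
#' counts); at \eqn{\rho = 1} all weights equal \eqn{1/N}.
#'
#' @param totals positive per-cell total counts.
#' @param rho ICC in `[0, 1]`.
#' @return Weights summing to 1.
#' @export
cluster_weights <- function(totals, rho) {
  if (length(rho) != 1 || !is.finite(rho) || rho < 0 || rho > 1)
    stop("rho must be a single value in [0, 1]")
  if (any(totals <= 0)) stop("totals must be positive")
  u <- totals / (1 + rho * (totals - 1))
  u / sum(u)
}

#' Weighted mean
#' @param values numeric values per cell.
#' @param weights normalized weights (sum 1).
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) stop("length mismatch")
  sum(weights * values)
}

#' Variance of a weighted mean and effective sample size
#'
#' Unbiased estimator for inverse-variance (accuracy) weights, the classical
#' formula for averaging measurements of non-uniform precision:
#' \deqn{Var(\bar x_w) = \frac{\sum_i w_i (x_i - \bar x_w)^2}{k - 1}}
#' with \eqn{k} cells and normalized weights. When the weights are
#' proportional to the inverse variances of the \eqn{x_i} this is exactly
#' unbiased for the true variance of \eqn{\bar x_w}; at equal weights it
#' reduces to \eqn{s^2/n} with \eqn{s^2} the ordinary unbiased sample
#' variance. The Kish effective sample size \eqn{n_{eff} = 1/\sum w_i^2}
#' accompanies it for degrees-of-freedom bookkeeping.
#'
#' @param values numeric values per cell (at least 2 cells).
#' @param weights normalized weights.
#' @return List with `var_mean` and `n_eff`.
#' @export
weighted_mean_variance <- function(values, weights) {
  if (length(values) != length(weights)) stop("length mismatch")
  if (length(values) < 2) stop("at least 2 cells required")
  sw2 <- sum(weights^2)
  if (sw2 >= 1 - 1e-12) stop("degenerate weights: all mass on one cell")
  xbar <- sum(weights * values)
  q <- sum(weights * (values - xbar)^2)
  list(var_mean = max(0, q / (length(values) - 1)), n_eff = 1 / sw2)
}

#' Weight distribution coefficient
#'
#' \eqn{WDC = Var(w)/Var(w_{AC})}, the population variance of the gene's
#' weights normalized by the population variance of the aggregate-count
#' weights \eqn{w_{AC,i} = N_i/\sum N_i}. WDC = 0 in the equal-weight
#' (unweighted averaging) regime and 1 in the aggregate-count (pseudo-bulk)
#' regime; values above 1 are mathematically possible.
#'
#' @param weights normalized per-cell weights.
#' @param totals per-cell total counts (not all equal).
#' @return Scalar WDC; `NA` with a warning when `Var(w_AC) = 0`.
#' @export
wdc <- function(weights, totals) {
  k <- length(weights)
  if (k < 2 || length(totals) != k) stop("need >= 2 cells and matching totals")
  pop_var <- function(x) mean(x^2) - mean(x)^2
  w_ac <- totals / sum(totals)
  v_ac <- pop_var(w_ac)
  if (v_ac <= 0) {
    warning("Var(w_AC) = 0 (all totals equal): WDC undefined")
    return(NA_real_)
  }
  pop_var(weights) / v_ac
}

#' Weight profile for a single gene
#'
#' Composes [estimate_icc()], [cluster_weights()], [weighted_mean()],
#' [weighted_mean_variance()] and [wdc()] into one consistent record.
#'
#' @param group a [cell_group()] (all cells must have positive totals).
#' @param gene gene id or row index.
#' @param rho_mode `"estimate"` (default) or `"zero"` (spatial/aggregate
#'   mode), or a fixed numeric ICC.
#' @return List of class `GeneWeightProfile`: `gene`, `rho`, `weights`,
#'   `wdc`, `mean_w`, `var_mean`, `n_eff`.
#' @export
gene_profile <- function(group, gene, rho_mode = "estimate") {
  gc <- group_counts(group)
  if (any(gc$totals <= 0)) stop("zero-total cell included; pre-filter the group")
  if (is.character(gene)) {
    gi <- match(gene, group$matrix$gene_ids)
    if (is.na(gi)) stop("unknown gene id: ", gene)
  } else gi <- as.integer(gene)
  x <- as.numeric(gc$counts[gi, ])
  n <- relative_expression(x, gc$totals)
  rho <- if (is.numeric(rho_mode)) rho_mode
         else if (rho_mode == "zero") 0
         else estimate_icc(x, gc$totals)
  w <- cluster_weights(gc$totals, rho)
  v <- weighted_mean_variance(n, w)
  structure(list(gene = group$matrix$gene_ids[gi], rho = rho, weights = w,
                 wdc = suppressWarnings(wdc(w, gc$totals)),
                 mean_w = weighted_mean(n, w),
                 var_mean = v$var_mean, n_eff = v$n_eff),
            class = "GeneWeightProfile")
}

#' Weight profiles for many genes at once
#'
#' Vectorised equivalent of [gene_profile()] across a set of genes; the
#' workhorse behind [run_dge()]. Identical results to the per-gene
#' composition, computed blockwise for throughput on 10^4-gene matrices.
#'
#' @param group a [cell_group()]; zero-total cells are dropped with a warning.
#' @param genes integer indices or character ids (default: all genes).
#' @param rho_mode `"estimate"`, `"zero"`, or a fixed numeric ICC.
#' @param block genes per dense block (memory/speed trade-off).
#' @return `data.frame` with columns `gene`, `rho`, `wdc`, `mean_w`,
#'   `var_mean`, `n_eff`, `agg` (aggregate gene count) and `tot` (aggregate
#'   total); one row per gene, in the order requested.
#' @export
gene_profiles <- function(group, genes = NULL, rho_mode = "estimate",
                          block = 2000L) {
  gc <- group_counts(group, drop_zero_totals = TRUE)
  cmx <- gc$counts
  N <- gc$totals
  k <- length(N)
  if (k < 2) stop("at least 2 cells with positive totals required")
  ids <- group$matrix$gene_ids
  gi <- if (is.null(genes)) seq_along(ids)
        else if (is.character(genes)) {
          m <- match(genes, ids)
          if (anyNA(m)) stop("unknown gene id(s)")
          m
        } else as.integer(genes)

  cmx <- cmx[gi, , drop = FALSE]
  M <- sum(N)
  T_z <- Matrix::rowSums(cmx)
  rel <- cmx %*% Matrix::Diagonal(x = 1 / N)          # n_{Z,i}, sparse
  S2 <- Matrix::rowSums(cmx * rel)                    # sum_i N_i p_i^2
  # ICC (Fleiss-Donner), vectorised
  if (is.numeric(rho_mode)) {
    rho <- rep(clamp01(rho_mode), length(gi))
  } else if (rho_mode == "zero") {
    rho <- rep(0, length(gi))
  } else {
    msb <- (S2 - T_z^2 / M) / (k - 1)
    msw <- (T_z - S2) / (M - k)
    n0 <- (M - sum(N^2) / M) / (k - 1)
    denom <- msb + (n0 - 1) * msw
    rho <- ifelse(is.finite(denom) & denom > 0, (msb - msw) / denom, 0)
    rho <- clamp01(rho)
  }

  ng <- length(gi)
  mean_w <- var_mean <- n_eff <- wdc_z <- numeric(ng)
  w_ac <- N / M
  v_ac <- mean(w_ac^2) - mean(w_ac)^2
  relT <- methods::as(rel, "TsparseMatrix")
  ord_i <- relT@i + 1L
  ord_j <- relT@j + 1L
  relx <- relT@x
  for (s in seq(1L, ng, by = block)) {
    e <- min(s + block - 1L, ng)
    bidx <- s:e
    nb <- length(bidx)
    # unnormalized weights u[g, i] = N_i / (1 + rho_g (N_i - 1))
    U <- 1 + outer(rho[bidx], N - 1)
    U <- matrix(rep(N, each = nb), nrow = nb) / U
    D <- rowSums(U)
    SW2 <- rowSums(U * U) / D^2
    sel <- which(ord_i >= s & ord_i <= e)
    ib <- ord_i[sel] - s + 1L
    jb <- ord_j[sel]
    xv <- relx[sel]
    uv <- U[cbind(ib, jb)]
    num1 <- rowsum(uv * xv, ib, reorder = FALSE)
    num2 <- rowsum(uv * xv * xv, ib, reorder = FALSE)
    rows_present <- as.integer(rownames(num1))
    m1 <- m2 <- numeric(nb)
    m1[rows_present] <- num1[, 1]
    m2[rows_present] <- num2[, 1]
    mw <- m1 / D
    q <- pmax(0, m2 / D - mw^2)                        # sum w (x - xbar)^2
    mean_w[bidx] <- mw
    var_mean[bidx] <- q / (k - 1)
    n_eff[bidx] <- 1 / SW2
    # population variance of normalized weights vs aggregate-count weights
    wvar <- SW2 / k - (1 / k)^2
    wdc_z[bidx] <- if (v_ac > 0) wvar / v_ac else NA_real_
  }
  data.frame(gene = ids[gi], rho = rho, wdc = wdc_z, mean_w = mean_w,
             var_mean = var_mean, n_eff = n_eff,
             agg = T_z, tot = M, row.names = NULL,
             stringsAsFactors = FALSE)
}
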