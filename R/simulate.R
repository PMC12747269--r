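# Benchmark machinery: UMI thinning, the calibrated uniform noise model,
# proportional upregulation, a ground-truth-bearing synthetic count-matrix
# generator, and a beta-binomial generator for ICC parameter recovery.

#' Thin a count matrix by UMI subsampling
#'
#' Two modes. `"binomial"` (default): every entry is replaced by an
#' independent `Binomial(N, retain_p)` draw - per-UMI Bernoulli retention,
#' the canonical model of reduced sequencing depth. `"per_gene"`: exactly
#' `round(retain_p * total)` of each gene's UMIs are retained, selected
#' uniformly at random across cells (multivariate hypergeometric); per-gene
#' aggregate counts are then deterministic, so any aggregate-level signal is
#' removed by construction and only the redistribution across cells remains.
#'
#' @param cm a [count_matrix()].
#' @param retain_p retention probability in `[0, 1]`.
#' @param seed integer seed (reproducible, isolated RNG stream).
#' @param mode `"binomial"` or `"per_gene"`.
#' @return A thinned [count_matrix()] with the same gene ids and barcodes.
#' @export
subsample_umis <- function(cm, retain_p, seed = NULL,
                           mode = c("binomial", "per_gene")) {
  stopifnot(inherits(cm, "CountMatrix"), retain_p >= 0, retain_p <= 1)
  mode <- match.arg(mode)
  m <- cm$counts
  with_stream(seed, paste0("subsample_", mode), {
    if (mode == "binomial") {
      if (length(m@x)) {
        m@x <- as.double(stats::rbinom(length(m@x), m@x, retain_p))
        m <- Matrix::drop0(m)
      }
    } else {
      tm <- methods::as(m, "TsparseMatrix")
      dt <- data.table::data.table(g = tm@i, j = tm@j + 1L, x = as.integer(tm@x))
      umis <- dt[rep(seq_len(.N), x), .(g, j)]
      umis[, u := stats::runif(.N)]
      data.table::setorder(umis, g, u)
      umis[, rnk := seq_len(.N), by = g]
      umis[, K := round(retain_p * .N), by = g]
      agg <- umis[rnk <= K, .(x = .N), by = .(g, j)]
      m <- Matrix::sparseMatrix(i = agg$g + 1L, j = agg$j, x = as.double(agg$x),
                                dims = dim(tm))
    }
    count_matrix(m, gene_ids = cm$gene_ids, barcodes = cm$barcodes)
  })
}

# scaling factor of the uniform noise amplitude; sf(alpha, 0) = 1 and
# sf -> sqrt(3 alpha) as N grows, so Var(round(U * sf * sqrt(N))) -> alpha N.
#' @keywords internal
#' @noRd
noise_sf <- function(alpha, n) {
  s <- sqrt(3 * alpha)
  s - (s - 1) / (1 + 0.1 * n)
}

#' Uniform count noise
#'
#' Integer perturbations `round(U * A(alpha, N))` with `U ~ Uniform(-1, 1)`
#' and amplitude `A(alpha, N) = sf(alpha, N) * sqrt(N)` where
#' `sf = sqrt(3 alpha) - (sqrt(3 alpha) - 1)/(1 + 0.1 N)`. The amplitude is
#' calibrated so that the noise has zero mean, `fn(alpha, 0) = 0`,
#' `Var(fn) -> alpha N` at large `N`, maximum amplitude close to `N` for
#' small counts, and `N + fn >= 0` for `alpha < 10`. Rounding is
#' round-half-even.
#'
#' @param alpha noise scale in `(0, 10)`.
#' @param n vector of non-negative integer counts.
#' @param draws draws per count value (default one per element of `n`).
#' @return Integer perturbations, same length as `n` (times `draws`).
#' @export
noise_fn <- function(alpha, n, draws = 1L) {
  if (alpha <= 0 || alpha >= 10) stop("alpha must be in (0, 10)")
  if (any(n < 0)) stop("counts must be non-negative")
  n <- rep(n, times = draws)
  amp <- noise_sf(alpha, n) * sqrt(n)
  round(stats::runif(length(n), -1, 1) * amp)
}

#' Noise specification
#' @param alpha noise scale in `(0, 10)`; the mid-range default 5 matches
#'   the benchmark setting.
#' @param target_genes gene ids (or indices) to perturb.
#' @param seed integer seed.
#' @export
noise_spec <- function(alpha = 5, target_genes, seed = NULL) {
  if (alpha <= 0 || alpha >= 10) stop("alpha must be in (0, 10)")
  structure(list(alpha = alpha, target_genes = target_genes, seed = seed),
            class = "NoiseSpec")
}

#' Apply uniform noise to a subset of genes
#'
#' Targeted entries become `N + fn(alpha, N)`; untargeted entries are
#' untouched. A draw that would push a count below zero is clamped at 0
#' (defensive; does not occur for `alpha < 10`) and counted in the
#' `clamped` attribute.
#'
#' @param cm a [count_matrix()].
#' @param spec a [noise_spec()].
#' @return Perturbed [count_matrix()].
#' @export
apply_noise <- function(cm, spec) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(spec, "NoiseSpec"))
  tg <- spec$target_genes
  if (is.character(tg)) {
    idx <- match(tg, cm$gene_ids)
    if (anyNA(idx)) stop("unknown target gene id")
  } else idx <- as.integer(tg)
  m <- methods::as(cm$counts, "TsparseMatrix")
  sel <- which((m@i + 1L) %in% idx)
  clamped <- 0L
  with_stream(spec$seed, "apply_noise", {
    if (length(sel)) {
      x <- m@x[sel]
      xn <- x + noise_fn(spec$alpha, x)
      clamped <- sum(xn < 0)
      if (clamped > 0) warning(clamped, " counts clamped at 0 after noise")
      m@x[sel] <- pmax(0, xn)
    }
    out <- count_matrix(Matrix::drop0(m), gene_ids = cm$gene_ids,
                        barcodes = cm$barcodes)
    attr(out, "clamped") <- clamped
    out
  })
}

#' Apply proportional upregulation to a subset of genes
#'
#' Targeted entries become `N + round((beta - 1) * N)`: an expected
#' multiplicative change of `beta` (exact for counts where `(beta-1)*N` is
#' integral, e.g. +50% on even counts at `beta = 1.5`). Round-half-even.
#'
#' @param cm a [count_matrix()].
#' @param genes gene ids or indices to upregulate.
#' @param beta fold factor `>= 1` (`beta = 1.5` models 50% upregulation).
#' @return Modified [count_matrix()].
#' @export
apply_upregulation <- function(cm, genes, beta) {
  stopifnot(inherits(cm, "CountMatrix"), beta >= 1)
  if (is.character(genes)) {
    idx <- match(genes, cm$gene_ids)
    if (anyNA(idx)) stop("unknown gene id")
  } else idx <- as.integer(genes)
  m <- methods::as(cm$counts, "TsparseMatrix")
  sel <- which((m@i + 1L) %in% idx)
  if (length(sel)) m@x[sel] <- m@x[sel] + round((beta - 1) * m@x[sel])
  count_matrix(Matrix::drop0(m), gene_ids = cm$gene_ids, barcodes = cm$barcodes)
}

#' Synthetic count-matrix configuration
#'
#' Defaults emulate the structure of a deeply characterised embryonic-brain
#' 10x dataset: per-cell totals log-normal with ~25-fold central spread
#' (~100-fold across the full population), a heavy-tailed gene-abundance
#' distribution leaving roughly 12,000 of 14,000 genes above 30 total
#' counts at 1,000 cells, and per-gene biological dispersion spanning three
#' orders of magnitude so that estimated ICC/WDC values cover the observed
#' range.
#'
#' @param n_cells cells per group.
#' @param n_genes number of genes.
#' @param depth_meanlog,depth_sdlog log-normal parameters of per-cell totals.
#' @param abundance_sdlog log-normal sd of relative gene abundances.
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   per-gene biological dispersion (variance of the gamma expression
#'   multiplier; 0 dispersion = pure multinomial sampling).
#' @param n_groups 1 or 2 groups of cells.
#' @param group_depth_mult multiplier on group-2 depths (depth imbalance).
#' @param upreg_genes,upreg_beta optional planted fold change: gene indices
#'   (or count of randomly chosen genes) upregulated by `upreg_beta` in
#'   group 2.
#' @param seed mandatory integer seed.
#' @export
synth_config <- function(n_cells = 1000, n_genes = 14000,
                         depth_meanlog = log(1e4), depth_sdlog = 0.82,
                         abundance_sdlog = 1.6,
                         dispersion_meanlog = log(0.25),
                         dispersion_sdlog = log(10) * 0.75,
                         n_groups = 1, group_depth_mult = 1,
                         upreg_genes = NULL, upreg_beta = 1.5,
                         seed) {
  stopifnot(n_cells > 0, n_genes > 0, n_groups %in% c(1, 2),
            group_depth_mult > 0, !missing(seed))
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 abundance_sdlog = abundance_sdlog,
                 dispersion_meanlog = dispersion_meanlog,
                 dispersion_sdlog = dispersion_sdlog,
                 n_groups = n_groups, group_depth_mult = group_depth_mult,
                 upreg_genes = upreg_genes, upreg_beta = upreg_beta,
                 seed = seed), class = "SynthConfig")
}

#' Generate a synthetic UMI count matrix with known truth
#'
#' Per cell: a log-normal sequencing depth \eqn{N_i}. Per gene: a base
#' relative abundance from a heavy-tailed (log-normal) distribution. Per
#' gene and cell: the expected proportion is multiplied by a gamma variate
#' with gene-specific dispersion (mean 1, variance = dispersion),
#' renormalized within the cell, and counts are drawn
#' `multinomial(N_i, proportions)` - so column sums equal the drawn depths
#' exactly. Dispersion 0 gives pure transcript-sampling noise (true ICC 0).
#' Fully reproducible under the config seed.
#'
#' @param config a [synth_config()].
#' @return List: `matrix` (a [count_matrix()]), `truth` (`data.frame` with
#'   `gene`, `status` in unmodified/upregulated, `beta`, `abundance`,
#'   `dispersion`), and `groups` (list of [cell_group()]s, one per group).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  ng <- config$n_genes; nc <- config$n_cells
  with_stream(config$seed, "generate_synthetic", {
    abun <- stats::rlnorm(ng, 0, config$abundance_sdlog)
    disp <- stats::rlnorm(ng, config$dispersion_meanlog, config$dispersion_sdlog)
    total_cells <- nc * config$n_groups
    grp <- rep(seq_len(config$n_groups), each = nc)
    ml <- config$depth_meanlog + ifelse(grp == 2, log(config$group_depth_mult), 0)
    depth <- pmax(1, round(stats::rlnorm(total_cells, ml, config$depth_sdlog)))
    upreg <- integer(0)
    beta <- config$upreg_beta
    if (!is.null(config$upreg_genes)) {
      upreg <- if (length(config$upreg_genes) == 1 && config$upreg_genes < ng &&
                   is.numeric(config$upreg_genes) && config$upreg_genes == round(config$upreg_genes) &&
                   length(config$upreg_genes) == 1)
        sample.int(ng, config$upreg_genes) else as.integer(config$upreg_genes)
    }
    base_p <- abun / sum(abun)
    ii <- jj <- list(); xx <- list()
    shape <- 1 / disp
    nodisp <- disp < 1e-12
    for (i in seq_len(total_cells)) {
      g <- stats::rgamma(ng, shape = shape, rate = shape)
      g[nodisp] <- 1
      p <- base_p * g
      if (grp[i] == 2 && length(upreg)) p[upreg] <- p[upreg] * beta
      cnt <- stats::rmultinom(1, depth[i], p)[, 1]
      nz <- which(cnt > 0)
      ii[[i]] <- nz; jj[[i]] <- rep(i, length(nz)); xx[[i]] <- cnt[nz]
    }
    m <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                              x = as.double(unlist(xx)),
                              dims = c(ng, total_cells))
    ids <- sprintf("g%05d", seq_len(ng))
    bcs <- sprintf("c%05d-%d", seq_len(total_cells), grp)
    cm <- count_matrix(m, gene_ids = ids, barcodes = bcs)
    status <- rep("unmodified", ng)
    status[upreg] <- "upregulated"
    truth <- data.frame(gene = ids, status = status,
                        beta = ifelse(status == "upregulated", beta, 1),
                        abundance = base_p, dispersion = disp,
                        stringsAsFactors = FALSE)
    groups <- lapply(seq_len(config$n_groups), function(k)
      cell_group(cm, which(grp == k), label = paste0("group", k)))
    list(matrix = cm, truth = truth, groups = groups)
  })
}

#' Beta-binomial clustered counts with known ICC
#'
#' Generator for ICC parameter-recovery checks: per cell a true proportion
#' `p_i ~ Beta(a, b)` with mean `p` and intracluster correlation `rho`
#' (`a + b = (1 - rho)/rho`), then counts `Binomial(N_i, p_i)`. `rho = 0`
#' gives pure binomial sampling.
#'
#' @param totals per-cell cluster sizes `N_i`.
#' @param p mean proportion.
#' @param rho true ICC in `[0, 1)`.
#' @param seed integer seed.
#' @return Integer counts per cell.
#' @export
simulate_beta_binomial <- function(totals, p, rho, seed = NULL) {
  stopifnot(p > 0, p < 1, rho >= 0, rho < 1)
  with_stream(seed, "beta_binomial", {
    if (rho == 0) {
      stats::rbinom(length(totals), totals, p)
    } else {
      nu <- (1 - rho) / rho
      pi <- stats::rbeta(length(totals), nu * p, nu * (1 - p))
      stats::rbinom(length(totals), totals, pi)
    }
  })
}

#' Tally false positives and negatives against simulation truth
#'
#' For each test column, replicate and p-threshold, computes the false
#' positive fraction among genes whose true status is in `null_status`
#' (default unmodified and noise-only) and the false negative fraction among
#' planted (upregulated) genes, under two tally modes: `p_only` (calls by
#' p-value alone) and `p_fc` (calls require `|log2fc| > fc_threshold` as
#' well, so a planted gene is missed when `p >= thr` and/or
#' `log2fc < fc_threshold`).
#'
#' @param results list of DGE tables (one per replicate) as from
#'   [run_dge()]; a single table is accepted.
#' @param truth truth `data.frame` with `gene` and `status`, or a list of
#'   such frames (one per replicate).
#' @param tests named character vector mapping test label to p-value column.
#' @param p_thresholds numeric p-value cutoffs.
#' @param fc_threshold |log2FC| cutoff for the `p_fc` mode (default 0.1).
#' @param fc_column fold-change column (default `log2fc_w`, falling back to
#'   `log2fc`).
#' @param null_status statuses counted as true nulls.
#' @return List with `per_replicate` (long `data.frame`: test, threshold,
#'   mode, replicate, fp, fn, n_null, n_planted) and `summary` (medians and
#'   25/75 percentiles across replicates).
#' @export
tally_benchmark <- function(results, truth,
                            tests = c(wt = "p_wt", chi2 = "p_chi2",
                                      comb = "p_combined", t_rc = "p_t_rc",
                                      t_log = "p_t_log",
                                      wilcoxon = "p_wilcoxon"),
                            p_thresholds = c(0.05, 0.001, 1e-5),
                            fc_threshold = 0.1,
                            fc_column = NULL,
                            null_status = c("unmodified", "noise_only")) {
  if (is.data.frame(results)) results <- list(results)
  truth_list <- if (is.data.frame(truth)) rep(list(truth), length(results))
                else truth
  rows <- list()
  for (r in seq_along(results)) {
    res <- results[[r]]
    idx <- match(res$gene, truth_list[[r]]$gene)
    if (anyNA(idx)) stop("result genes missing from truth")
    status <- truth_list[[r]]$status[idx]
    fc_col <- fc_column %||%
      (if ("log2fc_w" %in% names(res)) "log2fc_w" else "log2fc")
    fc <- res[[fc_col]]
    is_null <- status %in% null_status
    is_planted <- status == "upregulated"
    for (tn in names(tests)) {
      pcol <- tests[[tn]]
      if (!pcol %in% names(res)) next
      p <- res[[pcol]]
      for (thr in p_thresholds) {
        sig_p <- !is.na(p) & p < thr
        sig_fc <- sig_p & !is.na(fc) & abs(fc) > fc_threshold
        for (mode in c("p_only", "p_fc")) {
          sig <- if (mode == "p_only") sig_p else sig_fc
          fp <- if (any(is_null)) mean(sig[is_null]) else NA_real_
          fn <- if (any(is_planted)) mean(!sig[is_planted]) else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            test = tn, threshold = thr, mode = mode, replicate = r,
            fp = fp, fn = fn, n_null = sum(is_null),
            n_planted = sum(is_planted), stringsAsFactors = FALSE)
        }
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(fp, fn) ~ test + threshold + mode, per_rep,
                          function(x) stats::quantile(x, c(0.25, 0.5, 0.75),
                                                      na.rm = TRUE),
                          na.action = stats::na.pass)
  summary <- data.frame(test = agg$test, threshold = agg$threshold,
                        mode = agg$mode,
                        fp_q25 = agg$fp[, 1], fp_median = agg$fp[, 2],
                        fp_q75 = agg$fp[, 3],
                        fn_q25 = agg$fn[, 1], fn_median = agg$fn[, 2],
                        fn_q75 = agg$fn[, 3], stringsAsFactors = FALSE)
  list(per_replicate = per_rep, summary = summary)
}
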