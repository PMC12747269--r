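# Benchmark designs: original-vs-thinned null comparisons, noise-only and
# noise-plus-upregulation two-group designs, and the multi-sample (5 vs 5)
# design, each returning raw DGE tables plus FP/FN tallies.

# submatrix CountMatrix of a group's cells (columns renumbered)
#' @keywords internal
#' @noRd
group_submatrix <- function(group) {
  count_matrix(group$matrix$counts[, group$cells, drop = FALSE],
               gene_ids = group$matrix$gene_ids,
               barcodes = group$matrix$barcodes[group$cells])
}

#' Original-vs-thinned subsampling benchmark
#'
#' Compares a cell population against a UMI-thinned copy of itself over
#' several independent thinning replicates. Thinning does not change
#' relative expression, so every significant gene is a false positive. The
#' gene universe is fixed on the *original* data (total counts strictly
#' greater than `min_total`).
#'
#' @param base_group a [cell_group()] with the original cells.
#' @param retain_p retention probability (default 0.4).
#' @param reps number of thinning replicates (default 10).
#' @param seed integer seed; replicate r uses an independent stream.
#' @param min_total gene filter on the original data (default 30).
#' @param mode thinning mode, see [subsample_umis()]; the benchmark default
#'   `"per_gene"` removes per-gene aggregate totals from the comparison so
#'   only the redistribution of counts across cells is tested.
#' @param comparators include Wilcoxon/t comparator tests.
#' @param p_thresholds thresholds for the tally.
#' @return List: `results` (one DGE table per replicate), `truth` (all
#'   genes unmodified), `tally` (see [tally_benchmark()]; the `fp` column is
#'   the fraction of genes called significant).
#' @export
benchmark_subsample <- function(base_group, retain_p = 0.4, reps = 10,
                                seed = 1, min_total = 30,
                                mode = "per_gene", comparators = TRUE,
                                p_thresholds = c(0.05, 0.001, 1e-5)) {
  orig <- group_submatrix(base_group)
  all_cells <- cell_group(orig, label = "original")
  universe <- names(filter_genes_min_total(orig, all_cells, min_total))
  cfg <- dge_config(genes = universe, comparators = comparators)
  results <- vector("list", reps)
  for (r in seq_len(reps)) {
    thinned <- subsample_umis(orig, retain_p, seed = stream_seed(seed, paste0("rep", r)),
                              mode = mode)
    results[[r]] <- run_dge(all_cells, cell_group(thinned, label = "thinned"), cfg)
  }
  truth <- data.frame(gene = universe, status = "unmodified",
                      stringsAsFactors = FALSE)
  tally <- tally_benchmark(results, truth, p_thresholds = p_thresholds)
  list(results = results, truth = truth, tally = tally)
}

# pick noise/upregulation target genes: eligible by total count, optionally
# restricted to a mean counts-per-cell window
#' @keywords internal
#' @noRd
eligible_genes <- function(cm, min_total, expr_range = NULL) {
  tot <- Matrix::rowSums(cm$counts)
  ok <- tot > min_total
  if (!is.null(expr_range)) {
    cpc <- tot / ncol(cm$counts)
    ok <- ok & cpc >= expr_range[1] & cpc <= expr_range[2]
  }
  which(ok)
}

#' Noise / noise-plus-upregulation two-group benchmark
#'
#' Per replicate: draws a target gene set, perturbs a copy of the original
#' matrix with zero-mean uniform noise (`alpha`) and optionally upregulates
#' a subset by `beta`, then compares original vs modified cells. Only the
#' modified genes enter the DGE universe, so FP fractions are measured among
#' noise-only genes and FN fractions among upregulated ones.
#'
#' @param base_group a [cell_group()] with the original cells.
#' @param alpha noise scale (default 5).
#' @param n_noise genes modified by noise per replicate (default 1000).
#' @param n_upreg subset of those additionally upregulated (default 0).
#' @param beta upregulation factor (default 1.5).
#' @param expr_range optional mean counts-per-cell window for target
#'   selection (e.g. `c(0.3, 3)` for moderate-expression genes).
#' @param reps replicates (default 10).
#' @param seed integer seed.
#' @param min_total eligibility filter on the original data (default 30).
#' @param comparators include comparator tests.
#' @param p_thresholds thresholds for the tally.
#' @param fc_threshold |log2FC| threshold for the `p_fc` tally mode.
#' @return List: `results`, `truths` (per replicate), `tally`.
#' @export
benchmark_noise <- function(base_group, alpha = 5, n_noise = 1000,
                            n_upreg = 0, beta = 1.5, expr_range = NULL,
                            reps = 10, seed = 1, min_total = 30,
                            comparators = TRUE,
                            p_thresholds = c(0.05, 0.001, 1e-5),
                            fc_threshold = 0.1) {
  orig <- group_submatrix(base_group)
  all_cells <- cell_group(orig, label = "original")
  elig <- eligible_genes(orig, min_total, expr_range)
  if (length(elig) < n_noise) stop("not enough eligible genes")
  results <- truths <- vector("list", reps)
  for (r in seq_len(reps)) {
    rs <- stream_seed(seed, paste0("noiserep", r))
    targets <- with_stream(rs, "pick", sample(elig, n_noise))
    mod <- apply_noise(orig, noise_spec(alpha, targets,
                                        seed = stream_seed(rs, "noise")))
    up <- integer(0)
    if (n_upreg > 0) {
      up <- with_stream(rs, "pickup", sample(targets, n_upreg))
      mod <- apply_upregulation(mod, up, beta)
    }
    ids <- orig$gene_ids[sort(targets)]
    cfg <- dge_config(genes = ids, comparators = comparators)
    results[[r]] <- run_dge(all_cells, cell_group(mod, label = "modified"), cfg)
    status <- rep("noise_only", length(targets))
    status[sort(targets) %in% up] <- "upregulated"
    truths[[r]] <- data.frame(gene = ids, status = status,
                              stringsAsFactors = FALSE)
  }
  tally <- tally_benchmark(results, truths, p_thresholds = p_thresholds,
                           fc_threshold = fc_threshold)
  list(results = results, truths = truths, tally = tally)
}

#' Multi-sample (5 vs 5) benchmark
#'
#' Two conditions of `n_samples` samples each are generated from one base
#' population by random cell subsetting at the given `fractions` (mimicking
#' variable sample sizes). A target set of `n_noise` moderate-expression
#' genes - half chosen at random, half as the genes with the largest
#' cell-to-cell coefficient of variation - is modified by noise in every
#' sample; in condition B a random `n_upreg`-gene subset is additionally
#' upregulated by `beta`. The weighted across-sample t-test is compared
#' against the aggregate-count t-tests.
#'
#' @param base_group a [cell_group()].
#' @param n_samples samples per condition (default 5).
#' @param fractions cell fractions per sample (recycled; default 0.2-1).
#' @param n_noise,n_upreg,beta,alpha design parameters (defaults 1000, 300,
#'   1.3, 5).
#' @param expr_range counts-per-cell window for targets (default 0.3-3).
#' @param cv_fraction fraction of targets chosen by highest CV (default 0.5).
#' @param seed integer seed.
#' @param min_total eligibility filter (default 30).
#' @param p_thresholds,fc_threshold tally settings.
#' @return List: `result` (multi-sample DGE table), `truth`, `tally`.
#' @export
benchmark_multisample <- function(base_group, n_samples = 5,
                                  fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                                  n_noise = 1000, n_upreg = 300, beta = 1.3,
                                  alpha = 5, expr_range = c(0.3, 3),
                                  cv_fraction = 0.5, seed = 1, min_total = 30,
                                  p_thresholds = c(0.05, 0.001, 1e-5),
                                  fc_threshold = 0.1) {
  orig <- group_submatrix(base_group)
  nc <- ncol(orig$counts)
  elig <- eligible_genes(orig, min_total, expr_range)
  if (length(elig) < n_noise) stop("not enough eligible genes")
  # half random, half highest cell-to-cell CV of relative expression
  rel <- orig$counts[elig, , drop = FALSE] %*%
    Matrix::Diagonal(x = 1 / pmax(orig$cell_totals, 1))
  mu <- Matrix::rowMeans(rel)
  v <- Matrix::rowSums(rel * rel) / nc - mu^2
  cv <- sqrt(pmax(v, 0)) / mu
  n_cv <- round(cv_fraction * n_noise)
  cv_pick <- elig[order(cv, decreasing = TRUE)][seq_len(n_cv)]
  rest <- setdiff(elig, cv_pick)
  targets <- with_stream(seed, "ms_pick",
                         sort(c(cv_pick, sample(rest, n_noise - n_cv))))
  up <- with_stream(seed, "ms_pickup", sort(sample(targets, n_upreg)))
  ids <- orig$gene_ids[targets]
  fractions <- rep_len(fractions, n_samples)
  samples <- list()
  conditions <- character(0)
  for (cond in c("A", "B")) for (s in seq_len(n_samples)) {
    tag <- paste0("ms_", cond, s)
    cells <- with_stream(seed, paste0(tag, "_cells"),
                         sample.int(nc, round(fractions[s] * nc)))
    sm <- count_matrix(orig$counts[, sort(cells), drop = FALSE],
                       gene_ids = orig$gene_ids,
                       barcodes = orig$barcodes[sort(cells)])
    sm <- apply_noise(sm, noise_spec(alpha, targets,
                                     seed = stream_seed(seed, paste0(tag, "_noise"))))
    if (cond == "B") sm <- apply_upregulation(sm, up, beta)
    nm <- paste0(cond, s)
    samples[[nm]] <- cell_group(sm, label = nm)
    conditions[nm] <- cond
  }
  cfg <- dge_config(genes = ids)
  res <- run_dge_multisample(samples, conditions, cfg)
  status <- rep("noise_only", length(targets))
  status[targets %in% up] <- "upregulated"
  truth <- data.frame(gene = ids, status = status, stringsAsFactors = FALSE)
  tally <- tally_benchmark(res, truth,
                           tests = c(wt_samples = "p_wt_samples",
                                     aggr_t = "p_aggr_t",
                                     aggr_wt = "p_aggr_wt"),
                           p_thresholds = p_thresholds,
                           fc_threshold = fc_threshold)
  list(result = res, truth = truth, tally = tally)
}
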