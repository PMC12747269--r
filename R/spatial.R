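# Spatial (bin-level) DGE. Spatial bins carry few counts and may mix cells,
# so the aggregate-count limit (rho = 0) is forced and the conservative
# max-combination of the weighted-t and chi-squared p-values is the default.

#' Bin quality-control configuration
#'
#' Thresholds mirroring routine Visium-style bin QC: a minimum number of
#' detected features per bin, a minimum count excluding a set of dominating
#' genes, an allowed range for the mitochondrial UMI fraction, and minimum
#' UMI fractions for required marker genes. `>`-criteria are strict.
#'
#' @param min_features bins must have strictly more detected genes than this.
#' @param min_counts_excluding list `(threshold, genes)`: bins must have
#'   strictly more than `threshold` counts after removing the listed genes.
#' @param mito_fraction_range inclusive `[lo, hi]` range for the
#'   mitochondrial fraction of bin UMI.
#' @param mito_gene_rule case-insensitive gene-id prefix identifying
#'   mitochondrial genes (default `"mt-"`).
#' @param marker_min_fraction named numeric vector: each named gene must
#'   exceed the given fraction of bin UMI (strict).
#' @export
bin_qc_config <- function(min_features = 20,
                          min_counts_excluding = list(threshold = 100,
                                                      genes = character(0)),
                          mito_fraction_range = c(0.001, 0.05),
                          mito_gene_rule = "mt-",
                          marker_min_fraction = numeric(0)) {
  stopifnot(mito_fraction_range[1] >= 0, mito_fraction_range[2] <= 1,
            mito_fraction_range[1] < mito_fraction_range[2],
            min_features >= 0, min_counts_excluding$threshold >= 0)
  structure(list(min_features = min_features,
                 min_counts_excluding = min_counts_excluding,
                 mito_fraction_range = mito_fraction_range,
                 mito_gene_rule = mito_gene_rule,
                 marker_min_fraction = marker_min_fraction),
            class = "BinQCConfig")
}

#' Filter spatial bins by quality control
#'
#' Keeps the bins passing all criteria of a [bin_qc_config()]. Feature count
#' is the number of genes with a nonzero count in the bin; all fractions are
#' relative to the bin's total UMI count.
#'
#' @param cm a [count_matrix()] of bins.
#' @param qc a [bin_qc_config()].
#' @param label group label.
#' @return A [cell_group()] of passing bins (error if none pass or if a
#'   configured gene id is absent).
#' @export
bin_qc_filter <- function(cm, qc, label = "qc_pass") {
  stopifnot(inherits(cm, "CountMatrix"), inherits(qc, "BinQCConfig"))
  tot <- cm$cell_totals
  pass <- tot > 0
  nfeat <- Matrix::colSums(cm$counts > 0)
  pass <- pass & (nfeat > qc$min_features)
  excl <- qc$min_counts_excluding$genes
  if (length(excl)) {
    idx <- match(excl, cm$gene_ids)
    if (anyNA(idx)) stop("unknown gene id in QC config: ",
                         paste(excl[is.na(idx)], collapse = ", "))
    excl_counts <- Matrix::colSums(cm$counts[idx, , drop = FALSE])
  } else excl_counts <- 0
  pass <- pass & (tot - excl_counts > qc$min_counts_excluding$threshold)
  mito <- grepl(paste0("^", qc$mito_gene_rule), cm$gene_ids, ignore.case = TRUE)
  mito_frac <- if (any(mito))
    Matrix::colSums(cm$counts[mito, , drop = FALSE]) / pmax(tot, 1)
  else rep(0, length(tot))
  pass <- pass & mito_frac >= qc$mito_fraction_range[1] &
    mito_frac <= qc$mito_fraction_range[2]
  if (length(qc$marker_min_fraction)) {
    idx <- match(names(qc$marker_min_fraction), cm$gene_ids)
    if (anyNA(idx)) stop("unknown marker gene id in QC config: ",
                         paste(names(qc$marker_min_fraction)[is.na(idx)],
                               collapse = ", "))
    for (j in seq_along(idx)) {
      frac <- as.numeric(cm$counts[idx[j], ]) / pmax(tot, 1)
      pass <- pass & (frac > qc$marker_min_fraction[j])
    }
  }
  if (!any(pass)) stop("no bins pass QC")
  cell_group(cm, which(pass), label = label)
}

#' Spatial bin-level differential expression
#'
#' [run_dge()] with the spatial conventions: the ICC is forced to 0 in both
#' groups (weights proportional to bin totals, i.e. aggregate counts) and
#' the weighted-t and chi-squared p-values are combined conservatively with
#' the `max` rule by default; a 10% detection filter is applied.
#'
#' @param group_a,group_b [cell_group()]s of QC-passing bins.
#' @param config a [dge_config()]; defaults to
#'   `dge_config(detect_frac = 0.10, policy = combination_policy("max"),
#'   rho_mode = "zero")`.
#' @return As [run_dge()].
#' @export
spatial_dge <- function(group_a, group_b,
                        config = dge_config(detect_frac = 0.10,
                                            policy = combination_policy("max"),
                                            rho_mode = "zero")) {
  config$rho_mode <- "zero"
  run_dge(group_a, group_b, config)
}
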