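# Reading and writing count matrices (10x MTX triplets, dense TSV),
# group definitions, and gene/bin filters.

find_10x_file <- function(directory, base) {
  for (f in c(file.path(directory, base), file.path(directory, paste0(base, ".gz"))))
    if (file.exists(f)) return(f)
  stop("missing file: ", base, "[.gz] in ", directory)
}

read_id_table <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- max(lengths(parts))
  cols <- lapply(seq_len(ncol), function(j)
    vapply(parts, function(p) if (length(p) >= j) p[[j]] else NA_character_,
           character(1)))
  as.data.frame(cols, col.names = paste0("V", seq_len(ncol)),
                stringsAsFactors = FALSE)
}

#' Read a 10x-style MTX triplet directory
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` (each optionally
#' gzipped) into a [count_matrix()]. Genes are returned as rows and cells as
#' columns regardless of the on-disk orientation (decided by matching matrix
#' dimensions against the number of features and barcodes). Both
#' `coordinate integer` and `coordinate real` Matrix Market headers are
#' accepted, but non-integral values are rejected: the method is defined on
#' raw UMI counts. Duplicate feature identifiers are disambiguated
#' deterministically with suffixes `.1`, `.2`, ...
#'
#' @param directory path containing the three files.
#' @return A [count_matrix()].
#' @export
read_10x_mtx <- function(directory) {
  mtx_path <- find_10x_file(directory, "matrix.mtx")
  feat_path <- find_10x_file(directory, "features.tsv")
  bc_path <- find_10x_file(directory, "barcodes.tsv")
  con <- if (grepl("\\.gz$", mtx_path)) gzfile(mtx_path) else mtx_path
  m <- tryCatch(Matrix::readMM(con), error = function(e)
    stop("failed to read ", mtx_path, ": ", conditionMessage(e)))
  feats <- read_id_table(feat_path)
  bcs <- read_id_table(bc_path)[[1]]
  # first column is the id; second (if present) the display name
  gene_ids <- make.unique(feats[[1]], sep = ".")
  if (nrow(m) == length(gene_ids) && ncol(m) == length(bcs)) {
    # genes x cells as stored
  } else if (nrow(m) == length(bcs) && ncol(m) == length(gene_ids)) {
    m <- Matrix::t(m)
  } else {
    stop("dimension mismatch: matrix is ", nrow(m), "x", ncol(m), " but ",
         length(gene_ids), " features and ", length(bcs), " barcodes given")
  }
  count_matrix(m, gene_ids = gene_ids, barcodes = make.unique(bcs, sep = "."))
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' Inverse of [read_10x_mtx()]: writes `matrix.mtx`, `features.tsv` and
#' `barcodes.tsv` (uncompressed) so that reading the directory back yields a
#' bit-identical matrix.
#'
#' @param cm a [count_matrix()].
#' @param directory output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_counts <- function(cm, directory) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(directory, "matrix.mtx"))
  data.table::fwrite(data.table::data.table(id = cm$gene_ids, name = cm$gene_ids),
                     file.path(directory, "features.tsv"),
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::data.table(bc = cm$barcodes),
                     file.path(directory, "barcodes.tsv"),
                     sep = "\t", col.names = FALSE)
  invisible(directory)
}

#' Read a dense TSV count matrix (genes as rows, header = barcodes)
#' @param path TSV file; first column gene ids, remaining columns cells.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  count_matrix(m, gene_ids = make.unique(genes, sep = "."),
               barcodes = colnames(m))
}

#' Write a dense TSV count matrix
#' @param cm a [count_matrix()].
#' @param path output file.
#' @export
write_counts_tsv <- function(cm, path) {
  dt <- data.table::data.table(gene = cm$gene_ids)
  dense <- as.matrix(cm$counts)
  for (j in seq_along(cm$barcodes)) dt[[cm$barcodes[j]]] <- dense[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a barcode list (one barcode per line) as a cell group
#' @param cm a [count_matrix()].
#' @param path text file with one barcode per line.
#' @param label group label (defaults to the file name).
#' @export
read_barcode_group <- function(cm, path, label = basename(path)) {
  bcs <- readLines(path, warn = FALSE)
  bcs <- bcs[nzchar(bcs)]
  cell_group(cm, bcs, label = label)
}

#' Marker-gene selection rule
#'
#' Cells are selected when they have nonzero counts for *every* listed marker
#' gene, the scheme used to pull marker-defined neuron populations out of a
#' mixed dataset without clustering.
#'
#' @param genes character vector of gene ids.
#' @param mode selection mode; only `"all_nonzero"` is defined.
#' @export
marker_rule <- function(genes, mode = "all_nonzero") {
  mode <- match.arg(mode)
  stopifnot(is.character(genes), length(genes) > 0)
  structure(list(genes = genes, mode = mode), class = "MarkerRule")
}

#' Select cells by a marker rule
#'
#' @param cm a [count_matrix()].
#' @param rule a [marker_rule()].
#' @param label group label.
#' @return A [cell_group()] of the cells with nonzero counts for every rule
#'   gene. Errors if a rule gene is absent or the resulting group is empty.
#' @export
select_group <- function(cm, rule, label = paste(rule$genes, collapse = "+")) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(rule, "MarkerRule"))
  idx <- match(rule$genes, cm$gene_ids)
  if (anyNA(idx)) stop("unknown gene id: ",
                       paste(rule$genes[is.na(idx)], collapse = ", "))
  sub <- cm$counts[idx, , drop = FALSE]
  keep <- which(Matrix::colSums(sub > 0) == length(idx))
  if (length(keep) == 0L) stop("empty group: no cell has nonzero counts for all markers")
  cell_group(cm, keep, label = label)
}

group_gene_totals <- function(groups) {
  tot <- NULL
  for (g in groups) {
    s <- Matrix::rowSums(g$matrix$counts[, g$cells, drop = FALSE])
    tot <- if (is.null(tot)) s else tot + s
  }
  tot
}

#' Filter genes by total count across groups
#'
#' Keeps genes whose total count over the referenced cells *exceeds*
#' `min_total` (strict `>`, matching the "more than 30 total counts"
#' convention used throughout the benchmarks).
#'
#' @param cm a [count_matrix()] (defines the gene universe).
#' @param groups a [cell_group()] or list of them whose cells are summed.
#' @param min_total non-negative integer threshold.
#' @return Integer vector of surviving gene indices (named by gene id).
#' @export
filter_genes_min_total <- function(cm, groups, min_total = 30) {
  stopifnot(min_total >= 0)
  if (inherits(groups, "CellGroup")) groups <- list(groups)
  tot <- group_gene_totals(groups)
  idx <- which(tot > min_total)
  names(idx) <- cm$gene_ids[idx]
  idx
}

#' Filter genes by per-group detection fraction
#'
#' Keeps genes with a nonzero count in at least `min_frac` of the cells of
#' *each* group (per-group, not pooled: conservative and symmetric).
#'
#' @param cm a [count_matrix()].
#' @param groups a [cell_group()] or list of them.
#' @param min_frac fraction in `[0, 1]`.
#' @return Integer vector of surviving gene indices (named by gene id).
#' @export
detection_fraction_filter <- function(cm, groups, min_frac = 0.10) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  if (inherits(groups, "CellGroup")) groups <- list(groups)
  ok <- rep(TRUE, nrow(cm$counts))
  for (g in groups) {
    det <- Matrix::rowSums(g$matrix$counts[, g$cells, drop = FALSE] > 0)
    ok <- ok & (det >= min_frac * length(g$cells))
  }
  idx <- which(ok)
  names(idx) <- cm$gene_ids[idx]
  idx
}
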