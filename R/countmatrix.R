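#' UMI count matrix
#'
#' Container for a sparse gene-by-cell (or gene-by-bin) matrix of raw UMI
#' counts \eqn{N_{Z,i}}, together with gene identifiers, cell barcodes and the
#' cached per-cell totals \eqn{N_i = \sum_Z N_{Z,i}}. All downstream weighting
#' and testing operates on raw integer counts; no normalisation is stored.
#'
#' @param counts matrix-like object of non-negative integer counts, genes as
#'   rows and cells as columns. Coerced to a sparse `dgCMatrix`. Values must
#'   be integral to within `1e-9`.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(counts)`).
#' @param barcodes character vector of unique cell/bin barcodes (defaults to
#'   `colnames(counts)`).
#'
#' @return An object of class `CountMatrix` with fields `counts` (sparse
#'   matrix), `gene_ids`, `barcodes` and `cell_totals`.
#' @examples
#' m <- count_matrix(matrix(c(1, 0, 2, 3), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2"))))
#' m$cell_totals
#' @export
count_matrix <- function(counts, gene_ids = NULL, barcodes = NULL) {
  if (!inherits(counts, "Matrix")) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- gene_ids %||% rownames(counts)
  barcodes <- barcodes %||% colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(barcodes)) barcodes <- paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (length(gene_ids) != nrow(counts) || length(barcodes) != ncol(counts))
    stop("dimension mismatch between counts and identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  x <- counts@x
  if (length(x)) {
    if (any(x < 0)) stop("counts must be non-negative")
    if (max(abs(x - round(x))) > 1e-9) stop("counts must be integral")
    counts@x <- round(x)
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(
    list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
         cell_totals = Matrix::colSums(counts)),
    class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells, %d nonzero entries, %s total counts\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              format(sum(x$cell_totals), big.mark = ",")))
  invisible(x)
}

#' Subset of cells in a count matrix
#'
#' A `CellGroup` ties a `CountMatrix` to an index set of its columns (cells
#' or spatial bins). Groups are the unit of comparison for all differential
#' expression functions.
#'
#' @param cm a [count_matrix()].
#' @param cells integer column indices or character barcodes; `NULL` selects
#'   all cells.
#' @param label optional group label.
#' @return An object of class `CellGroup` with fields `matrix`, `cells`
#'   (integer indices) and `label`.
#' @export
cell_group <- function(cm, cells = NULL, label = "group") {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(cells)) cells <- seq_along(cm$barcodes)
  if (is.character(cells)) {
    idx <- match(cells, cm$barcodes)
    if (anyNA(idx)) stop("unknown barcodes: ", paste(utils::head(cells[is.na(idx)], 3), collapse = ", "))
    cells <- idx
  }
  cells <- as.integer(cells)
  if (length(cells) == 0L) stop("empty cell group")
  if (anyDuplicated(cells)) stop("duplicate cell indices")
  if (any(cells < 1L | cells > ncol(cm$counts))) stop("cell index out of bounds")
  structure(list(matrix = cm, cells = cells, label = label), class = "CellGroup")
}

#' @export
print.CellGroup <- function(x, ...) {
  cat(sprintf("CellGroup '%s': %d cells\n", x$label, length(x$cells)))
  invisible(x)
}

# counts submatrix and totals of a group, dropping zero-total cells on request
#' @keywords internal
#' @noRd
group_counts <- function(group, drop_zero_totals = FALSE, warn = TRUE) {
  stopifnot(inherits(group, "CellGroup"))
  m <- group$matrix$counts[, group$cells, drop = FALSE]
  tot <- group$matrix$cell_totals[group$cells]
  if (drop_zero_totals && any(tot == 0)) {
    if (warn) warning(sum(tot == 0), " zero-total cells dropped from group '",
                      group$label, "'")
    keep <- tot > 0
    m <- m[, keep, drop = FALSE]
    tot <- tot[keep]
  }
  list(counts = m, totals = tot)
}
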