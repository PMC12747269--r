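# Shared fixture builders; everything is generated in code.

# small random Poisson count matrix
rand_cm <- function(ng = 20, nc = 10, lambda = 3, seed = 1) {
  set.seed(seed)
  count_matrix(matrix(rpois(ng * nc, lambda), ng, nc))
}

# matrix with heterogeneous cell depths (columns scaled)
depth_cm <- function(ng = 60, nc = 40, seed = 2, depth_range = c(50, 2000)) {
  set.seed(seed)
  depths <- round(exp(runif(nc, log(depth_range[1]), log(depth_range[2]))))
  abun <- rexp(ng)
  p <- abun / sum(abun)
  m <- sapply(depths, function(d) rmultinom(1, d, p)[, 1])
  count_matrix(m)
}

# write a 10x triplet by hand; counts given as dense matrix, genes x cells
write_triplet <- function(dir, m, gene_ids = rownames(m), barcodes = colnames(m),
                          header = "%%MatrixMarket matrix coordinate integer general") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(m != 0, arr.ind = TRUE)
  lines <- c(header,
             paste(nrow(m), ncol(m), nrow(nz)),
             apply(nz, 1, function(rc) paste(rc[1], rc[2], m[rc[1], rc[2]])))
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(paste(gene_ids, gene_ids, sep = "\t"), file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}
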