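# shared fixture builders; everything is generated in code

toy_counts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  m
}

# positions data.frame for a full rectangular in-tissue grid
grid_positions <- function(rows, cols, pitch = 100) {
  g <- expand.grid(array_row = seq_len(rows), array_col = seq_len(cols))
  data.frame(
    barcode = sprintf("s%02d_%02d", g$array_row, g$array_col),
    in_tissue = 1L, array_row = g$array_row, array_col = g$array_col,
    pxl_row_in_fullres = g$array_row * pitch,
    pxl_col_in_fullres = g$array_col * pitch,
    stringsAsFactors = FALSE
  )
}

# positivity-call matrix from a named list gene -> logical vector
calls_from_list <- function(lst, barcodes) {
  m <- do.call(rbind, lst)
  dimnames(m) <- list(names(lst), barcodes)
  m
}

# independent KS D oracle: sup over pooled points of |ECDF_a - ECDF_b|,
# each ECDF evaluated by direct counting
ks_D_oracle <- function(a, b) {
  pooled <- c(a, b)
  max(vapply(pooled, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}

# independent minimum-distance oracle: exhaustive double loop
min_dist_oracle <- function(src, tgt) {
  out <- numeric(nrow(src))
  for (i in seq_len(nrow(src))) {
    best <- Inf
    for (j in seq_len(nrow(tgt))) {
      d <- sqrt((tgt[j, 1] - src[i, 1])^2 + (tgt[j, 2] - src[i, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# all-pairs shortest path oracle (Floyd-Warshall) from an igraph
all_pairs_oracle <- function(g) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    D[i, j] <- min(D[i, j], w[e])
    D[j, i] <- min(D[j, i], w[e])
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}

write_mtx_triplet <- function(dir, m) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  dir
}
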