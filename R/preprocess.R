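#' Log-normalize a count matrix
#'
#' Library-size normalization followed by a log transform:
#' `x' = ln(1 + count / column_total * scale_factor)`. Zeros map to zeros,
#' so sparsity is preserved.
#'
#' @param m Count matrix (genes x observations), dense or sparse.
#' @param scale_factor Positive scale factor; default 10,000.
#' @return A sparse `dgCMatrix` of normalized values with the same dimnames,
#'   carrying the scale factor as attribute `scale_factor`.
#' @export
normalize_counts <- function(m, scale_factor = 1e4) {
  validate_count_matrix(m)
  stopifnot(is.numeric(scale_factor), scale_factor > 0)
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    stop("all-zero observation column(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  }
  nm <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  # scale each column by sf/total, then log1p on the nonzero slots only
  j <- rep(seq_len(ncol(nm)), diff(nm@p))
  nm@x <- log1p(nm@x / totals[j] * scale_factor)
  attr(nm, "scale_factor") <- scale_factor
  nm
}

#' Call per-observation gene positivity
#'
#' An observation (cell or spot) is positive for a gene when its raw count
#' exceeds `threshold` (default 0, i.e. at least one count detected).
#'
#' @param m Count matrix (genes x observations).
#' @param genes Character vector of gene identifiers to call.
#' @param threshold Count threshold; positivity is `count > threshold`.
#' @return A logical matrix (length(genes) x observations) with dimnames.
#' @export
call_positive <- function(m, genes, threshold = 0) {
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  calls <- as.matrix(m[genes, , drop = FALSE] > threshold)
  dimnames(calls) <- list(genes, colnames(m))
  calls
}

gene_row_stats <- function(nm) {
  n <- ncol(nm)
  mu <- Matrix::rowMeans(nm)
  ex2 <- Matrix::rowSums(nm^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  v[v < 0] <- 0 # numerical guard
  list(mean = mu, var = v)
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: the per-gene variance of the
#' normalized values divided by the variance predicted from a degree-2
#' polynomial fit of log10(variance) on log10(mean), fitted over all genes
#' with positive mean and variance. Ties are broken by lexicographic gene id
#' so the selection is deterministic.
#'
#' @param nm Normalized matrix from [normalize_counts()].
#' @param n Number of genes to select.
#' @return Character vector of `n` gene ids, ordered by decreasing
#'   standardized variance.
#' @export
select_variable_genes <- function(nm, n) {
  if (n <= 0) stop("n must be positive")
  if (n > nrow(nm)) stop("n exceeds the number of genes")
  st <- gene_row_stats(nm)
  fit_idx <- st$mean > 0 & st$var > 0
  ratio <- rep(0, nrow(nm))
  lm10 <- log10(st$mean[fit_idx])
  if (sum(fit_idx) >= 3 && length(unique(lm10)) >= 3) {
    lv10 <- log10(st$var[fit_idx])
    fit <- stats::lm(lv10 ~ lm10 + I(lm10^2))
    pred <- 10^unname(stats::predict(fit))
    ratio[fit_idx] <- st$var[fit_idx] / pred
  } else {
    # degenerate mean spectrum: rank on raw variance
    ratio[fit_idx] <- st$var[fit_idx]
  }
  ord <- order(-ratio, rownames(nm), method = "radix")
  rownames(nm)[ord][seq_len(n)]
}

#' Principal component embedding
#'
#' Centers and unit-variance scales the selected genes (zero-variance genes
#' are dropped with a message), then projects observations onto the top `d`
#' principal components. Component signs are fixed so that each component's
#' largest-magnitude gene loading is positive, making the embedding
#' deterministic.
#'
#' @param nm Normalized matrix (genes x observations).
#' @param genes Gene ids to use (e.g. from [select_variable_genes()]).
#' @param d Number of components (default 15).
#' @return A numeric matrix (observations x d) with barcode row names;
#'   attribute `sdev` carries the component standard deviations.
#' @export
embed_pca <- function(nm, genes, d = 15) {
  unknown <- setdiff(genes, rownames(nm))
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  x <- t(as.matrix(nm[genes, , drop = FALSE])) # observations x genes
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    message(sprintf("embed_pca: dropping %d zero-variance gene(s)",
                    sum(v == 0)))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < d) {
    stop(sprintf("only %d non-degenerate genes for d = %d", ncol(x), d))
  }
  if (d > min(dim(x))) stop("d exceeds the data rank bound")
  x <- scale(x)
  sv <- svd(x, nu = d, nv = d)
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d)
  # deterministic sign: largest-|loading| entry of each component positive
  for (jj in seq_len(d)) {
    i_max <- which.max(abs(sv$v[, jj]))
    if (sv$v[i_max, jj] < 0) {
      sv$v[, jj] <- -sv$v[, jj]
      scores[, jj] <- -scores[, jj]
    }
  }
  rownames(scores) <- colnames(nm)
  colnames(scores) <- paste0("PC", seq_len(d))
  attr(scores, "sdev") <- sv$d[seq_len(d)] / sqrt(max(1, nrow(x) - 1))
  scores
}
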