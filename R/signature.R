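#' TGF-beta signature gene set presets
#'
#' Two published variants of the skin TGF-beta-induced signature circulate:
#' the `"methods"` set (NR4A1, HSPA1A, CTLA4, DUSP6, LITAF, KLRG1, JUNB,
#' NR4A2, PDCD1, CISH, EOMES, SOCS3) and the `"results"` set (NR4A1, NR4A2,
#' HSPA1A, HSPA1B, HSPA6, JUNB, SOCS3, DUSP6, CISH, CTLA4, MALAT1). The
#' two lists overlap but are not identical; the methods set is the default
#' throughout this package and the results set ships as an alternate.
#'
#' @param preset `"methods"` (default) or `"results"`.
#' @param name Optional name override.
#' @param genes Optional explicit gene list (overrides the preset).
#' @return Object of class `signature_spec`: list with `name`, `genes`.
#' @export
signature_spec <- function(preset = c("methods", "results"), name = NULL,
                           genes = NULL) {
  if (is.null(genes)) {
    preset <- match.arg(preset)
    genes <- switch(preset,
      methods = c("NR4A1", "HSPA1A", "CTLA4", "DUSP6", "LITAF", "KLRG1",
                  "JUNB", "NR4A2", "PDCD1", "CISH", "EOMES", "SOCS3"),
      results = c("NR4A1", "NR4A2", "HSPA1A", "HSPA1B", "HSPA6", "JUNB",
                  "SOCS3", "DUSP6", "CISH", "CTLA4", "MALAT1")
    )
    if (is.null(name)) name <- paste0("tgfb_", preset)
  } else {
    if (anyDuplicated(genes)) stop("signature genes must be unique")
    if (!length(genes)) stop("signature must be non-empty")
    if (is.null(name)) name <- "custom"
  }
  structure(list(name = name, genes = genes), class = "signature_spec")
}

#' Score cells for a gene signature
#'
#' The score of a cell is the mean, over the signature genes, of the
#' per-gene z-scored normalized expression (each gene centered and scaled
#' across the scored population). Genes missing from the matrix or with
#' zero variance are skipped with a message; by construction the score
#' averages to ~0 over the population.
#'
#' @param nm Normalized matrix (genes x cells).
#' @param spec A `signature_spec`.
#' @return Named numeric score vector over cells, with attribute
#'   `genes_used`.
#' @export
score_cells <- function(nm, spec) {
  stopifnot(inherits(spec, "signature_spec"))
  present <- intersect(spec$genes, rownames(nm))
  if (!length(present)) {
    stop("none of the signature genes are present in the matrix")
  }
  skipped <- setdiff(spec$genes, present)
  x <- as.matrix(nm[present, , drop = FALSE])
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    skipped <- c(skipped, present[v == 0])
    x <- x[v > 0, , drop = FALSE]
  }
  if (length(skipped)) {
    message("score_cells: skipping gene(s) ", paste(skipped, collapse = ", "))
  }
  if (!nrow(x)) stop("no signature gene with nonzero variance")
  z <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  score <- colMeans(z)
  attr(score, "genes_used") <- rownames(x)
  score
}

#' Compare signature scores between marker-positive and -negative cells
#'
#' Two-sided Wilcoxon rank-sum test of the score between cells positive
#' and negative for `gene`, with group medians and their difference.
#'
#' @param score Named score vector from [score_cells()].
#' @param calls Positivity matrix containing a row for `gene`.
#' @param gene Gene id defining the two groups.
#' @return List with `median_pos`, `median_neg`, `median_diff`
#'   (positive minus negative), `p`, `n_pos`, `n_neg`. When a group is
#'   empty the medians/p are `NA` and only counts are reported.
#' @export
compare_score_by_state <- function(score, calls, gene) {
  if (!gene %in% rownames(calls)) stop("no positivity calls for ", gene)
  common <- intersect(names(score), colnames(calls))
  s <- score[common]
  pos <- calls[gene, common]
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    return(list(median_pos = NA_real_, median_neg = NA_real_,
                median_diff = NA_real_, p = NA_real_,
                n_pos = n_pos, n_neg = n_neg))
  }
  wt <- stats::wilcox.test(s[pos], s[!pos], exact = (n_pos + n_neg) < 50)
  list(
    median_pos = stats::median(s[pos]),
    median_neg = stats::median(s[!pos]),
    median_diff = stats::median(s[pos]) - stats::median(s[!pos]),
    p = wt$p.value,
    n_pos = n_pos, n_neg = n_neg
  )
}
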