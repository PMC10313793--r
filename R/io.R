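#' Read a 10x-style count matrix triplet
#'
#' Reads a MatrixMarket coordinate file together with its `features.tsv` and
#' `barcodes.tsv` companions and returns a sparse integer gene x observation
#' matrix. Row names are gene identifiers (first tab-separated field of the
#' features file), column names are cell or spot barcodes.
#'
#' @param mtx_path Path to the MatrixMarket (`.mtx`) coordinate file.
#' @param features_path Path to the features/genes table (one gene per line;
#'   only the first tab-separated field is used).
#' @param barcodes_path Path to the barcodes file (one barcode per line).
#' @return A `dgCMatrix` with gene row names and barcode column names; all
#'   entries are non-negative integers (stored as doubles, as is usual for
#'   sparse matrices in R).
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(3, 5), dims = c(2, 2))
#' Matrix::writeMM(m, file.path(d, "matrix.mtx"))
#' writeLines(c("G1", "G2"), file.path(d, "features.tsv"))
#' writeLines(c("AAAC", "AAAG"), file.path(d, "barcodes.tsv"))
#' read_count_matrix(file.path(d, "matrix.mtx"),
#'                   file.path(d, "features.tsv"),
#'                   file.path(d, "barcodes.tsv"))
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  m <- Matrix::readMM(mtx_path)
  feats <- read_first_field(features_path)
  bcs <- read_first_field(barcodes_path)
  if (nrow(m) != length(feats)) {
    stop(sprintf(
      "dimension mismatch: %s declares %d rows but %s has %d lines",
      mtx_path, nrow(m), features_path, length(feats)
    ))
  }
  if (ncol(m) != length(bcs)) {
    stop(sprintf(
      "dimension mismatch: %s declares %d columns but %s has %d lines",
      mtx_path, ncol(m), barcodes_path, length(bcs)
    ))
  }
  # generalMatrix first: readMM may return a symmetric class whose
  # dimnames are forced equal
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  m <- methods::as(m, "dMatrix")
  dimnames(m) <- list(feats, bcs)
  validate_count_matrix(m)
  message(sprintf(
    "read_count_matrix: %d genes x %d observations, %d nonzero entries",
    nrow(m), ncol(m), Matrix::nnzero(m)
  ))
  m
}

read_first_field <- function(path) {
  lines <- readLines(path)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Validate a count matrix
#'
#' Checks the invariants expected of every raw count matrix: non-negative
#' integral entries, unique gene identifiers and unique barcodes.
#'
#' @param m A matrix or sparse Matrix with dimnames.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_count_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix must carry gene row names and barcode column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate barcodes")
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(x) && (min(x) < 0)) stop("negative entries in count matrix")
  if (length(x) && any(x != floor(x))) {
    stop("non-integer entries in count matrix")
  }
  invisible(m)
}

#' Write a count matrix as a 10x-style triplet
#'
#' Inverse of [read_count_matrix()]: writes `matrix.mtx`, `features.tsv`
#' and `barcodes.tsv` into `dir`.
#'
#' @param m Count matrix (genes x observations) with dimnames.
#' @param dir Output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  validate_count_matrix(m)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sm <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

POSITION_COLS <- c(
  "barcode", "in_tissue", "array_row", "array_col",
  "pxl_row_in_fullres", "pxl_col_in_fullres"
)

#' Read a Visium-style tissue positions table
#'
#' Parses the `tissue_positions` CSV dialect: either the headered layout
#' (Space Ranger >= 2.0) or the legacy headerless six-column layout. The
#' dialect is auto-detected from the first field of the first line (a header
#' is assumed when it starts with "barcode").
#'
#' @param csv_path Path to the positions CSV.
#' @return A data.frame with columns `barcode`, `in_tissue`, `array_row`,
#'   `array_col`, `pxl_row_in_fullres`, `pxl_col_in_fullres`. Out-of-tissue
#'   rows are retained with `in_tissue = 0`.
#' @export
read_positions <- function(csv_path) {
  if (!file.exists(csv_path)) stop("file not found: ", csv_path)
  first <- readLines(csv_path, n = 1L)
  has_header <- grepl("^\\s*\"?barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(csv_path, header = has_header,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 6L) {
    stop(sprintf("positions file %s has %d columns; 6 required",
                 csv_path, ncol(df)))
  }
  df <- df[, 1:6]
  names(df) <- POSITION_COLS
  df$barcode <- as.character(df$barcode)
  for (col in POSITION_COLS[-1]) df[[col]] <- as.numeric(df[[col]])
  bad <- !stats::complete.cases(df[-1])
  if (any(bad)) {
    message(sprintf("read_positions: dropping %d unparseable row(s)",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  df$in_tissue <- as.integer(df$in_tissue)
  validate_positions(df)
  message(sprintf("read_positions: %d spots (%d in tissue)",
                  nrow(df), sum(df$in_tissue == 1L)))
  rownames(df) <- NULL
  df
}

validate_positions <- function(df) {
  if (anyDuplicated(df$barcode)) {
    stop("duplicate barcode(s) in positions table: ",
         paste(unique(df$barcode[duplicated(df$barcode)]), collapse = ", "))
  }
  it <- df[df$in_tissue == 1L, , drop = FALSE]
  if (anyDuplicated(it[, c("array_row", "array_col")])) {
    stop("duplicate (array_row, array_col) among in-tissue spots")
  }
  invisible(df)
}

#' Write a tissue positions table
#'
#' Writes the headered `tissue_positions` dialect read by
#' [read_positions()].
#'
#' @param df Positions data.frame as returned by [read_positions()].
#' @param csv_path Output path.
#' @return The path, invisibly.
#' @export
write_positions <- function(df, csv_path) {
  validate_positions(df)
  utils::write.csv(df[, POSITION_COLS], csv_path, row.names = FALSE,
                   quote = FALSE)
  invisible(csv_path)
}

#' Read a cell barcode to clonotype assignment table
#'
#' @param csv_path CSV with at least columns `barcode` and `clonotype_id`;
#'   extra columns are ignored.
#' @return A data.frame with columns `barcode` and `clonotype_id`, one row
#'   per barcode.
#' @export
read_clonotypes <- function(csv_path) {
  if (!file.exists(csv_path)) stop("file not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("barcode", "clonotype_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("clonotype table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, need]
  df$barcode <- as.character(df$barcode)
  df$clonotype_id <- as.character(df$clonotype_id)
  if (anyDuplicated(df$barcode)) {
    stop("duplicate barcode(s) in clonotype table: ",
         paste(unique(df$barcode[duplicated(df$barcode)]), collapse = ", "))
  }
  message(sprintf("read_clonotypes: %d cells, %d clonotypes",
                  nrow(df), length(unique(df$clonotype_id))))
  rownames(df) <- NULL
  df
}

#' Write a clonotype assignment table
#'
#' @param df data.frame with columns `barcode`, `clonotype_id`.
#' @param csv_path Output path.
#' @return The path, invisibly.
#' @export
write_clonotypes <- function(df, csv_path) {
  if (anyDuplicated(df$barcode)) stop("duplicate barcode(s)")
  utils::write.csv(df[, c("barcode", "clonotype_id")], csv_path,
                   row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}
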