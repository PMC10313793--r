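#' Assign tissue compartments and junction status to spots
#'
#' Every in-tissue spot is assigned to the epidermis when the epidermis
#' gate rule (default: any keratin of KRT5/KRT14/KRT1/KRT10/KRTDAP) is
#' positive, and to the dermis otherwise. A spot is flagged as lying at the
#' dermo-epidermal junction when at least one adjacent spot (center
#' distance <= 1.2 x pitch) belongs to the other compartment.
#'
#' Spot coordinates in micrometers are derived either from the array grid
#' (`array_col`/`array_row` times `pitch`) or from full-resolution pixel
#' coordinates scaled by `um_per_px`.
#'
#' @param positions Positions data.frame from [read_positions()].
#' @param calls Positivity matrix over spots from [call_positive()].
#' @param epidermis_rule A `gate_rule`; default keratin gate from
#'   [default_gate_rules()].
#' @param pitch Center-to-center spot spacing in micrometers (default 100).
#' @param coords `"array"` (default) or `"pixel"`.
#' @param um_per_px Micrometers per pixel, required for `coords = "pixel"`.
#' @return A `spot_frame` data.frame: `barcode`, `x`, `y` (micrometers),
#'   `compartment` (factor epidermis/dermis), `junction` (logical).
#' @export
assign_compartments <- function(positions, calls, epidermis_rule = NULL,
                                pitch = 100, coords = c("array", "pixel"),
                                um_per_px = NULL) {
  coords <- match.arg(coords)
  if (pitch <= 0) stop("pitch must be positive")
  if (is.null(epidermis_rule)) epidermis_rule <- default_gate_rules()$epidermis
  pos <- positions[positions$in_tissue == 1L, , drop = FALSE]
  pos <- pos[pos$barcode %in% colnames(calls), , drop = FALSE]
  if (!nrow(pos)) stop("no in-tissue spots with positivity calls")
  if (coords == "array") {
    x <- pos$array_col * pitch
    y <- pos$array_row * pitch
  } else {
    if (is.null(um_per_px)) stop("um_per_px required for pixel coordinates")
    x <- pos$pxl_col_in_fullres * um_per_px
    y <- pos$pxl_row_in_fullres * um_per_px
  }
  epi <- gate_spots(calls[, pos$barcode, drop = FALSE], epidermis_rule)
  compartment <- factor(ifelse(epi, "epidermis", "dermis"),
                        levels = c("epidermis", "dermis"))
  if (!any(epi)) {
    warning("no epidermal spots under the epidermis rule; ",
            "junction flags all FALSE")
  }
  junction <- rep(FALSE, nrow(pos))
  if (any(epi) && any(!epi)) {
    dm <- as.matrix(stats::dist(cbind(x, y)))
    adj <- dm <= 1.2 * pitch & dm > 0
    other <- outer(epi, epi, FUN = "!=")
    junction <- apply(adj & other, 1, any)
  }
  sf <- data.frame(barcode = pos$barcode, x = x, y = y,
                   compartment = compartment, junction = junction,
                   stringsAsFactors = FALSE)
  rownames(sf) <- sf$barcode
  class(sf) <- c("spot_frame", "data.frame")
  sf
}

#' Minimum Euclidean distance from each source spot to a target class
#'
#' For every source spot, the exact minimum over target spots of the
#' Euclidean distance between spot centers (micrometers).
#'
#' @param sources Two-column matrix or data.frame of source coordinates
#'   (x, y), or a `spot_frame` subset.
#' @param targets Same, for the target class; must be non-empty.
#' @param target_class Label used in error messages.
#' @return Numeric vector, one minimum distance per source spot.
#' @export
min_distance_to_class <- function(sources, targets,
                                  target_class = "target") {
  sources <- spot_xy(sources)
  targets <- spot_xy(targets)
  if (!nrow(targets)) {
    stop("empty target spot set for class '", target_class, "'")
  }
  if (!nrow(sources)) return(numeric(0))
  tx <- targets[, 1]
  ty <- targets[, 2]
  vapply(seq_len(nrow(sources)), function(i) {
    min(sqrt((tx - sources[i, 1])^2 + (ty - sources[i, 2])^2))
  }, numeric(1))
}

spot_xy <- function(s) {
  if (is.data.frame(s)) {
    if (all(c("x", "y") %in% names(s))) {
      return(as.matrix(s[, c("x", "y")]))
    }
    return(as.matrix(s[, 1:2]))
  }
  m <- as.matrix(s)
  if (length(m) == 0) matrix(numeric(0), 0, 2) else m
}

ks_D_stat <- function(a, b) {
  pooled <- sort(c(a, b))
  fa <- findInterval(pooled, sort(a)) / length(a)
  fb <- findInterval(pooled, sort(b)) / length(b)
  max(abs(fa - fb))
}

ks_asymptotic_p <- function(D, n, m, tol = 1e-12) {
  lambda <- sqrt(n * m / (n + m)) * D
  if (lambda == 0) return(1)
  p <- 0
  j <- 1
  repeat {
    term <- 2 * (-1)^(j - 1) * exp(-2 * j^2 * lambda^2)
    p <- p + term
    if (abs(term) < tol) break
    j <- j + 1
    if (j > 10000) break
  }
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic `D` is the supremum over the pooled sample points of the
#' absolute difference between the two empirical cumulative distribution
#' functions (for step ECDFs the supremum is attained at a pooled point).
#' The two-sided p-value comes from the asymptotic series
#' `Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2)` with
#' `lambda = sqrt(nm/(n+m)) * D`, truncated when a term drops below 1e-12
#' and clamped to \[0, 1\]. Optionally a permutation p-value from seeded
#' label shuffles is computed as well.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param n_perm Number of label permutations for the optional permutation
#'   p-value (0 to skip).
#' @param seed Seed for the permutation shuffles.
#' @param alpha Significance threshold carried in the result (default
#'   0.05).
#' @return Object of class `ks_result`: list with `D`, `p` (asymptotic),
#'   `p_perm` (or `NA`), `n`, `m`, `alpha`, `significant`.
#' @export
ks_two_sample <- function(a, b, n_perm = 0, seed = NULL, alpha = 0.05) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n <- length(a)
  m <- length(b)
  D <- ks_D_stat(a, b)
  p <- ks_asymptotic_p(D, n, m)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    pool <- c(a, b)
    ge <- 0L
    for (r in seq_len(n_perm)) {
      idx <- sample.int(n + m, n)
      if (ks_D_stat(pool[idx], pool[-idx]) >= D - 1e-15) ge <- ge + 1L
    }
    p_perm <- (1 + ge) / (n_perm + 1)
  }
  structure(
    list(D = D, p = p, p_perm = p_perm, n = n, m = m, alpha = alpha,
         significant = p < alpha),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "Two-sample KS test: D = %.4f, p = %.4g (n = %d, m = %d)%s\n",
    x$D, x$p, x$n, x$m,
    if (!is.na(x$p_perm)) sprintf(", permutation p = %.4g", x$p_perm) else ""
  ))
  cat(sprintf("  %s at alpha = %g\n",
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Count class-flagged spots in contact with the epidermis
#'
#' A class-flagged spot is "in contact" when it is itself epidermal or
#' carries the junction flag (i.e. is adjacent to the other compartment);
#' dermal spots away from the junction are "not in contact".
#'
#' @param sf A `spot_frame` from [assign_compartments()].
#' @param classes Named list of logical vectors over the spots of `sf`
#'   (e.g. outputs of [gate_spots()] subset to `sf$barcode`).
#' @return data.frame with columns `class`, `in_contact`,
#'   `not_in_contact`.
#' @export
contact_counts <- function(sf, classes) {
  contact <- sf$compartment == "epidermis" | sf$junction
  res <- lapply(names(classes), function(nm) {
    fl <- classes[[nm]][sf$barcode]
    data.frame(class = nm,
               in_contact = sum(fl & contact),
               not_in_contact = sum(fl & !contact))
  })
  do.call(rbind, res)
}

#' Co-expression of a secondary gene in junction spots of a primary class
#'
#' Among junction-flagged spots that pass the primary gate, the percentage
#' that are also positive for the secondary gene. Exact counts are always
#' reported; with an empty denominator the percentage is undefined (`NA`),
#' not zero.
#'
#' @param sf A `spot_frame`.
#' @param primary_flags Logical vector over spots (e.g. the IL26 T-cell
#'   gate from [gate_spots()]).
#' @param calls Positivity matrix over spots.
#' @param secondary_gene Gene id looked up in `calls` (e.g. `"TGFB1"`).
#' @return List with `percent`, `n_pos`, `n_junction_primary`.
#' @export
junction_coexpression <- function(sf, primary_flags, calls,
                                  secondary_gene) {
  if (!secondary_gene %in% rownames(calls)) {
    stop("no positivity calls for ", secondary_gene)
  }
  prim <- primary_flags[sf$barcode] & sf$junction
  denom <- sum(prim)
  n_pos <- if (denom) {
    sum(calls[secondary_gene, sf$barcode[prim]])
  } else 0L
  list(
    percent = if (denom) 100 * n_pos / denom else NA_real_,
    n_pos = as.integer(n_pos),
    n_junction_primary = as.integer(denom)
  )
}
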