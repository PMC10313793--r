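#' Build a k-nearest-neighbor cell graph
#'
#' Constructs the union k-NN graph on an embedding: an undirected edge joins
#' two observations when either lists the other among its `k` nearest
#' neighbors (Euclidean distance). Neighbor ties are broken by observation
#' id order. If the union graph is disconnected, the single shortest
#' inter-component point pair is joined, iterating until connected, so that
#' geodesic distances are finite everywhere.
#'
#' @param e Embedding matrix (observations x d) with barcode row names.
#' @param k Neighbor count (default 15).
#' @return An `igraph` undirected graph with vertex names and a `weight`
#'   edge attribute (Euclidean distances; coincident points get weight 0).
#' @export
build_cell_graph <- function(e, k = 15) {
  n <- nrow(e)
  if (n < 2) stop("need at least 2 observations")
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of observations")
  if (is.null(rownames(e))) rownames(e) <- as.character(seq_len(n))
  dm <- as.matrix(stats::dist(e))
  ids <- rownames(e)
  # k nearest per node, ties broken by observation id order
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ], ids, method = "radix")
    ord <- ord[ord != i][seq_len(k)]
    edges[[i]] <- cbind(i, ord)
  }
  ep <- do.call(rbind, edges)
  ep <- cbind(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2]))
  ep <- unique(ep)
  g <- igraph::graph_from_edgelist(ep, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::V(g)$name <- ids
  igraph::E(g)$weight <- dm[ep]
  # augment until connected: globally shortest inter-component pair
  repeat {
    comp <- igraph::components(g)
    if (comp$no == 1) break
    best <- NULL
    best_d <- Inf
    for (a in seq_len(comp$no - 1)) {
      ia <- which(comp$membership == a)
      for (b in seq(a + 1, comp$no)) {
        ib <- which(comp$membership == b)
        sub <- dm[ia, ib, drop = FALSE]
        w <- which.min(sub)
        if (sub[w] < best_d) {
          best_d <- sub[w]
          ri <- (w - 1) %% length(ia) + 1
          ci <- (w - 1) %/% length(ia) + 1
          best <- c(ia[ri], ib[ci])
        }
      }
    }
    g <- igraph::add_edges(g, best, weight = best_d)
  }
  g
}

#' Infer geodesic pseudotime from marker-defined roots
#'
#' Root cells are those whose normalized expression of `root_marker` exceeds
#' `root_threshold`; each cell's pseudotime is the shortest-path (geodesic)
#' distance in the cell graph to its nearest root. Roots sit at pseudotime
#' zero.
#'
#' @param g Cell graph from [build_cell_graph()].
#' @param nm Normalized matrix (genes x observations) on the log scale on
#'   which the threshold is meaningful.
#' @param root_marker Gene id defining the root population (default
#'   `"CCR7"`).
#' @param root_threshold Normalized-expression threshold (default 2.5).
#' @return An object of class `pseudotime_result`: list with `pseudotime`
#'   (named numeric, one entry per cell), `root_set`, `root_marker`,
#'   `root_threshold`.
#' @export
infer_pseudotime <- function(g, nm, root_marker = "CCR7",
                             root_threshold = 2.5) {
  ids <- igraph::V(g)$name
  if (!root_marker %in% rownames(nm)) {
    stop("root marker ", root_marker, " not in the matrix")
  }
  expr <- as.numeric(nm[root_marker, ids])
  roots <- ids[expr > root_threshold]
  if (!length(roots)) {
    stop("no cell exceeds ", root_marker, " > ", root_threshold,
         " on the normalized scale; lower root_threshold")
  }
  dmat <- igraph::distances(g, v = roots, to = igraph::V(g),
                            algorithm = "dijkstra")
  pt <- apply(dmat, 2, min)
  names(pt) <- ids
  structure(
    list(pseudotime = pt, root_set = roots, root_marker = root_marker,
         root_threshold = root_threshold),
    class = "pseudotime_result"
  )
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf(
    "Geodesic pseudotime over %d cells\n  roots: %d cells with %s > %g\n  range: [0, %.4g]\n",
    length(x$pseudotime), length(x$root_set), x$root_marker,
    x$root_threshold, max(x$pseudotime)
  ))
  invisible(x)
}

#' Bin cells into early / intermediate / late pseudotime stages
#'
#' Default mode bins at the 1/3 and 2/3 pseudotime quantiles; absolute mode
#' uses fixed thresholds (default 10 and 15, matching pseudotime units of
#' the principal-graph toolchain this package's geodesic scale replaces).
#' Cells strictly below the lower threshold are early, strictly above the
#' upper are late; boundary values fall in the intermediate stage.
#'
#' @param pt A `pseudotime_result` or named numeric vector.
#' @param mode `"quantile"` or `"absolute"`.
#' @param thresholds Length-2 numeric: quantile probabilities in (0,1) for
#'   quantile mode (default `c(1/3, 2/3)`), pseudotime values for absolute
#'   mode (default `c(10, 15)`).
#' @return An object of class `stage_assignment`: list with `stage` (named
#'   factor with levels early/intermediate/late), `t1`, `t2`, `mode`.
#' @export
assign_stage <- function(pt, mode = c("quantile", "absolute"),
                         thresholds = NULL) {
  mode <- match.arg(mode)
  if (inherits(pt, "pseudotime_result")) pt <- pt$pseudotime
  if (is.null(thresholds)) {
    thresholds <- if (mode == "quantile") c(1 / 3, 2 / 3) else c(10, 15)
  }
  if (thresholds[1] >= thresholds[2]) stop("thresholds must satisfy t1 < t2")
  if (mode == "quantile") {
    if (any(thresholds <= 0 | thresholds >= 1)) {
      stop("quantile thresholds must lie in (0, 1)")
    }
    tt <- stats::quantile(pt, thresholds, names = FALSE)
  } else {
    tt <- thresholds
  }
  stage <- ifelse(pt < tt[1], "early", ifelse(pt > tt[2], "late",
                                              "intermediate"))
  stage <- factor(stage, levels = c("early", "intermediate", "late"))
  names(stage) <- names(pt)
  structure(list(stage = stage, t1 = tt[1], t2 = tt[2], mode = mode),
            class = "stage_assignment")
}

#' @export
print.stage_assignment <- function(x, ...) {
  tab <- table(x$stage)
  cat(sprintf(
    "Stage assignment (%s mode, t1 = %.4g, t2 = %.4g)\n  early %d | intermediate %d | late %d\n",
    x$mode, x$t1, x$t2, tab["early"], tab["intermediate"], tab["late"]
  ))
  invisible(x)
}

#' Fit an expression trend over pseudotime
#'
#' Least-squares fit of expression on a natural cubic spline basis in
#' pseudotime with `df` degrees of freedom (internal knots at equispaced
#' pseudotime quantiles, the `splines::ns` default), evaluated over a grid
#' spanning the observed pseudotime range.
#'
#' @param pt A `pseudotime_result` or numeric vector.
#' @param expr Numeric expression vector aligned with `pt`.
#' @param df Spline degrees of freedom (default 4).
#' @param n_grid Grid resolution for the fitted curve (default 100).
#' @param gene Optional gene label carried in the result.
#' @return Object of class `trend_fit`: list with `gene`, `df`,
#'   `coefficients`, `grid`, `fitted` (curve on the grid), and the in-sample
#'   `residuals`.
#' @export
fit_trend <- function(pt, expr, df = 4, n_grid = 100, gene = NULL) {
  if (inherits(pt, "pseudotime_result")) pt <- pt$pseudotime
  if (length(pt) != length(expr)) stop("pt and expr lengths differ")
  if (df < 1) stop("df must be >= 1")
  if (length(unique(pt)) < df + 2) {
    stop("need at least df + 2 distinct pseudotime values")
  }
  basis <- splines::ns(pt, df = df)
  fit <- stats::lm(expr ~ basis)
  grid <- seq(min(pt), max(pt), length.out = n_grid)
  gb <- stats::predict(basis, grid)
  fitted <- drop(cbind(1, gb) %*% stats::coef(fit))
  structure(
    list(gene = gene, df = df, coefficients = stats::coef(fit),
         grid = grid, fitted = fitted, residuals = stats::resid(fit)),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Natural-spline trend fit%s (df = %d)\n  grid [%.4g, %.4g], fitted range [%.4g, %.4g]\n",
    if (is.null(x$gene)) "" else paste0(" for ", x$gene), x$df,
    min(x$grid), max(x$grid), min(x$fitted), max(x$fitted)
  ))
  invisible(x)
}
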