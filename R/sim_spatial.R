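#' Configuration for the synthetic spatial dataset
#'
#' A rectangular spot grid with an epidermal band on top and dermis below.
#' TGFB1-expressing keratinocytes sit mostly in the basal epidermal row;
#' IL26 T-cell spots are placed in the dermis with a row-offset law that is
#' either exponentially concentrated below the dermo-epidermal junction or
#' uniform (the null), while IFNG T-cell spots are always uniform over the
#' dermis. Junction-adjacent IL26 spots co-express TGFB1 at a configurable
#' rate.
#'
#' @param rows,cols Grid dimensions (defaults 40 x 40).
#' @param pitch Spot spacing in micrometers (default 100).
#' @param epidermis_rows Number of epidermal rows at the top (default 6);
#'   the deepest of them is the basal row.
#' @param p_basal,p_suprabasal Probability that a basal / suprabasal
#'   epidermal spot is a TGFB1+ keratinocyte (defaults 0.6, 0.05).
#' @param n_t_spots T-cell spots per class (default 50).
#' @param il26_law `"exponential"` (colocalized, default) or `"uniform"`
#'   (the delta = 0 null in which both T classes follow the same law).
#' @param il26_rate Rate (per row) of the exponential row-offset law for
#'   IL26 spots (default 0.8).
#' @param copos_rate TGFB1 co-positivity rate of junction-adjacent IL26
#'   spots (default 0.97).
#' @param lambda_high Poisson mean of designated marker emission
#'   (default 5).
#' @param lambda_low Poisson mean of background marker emission (default
#'   0.05). Structural keratin genes are emitted only in the epidermis so
#'   that compartment labels reflect the designed anatomy.
#' @param n_background_genes Pure-noise genes (default 10).
#' @param seed Global seed; substreams use fixed offsets.
#' @return List of class `spatial_sim_config`.
#' @export
spatial_sim_config <- function(rows = 40, cols = 40, pitch = 100,
                               epidermis_rows = 6,
                               p_basal = 0.6, p_suprabasal = 0.05,
                               n_t_spots = 50,
                               il26_law = c("exponential", "uniform"),
                               il26_rate = 0.8,
                               copos_rate = 0.97,
                               lambda_high = 5, lambda_low = 0.05,
                               n_background_genes = 10,
                               seed = 0) {
  il26_law <- match.arg(il26_law)
  stopifnot(rows >= 3, cols >= 2, pitch > 0,
            epidermis_rows >= 1, epidermis_rows < rows,
            p_basal >= 0, p_basal <= 1, p_suprabasal >= 0,
            p_suprabasal <= 1, copos_rate >= 0, copos_rate <= 1,
            il26_rate > 0, lambda_high > 0, lambda_low >= 0)
  structure(as.list(environment()), class = "spatial_sim_config")
}

#' Generate a synthetic spatial spot dataset with ground truth
#'
#' @param cfg A `spatial_sim_config`.
#' @return List with `counts` (genes x spots sparse matrix), `positions`
#'   (tissue-positions data.frame, all in tissue), `truth` (per-spot
#'   placement class and designed row offset below the junction) and
#'   `config`. Deterministic given config and seed.
#' @export
generate_spatial_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "spatial_sim_config"))
  grid <- expand.grid(array_row = seq_len(cfg$rows),
                      array_col = seq_len(cfg$cols))
  n_spots <- nrow(grid)
  barcodes <- sprintf("spot_%03d_%03d", grid$array_row, grid$array_col)
  epi <- grid$array_row <= cfg$epidermis_rows
  basal <- grid$array_row == cfg$epidermis_rows
  dermal_rows <- cfg$rows - cfg$epidermis_rows
  if (2 * cfg$n_t_spots > sum(!epi)) {
    stop("more T spots requested than dermal positions")
  }

  # TGFB1+ keratinocyte designation
  set.seed(cfg$seed + 11L)
  kc_tgfb1 <- rep(FALSE, n_spots)
  kc_tgfb1[basal] <- stats::runif(sum(basal)) < cfg$p_basal
  supra <- epi & !basal
  kc_tgfb1[supra] <- stats::runif(sum(supra)) < cfg$p_suprabasal

  # T-spot placement in the dermis; offset = rows below the junction
  place_class <- rep("none", n_spots)
  offset <- rep(NA_integer_, n_spots)
  draw_offsets <- function(nn, law) {
    if (law == "exponential") {
      pmin(1L + as.integer(floor(stats::rexp(nn, rate = cfg$il26_rate))),
           dermal_rows)
    } else {
      sample.int(dermal_rows, nn, replace = TRUE)
    }
  }
  place_spots <- function(offs, taken) {
    chosen <- integer(0)
    for (off in offs) {
      repeat {
        row <- cfg$epidermis_rows + off
        free <- which(grid$array_row == row & !taken)
        if (length(free)) break
        off <- if (off < dermal_rows) off + 1L else 1L
      }
      pick <- free[sample.int(length(free), 1)]
      taken[pick] <- TRUE
      chosen <- c(chosen, pick)
    }
    list(idx = chosen, taken = taken)
  }
  taken <- epi
  set.seed(cfg$seed + 12L)
  off26 <- draw_offsets(cfg$n_t_spots, cfg$il26_law)
  pl26 <- place_spots(off26, taken)
  taken <- pl26$taken
  set.seed(cfg$seed + 13L)
  offifng <- draw_offsets(cfg$n_t_spots, "uniform")
  plifng <- place_spots(offifng, taken)
  place_class[pl26$idx] <- "il26_t"
  place_class[plifng$idx] <- "ifng_t"
  offset[pl26$idx] <- grid$array_row[pl26$idx] - cfg$epidermis_rows
  offset[plifng$idx] <- grid$array_row[plifng$idx] - cfg$epidermis_rows

  # junction co-positivity: IL26 spots directly below the basal row
  set.seed(cfg$seed + 14L)
  junction_il26 <- place_class == "il26_t" &
    grid$array_row == cfg$epidermis_rows + 1L
  copos <- rep(FALSE, n_spots)
  copos[junction_il26] <- stats::runif(sum(junction_il26)) < cfg$copos_rate

  keratins <- c("KRT5", "KRT14", "KRT1", "KRT10", "KRTDAP")
  markers <- c(keratins, "TGFB1", "CD3D", "CD3E", "CD3G", "IL26", "IFNG",
               "IL17A")
  bg_genes <- if (cfg$n_background_genes > 0) {
    sprintf("BG%03d", seq_len(cfg$n_background_genes))
  } else character(0)
  genes <- c(markers, bg_genes)

  set.seed(cfg$seed + 15L)
  counts <- matrix(stats::rpois(length(genes) * n_spots, cfg$lambda_low),
                   length(genes), n_spots,
                   dimnames = list(genes, barcodes))
  # structural keratins: epidermis only, so compartments are anatomical
  counts[keratins, !epi] <- 0L
  add_high <- function(gene, which_spots) {
    nn <- sum(which_spots)
    if (nn) {
      counts[gene, which_spots] <<- counts[gene, which_spots] +
        stats::rpois(nn, cfg$lambda_high)
    }
  }
  for (kg in keratins) add_high(kg, epi)
  add_high("TGFB1", kc_tgfb1)
  is_t <- place_class != "none"
  for (cg in c("CD3D", "CD3E", "CD3G")) add_high(cg, is_t)
  add_high("IL26", place_class == "il26_t")
  add_high("IFNG", place_class == "ifng_t")
  add_high("TGFB1", copos)
  # junction IL26 spots not designated co-positive carry no background
  # TGFB1 either, so the designed co-positivity rate is exact
  counts["TGFB1", junction_il26 & !copos] <- 0L

  positions <- data.frame(
    barcode = barcodes, in_tissue = 1L,
    array_row = grid$array_row, array_col = grid$array_col,
    pxl_row_in_fullres = grid$array_row * cfg$pitch,
    pxl_col_in_fullres = grid$array_col * cfg$pitch,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    barcode = barcodes,
    epidermis = epi,
    kc_tgfb1 = kc_tgfb1,
    place_class = place_class,
    row_offset = offset,
    junction_il26 = junction_il26,
    tgfb1_copositive = copos,
    stringsAsFactors = FALSE
  )
  list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                         "CsparseMatrix"),
    positions = positions,
    truth = truth,
    config = cfg
  )
}
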