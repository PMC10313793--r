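#' Default gene expression programs for the cell simulator
#'
#' The stock program table emulates a single TH17 differentiation
#' continuum: a CCR7-high root program that decays along latent time, an
#' early IL26 bump, a late logistic IL17A program, TGF-beta signature
#' genes rising monotonically, plus co-regulated naive and effector
#' markers that give the continuum a recoverable multi-gene footprint.
#'
#' @return data.frame with columns `gene`, `type` (one of `root_marker`,
#'   `early_bump`, `late_logistic`, `monotone_up`, `constant`),
#'   `amplitude`, `center`, `scale`, `baseline`.
#' @export
default_gene_programs <- function() {
  sig <- signature_spec("methods")$genes
  naive <- c("SELL", "TCF7", "LEF1", "IL7R", "CD27")
  effector <- c("IL22", "IL21", "IFNG", "TNF", "CSF2", "GZMB")
  mid <- c("IL2", "TNFRSF4")
  rbind(
    data.frame(gene = "CCR7", type = "root_marker", amplitude = 3,
               center = 0.08, scale = 0.03, baseline = 0.02),
    data.frame(gene = "IL26", type = "early_bump", amplitude = 6,
               center = 0.25, scale = 0.12, baseline = 0.02),
    data.frame(gene = "IL17A", type = "late_logistic", amplitude = 6,
               center = 0.7, scale = 0.08, baseline = 0.01),
    data.frame(gene = sig, type = "monotone_up", amplitude = 3,
               center = NA, scale = NA, baseline = 0.3),
    data.frame(gene = naive, type = "root_marker", amplitude = 4,
               center = 0.3, scale = 0.1, baseline = 0.1),
    data.frame(gene = effector, type = "late_logistic", amplitude = 4,
               center = 0.65, scale = 0.1, baseline = 0.05),
    data.frame(gene = mid, type = "early_bump", amplitude = 3,
               center = 0.45, scale = 0.15, baseline = 0.1)
  )
}

#' Configuration for the synthetic single-cell dataset
#'
#' @param n_cells Number of cells (default 2000).
#' @param t_max Latent-time horizon (default 1).
#' @param lib_meanlog,lib_sdlog Lognormal library-size parameters
#'   (defaults log(2500), 0.35).
#' @param dispersion Negative-binomial size parameter (default 2); use
#'   `Inf` for the Poisson limit.
#' @param programs Gene program table (see [default_gene_programs()]).
#' @param n_background_genes Constant background genes (default 200).
#' @param background_baseline Relative mean of background genes (default 1).
#' @param zipf_exponent Clone-size power-law exponent (default 2).
#' @param persistent_fraction Fraction of clones whose cells span the full
#'   latent-time range (default 0.2); the rest are transient.
#' @param transient_window Width of the latent-time window of transient
#'   clones, as a fraction of `t_max` (default 0.25).
#' @param force_il26_provenance When `TRUE`, IL17A expression is restricted
#'   to designated persistent clones (those with at least
#'   `min_designed_cells` cells in each latent-time third), which are
#'   guaranteed IL17A-positive cells late and IL26-positive cells early —
#'   so the designed late-IL17A clone provenance fraction is exactly 1.
#' @param min_designed_cells Minimum cells per latent-time third for a
#'   clone to be designated under `force_il26_provenance` (default 4).
#' @param seed Global seed; per-stream substreams use fixed offsets.
#' @return List of class `cell_sim_config`.
#' @export
cell_sim_config <- function(n_cells = 2000, t_max = 1,
                            lib_meanlog = log(4000), lib_sdlog = 0.35,
                            dispersion = 2,
                            programs = default_gene_programs(),
                            n_background_genes = 200,
                            background_baseline = 1,
                            zipf_exponent = 2,
                            persistent_fraction = 0.2,
                            transient_window = 0.25,
                            force_il26_provenance = FALSE,
                            min_designed_cells = 4,
                            seed = 0) {
  if (anyDuplicated(programs$gene)) {
    stop("gene programs reference duplicate gene ids")
  }
  stopifnot(n_cells >= 2, t_max > 0, dispersion > 0,
            persistent_fraction >= 0, persistent_fraction <= 1,
            transient_window > 0, transient_window <= 1,
            all(programs$amplitude >= 0))
  structure(as.list(environment()), class = "cell_sim_config")
}

program_mean <- function(prog, t, t_max) {
  sigmoid <- function(z) 1 / (1 + exp(-z))
  switch(prog$type,
    root_marker = prog$baseline +
      prog$amplitude * sigmoid((prog$center - t) / prog$scale),
    early_bump = prog$baseline +
      prog$amplitude * exp(-(t - prog$center)^2 / (2 * prog$scale^2)),
    late_logistic = prog$baseline +
      prog$amplitude * sigmoid((t - prog$center) / prog$scale),
    monotone_up = prog$baseline + prog$amplitude * t / t_max,
    constant = rep(prog$baseline, length(t)),
    stop("unknown program type: ", prog$type)
  )
}

draw_clone_sizes <- function(n_cells, exponent) {
  smax <- n_cells
  probs <- (1:smax)^(-exponent)
  probs <- probs / sum(probs)
  sizes <- integer(0)
  while (sum(sizes) < n_cells) {
    sizes <- c(sizes, sample.int(smax, 200, replace = TRUE, prob = probs))
  }
  cum <- cumsum(sizes)
  k <- which(cum >= n_cells)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n_cells)
  sizes[sizes > 0]
}

#' Generate a synthetic single-cell dataset with ground truth
#'
#' Cells get latent times uniform on `[0, t_max]`; each gene's mean follows
#' its program curve, counts are negative-binomial around per-cell library
#' sizes, and clones (Zipf-distributed sizes) draw their member cells
#' either from the whole time range (persistent) or from a random window
#' (transient). The output is deterministic given the config and seed.
#'
#' @param cfg A `cell_sim_config`.
#' @return List with `counts` (sparse gene x cell matrix), `clonotypes`
#'   (data.frame barcode/clonotype_id), `truth` (data.frame with latent
#'   time, clone id, clone class, designation flag and realized IL26/IL17A
#'   positivity per cell) and `config`.
#' @export
generate_cell_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "cell_sim_config"))
  n <- cfg$n_cells
  barcodes <- sprintf("cell_%05d", seq_len(n))

  set.seed(cfg$seed + 1L)
  t <- stats::runif(n, 0, cfg$t_max)

  set.seed(cfg$seed + 2L)
  lib <- stats::rlnorm(n, cfg$lib_meanlog, cfg$lib_sdlog)

  progs <- cfg$programs
  bg_genes <- if (cfg$n_background_genes > 0) {
    sprintf("BG%04d", seq_len(cfg$n_background_genes))
  } else character(0)
  genes <- c(progs$gene, bg_genes)
  mu <- matrix(cfg$background_baseline, length(genes), n,
               dimnames = list(genes, barcodes))
  for (i in seq_len(nrow(progs))) {
    mu[progs$gene[i], ] <- program_mean(progs[i, ], t, cfg$t_max)
  }
  mu <- sweep(mu, 2, colSums(mu), "/")
  mu <- sweep(mu, 2, lib, "*")

  set.seed(cfg$seed + 3L)
  counts <- if (is.finite(cfg$dispersion)) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion),
           nrow(mu), ncol(mu), dimnames = dimnames(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu),
           nrow(mu), ncol(mu), dimnames = dimnames(mu))
  }

  # clones: transient clones draw from a latent-time window, persistent
  # clones from the full range
  set.seed(cfg$seed + 4L)
  sizes <- draw_clone_sizes(n, cfg$zipf_exponent)
  n_clones <- length(sizes)
  clone_ids <- sprintf("clone_%04d", seq_len(n_clones))
  n_pers <- round(cfg$persistent_fraction * n_clones)
  pers <- rep(FALSE, n_clones)
  if (n_pers > 0) pers[sample.int(n_clones, n_pers)] <- TRUE
  width <- cfg$transient_window * cfg$t_max
  assignment <- rep(NA_character_, n)
  pool <- seq_len(n)
  designated_idx <- integer(0)
  if (cfg$force_il26_provenance) {
    # construct designated clones deliberately: the largest clones are
    # made persistent with a guaranteed spread over the latent thirds
    need <- 3 * cfg$min_designed_cells
    big <- order(-sizes)[seq_len(min(6, sum(sizes >= need)))]
    if (!length(big)) {
      stop("force_il26_provenance: no clone is large enough to hold ",
           cfg$min_designed_cells, " cells in every latent-time third")
    }
    designated_idx <- big
    pers[big] <- TRUE
    third_of <- findInterval(t, c(cfg$t_max / 3, 2 * cfg$t_max / 3)) + 1L
    for (ci in big) {
      sz <- sizes[ci]
      quota <- rep(sz %/% 3, 3) + (seq_len(3) <= sz %% 3)
      take <- integer(0)
      for (th in 1:3) {
        cand <- pool[third_of[pool] == th]
        k_take <- min(quota[th], length(cand))
        if (k_take) take <- c(take, cand[sample.int(length(cand), k_take)])
        pool <- setdiff(pool, take)
      }
      short <- sz - length(take)
      if (short > 0 && length(pool)) {
        extra <- pool[sample.int(length(pool), min(short, length(pool)))]
        take <- c(take, extra)
        pool <- setdiff(pool, extra)
      }
      assignment[take] <- clone_ids[ci]
    }
  }
  # persistent clones first, so windowed clones cannot drain any part
  # of the time range before the spanning clones are placed
  for (ci in setdiff(c(which(pers), which(!pers)), designated_idx)) {
    sz <- sizes[ci]
    if (!length(pool)) break
    if (pers[ci]) {
      if (sz >= 9 && length(pool) >= sz) {
        # large persistent clones spread over the latent thirds by
        # design, so stage-spanning clones exist at every seed
        third_of <- findInterval(t[pool], c(cfg$t_max / 3,
                                            2 * cfg$t_max / 3)) + 1L
        quota <- rep(sz %/% 3, 3) + (seq_len(3) <= sz %% 3)
        take <- integer(0)
        for (th in 1:3) {
          cand <- pool[third_of == th & !(pool %in% take)]
          k_take <- min(quota[th], length(cand))
          if (k_take) {
            take <- c(take, cand[sample.int(length(cand), k_take)])
          }
        }
        short <- sz - length(take)
        if (short > 0) {
          rest <- setdiff(pool, take)
          take <- c(take, rest[sample.int(length(rest),
                                          min(short, length(rest)))])
        }
      } else {
        take <- pool[sample.int(length(pool), min(sz, length(pool)))]
      }
    } else {
      w0 <- stats::runif(1, 0, cfg$t_max - width)
      cand <- pool[t[pool] >= w0 & t[pool] <= w0 + width]
      if (length(cand) >= sz) {
        take <- cand[sample.int(length(cand), sz)]
      } else {
        # window underfilled: complete with the nearest remaining cells
        rest <- setdiff(pool, cand)
        extra <- rest[order(abs(t[rest] - (w0 + width / 2)))]
        take <- c(cand, extra[seq_len(sz - length(cand))])
      }
    }
    assignment[take] <- clone_ids[ci]
    pool <- setdiff(pool, take)
  }
  if (length(pool)) assignment[pool] <- clone_ids[n_clones]

  designated <- character(0)
  if (cfg$force_il26_provenance) {
    thirds <- cut(t, breaks = c(-Inf, cfg$t_max / 3, 2 * cfg$t_max / 3, Inf),
                  labels = c("T1", "T2", "T3"))
    tab <- table(assignment, thirds)
    ok <- rownames(tab)[apply(tab >= cfg$min_designed_cells, 1, all)]
    designated <- intersect(ok, clone_ids[designated_idx])
    if (!length(designated)) {
      stop("force_il26_provenance: designated clones lost their ",
           "latent-time spread; increase n_cells")
    }
    in_desig <- assignment %in% designated
    counts["IL17A", !in_desig] <- 0
    late_cells <- in_desig & t > 2 * cfg$t_max / 3
    counts["IL17A", late_cells] <- pmax(counts["IL17A", late_cells], 1)
    early_cells <- in_desig & t < cfg$t_max / 2
    counts["IL26", early_cells] <- pmax(counts["IL26", early_cells], 1)
  }

  truth <- data.frame(
    barcode = barcodes,
    latent_time = t,
    clonotype_id = assignment,
    clone_class = ifelse(assignment %in% clone_ids[pers],
                         "persistent", "transient"),
    designated = assignment %in% designated,
    il26_pos = counts["IL26", ] > 0,
    il17a_pos = counts["IL17A", ] > 0,
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  sm <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  list(
    counts = sm,
    clonotypes = data.frame(barcode = barcodes, clonotype_id = assignment,
                            stringsAsFactors = FALSE),
    truth = truth,
    config = cfg
  )
}
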