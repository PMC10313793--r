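config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[setdiff(names(cfg), "programs")]), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, cfg, seed, counts_in,
                           name = "manifest.json") {
  manifest <- list(
    tool = "th17traj",
    version = as.character(utils::packageVersion("th17traj")),
    seed = seed,
    config_hash = config_hash(cfg),
    record_counts = counts_in
  )
  jsonlite::write_json(manifest, file.path(out_dir, name),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the single-cell trajectory and clone-tracking pipeline
#'
#' Generates (or accepts) a cell dataset, normalizes it, embeds it,
#' infers geodesic pseudotime from the marker-defined roots, bins stages,
#' fits cytokine trends, tracks clonotypes across stages and scores the
#' TGF-beta signature. All stage outputs are written as plain CSV/JSON
#' into `out_dir` together with a run manifest; reruns with the same
#' config and seed produce byte-identical files.
#'
#' @param cfg A `cell_sim_config`; its `seed` drives all randomness.
#' @param out_dir Output directory (created).
#' @param n_var_genes Variable genes to select (capped at the gene count;
#'   default 7500).
#' @param d Embedding dimensionality (default 15).
#' @param k Neighbor count of the cell graph (default 15).
#' @param root_marker,root_threshold Root definition (defaults CCR7, 2.5
#'   on the log-normalized scale).
#' @param stage_mode `"quantile"` (default) or `"absolute"` stage binning.
#' @param stage_thresholds Optional thresholds passed to [assign_stage()].
#' @param trend_genes Genes whose pseudotime trends are fitted
#'   (default IL26 and IL17A).
#' @param signature A `signature_spec` (default the methods preset).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_cell_pipeline <- function(cfg = cell_sim_config(), out_dir,
                              n_var_genes = 7500, d = 15, k = 15,
                              root_marker = "CCR7", root_threshold = 2.5,
                              stage_mode = "quantile",
                              stage_thresholds = NULL,
                              trend_genes = c("IL26", "IL17A"),
                              signature = signature_spec("methods")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- generate_cell_dataset(cfg)
  write_count_matrix(sim$counts, file.path(out_dir, "cell_counts"))
  write_clonotypes(sim$clonotypes, file.path(out_dir, "clonotypes.csv"))
  utils::write.csv(sim$truth, file.path(out_dir, "cell_truth.csv"),
                   row.names = FALSE, quote = FALSE)

  nm <- normalize_counts(sim$counts)
  calls <- call_positive(sim$counts, c("IL26", "IL17A"))
  hv <- select_variable_genes(nm, min(n_var_genes, nrow(nm)))
  emb <- embed_pca(nm, hv, d = min(d, length(hv), ncol(nm)))
  g <- build_cell_graph(emb, k = k)
  pt <- infer_pseudotime(g, nm, root_marker, root_threshold)
  stages <- assign_stage(pt, mode = stage_mode,
                         thresholds = stage_thresholds)
  pt_df <- data.frame(
    barcode = names(pt$pseudotime),
    pseudotime = unname(pt$pseudotime),
    stage = as.character(stages$stage[names(pt$pseudotime)]),
    is_root = names(pt$pseudotime) %in% pt$root_set
  )
  utils::write.csv(pt_df, file.path(out_dir, "pseudotime.csv"),
                   row.names = FALSE, quote = FALSE)

  trends <- lapply(trend_genes, function(gg) {
    fit_trend(pt, as.numeric(nm[gg, names(pt$pseudotime)]), gene = gg)
  })
  names(trends) <- trend_genes
  trend_df <- data.frame(pseudotime = trends[[1]]$grid)
  for (gg in trend_genes) trend_df[[gg]] <- trends[[gg]]$fitted
  utils::write.csv(trend_df, file.path(out_dir, "trend.csv"),
                   row.names = FALSE, quote = FALSE)

  cst <- clone_stage_table(sim$clonotypes, stages, calls)
  utils::write.csv(cst, file.path(out_dir, "clone_stage_table.csv"),
                   row.names = FALSE, quote = FALSE)
  vc <- venn_counts(cst)
  utils::write.csv(
    data.frame(subset = names(vc), n_clones = as.integer(vc)),
    file.path(out_dir, "venn.csv"), row.names = FALSE, quote = FALSE
  )
  flows <- sankey_flows(cst)
  utils::write.csv(flows, file.path(out_dir, "flows.csv"),
                   row.names = FALSE, quote = FALSE)
  prov <- late_producer_provenance(cst)
  jsonlite::write_json(unclass(prov)[1:5],
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  score <- score_cells(nm, signature)
  utils::write.csv(
    data.frame(barcode = names(score), score = unname(score)),
    file.path(out_dir, "score.csv"), row.names = FALSE, quote = FALSE
  )
  cmp <- list(IL17A = compare_score_by_state(score, calls, "IL17A"),
              IL26 = compare_score_by_state(score, calls, "IL26"))
  jsonlite::write_json(cmp, file.path(out_dir, "signature_comparison.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  write_manifest(out_dir, cfg, cfg$seed, list(
    cells = ncol(sim$counts), genes = nrow(sim$counts),
    clones = length(unique(sim$clonotypes$clonotype_id)),
    roots = length(pt$root_set)
  ), name = "cell_manifest.json")
  invisible(list(sim = sim, nm = nm, calls = calls, embedding = emb,
                 graph = g, pseudotime = pt, stages = stages,
                 trends = trends, clone_stage_table = cst, venn = vc,
                 flows = flows, provenance = prov, score = score,
                 comparison = cmp))
}

#' Run the spatial gating and colocalization pipeline
#'
#' Generates (or accepts) a spatial dataset, calls spot positivity,
#' assigns compartments and junction flags, gates the marker classes,
#' computes minimum distances between the TGFB1+ keratinocyte class and
#' each T-cell class, compares the two distance distributions with the
#' two-sample KS test, counts epidermal contact of cytokine spots and
#' estimates junction co-expression. Outputs are written to `out_dir` as
#' CSV/JSON plus a manifest; reruns are byte-identical.
#'
#' @param cfg A `spatial_sim_config`.
#' @param out_dir Output directory (created).
#' @param direction `"kc_to_t"` (default; per keratinocyte spot, distance
#'   to the nearest T-cell spot of each class) or `"t_to_kc"` (per T-cell
#'   spot, distance to the nearest TGFB1+ keratinocyte spot).
#' @param n_perm Permutations for the optional KS permutation p (0 off).
#' @param rules Gate rules (default [default_gate_rules()]).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_spatial_pipeline <- function(cfg = spatial_sim_config(), out_dir,
                                 direction = c("kc_to_t", "t_to_kc"),
                                 n_perm = 0,
                                 rules = default_gate_rules()) {
  direction <- match.arg(direction)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- generate_spatial_dataset(cfg)
  write_count_matrix(sim$counts, file.path(out_dir, "spatial_counts"))
  write_positions(sim$positions, file.path(out_dir, "tissue_positions.csv"))
  utils::write.csv(sim$truth, file.path(out_dir, "spatial_truth.csv"),
                   row.names = FALSE, quote = FALSE)

  calls <- call_positive(sim$counts, rownames(sim$counts))
  sf <- assign_compartments(sim$positions, calls, rules$epidermis,
                            pitch = cfg$pitch)
  flags <- lapply(rules[c("t_il26", "t_ifng", "t_il17a", "kc_tgfb1")],
                  function(r) gate_spots(calls, r)[sf$barcode])
  cls_df <- data.frame(barcode = sf$barcode,
                       compartment = as.character(sf$compartment),
                       junction = sf$junction)
  for (nm2 in names(flags)) cls_df[[nm2]] <- flags[[nm2]]
  utils::write.csv(cls_df, file.path(out_dir, "spot_classes.csv"),
                   row.names = FALSE, quote = FALSE)

  kc_xy <- sf[flags$kc_tgfb1, c("x", "y")]
  il26_xy <- sf[flags$t_il26, c("x", "y")]
  ifng_xy <- sf[flags$t_ifng, c("x", "y")]
  if (direction == "kc_to_t") {
    d_il26 <- min_distance_to_class(kc_xy, il26_xy, "t_il26")
    d_ifng <- min_distance_to_class(kc_xy, ifng_xy, "t_ifng")
  } else {
    d_il26 <- min_distance_to_class(il26_xy, kc_xy, "kc_tgfb1")
    d_ifng <- min_distance_to_class(ifng_xy, kc_xy, "kc_tgfb1")
  }
  dist_df <- rbind(
    data.frame(class = "il26", distance_um = d_il26),
    data.frame(class = "ifng", distance_um = d_ifng)
  )
  utils::write.csv(dist_df, file.path(out_dir, "distances.csv"),
                   row.names = FALSE, quote = FALSE)
  ks <- ks_two_sample(d_il26, d_ifng, n_perm = n_perm,
                      seed = cfg$seed + 21L)
  jsonlite::write_json(
    c(unclass(ks)[c("D", "p", "p_perm", "n", "m", "alpha")],
      list(direction = direction)),
    file.path(out_dir, "ks.json"), auto_unbox = TRUE, digits = NA,
    na = "null"
  )

  cc <- contact_counts(sf, flags[c("t_il26", "t_il17a")])
  utils::write.csv(cc, file.path(out_dir, "contact_counts.csv"),
                   row.names = FALSE, quote = FALSE)
  jc <- junction_coexpression(sf, flags$t_il26, calls, "TGFB1")
  jsonlite::write_json(jc, file.path(out_dir,
                                     "junction_coexpression.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  write_manifest(out_dir, cfg, cfg$seed, list(
    spots = ncol(sim$counts), genes = nrow(sim$counts),
    kc_tgfb1 = sum(flags$kc_tgfb1), t_il26 = sum(flags$t_il26),
    t_ifng = sum(flags$t_ifng)
  ), name = "spatial_manifest.json")
  invisible(list(sim = sim, calls = calls, spot_frame = sf, flags = flags,
                 distances = list(il26 = d_il26, ifng = d_ifng), ks = ks,
                 contact = cc, junction_coexpression = jc))
}
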