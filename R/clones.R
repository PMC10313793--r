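#' Per-clone, per-stage cell counts with cytokine positivity
#'
#' Inner-joins the clonotype table, the stage assignment and the positivity
#' calls on cell barcodes and tabulates, for every observed (clonotype,
#' stage) pair, the number of cells and the number of IL26- and
#' IL17A-positive cells. Barcodes missing from any input are logged and
#' dropped; pairs with no cells are implicitly zero.
#'
#' @param clones data.frame with `barcode`, `clonotype_id` (see
#'   [read_clonotypes()]).
#' @param stages A `stage_assignment` from [assign_stage()].
#' @param calls Positivity matrix from [call_positive()] containing rows
#'   for `il26_gene` and `il17a_gene`.
#' @param il26_gene,il17a_gene Row names in `calls` used as the early and
#'   late cytokine markers (defaults `"IL26"`, `"IL17A"`).
#' @return data.frame of class `clone_stage_table` with columns
#'   `clonotype_id`, `stage`, `n_cells`, `n_IL26_pos`, `n_IL17A_pos`.
#' @export
clone_stage_table <- function(clones, stages, calls,
                              il26_gene = "IL26", il17a_gene = "IL17A") {
  if (inherits(stages, "stage_assignment")) stages <- stages$stage
  for (gg in c(il26_gene, il17a_gene)) {
    if (!gg %in% rownames(calls)) stop("no positivity calls for ", gg)
  }
  common <- intersect(clones$barcode,
                      intersect(names(stages), colnames(calls)))
  dropped <- nrow(clones) - length(common)
  if (dropped > 0) {
    message(sprintf(
      "clone_stage_table: %d clonotype-assigned barcode(s) not in stage/positivity inputs; dropped",
      dropped))
  }
  if (!length(common)) stop("no barcodes shared across inputs")
  df <- data.frame(
    clonotype_id = clones$clonotype_id[match(common, clones$barcode)],
    stage = stages[common],
    il26 = calls[il26_gene, common],
    il17a = calls[il17a_gene, common],
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(
    cbind(n_cells = 1L, n_IL26_pos = df$il26, n_IL17A_pos = df$il17a),
    by = list(clonotype_id = df$clonotype_id, stage = df$stage), FUN = sum
  )
  agg <- agg[order(agg$clonotype_id, agg$stage), ]
  rownames(agg) <- NULL
  agg$stage <- factor(agg$stage, levels = c("early", "intermediate", "late"))
  class(agg) <- c("clone_stage_table", "data.frame")
  agg
}

presence_matrix <- function(t, min_cells = 1) {
  stopifnot(min_cells >= 1)
  clones <- sort(unique(t$clonotype_id))
  pm <- matrix(FALSE, length(clones), 3,
               dimnames = list(clones, c("early", "intermediate", "late")))
  keep <- t$n_cells >= min_cells
  pm[cbind(match(t$clonotype_id[keep], clones),
           as.integer(t$stage[keep]))] <- TRUE
  pm
}

#' Venn counts of clone presence across stages
#'
#' A clone is present in a stage when it has at least `min_cells` cells
#' there; every clone present in at least one stage is assigned to exactly
#' one of the 7 non-empty subsets of \{early, intermediate, late\}.
#'
#' @param t A `clone_stage_table`.
#' @param min_cells Presence threshold (default 1).
#' @return Named integer vector over the 7 subsets
#'   (`early`, `intermediate`, `late`, `early&intermediate`,
#'   `early&late`, `intermediate&late`, `early&intermediate&late`),
#'   with attribute `n_clones` (clones present in >= 1 stage).
#' @export
venn_counts <- function(t, min_cells = 1) {
  pm <- presence_matrix(t, min_cells)
  pm <- pm[rowSums(pm) > 0, , drop = FALSE]
  subsets <- apply(pm, 1, function(r) paste(colnames(pm)[r], collapse = "&"))
  labels <- c("early", "intermediate", "late",
              "early&intermediate", "early&late", "intermediate&late",
              "early&intermediate&late")
  counts <- stats::setNames(integer(7), labels)
  tab <- table(subsets)
  counts[names(tab)] <- as.integer(tab)
  attr(counts, "n_clones") <- nrow(pm)
  counts
}

#' Provenance of late-stage IL17A-producing clones
#'
#' A clone is a late IL17A producer when it has at least one IL17A-positive
#' cell in the late stage. For those clones, counts how many were present
#' in the early stage at all, and how many had an IL26-positive cell there
#' ("early IL26+ correspondence"). Fractions are reported with their exact
#' numerator and denominator; when there are no late IL17A+ clones the
#' fractions are undefined (`NA`), not zero.
#'
#' @param t A `clone_stage_table`.
#' @param min_cells Presence threshold for "present in early" (default 1).
#' @return Object of class `clone_provenance`: list with
#'   `n_late_IL17A_clones`, `n_with_early_presence`,
#'   `n_with_early_IL26pos`, `frac_early_presence`, `frac_early_IL26pos`.
#' @export
late_producer_provenance <- function(t, min_cells = 1) {
  late <- t[t$stage == "late" & t$n_IL17A_pos >= 1, ]
  late_clones <- unique(late$clonotype_id)
  early <- t[t$stage == "early" & t$n_cells >= min_cells, ]
  early_pres <- unique(early$clonotype_id)
  early_il26 <- unique(early$clonotype_id[early$n_IL26_pos >= 1])
  n_late <- length(late_clones)
  n_pres <- sum(late_clones %in% early_pres)
  n_il26 <- sum(late_clones %in% early_il26)
  structure(
    list(
      n_late_IL17A_clones = n_late,
      n_with_early_presence = n_pres,
      n_with_early_IL26pos = n_il26,
      frac_early_presence = if (n_late) n_pres / n_late else NA_real_,
      frac_early_IL26pos = if (n_late) n_il26 / n_late else NA_real_,
      late_clones = late_clones
    ),
    class = "clone_provenance"
  )
}

#' @export
print.clone_provenance <- function(x, ...) {
  cat(sprintf("Late IL17A+ clones: %d\n", x$n_late_IL17A_clones))
  if (x$n_late_IL17A_clones == 0) {
    cat("  provenance fractions undefined (no late IL17A+ clones)\n")
  } else {
    cat(sprintf("  with early-stage presence: %d/%d (%.3f)\n",
                x$n_with_early_presence, x$n_late_IL17A_clones,
                x$frac_early_presence))
    cat(sprintf("  with early IL26+ correspondence: %d/%d (%.3f)\n",
                x$n_with_early_IL26pos, x$n_late_IL17A_clones,
                x$frac_early_IL26pos))
  }
  invisible(x)
}

#' Early-to-late cytokine-state flows of shared clones
#'
#' Clones present in both the early and the late stage are classified by
#' their early IL26 state and late IL17A state (a clone is positive in a
#' stage when it has any positive cell there), yielding the four flows of
#' a Sankey diagram.
#'
#' @param t A `clone_stage_table`.
#' @param min_cells Presence threshold (default 1).
#' @return data.frame with columns `source_state` (early IL26+/IL26-),
#'   `target_state` (late IL17A+/IL17A-), `n_clones`; total equals the
#'   number of clones present in both early and late.
#' @export
sankey_flows <- function(t, min_cells = 1) {
  pm <- presence_matrix(t, min_cells)
  shared <- rownames(pm)[pm[, "early"] & pm[, "late"]]
  flows <- expand.grid(
    source_state = c("early_IL26+", "early_IL26-"),
    target_state = c("late_IL17A+", "late_IL17A-"),
    stringsAsFactors = FALSE
  )
  flows$n_clones <- 0L
  if (length(shared)) {
    e <- t[t$stage == "early" & t$clonotype_id %in% shared, ]
    l <- t[t$stage == "late" & t$clonotype_id %in% shared, ]
    il26 <- stats::setNames(e$n_IL26_pos >= 1, e$clonotype_id)[shared]
    il17 <- stats::setNames(l$n_IL17A_pos >= 1, l$clonotype_id)[shared]
    src <- ifelse(il26, "early_IL26+", "early_IL26-")
    tgt <- ifelse(il17, "late_IL17A+", "late_IL17A-")
    tab <- table(src, tgt)
    for (r in seq_len(nrow(flows))) {
      s <- flows$source_state[r]
      g <- flows$target_state[r]
      if (s %in% rownames(tab) && g %in% colnames(tab)) {
        flows$n_clones[r] <- tab[s, g]
      }
    }
  }
  flows
}
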