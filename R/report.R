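#' Assemble a run report from pipeline stage outputs
#'
#' Collects the stage CSV/JSON outputs found in `run_dir` (cell and/or
#' spatial pipeline runs) into a report directory holding the Venn table,
#' the Sankey flow table, the distance ECDF data annotated with the KS
#' statistic, the contact-count table and the fitted trend curves, plus
#' static ECDF and trend figures. Every number in the report tables is
#' copied from the stage outputs; nothing is recomputed. Missing stage
#' outputs yield a partial report and an error listing the gaps.
#'
#' @param run_dir Directory holding pipeline outputs (and a manifest).
#' @param out_dir Report directory (default `run_dir`/report).
#' @return Invisibly, the paths of the report files written.
#' @export
build_report <- function(run_dir, out_dir = file.path(run_dir, "report")) {
  if (!dir.exists(run_dir)) stop("run directory not found: ", run_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  missing <- character(0)
  grab <- function(name) {
    p <- file.path(run_dir, name)
    if (file.exists(p)) p else {
      missing <<- c(missing, name)
      NULL
    }
  }

  venn <- grab("venn.csv")
  if (!is.null(venn)) {
    file.copy(venn, file.path(out_dir, "report_venn.csv"),
              overwrite = TRUE)
    written <- c(written, file.path(out_dir, "report_venn.csv"))
  }
  flows <- grab("flows.csv")
  if (!is.null(flows)) {
    file.copy(flows, file.path(out_dir, "report_flows.csv"),
              overwrite = TRUE)
    written <- c(written, file.path(out_dir, "report_flows.csv"))
  }
  trends <- grab("trend.csv")
  if (!is.null(trends)) {
    file.copy(trends, file.path(out_dir, "report_trends.csv"),
              overwrite = TRUE)
    written <- c(written, file.path(out_dir, "report_trends.csv"))
    tr <- utils::read.csv(trends)
    fig <- file.path(out_dir, "trends.png")
    grDevices::png(fig, width = 640, height = 480)
    genes <- setdiff(names(tr), "pseudotime")
    graphics::matplot(tr$pseudotime, as.matrix(tr[genes]), type = "l",
                      lty = 1, lwd = 2, xlab = "pseudotime",
                      ylab = "fitted normalized expression",
                      main = "Expression trends over pseudotime")
    graphics::legend("topright", legend = genes, lty = 1, lwd = 2,
                     col = seq_along(genes))
    grDevices::dev.off()
    written <- c(written, fig)
  }
  dists <- grab("distances.csv")
  ksj <- grab("ks.json")
  if (!is.null(dists) && !is.null(ksj)) {
    dd <- utils::read.csv(dists)
    ks <- jsonlite::read_json(ksj)
    ecdf_rows <- do.call(rbind, lapply(split(dd, dd$class), function(s) {
      x <- sort(s$distance_um)
      data.frame(class = s$class[1], distance_um = x,
                 ecdf = seq_along(x) / length(x))
    }))
    ecdf_rows$ks_D <- ks$D
    ecdf_rows$ks_p <- ks$p
    utils::write.csv(ecdf_rows, file.path(out_dir, "report_ecdf.csv"),
                     row.names = FALSE, quote = FALSE)
    written <- c(written, file.path(out_dir, "report_ecdf.csv"))
    fig <- file.path(out_dir, "ecdf.png")
    grDevices::png(fig, width = 640, height = 480)
    cls <- split(dd$distance_um, dd$class)
    graphics::plot(stats::ecdf(cls[[1]]), col = "forestgreen",
                   main = sprintf("Minimum-distance ECDFs (D = %.3f, p = %.3g)",
                                  ks$D, ks$p),
                   xlab = "minimum distance (um)", ylab = "ECDF")
    graphics::plot(stats::ecdf(cls[[2]]), col = "gray40", add = TRUE)
    graphics::legend("bottomright", legend = names(cls), lty = 1,
                     col = c("forestgreen", "gray40"))
    grDevices::dev.off()
    written <- c(written, fig)
  } else if (is.null(dists) || is.null(ksj)) {
    # either file missing is already recorded by grab()
  }
  contact <- grab("contact_counts.csv")
  if (!is.null(contact)) {
    file.copy(contact, file.path(out_dir, "report_contact_counts.csv"),
              overwrite = TRUE)
    written <- c(written, file.path(out_dir, "report_contact_counts.csv"))
  }

  if (length(missing)) {
    stop("report incomplete; missing stage output(s): ",
         paste(unique(missing), collapse = ", "),
         " (partial report written to ", out_dir, ")")
  }
  invisible(written)
}
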