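#' Heat map of SLR profiles
#'
#' Probe x (replicate, timepoint) grid on a diverging scale centered at
#' SLR 0 (up-regulation warm, down-regulation cool), rows ordered by
#' agglomerative clustering under Euclidean distance via
#' [hierarchical_order()]. Requires the pheatmap package.
#'
#' @param tcs a `time_course_set`.
#' @param probes probe subset to draw (>= 2).
#' @param filename optional output image path (passed to pheatmap).
#' @param ... further arguments passed to [pheatmap::pheatmap()].
#' @return invisibly, the pheatmap object.
#' @export
plot_slr_heatmap <- function(tcs, probes, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop_format("plot_slr_heatmap requires the pheatmap package")
  }
  stopifnot(inherits(tcs, "time_course_set"))
  cols <- list()
  for (ti in seq_along(tcs$timepoints_weeks)) {
    for (ri in seq_along(tcs$replicates)) {
      if (tcs$available[ri, ti]) {
        cols[[sprintf("%dwk_rep%d", tcs$timepoints_weeks[ti],
                      tcs$replicates[ri])]] <- tcs$slr[probes, ri, ti]
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- probes
  ord <- hierarchical_order(m)$order
  lim <- max(abs(m))
  p <- pheatmap::pheatmap(
    m[ord, , drop = FALSE], cluster_rows = FALSE, cluster_cols = FALSE,
    breaks = seq(-lim, lim, length.out = 101),
    color = grDevices::colorRampPalette(c("blue", "white", "red"))(100),
    filename = filename, ...)
  invisible(p)
}
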