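# Global summaries over filtered probe sets: dataset intersection,
# direction-of-change counts, SLR distributions, the functional-annotation
# enrichment-score convention, and fold-change table summarization.

#' Intersect two filtered probe sets
#'
#' Set algebra between the survivors of two comparisons (e.g. sham and
#' DMM time courses), with gene counts through the annotation.
#'
#' @param set_a,set_b character vectors of probe ids.
#' @param annotation optional `"probe_annotation"` for gene counts.
#' @param labels names of the two sets for reporting.
#' @return object of class `"overlap_result"`: list with `both`,
#'   `a_only`, `b_only`, `labels`, and `gene_counts` (named integer
#'   vector, `NA` without annotation).
#' @export
intersect_sets <- function(set_a, set_b, annotation = NULL,
                           labels = c("a", "b")) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  both <- intersect(set_a, set_b)
  a_only <- setdiff(set_a, set_b)
  b_only <- setdiff(set_b, set_a)
  gc_fun <- function(p) if (is.null(annotation)) NA_integer_
                        else gene_count(annotation, p)
  structure(
    list(both = both, a_only = a_only, b_only = b_only, labels = labels,
         gene_counts = c(both = gc_fun(both), a_only = gc_fun(a_only),
                         b_only = gc_fun(b_only))),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d probe sets in both; %d only in %s; %d only in %s\n",
              length(x$both), length(x$a_only), x$labels[1],
              length(x$b_only), x$labels[2]))
  if (!is.na(x$gene_counts["both"])) {
    cat(sprintf("gene counts: both %d, %s-only %d, %s-only %d\n",
                x$gene_counts["both"], x$labels[1], x$gene_counts["a_only"],
                x$labels[2], x$gene_counts["b_only"]))
  }
  invisible(x)
}

#' Per-timepoint direction-of-change summary
#'
#' Counts probes up- (mean SLR at or above the bound), down- (at or below
#' the negative bound) and unregulated at each timepoint, using the
#' replicate-mean SLR and the same magnitude bound as the filter. Also
#' returns the long per-replicate SLR table that supports distribution
#' (density) plots, where uni- vs bi-modality of the SLR distribution
#' distinguishes globally drifting from phasically regulated sets.
#'
#' @param tcs a `time_course_set`.
#' @param probes probe subset (default: all probes in `tcs`).
#' @param slr_abs_min magnitude bound; default 0.5.
#' @return object of class `"direction_summary"`: list with `counts`
#'   (data frame timepoint_weeks / up / down / unchanged) and `slr_long`
#'   (probe_id, replicate, timepoint_weeks, slr).
#' @export
direction_summary <- function(tcs, probes = NULL, slr_abs_min = 0.5) {
  stopifnot(inherits(tcs, "time_course_set"))
  if (is.null(probes)) probes <- tcs$probe_ids
  mp <- mean_profiles(tcs, probes)
  counts <- data.frame(
    timepoint_weeks = tcs$timepoints_weeks,
    up = colSums(mp >= slr_abs_min),
    down = colSums(mp <= -slr_abs_min),
    unchanged = colSums(mp > -slr_abs_min & mp < slr_abs_min),
    row.names = NULL
  )
  idx <- expand.grid(probe = probes, rep = seq_along(tcs$replicates),
                     tp = seq_along(tcs$timepoints_weeks))
  slr_long <- data.frame(
    probe_id = as.character(idx$probe),
    replicate = tcs$replicates[idx$rep],
    timepoint_weeks = tcs$timepoints_weeks[idx$tp],
    slr = tcs$slr[cbind(match(as.character(idx$probe), tcs$probe_ids),
                        idx$rep, idx$tp)],
    stringsAsFactors = FALSE
  )
  slr_long <- slr_long[!is.na(slr_long$slr), , drop = FALSE]
  rownames(slr_long) <- NULL
  structure(list(counts = counts, slr_long = slr_long,
                 slr_abs_min = slr_abs_min),
            class = "direction_summary")
}

#' @export
print.direction_summary <- function(x, ...) {
  cat(sprintf("direction of change at |SLR| >= %g (replicate-mean SLR):\n",
              x$slr_abs_min))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Functional-annotation enrichment score
#'
#' The DAVID convention: minus the log10 of the geometric mean of the
#' member annotation p-values, so a score of 1.3 corresponds to a
#' geometric-mean p of 0.05.
#'
#' @param p_values numeric vector with all values in `(0, 1]`.
#' @return the enrichment score (a non-negative number when all p <= 1).
#' @export
enrichment_score <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0) stop_format("no p-values supplied")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_format("all p-values must lie in (0, 1]")
  }
  -log10(exp(mean(log(p_values))))
}

#' Summarize a fold-change table per timepoint
#'
#' Unweighted arithmetic mean of the linear fold changes down each
#' timepoint column, rounded to 2 decimals for reporting. Gene row order
#' is irrelevant; missing cells are an error (no imputation).
#'
#' @param fold_changes numeric matrix or data frame, genes x timepoints,
#'   all values > 0.
#' @return named numeric vector of per-timepoint mean fold changes.
#' @export
summarize_fold_changes <- function(fold_changes) {
  m <- as.matrix(fold_changes)
  if (!is.numeric(m)) stop_format("fold-change table must be numeric")
  if (anyNA(m)) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    stop_format("missing fold-change cell(s): %s",
                paste(sprintf("[%s, %s]",
                              rownames(m)[gaps[, 1]] %||% gaps[, 1],
                              colnames(m)[gaps[, 2]] %||% gaps[, 2]),
                      collapse = ", "))
  }
  if (any(m <= 0)) stop_format("fold changes must be > 0")
  round(colMeans(m), 2)
}

#' Bundled RT-PCR fold-change table
#'
#' Example table of RT-PCR fold changes (DMM joints relative to
#' time-matched sham controls) for a 16-gene validation panel at 2, 4, 8
#' and 16 weeks after surgery, with the reported per-gene p-values
#' (non-significant entries stored as `NA`).
#'
#' @return list with `fold_change` (16 x 4 numeric matrix, genes in rows)
#'   and `p_value` (same shape).
#' @export
rtpcr_fold_changes <- function() {
  path <- system.file("extdata", "rtpcr_dmm_fold_changes.tsv",
                      package = "slrpipe", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tps <- c("2wk", "4wk", "8wk", "16wk")
  fc <- as.matrix(tab[paste0("fold_change_", tps)])
  pv <- as.matrix(tab[paste0("p_value_", tps)])
  dimnames(fc) <- dimnames(pv) <- list(tab$gene, tps)
  list(fold_change = fc, p_value = pv)
}
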