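#' Construct a dual-layer expression matrix
#'
#' Container for normalized microarray data carrying, per probe set and
#' array, both the log2 signal intensity and the detection p-value (the
#' per-array evidence that the transcript was measured above background).
#' Samples are normalized to a canonical order (group, timepoint,
#' replicate) so that files whose columns arrive permuted yield identical
#' objects.
#'
#' @param intensity numeric matrix of log2 signal intensities, probes in
#'   rows (rownames are probe-set ids), arrays in columns (colnames are
#'   array ids).
#' @param detection_p numeric matrix of detection p-values in `[0, 1]`,
#'   same shape and dimnames as `intensity`.
#' @param samples data frame with columns `array_id`, `group` (one of
#'   `"baseline"`, `"sham"`, `"dmm"`), `timepoint_weeks` (0 for baseline,
#'   otherwise 2/4/8/16) and `replicate_index` (>= 1); one row per array.
#' @return An object of class `"expr_matrix"`: a list with elements
#'   `intensity`, `detection_p` and `samples`, columns ordered by
#'   (group, timepoint, replicate).
#' @export
expression_matrix <- function(intensity, detection_p, samples) {
  intensity <- as.matrix(intensity)
  detection_p <- as.matrix(detection_p)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  required <- c("array_id", "group", "timepoint_weeks", "replicate_index")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop_format("sample sheet is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  samples$array_id <- as.character(samples$array_id)
  samples$group <- as.character(samples$group)
  samples$timepoint_weeks <- as.integer(samples$timepoint_weeks)
  samples$replicate_index <- as.integer(samples$replicate_index)

  bad_group <- setdiff(unique(samples$group), c("baseline", "sham", "dmm"))
  if (length(bad_group) > 0) {
    stop_format("unknown group(s): %s", paste(bad_group, collapse = ", "))
  }
  if (any(!samples$timepoint_weeks %in% c(0L, 2L, 4L, 8L, 16L))) {
    stop_format("timepoint_weeks must be one of 0, 2, 4, 8, 16")
  }
  if (any(samples$group == "baseline" & samples$timepoint_weeks != 0L)) {
    stop_format("baseline samples must have timepoint_weeks = 0")
  }
  if (any(samples$group != "baseline" & samples$timepoint_weeks == 0L)) {
    stop_format("non-baseline samples must have a non-zero timepoint")
  }
  if (any(samples$replicate_index < 1L)) {
    stop_format("replicate_index must be >= 1")
  }
  key <- paste(samples$group, samples$timepoint_weeks, samples$replicate_index)
  if (anyDuplicated(key)) {
    stop_format("duplicate (group, timepoint, replicate) in sample sheet: %s",
                key[duplicated(key)][1])
  }
  if (anyDuplicated(samples$array_id)) {
    stop_format("duplicate array_id in sample sheet")
  }

  if (!identical(dim(intensity), dim(detection_p))) {
    stop_format("intensity and detection_p must have identical shape")
  }
  if (is.null(rownames(intensity))) {
    stop_format("intensity must carry probe ids as rownames")
  }
  if (anyDuplicated(rownames(intensity))) {
    stop_format("duplicate probe_id: %s",
                rownames(intensity)[duplicated(rownames(intensity))][1])
  }
  missing_arrays <- setdiff(samples$array_id, colnames(intensity))
  if (length(missing_arrays) > 0) {
    stop_format("expression matrix has no columns for declared array(s): %s",
                paste(missing_arrays, collapse = ", "))
  }
  # Canonical sample order; drop any matrix columns not on the sheet.
  grp <- factor(samples$group, levels = c("baseline", "sham", "dmm"))
  ord <- order(grp, samples$timepoint_weeks, samples$replicate_index)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  intensity <- intensity[, samples$array_id, drop = FALSE]
  detection_p <- detection_p[, samples$array_id, drop = FALSE]
  dimnames(detection_p) <- dimnames(intensity)

  if (anyNA(intensity) || anyNA(detection_p)) {
    stop_format("missing values within a present array are not allowed")
  }
  if (any(!is.finite(intensity))) {
    stop_format("non-finite log2 intensities are not allowed")
  }
  if (any(detection_p < 0 | detection_p > 1)) {
    stop_format("detection p-values must lie in [0, 1]")
  }

  structure(
    list(intensity = intensity, detection_p = detection_p, samples = samples),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probe sets x %d arrays\n",
              nrow(x$intensity), ncol(x$intensity)))
  tab <- table(x$samples$group, x$samples$timepoint_weeks)
  cat("arrays per (group, timepoint in weeks):\n")
  print(tab)
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$intensity)

#' Probe-set identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of probe-set ids.
#' @export
probe_ids <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  rownames(x$intensity)
}

# Arrays belonging to one design cell, in replicate order.
arrays_for <- function(x, group, timepoint) {
  s <- x$samples
  sel <- s[s$group == group & s$timepoint_weeks == timepoint, , drop = FALSE]
  sel <- sel[order(sel$replicate_index), , drop = FALSE]
  sel
}
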