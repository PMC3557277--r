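# Signal-log-ratio (SLR) time courses. The SLR is the log2 fold change of
# a sample pool over its control average; an SLR of 0.5 is a 1.4-fold
# change. Controls are averaged on the log2 scale (the stored layer), i.e.
# the geometric mean of linear intensities, to give a consistent baseline.

TIMEPOINTS_WEEKS <- c(2L, 4L, 8L, 16L)

#' Average control intensities for one design cell
#'
#' Per-probe arithmetic mean of log2 intensities over all arrays of one
#' (group, timepoint) cell.
#'
#' @param x an `expr_matrix`.
#' @param group `"baseline"`, `"sham"` or `"dmm"`.
#' @param timepoint timepoint in weeks (0 for baseline).
#' @return named numeric vector, one value per probe set.
#' @export
average_baseline <- function(x, group, timepoint) {
  stopifnot(inherits(x, "expr_matrix"))
  sel <- arrays_for(x, group, timepoint)
  if (nrow(sel) == 0) {
    stop_format("no arrays for group '%s' at %d weeks", group, timepoint)
  }
  rowMeans(x$intensity[, sel$array_id, drop = FALSE])
}

#' Signal log ratio of a sample over its control
#'
#' `SLR = sample_log2 - baseline_log2`; the linear fold change is
#' `2^SLR`.
#'
#' @param sample_log2,baseline_log2 finite numeric vectors (recycled).
#' @return numeric vector of SLR values (log2 fold-change units).
#' @export
compute_slr <- function(sample_log2, baseline_log2) {
  sample_log2 - baseline_log2
}

#' Convert between SLR and linear fold change
#' @param slr numeric SLR values.
#' @return `slr_to_fold()`: `2^slr`; `fold_to_slr()`: `log2(fold)`.
#' @export
slr_to_fold <- function(slr) 2^slr

#' @rdname slr_to_fold
#' @param fold positive numeric fold changes.
#' @export
fold_to_slr <- function(fold) log2(fold)

#' Build replicate SLR time courses for one comparison
#'
#' For `"sham_vs_baseline"`, each sham replicate pool at each timepoint is
#' compared against the average of the time-0 baseline arrays (one shared
#' denominator). For `"dmm_vs_sham"`, each DMM replicate pool is compared
#' against the average of the time-matched sham arrays (one denominator per
#' timepoint). Each replicate is kept separate so replicate-to-replicate
#' consistency can be scored downstream; a missing array yields
#' `available = FALSE` at that (replicate, timepoint) and no SLR value.
#'
#' With the full design this gives 12 SLR values per probe for the sham
#' comparison (3 replicates x 4 timepoints) and 11 for the DMM comparison
#' when one 2-week pool is missing.
#'
#' @param x an `expr_matrix`.
#' @param comparison `"sham_vs_baseline"` or `"dmm_vs_sham"`.
#' @return an object of class `"time_course_set"`: list with
#'   \describe{
#'     \item{slr}{3-d array probe x replicate x timepoint, `NA` where
#'       masked}
#'     \item{available}{logical replicate x timepoint design mask}
#'     \item{numerator_arrays}{array ids per (replicate, timepoint), `NA`
#'       where missing}
#'     \item{denominator_arrays}{list per timepoint of the control array
#'       ids averaged into the SLR denominator}
#'     \item{comparison, probe_ids, replicates, timepoints_weeks}{design
#'       metadata}
#'   }
#' @export
build_time_course_set <- function(x, comparison = c("sham_vs_baseline",
                                                    "dmm_vs_sham")) {
  stopifnot(inherits(x, "expr_matrix"))
  comparison <- match.arg(comparison)
  num_group <- if (comparison == "sham_vs_baseline") "sham" else "dmm"

  s <- x$samples
  reps <- sort(unique(s$replicate_index[s$group == num_group]))
  if (length(reps) == 0) {
    stop_format("no '%s' arrays in the sample sheet", num_group)
  }
  tps <- TIMEPOINTS_WEEKS
  n_probe <- nrow(x$intensity)

  slr <- array(NA_real_, dim = c(n_probe, length(reps), length(tps)),
               dimnames = list(probe_ids(x), paste0("rep", reps),
                               paste0(tps, "wk")))
  available <- matrix(FALSE, length(reps), length(tps),
                      dimnames = dimnames(slr)[2:3])
  numerator_arrays <- matrix(NA_character_, length(reps), length(tps),
                             dimnames = dimnames(slr)[2:3])
  denominator_arrays <- vector("list", length(tps))
  names(denominator_arrays) <- paste0(tps, "wk")

  for (ti in seq_along(tps)) {
    if (comparison == "sham_vs_baseline") {
      den <- arrays_for(x, "baseline", 0L)
      if (nrow(den) == 0) stop_format("no baseline (time 0) arrays")
    } else {
      den <- arrays_for(x, "sham", tps[ti])
      if (nrow(den) == 0) {
        stop_format("no sham arrays at %d weeks to serve as control", tps[ti])
      }
    }
    denominator_arrays[[ti]] <- den$array_id
    base <- rowMeans(x$intensity[, den$array_id, drop = FALSE])
    cell <- arrays_for(x, num_group, tps[ti])
    for (ri in seq_along(reps)) {
      arr <- cell$array_id[cell$replicate_index == reps[ri]]
      if (length(arr) == 1) {
        slr[, ri, ti] <- compute_slr(x$intensity[, arr], base)
        available[ri, ti] <- TRUE
        numerator_arrays[ri, ti] <- arr
      }
    }
  }

  structure(
    list(slr = slr, available = available,
         numerator_arrays = numerator_arrays,
         denominator_arrays = denominator_arrays,
         comparison = comparison, probe_ids = probe_ids(x),
         replicates = reps, timepoints_weeks = tps),
    class = "time_course_set"
  )
}

#' @export
print.time_course_set <- function(x, ...) {
  cat(sprintf("time_course_set (%s): %d probe sets, %d replicates, %d SLR values/probe\n",
              x$comparison, length(x$probe_ids), length(x$replicates),
              sum(x$available)))
  invisible(x)
}

#' Number of SLR values per probe in a time-course set
#' @param tcs a `time_course_set`.
#' @return integer: replicates x timepoints minus masked cells.
#' @export
n_slr_values <- function(tcs) {
  stopifnot(inherits(tcs, "time_course_set"))
  sum(tcs$available)
}

#' Replicate-mean SLR profiles
#'
#' Per-probe mean SLR across available replicates at each timepoint.
#'
#' @param tcs a `time_course_set`.
#' @param probes optional probe subset.
#' @return numeric matrix, probes x timepoints.
#' @export
mean_profiles <- function(tcs, probes = NULL) {
  stopifnot(inherits(tcs, "time_course_set"))
  sl <- tcs$slr
  if (!is.null(probes)) sl <- sl[probes, , , drop = FALSE]
  apply(sl, c(1, 3), mean, na.rm = TRUE)
}

#' One replicate's SLR profiles in its reduced dimension
#'
#' Masked timepoints are dropped (not imputed), so a replicate missing the
#' 2-week arrays yields 3-dimensional profiles.
#'
#' @param tcs a `time_course_set`.
#' @param replicate replicate index (position within `tcs$replicates`).
#' @param probes optional probe subset.
#' @return numeric matrix, probes x available timepoints.
#' @export
replicate_profiles <- function(tcs, replicate, probes = NULL) {
  stopifnot(inherits(tcs, "time_course_set"))
  keep_tp <- tcs$available[replicate, ]
  m <- tcs$slr[, replicate, keep_tp, drop = FALSE]
  m <- matrix(m, nrow = dim(m)[1],
              dimnames = list(dimnames(m)[[1]], dimnames(m)[[3]]))
  if (!is.null(probes)) m <- m[probes, , drop = FALSE]
  m
}

#' Write replicate SLR time courses as TSV
#'
#' Columns: probe_id, comparison, replicate_index, slr_2wk, slr_4wk,
#' slr_8wk, slr_16wk; masked cells are left empty.
#'
#' @param tcs a `time_course_set`.
#' @param path output path.
#' @return invisibly, the data frame written.
#' @export
write_time_courses <- function(tcs, path) {
  stopifnot(inherits(tcs, "time_course_set"))
  rows <- do.call(rbind, lapply(seq_along(tcs$replicates), function(ri) {
    d <- data.frame(probe_id = tcs$probe_ids,
                    comparison = tcs$comparison,
                    replicate_index = tcs$replicates[ri],
                    stringsAsFactors = FALSE)
    for (ti in seq_along(tcs$timepoints_weeks)) {
      d[[sprintf("slr_%dwk", tcs$timepoints_weeks[ti])]] <- tcs$slr[, ri, ti]
    }
    d
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(rows)
}
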