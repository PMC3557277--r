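# Four-stage replicate-consistency filter. Probe sets must be (1)
# detected above background in every contributing array, (2) differentially
# expressed at >= 1 timepoint, independently in each replicate; (3) pass
# both in all replicates (overlap); and (4) show replicate-consistent
# pattern (Pearson correlation) and magnitude (Euclidean distance) with a
# 2-of-3 pairwise rule. All threshold comparisons are inclusive.

#' Filter parameters
#'
#' @param detection_p_max detection p-value bound (inclusive); default
#'   0.06.
#' @param slr_abs_min minimum absolute SLR at >= 1 timepoint (inclusive);
#'   default 0.5, i.e. 1.4-fold.
#' @param pcc_min minimum pairwise Pearson correlation (inclusive);
#'   default 0.70, a standard threshold for positive correlation.
#' @param ed_max maximum pairwise Euclidean distance (inclusive, SLR
#'   units): either a number or `"median"` to derive the cutoff as the
#'   median of all pairwise ED scores of the probes entering the
#'   consistency step. The study's derived values were 0.60 (DMM) and
#'   0.81 (sham).
#' @param min_passing_pairs how many of the 3 replicate pairs must pass
#'   each of the PCC and ED criteria; default 2.
#' @return an object of class `"filter_params"`.
#' @export
filter_params <- function(detection_p_max = 0.06, slr_abs_min = 0.5,
                          pcc_min = 0.70, ed_max = "median",
                          min_passing_pairs = 2L) {
  if (!(detection_p_max > 0 && detection_p_max < 1)) {
    stop_format("detection_p_max must lie in (0, 1)")
  }
  if (!(slr_abs_min > 0)) stop_format("slr_abs_min must be > 0")
  if (!(pcc_min >= -1 && pcc_min <= 1)) {
    stop_format("pcc_min must lie in [-1, 1]")
  }
  if (is.character(ed_max)) {
    if (!identical(ed_max, "median")) {
      stop_format("ed_max must be a number or \"median\"")
    }
  } else if (!(is.numeric(ed_max) && ed_max >= 0)) {
    stop_format("ed_max must be a number >= 0 or \"median\"")
  }
  min_passing_pairs <- as.integer(min_passing_pairs)
  if (min_passing_pairs < 1L) stop_format("min_passing_pairs must be >= 1")
  structure(
    list(detection_p_max = detection_p_max, slr_abs_min = slr_abs_min,
         pcc_min = pcc_min, ed_max = ed_max,
         min_passing_pairs = min_passing_pairs),
    class = "filter_params"
  )
}

#' Detection p-value filter, per replicate
#'
#' A replicate keeps a probe set only if its detection p-value is at or
#' below the bound in every array contributing to that replicate's SLR
#' profile: the replicate's own arrays at all available timepoints and the
#' control arrays averaged into its denominators. Arrays of masked
#' (missing) timepoints are simply absent and cannot fail a probe.
#'
#' @param x the `expr_matrix` the time courses were built from.
#' @param tcs a `time_course_set`.
#' @param params a `filter_params`.
#' @return named list, one character vector of surviving probe ids per
#'   replicate.
#' @export
detection_filter <- function(x, tcs, params = filter_params()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(tcs, "time_course_set"))
  out <- lapply(seq_along(tcs$replicates), function(ri) {
    tp_ok <- tcs$available[ri, ]
    arrays <- unique(c(
      stats::na.omit(tcs$numerator_arrays[ri, tp_ok]),
      unlist(tcs$denominator_arrays[tp_ok], use.names = FALSE)
    ))
    p <- x$detection_p[, arrays, drop = FALSE]
    probe_ids(x)[rowSums(p > params$detection_p_max) == 0]
  })
  names(out) <- rownames(tcs$available)
  out
}

#' SLR magnitude filter, per replicate
#'
#' A replicate keeps a probe set if its |SLR| reaches the bound at one or
#' more available timepoints.
#'
#' @inheritParams detection_filter
#' @return named list of surviving probe ids per replicate.
#' @export
slr_filter <- function(tcs, params = filter_params()) {
  stopifnot(inherits(tcs, "time_course_set"))
  out <- lapply(seq_along(tcs$replicates), function(ri) {
    m <- tcs$slr[, ri, , drop = FALSE]
    hit <- apply(abs(m) >= params$slr_abs_min, 1, any, na.rm = TRUE)
    tcs$probe_ids[hit]
  })
  names(out) <- rownames(tcs$available)
  out
}

#' Overlap filter: intersect per-replicate survivor lists
#'
#' @param sets list (length >= 2) of probe-id character vectors.
#' @return character vector, the probes surviving in every replicate.
#' @export
overlap_filter <- function(sets) {
  if (length(sets) < 2) stop_format("overlap_filter needs >= 2 replicate sets")
  Reduce(intersect, sets)
}

#' All-by-all replicate consistency scores
#'
#' For every replicate pair, the Pearson correlation (pattern) and
#' Euclidean distance (magnitude) between the two SLR profiles, computed
#' over the timepoints available in both. With a replicate missing its
#' 2-week arrays, pairs involving it are scored on the 4-, 8- and 16-week
#' points only; `n_shared_timepoints` records the mix. Distances are not
#' rescaled for profile length. A pair in which either profile has zero
#' variance over the shared timepoints has an undefined (NA) correlation.
#'
#' @param tcs a `time_course_set` with >= 2 replicates.
#' @param probes probe subset to score (default: all).
#' @return object of class `"consistency_scores"`: list with `probe_ids`,
#'   `pairs` (2-row matrix of replicate positions), `pcc` and `ed`
#'   (probe x pair matrices) and `n_shared_timepoints` (per pair).
#' @export
pairwise_scores <- function(tcs, probes = NULL) {
  stopifnot(inherits(tcs, "time_course_set"))
  n_rep <- length(tcs$replicates)
  if (n_rep < 2) stop_format("consistency scoring needs >= 2 replicates")
  if (is.null(probes)) probes <- tcs$probe_ids
  pairs <- utils::combn(n_rep, 2)
  pair_names <- apply(pairs, 2, function(p) {
    paste0(rownames(tcs$available)[p], collapse = "-")
  })
  pcc <- ed <- matrix(NA_real_, length(probes), ncol(pairs),
                      dimnames = list(probes, pair_names))
  n_shared <- integer(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    shared <- tcs$available[a, ] & tcs$available[b, ]
    n_shared[j] <- sum(shared)
    if (n_shared[j] < 2) {
      stop_format("replicates %s share fewer than 2 timepoints", pair_names[j])
    }
    X <- matrix(tcs$slr[probes, a, shared], nrow = length(probes))
    Y <- matrix(tcs$slr[probes, b, shared], nrow = length(probes))
    ed[, j] <- sqrt(rowSums((X - Y)^2))
    xc <- X - rowMeans(X)
    yc <- Y - rowMeans(Y)
    den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
    r <- ifelse(den > 0, rowSums(xc * yc) / den, NA_real_)
    pcc[, j] <- pmin(1, pmax(-1, r))
  }
  names(n_shared) <- pair_names
  structure(
    list(probe_ids = probes, pairs = pairs, pcc = pcc, ed = ed,
         n_shared_timepoints = n_shared),
    class = "consistency_scores"
  )
}

#' Median Euclidean-distance cutoff
#'
#' The ED cutoff derived from the data: the median (mean of the middle two
#' for even counts) of all pairwise ED scores of the probes entering the
#' consistency step.
#'
#' @param scores a `"consistency_scores"` object or a numeric vector of ED
#'   scores.
#' @return the median ED.
#' @export
median_ed_cutoff <- function(scores) {
  ed <- if (inherits(scores, "consistency_scores")) as.vector(scores$ed)
        else as.numeric(scores)
  ed <- ed[!is.na(ed)]
  if (length(ed) == 0) stop_format("no ED scores to take a median over")
  stats::median(ed)
}

#' Consistency filter: 2-of-3 rule on PCC and ED
#'
#' A probe set is kept iff at least `min_passing_pairs` of its replicate
#' pairs have PCC >= `pcc_min` and, independently, at least
#' `min_passing_pairs` have ED <= the cutoff. Requiring all pairs to pass
#' both was found too strict in practice, hence the 2-of-3 default. An
#' undefined (zero-variance) correlation counts as a failing pair rather
#' than fabricating a score.
#'
#' @param scores a `"consistency_scores"` object.
#' @param params a `filter_params`; if `params$ed_max == "median"` the
#'   cutoff is derived from `scores` via [median_ed_cutoff()].
#' @return list with `probes` (survivors) and `ed_cutoff` (the cutoff
#'   applied).
#' @export
consistency_filter <- function(scores, params = filter_params()) {
  stopifnot(inherits(scores, "consistency_scores"))
  ed_cutoff <- if (identical(params$ed_max, "median")) {
    median_ed_cutoff(scores)
  } else {
    params$ed_max
  }
  pcc_ok <- rowSums(scores$pcc >= params$pcc_min, na.rm = TRUE)
  ed_ok <- rowSums(scores$ed <= ed_cutoff, na.rm = TRUE)
  keep <- pcc_ok >= params$min_passing_pairs &
    ed_ok >= params$min_passing_pairs
  list(probes = scores$probe_ids[keep], ed_cutoff = ed_cutoff)
}

#' Run the full filter cascade
#'
#' Detection filter and SLR filter per replicate, overlap (intersection)
#' across replicates, then the PCC/ED consistency filter. Survivors are
#' the probe sets considered consistently and significantly differentially
#' expressed for the comparison.
#'
#' @param x an `expr_matrix`.
#' @param comparison `"sham_vs_baseline"` or `"dmm_vs_sham"`.
#' @param params a `filter_params`.
#' @param annotation optional `"probe_annotation"` for gene counts in the
#'   report.
#' @return object of class `"filter_result"`: list with `probes` (final
#'   survivors), `report` (a `"filter_report"`), `scores` (the
#'   consistency scores of probes entering the last step), `tcs` (the
#'   `time_course_set`), and `per_replicate` intermediate sets.
#' @export
run_filter_pipeline <- function(x, comparison = c("sham_vs_baseline",
                                                  "dmm_vs_sham"),
                                params = filter_params(),
                                annotation = NULL) {
  comparison <- match.arg(comparison)
  tcs <- build_time_course_set(x, comparison)

  det <- detection_filter(x, tcs, params)
  slr <- slr_filter(tcs, params)
  both <- mapply(intersect, det, slr, SIMPLIFY = FALSE)
  overlap <- overlap_filter(both)

  scores <- NULL
  ed_cutoff <- NA_real_
  final <- character(0)
  if (length(overlap) > 0) {
    scores <- pairwise_scores(tcs, overlap)
    cons <- consistency_filter(scores, params)
    final <- cons$probes
    ed_cutoff <- cons$ed_cutoff
  }

  gc_fun <- function(p) if (is.null(annotation)) NA_integer_
                        else gene_count(annotation, p)
  rep_names <- rownames(tcs$available)
  report_rows <- rbind(
    data.frame(step = "input", replicate = "all",
               n_probes = length(tcs$probe_ids),
               n_genes = gc_fun(tcs$probe_ids), stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_along(rep_names), function(i) {
      data.frame(step = c("detection", "slr", "detection+slr"),
                 replicate = rep_names[i],
                 n_probes = c(length(det[[i]]), length(slr[[i]]),
                              length(both[[i]])),
                 n_genes = c(gc_fun(det[[i]]), gc_fun(slr[[i]]),
                             gc_fun(both[[i]])),
                 stringsAsFactors = FALSE)
    })),
    data.frame(step = c("overlap", "consistency"), replicate = "all",
               n_probes = c(length(overlap), length(final)),
               n_genes = c(gc_fun(overlap), gc_fun(final)),
               stringsAsFactors = FALSE)
  )
  report <- structure(
    list(counts = report_rows, params = params, ed_cutoff = ed_cutoff,
         comparison = comparison),
    class = "filter_report"
  )
  structure(
    list(probes = final, report = report, scores = scores, tcs = tcs,
         per_replicate = list(detection = det, slr = slr, both = both),
         overlap = overlap),
    class = "filter_result"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter cascade (%s)\n", x$comparison))
  cat(sprintf("  detection p <= %g, |SLR| >= %g, PCC >= %g, ED <= %s (%s), %d of 3 pairs\n",
              x$params$detection_p_max, x$params$slr_abs_min,
              x$params$pcc_min,
              if (is.na(x$ed_cutoff)) "?" else format(x$ed_cutoff, digits = 3),
              if (identical(x$params$ed_max, "median")) "median-derived"
              else "explicit",
              x$params$min_passing_pairs))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
print.filter_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `"filter_report"`.
#' @param path output path.
#' @return invisibly, the counts data frame.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  utils::write.table(report$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report$counts)
}
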