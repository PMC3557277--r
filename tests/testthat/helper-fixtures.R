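# Fixture builders used across test files. Everything is constructed in
# code; intensities are chosen so that SLR values are exact by design.

# Expression matrix with exact, caller-chosen SLR values.
#
# Baseline arrays are flat at 10, so sham SLRs equal sham - 10; DMM arrays
# are laid on top of the time-matched sham mean, so DMM SLRs equal the
# requested values exactly. `sham_slr` / `dmm_slr` are [probe, rep, tp]
# arrays over timepoints (2, 4, 8, 16) weeks; `detection` is a single
# p-value or a probe x array matrix applied after assembly.
toy_em <- function(n_probes = 2, sham_slr = NULL, dmm_slr = NULL,
                   detection = 0.001, missing_dmm_2wk_rep = NULL,
                   n_reps = 3) {
  tps <- c(2L, 4L, 8L, 16L)
  probes <- sprintf("p%02d", seq_len(n_probes))
  if (is.null(sham_slr)) sham_slr <- array(0, c(n_probes, n_reps, 4))
  if (is.null(dmm_slr)) dmm_slr <- array(0, c(n_probes, n_reps, 4))

  samples <- rbind(
    data.frame(array_id = sprintf("b_r%d", 1:3), group = "baseline",
               timepoint_weeks = 0L, replicate_index = 1:3),
    expand.grid(replicate_index = seq_len(n_reps), timepoint_weeks = tps) |>
      transform(group = "sham",
                array_id = sprintf("s_%dwk_r%d", timepoint_weeks,
                                   replicate_index)),
    expand.grid(replicate_index = seq_len(n_reps), timepoint_weeks = tps) |>
      transform(group = "dmm",
                array_id = sprintf("d_%dwk_r%d", timepoint_weeks,
                                   replicate_index))
  )
  if (!is.null(missing_dmm_2wk_rep)) {
    samples <- samples[!(samples$group == "dmm" &
                           samples$timepoint_weeks == 2L &
                           samples$replicate_index %in% missing_dmm_2wk_rep), ]
  }
  intensity <- matrix(10, n_probes, nrow(samples),
                      dimnames = list(probes, samples$array_id))
  for (ti in seq_along(tps)) {
    for (r in seq_len(n_reps)) {
      a <- sprintf("s_%dwk_r%d", tps[ti], r)
      intensity[, a] <- 10 + sham_slr[, r, ti]
    }
    sham_mean <- rowMeans(intensity[, sprintf("s_%dwk_r%d", tps[ti],
                                              seq_len(n_reps)),
                                    drop = FALSE])
    for (r in seq_len(n_reps)) {
      a <- sprintf("d_%dwk_r%d", tps[ti], r)
      if (a %in% samples$array_id) intensity[, a] <- sham_mean + dmm_slr[, r, ti]
    }
  }
  detection_p <- if (is.matrix(detection)) detection else
    matrix(detection, n_probes, nrow(samples),
           dimnames = dimnames(intensity))
  expression_matrix(intensity, detection_p, samples)
}

# Bare consistency_scores object for direct tests of the 2-of-3 rule.
make_scores <- function(pcc, ed, probe_ids = NULL) {
  pcc <- rbind(pcc)
  ed <- rbind(ed)
  if (is.null(probe_ids)) probe_ids <- sprintf("p%02d", seq_len(nrow(pcc)))
  rownames(pcc) <- rownames(ed) <- probe_ids
  structure(
    list(probe_ids = probe_ids, pairs = utils::combn(3, 2), pcc = pcc,
         ed = ed, n_shared_timepoints = rep(4L, ncol(pcc))),
    class = "consistency_scores"
  )
}

# Independent oracle: reachability closure of a thresholded co-fraction
# matrix by repeated boolean matrix multiplication.
closure_components <- function(co_fraction, threshold) {
  adj <- (co_fraction >= threshold)
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  membership <- match(
    apply(reach, 1, function(r) paste(which(r), collapse = ",")),
    unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
  )
  membership
}

# Normalize a partition (list of id sets or membership vector) to a
# canonical form for equality comparison.
canonical_partition <- function(membership, ids) {
  unname(lapply(unname(split(ids, membership)), sort)) |>
    (\(x) x[order(vapply(x, `[`, "", 1))])()
}
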