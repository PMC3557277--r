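# Synthetic dual-layer expression matrices with the study's design —
# 3 baseline pools at time 0, sham and DMM groups at 2/4/8/16 weeks with
# 3 pools each and one DMM 2-week pool missing — and planted truth labels
# so every pipeline stage can be benchmarked without array data.

#' Default planted SLR templates
#'
#' Five temporal motifs over (2, 4, 8, 16) weeks in unit SLR, echoing the
#' shapes seen in surgically induced osteoarthritis time courses: phasic
#' (up at 2 and 4 weeks, quiet at 8, up again at 16), mid-course
#' up-regulation, biphasic (an early pulse and renewed late activity),
#' late-only up-regulation, and mid-course down-regulation. Every pair of
#' templates differs in at least two timepoints, so they stay separated by
#' a Euclidean distance of at least 1 in every leave-one-timepoint-out
#' subspace — including the 4/8/16-week subspace used when a replicate's
#' 2-week arrays are missing — and every template reaches |SLR| >= 0.5 at
#' a timepoint that subspace retains. This keeps the planted cluster count
#' resolvable both by the figure-of-merit scan and by the masked
#' replicate's clustering.
#'
#' @return named list of length-4 numeric template vectors.
#' @export
default_templates <- function() {
  list(
    phasic = c(1, 1, 0, 1),
    mid = c(0, 1, 1, 0),
    biphasic = c(1, 0, 1, 1),
    late = c(0, 0, 0, 1),
    repressed = c(0, -1, -1, 0)
  )
}

#' Specification for a synthetic dataset
#'
#' @param n_probes total probe sets; default 1000 (a scaled-down probe
#'   universe keeping benchmarks fast while leaving planted signal rare).
#' @param n_de number of differentially expressed probes; default 100.
#' @param templates list of length-4 SLR template vectors cycled over the
#'   DE probes; default [default_templates()].
#' @param effect_size multiplier applied to templates (SLR units);
#'   default 1.0.
#' @param replicate_noise_sd pool-to-pool noise on the log2 scale;
#'   default 0.15.
#' @param baseline_mean,baseline_sd distribution of per-probe expected
#'   log2 intensity; defaults 8 and 1 (typical of normalized arrays).
#' @param frac_inconsistent fraction of DE probes that receive their
#'   template in exactly one (randomly chosen) DMM replicate only, so they
#'   are differential but replicate-inconsistent; default 0.1.
#' @param frac_undetected fraction of non-DE probes assigned high
#'   detection p-values in every array (planted DE probes are always
#'   detected, so detection status cannot silently remove planted
#'   positives); default 0.1.
#' @param missing_dmm_2wk_replicate omit the 2-week arrays of DMM
#'   replicate 1, reproducing the study's missing pool; default `TRUE`.
#' @param seed generator seed.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_probes = 1000L, n_de = 100L,
                           templates = default_templates(),
                           effect_size = 1.0, replicate_noise_sd = 0.15,
                           baseline_mean = 8, baseline_sd = 1,
                           frac_inconsistent = 0.1, frac_undetected = 0.1,
                           missing_dmm_2wk_replicate = TRUE, seed = 1L) {
  n_probes <- as.integer(n_probes)
  n_de <- as.integer(n_de)
  if (n_de > n_probes) stop_format("n_de must be <= n_probes")
  if (n_probes < 1L) stop_format("n_probes must be >= 1")
  if (effect_size < 0) stop_format("effect_size must be >= 0")
  if (replicate_noise_sd < 0) stop_format("replicate_noise_sd must be >= 0")
  if (frac_inconsistent < 0 || frac_inconsistent > 1 ||
      frac_undetected < 0 || frac_undetected > 1) {
    stop_format("fractions must lie in [0, 1]")
  }
  if (length(templates) < 1 ||
      !all(vapply(templates, length, integer(1)) == 4L)) {
    stop_format("templates must be length-4 SLR vectors over (2,4,8,16) weeks")
  }
  if (is.null(names(templates))) {
    names(templates) <- paste0("template_", seq_along(templates))
  }
  structure(
    list(n_probes = n_probes, n_de = n_de, templates = templates,
         effect_size = effect_size, replicate_noise_sd = replicate_noise_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         frac_inconsistent = frac_inconsistent,
         frac_undetected = frac_undetected,
         missing_dmm_2wk_replicate = isTRUE(missing_dmm_2wk_replicate),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic dataset with planted truth
#'
#' Per probe, an expected log2 level is drawn from
#' `Normal(baseline_mean, baseline_sd)`; baseline and sham arrays add
#' `Normal(0, replicate_noise_sd)` pool noise to that expectation; DMM
#' arrays add the probe's template x effect_size on top (in the perturbed
#' replicate only, for inconsistent DE probes). Noise is additive on the
#' log2 scale, matching the SLR arithmetic. Detection p-values are drawn
#' in `[0, 0.01]` for detected probes and `[0.5, 1]` for undetected ones.
#' A fixed seed reproduces the dataset bit-identically.
#'
#' @param spec a `"synthetic_spec"`.
#' @return list with `matrix` (an `expr_matrix`) and `truth` (data frame
#'   with `probe_id`, `is_de`, `template_id`, `is_consistent`,
#'   `is_detected`).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_probes
    probes <- sprintf("probe_%04d", seq_len(n))
    tps <- TIMEPOINTS_WEEKS
    reps <- 1:3

    samples <- rbind(
      data.frame(array_id = sprintf("baseline_r%d", reps),
                 group = "baseline", timepoint_weeks = 0L,
                 replicate_index = reps, stringsAsFactors = FALSE),
      expand.grid(replicate_index = reps, timepoint_weeks = tps,
                  stringsAsFactors = FALSE) |>
        transform(group = "sham") |>
        transform(array_id = sprintf("sham_%dwk_r%d", timepoint_weeks,
                                     replicate_index)),
      expand.grid(replicate_index = reps, timepoint_weeks = tps,
                  stringsAsFactors = FALSE) |>
        transform(group = "dmm") |>
        transform(array_id = sprintf("dmm_%dwk_r%d", timepoint_weeks,
                                     replicate_index))
    )
    if (spec$missing_dmm_2wk_replicate) {
      samples <- samples[!(samples$group == "dmm" &
                             samples$timepoint_weeks == 2L &
                             samples$replicate_index == 1L), , drop = FALSE]
    }

    mu <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)

    de_idx <- sort(sample.int(n, spec$n_de))
    is_de <- seq_len(n) %in% de_idx
    template_id <- rep(NA_character_, n)
    template_id[de_idx] <- rep_len(names(spec$templates), spec$n_de)
    n_incons <- round(spec$frac_inconsistent * spec$n_de)
    incons_idx <- if (n_incons > 0) sample(de_idx, n_incons) else integer(0)
    is_consistent <- ifelse(is_de, !(seq_len(n) %in% incons_idx), NA)
    perturbed_rep <- rep(NA_integer_, n)
    perturbed_rep[incons_idx] <- sample(reps, length(incons_idx),
                                        replace = TRUE)

    non_de <- setdiff(seq_len(n), de_idx)
    n_undet <- round(spec$frac_undetected * length(non_de))
    undet_idx <- if (n_undet > 0) sample(non_de, n_undet) else integer(0)
    is_detected <- !(seq_len(n) %in% undet_idx)

    n_arr <- nrow(samples)
    intensity <- matrix(NA_real_, n, n_arr,
                        dimnames = list(probes, samples$array_id))
    tmpl_mat <- do.call(rbind, spec$templates) * spec$effect_size
    for (j in seq_len(n_arr)) {
      expected <- mu
      if (samples$group[j] == "dmm") {
        ti <- match(samples$timepoint_weeks[j], tps)
        add <- is_de &
          (is_consistent %in% TRUE |
             perturbed_rep == samples$replicate_index[j]) %in% TRUE
        expected <- expected +
          ifelse(add, tmpl_mat[match(template_id, names(spec$templates)),
                               ti], 0)
      }
      intensity[, j] <- expected +
        stats::rnorm(n, 0, spec$replicate_noise_sd)
    }
    detection_p <- matrix(stats::runif(n * n_arr, 0, 0.01), n, n_arr,
                          dimnames = dimnames(intensity))
    if (length(undet_idx) > 0) {
      detection_p[undet_idx, ] <- stats::runif(length(undet_idx) * n_arr,
                                               0.5, 1)
    }

    truth <- data.frame(probe_id = probes, is_de = is_de,
                        template_id = template_id,
                        is_consistent = is_consistent,
                        is_detected = is_detected,
                        stringsAsFactors = FALSE)
    list(matrix = expression_matrix(intensity, detection_p, samples),
         truth = truth)
  })
}

#' Write a synthetic dataset as the TSV trio plus truth labels
#'
#' Produces the expression matrix and sample sheet in the format
#' [read_expression()] reads, plus `truth.tsv`.
#'
#' @param dataset a list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "samples.tsv", "truth.tsv"))
  write_expression(dataset$matrix, paths[1], paths[2])
  utils::write.table(dataset$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Recovery report against planted truth
#'
#' Confusion-matrix rates for the filter — positives are the probes
#' planted as consistently differentially expressed (and detected) — and,
#' optionally, the adjusted Rand index between a consensus clustering and
#' the planted template labels (singletons each count as their own
#' cluster).
#'
#' @param selected probe ids surviving the filter.
#' @param truth the truth data frame from [generate_dataset()].
#' @param consensus optional `"consensus_result"` over a subset of the
#'   truth's probes.
#' @return list with `sensitivity`, `specificity`, `n_positive`,
#'   `n_negative` and (if `consensus` given) `ari`.
#' @export
planted_recovery_report <- function(selected, truth, consensus = NULL) {
  positive <- truth$is_de & (truth$is_consistent %in% TRUE) &
    truth$is_detected
  negative <- !positive
  sel <- truth$probe_id %in% selected
  out <- list(
    sensitivity = if (any(positive)) sum(sel & positive) / sum(positive)
                  else NA_real_,
    specificity = if (any(negative)) sum(!sel & negative) / sum(negative)
                  else NA_real_,
    n_positive = sum(positive),
    n_negative = sum(negative)
  )
  if (!is.null(consensus)) {
    lab <- cluster_labels(consensus)
    ref <- truth$template_id[match(names(lab), truth$probe_id)]
    ref[is.na(ref)] <- "none"
    out$ari <- mclust::adjustedRandIndex(lab, ref)
  }
  out
}
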