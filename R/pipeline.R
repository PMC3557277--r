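# Single entry point wiring the stages: (optional) simulation -> SLR time
# courses -> filter (sham, DMM) -> intersection -> FOM -> consensus
# clustering -> summaries, with a YAML config and a run manifest recording
# parameters, seeds, per-stage counts and output hashes.

#' Assemble a run configuration
#'
#' Either `synthetic = synthetic_spec(...)` or both `matrix_path` and
#' `sample_sheet_path` must be supplied.
#'
#' @param out_dir output directory.
#' @param synthetic optional `"synthetic_spec"`; when given, the input
#'   matrix is generated rather than read.
#' @param matrix_path,sample_sheet_path,annotation_path input files (used
#'   when `synthetic` is `NULL`; annotation is optional either way).
#' @param filter a `"filter_params"`.
#' @param consensus a `"consensus_params"`; its `k` is replaced by the
#'   FOM-selected value when `select_k_by_fom` is `TRUE`.
#' @param select_k_by_fom choose the consensus k at the FOM elbow
#'   computed on the filtered DMM replicate datasets; default `FALSE`
#'   (use `consensus$k` as given).
#' @param fom_k_range candidate cluster counts for the FOM scan.
#' @param seed master seed recorded in the manifest and used for every
#'   stochastic stage.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(out_dir, synthetic = NULL, matrix_path = NULL,
                       sample_sheet_path = NULL, annotation_path = NULL,
                       filter = filter_params(),
                       consensus = consensus_params(),
                       select_k_by_fom = FALSE, fom_k_range = 2:15,
                       seed = 1L) {
  if (is.null(synthetic)) {
    if (is.null(matrix_path) || is.null(sample_sheet_path)) {
      stop_format("config needs either a synthetic spec or matrix_path + sample_sheet_path")
    }
    for (p in c(matrix_path, sample_sheet_path, annotation_path)) {
      if (!is.null(p) && !file.exists(p)) {
        stop_format("configured path does not exist: %s", p)
      }
    }
  } else {
    stopifnot(inherits(synthetic, "synthetic_spec"))
  }
  stopifnot(inherits(filter, "filter_params"),
            inherits(consensus, "consensus_params"))
  structure(
    list(out_dir = out_dir, synthetic = synthetic,
         matrix_path = matrix_path, sample_sheet_path = sample_sheet_path,
         annotation_path = annotation_path, filter = filter,
         consensus = consensus, select_k_by_fom = isTRUE(select_k_by_fom),
         fom_k_range = as.integer(fom_k_range), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `filter`,
#' `consensus` and `synthetic` are nested maps passed to
#' [filter_params()], [consensus_params()] and [synthetic_spec()]. Every
#' omitted value takes the pipeline default.
#'
#' @param path YAML file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format("config file does not exist: %s", path)
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(synthetic_spec, y$synthetic)
  run_config(
    out_dir = y$out_dir %||% ".",
    synthetic = syn,
    matrix_path = y$matrix_path,
    sample_sheet_path = y$sample_sheet_path,
    annotation_path = y$annotation_path,
    filter = do.call(filter_params, y$filter %||% list()),
    consensus = do.call(consensus_params, y$consensus %||% list()),
    select_k_by_fom = y$select_k_by_fom %||% FALSE,
    fom_k_range = y$fom_k_range %||% 2:15,
    seed = y$seed %||% 1L
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_format("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline
#'
#' Executes simulation (if configured) or file input, SLR construction and
#' filtering for both comparisons, intersection, FOM analysis and
#' consensus clustering of the filtered DMM time course (the comparison
#' the study clustered), and direction summaries; writes all outputs
#' under `config$out_dir` and a `manifest.yaml` with parameters, seeds,
#' per-stage counts and MD5 hashes of every output file. Reruns with the
#' same seed are bit-identical.
#'
#' @param config a `"run_config"` or the path to a YAML config file.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  truth <- NULL
  if (!is.null(config$synthetic)) {
    ds <- run_stage("simulate", generate_dataset(config$synthetic))
    em <- ds$matrix
    truth <- ds$truth
    run_stage("simulate", write_synthetic(ds, config$out_dir))
  } else {
    em <- run_stage("read", read_expression(config$matrix_path,
                                            config$sample_sheet_path))
  }
  annotation <- if (!is.null(config$annotation_path)) {
    run_stage("read", read_annotation(config$annotation_path))
  }

  results <- list()
  for (cmp in c("sham_vs_baseline", "dmm_vs_sham")) {
    short <- if (cmp == "sham_vs_baseline") "sham" else "dmm"
    res <- run_stage(paste0("filter_", short),
                     run_filter_pipeline(em, cmp, config$filter, annotation))
    run_stage(paste0("filter_", short), {
      write_time_courses(res$tcs, out(sprintf("slr_%s.tsv", short)))
      write_filter_report(res$report, out(sprintf("filter_report_%s.tsv", short)))
      writeLines(res$probes, out(sprintf("filtered_probes_%s.txt", short)))
      ds <- direction_summary(res$tcs, res$probes)
      utils::write.table(ds$counts, out(sprintf("direction_%s.tsv", short)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    results[[short]] <- res
  }

  ov <- run_stage("intersect",
                  intersect_sets(results$sham$probes, results$dmm$probes,
                                 annotation, labels = c("sham", "dmm")))
  run_stage("intersect", writeLines(ov$both, out("overlap_probes.txt")))

  manifest_counts <- list(
    sham = stats::setNames(as.list(results$sham$report$counts$n_probes),
                           paste(results$sham$report$counts$step,
                                 results$sham$report$counts$replicate,
                                 sep = ".")),
    dmm = stats::setNames(as.list(results$dmm$report$counts$n_probes),
                          paste(results$dmm$report$counts$step,
                                results$dmm$report$counts$replicate,
                                sep = ".")),
    overlap = length(ov$both)
  )

  fom_tab <- NULL
  consensus <- NULL
  dmm_probes <- results$dmm$probes
  cpar <- config$consensus
  cpar$seed <- config$seed
  if (length(dmm_probes) >= max(2L, min(config$fom_k_range))) {
    datasets <- lapply(seq_along(results$dmm$tcs$replicates), function(ri) {
      replicate_profiles(results$dmm$tcs, ri, dmm_probes)
    })
    k_range <- config$fom_k_range[config$fom_k_range <= length(dmm_probes)]
    fom_tab <- run_stage("fom",
                         fom_analysis(datasets[[length(datasets)]], k_range,
                                      seed = config$seed))
    run_stage("fom", utils::write.table(as.data.frame(fom_tab),
                                        out("fom.tsv"), sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    if (config$select_k_by_fom) cpar$k <- fom_pick_k(fom_tab)
    if (length(dmm_probes) >= cpar$k) {
      consensus <- run_stage("cluster", consensus_cluster(datasets, cpar))
      run_stage("cluster",
                write_consensus(consensus, out("clusters.tsv"),
                                out("co_fraction.tsv")))
    }
  }

  manifest <- list(
    seed = config$seed,
    parameters = list(
      filter = unclass(config$filter),
      consensus = unclass(cpar),
      ed_cutoff = list(sham = results$sham$report$ed_cutoff,
                       dmm = results$dmm$report$ed_cutoff)
    ),
    counts = manifest_counts,
    n_clusters = if (is.null(consensus)) 0L else length(consensus$clusters),
    n_singletons = if (is.null(consensus)) 0L
                   else length(consensus$singletons),
    outputs = as.list(tools::md5sum(
      list.files(config$out_dir, full.names = TRUE,
                 pattern = "\\.(tsv|txt)$")))
  )
  names(manifest$outputs) <- basename(names(manifest$outputs))
  yaml::write_yaml(manifest, out("manifest.yaml"))

  invisible(c(manifest,
              list(results = results, overlap = ov, consensus = consensus,
                   fom = fom_tab, truth = truth)))
}
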