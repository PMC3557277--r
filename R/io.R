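# Tab-delimited readers and writers for the pipeline's external formats.
# Matrix dialect: one header row; a "probe_id" column plus, per array, the
# column pair "<array_id>.signal" (log2 intensity) and "<array_id>.pval"
# (detection p-value), mirroring the two quantities reported per probe set.

#' Read a dual-layer expression matrix and its sample sheet
#'
#' @param matrix_path path to a tab-delimited file with a `probe_id`
#'   column and, per array, columns `<array_id>.signal` and
#'   `<array_id>.pval`.
#' @param sample_sheet_path path to a tab-delimited sample sheet with
#'   columns `array_id`, `group`, `timepoint_weeks`, `replicate_index`.
#' @return an [expression_matrix()] object.
#' @seealso [write_expression()] for the inverse operation.
#' @export
read_expression <- function(matrix_path, sample_sheet_path) {
  samples <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(raw)) {
    stop_format("expression matrix file lacks a 'probe_id' column")
  }
  if (anyDuplicated(raw$probe_id)) {
    stop_format("duplicate probe_id in %s: %s", matrix_path,
                raw$probe_id[duplicated(raw$probe_id)][1])
  }
  ids <- as.character(samples$array_id)
  need <- c(paste0(ids, ".signal"), paste0(ids, ".pval"))
  absent <- setdiff(need, names(raw))
  if (length(absent) > 0) {
    stop_format("expression matrix is missing column(s) for declared array(s): %s",
                paste(absent, collapse = ", "))
  }
  to_mat <- function(cols) {
    m <- as.matrix(raw[cols])
    if (!is.numeric(m)) stop_format("non-numeric values in expression matrix")
    rownames(m) <- raw$probe_id
    colnames(m) <- ids
    m
  }
  expression_matrix(
    intensity = to_mat(paste0(ids, ".signal")),
    detection_p = to_mat(paste0(ids, ".pval")),
    samples = samples
  )
}

#' Write an expression matrix and sample sheet to tab-delimited files
#'
#' Values are written with full precision (17 significant digits) so that
#' `read_expression()` round-trips both layers bit-identically.
#'
#' @param x an `expr_matrix`.
#' @param matrix_path,sample_sheet_path output paths.
#' @return invisibly, `x`.
#' @export
write_expression <- function(x, matrix_path, sample_sheet_path) {
  stopifnot(inherits(x, "expr_matrix"))
  ids <- x$samples$array_id
  out <- data.frame(probe_id = probe_ids(x), stringsAsFactors = FALSE)
  for (a in ids) {
    out[[paste0(a, ".signal")]] <- sprintf("%.17g", x$intensity[, a])
    out[[paste0(a, ".pval")]] <- sprintf("%.17g", x$detection_p[, a])
  }
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a probe-set to gene-symbol annotation table
#'
#' @param path two-column tab-delimited file (`probe_id`, `gene_symbol`).
#'   A header row is expected. Rows repeating a probe with the same symbol
#'   are tolerated; rows assigning one probe two different symbols are a
#'   format error.
#' @return a named character vector mapping probe id to symbol, with class
#'   `"probe_annotation"`. Probes absent from the file resolve to
#'   `"unannotated"` through [annotation_lookup()].
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) {
    if (nrow(tab) == 0) {
      return(structure(character(0), class = "probe_annotation"))
    }
    stop_format("annotation file must have two tab-separated columns")
  }
  probe <- tab[[1]]
  sym <- tab[[2]]
  dup <- duplicated(probe)
  if (any(dup)) {
    for (p in unique(probe[dup])) {
      if (length(unique(sym[probe == p])) > 1) {
        stop_format("conflicting annotation rows for probe %s", p)
      }
    }
    sym <- sym[!dup]
    probe <- probe[!dup]
  }
  structure(stats::setNames(sym, probe), class = "probe_annotation")
}

#' Resolve probe ids to gene symbols
#'
#' @param annotation a `"probe_annotation"` (or `NULL`, in which case every
#'   probe resolves to `"unannotated"`).
#' @param probes character vector of probe ids.
#' @return character vector of symbols; unmapped probes give
#'   `"unannotated"`.
#' @export
annotation_lookup <- function(annotation, probes) {
  if (is.null(annotation)) {
    return(rep("unannotated", length(probes)))
  }
  out <- unclass(annotation)[probes]
  out[is.na(out) | out == ""] <- "unannotated"
  unname(out)
}

#' Count distinct genes among a set of probe sets
#'
#' Distinct symbols among annotated probes; each unannotated probe counts
#' once (so probe-set and gene counts can both be reported, as several
#' probe sets may interrogate one gene).
#'
#' @inheritParams annotation_lookup
#' @return integer gene count.
#' @export
gene_count <- function(annotation, probes) {
  sym <- annotation_lookup(annotation, probes)
  un <- sum(sym == "unannotated")
  length(unique(sym[sym != "unannotated"])) + un
}

#' Export a gene or probe list for external annotation tools
#'
#' Writes one identifier per line, deduplicated, preserving first-occurrence
#' order — the plain-list format functional-annotation web tools ingest.
#'
#' @param probes character vector of probe-set ids.
#' @param annotation a `"probe_annotation"` or `NULL`.
#' @param path output path.
#' @param mode `"genes"` (translate to symbols) or `"probes"`.
#' @return invisibly, the character vector written.
#' @export
write_gene_list <- function(probes, annotation = NULL, path,
                            mode = c("genes", "probes")) {
  mode <- match.arg(mode)
  out <- if (mode == "genes") annotation_lookup(annotation, probes) else probes
  out <- out[!duplicated(out)]
  writeLines(out, path)
  invisible(out)
}
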