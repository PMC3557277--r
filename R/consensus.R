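# Threshold-resolved consensus clustering. Each replicate dataset is
# k-means clustered several times from random starts; the fraction of runs
# in which two probes co-cluster forms a consensus matrix, thresholded
# into an adjacency matrix whose connected components (depth-first search)
# are the consensus clusters. Size-1 components are reported as
# singletons (outliers), not clusters.

#' Consensus clustering parameters
#'
#' @param k number of starting clusters for each k-means run; default 10.
#' @param runs_per_replicate stochastic runs per replicate dataset;
#'   default 10 (more did not materially improve homogeneity in the
#'   motivating study).
#' @param threshold co-clustering fraction (inclusive) required for an
#'   edge; default 0.83, i.e. 25 of 30 runs pass and 24 of 30 fail.
#' @param seed master seed; per-(replicate, run) sub-seeds are spawned by
#'   fixed arithmetic.
#' @return an object of class `"consensus_params"`.
#' @export
consensus_params <- function(k = 10L, runs_per_replicate = 10L,
                             threshold = 0.83, seed = 1L) {
  k <- as.integer(k)
  runs_per_replicate <- as.integer(runs_per_replicate)
  if (k < 2L) stop_format("k must be >= 2")
  if (runs_per_replicate < 1L) stop_format("runs_per_replicate must be >= 1")
  if (!(threshold > 0 && threshold <= 1)) {
    stop_format("threshold must lie in (0, 1]")
  }
  structure(list(k = k, runs_per_replicate = runs_per_replicate,
                 threshold = threshold, distance = "euclidean",
                 algorithm = "kmeans", seed = as.integer(seed)),
            class = "consensus_params")
}

#' One k-means partition (Lloyd's algorithm)
#'
#' Initialized by sampling `k` distinct profiles (rows) with the given
#' seed; Lloyd iterations until assignments stop changing or 300
#' iterations; a cluster that empties is reseeded with the profile
#' farthest from its assigned centroid. Distances are Euclidean.
#'
#' @param profiles numeric matrix, profiles in rows.
#' @param k number of clusters, `1 <= k <= nrow(profiles)`.
#' @param seed integer seed for the initialization draw.
#' @param max_iter iteration cap; default 300.
#' @return integer vector of cluster labels in `1:k`, named by rownames.
#' @export
kmeans_partition <- function(profiles, k, seed = 1L, max_iter = 300L) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  k <- as.integer(k)
  if (k < 1L) stop_format("k must be >= 1")
  if (k > n) stop_format("fewer profiles (%d) than clusters (%d)", n, k)
  if (k == 1L) {
    return(stats::setNames(rep(1L, n), rownames(profiles)))
  }
  centers <- with_seed(seed, profiles[sample.int(n, k), , drop = FALSE])
  labels <- integer(n)
  pt_sq <- rowSums(profiles^2)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(pt_sq, rowSums(centers^2), "+") - 2 * profiles %*% t(centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # reseed empty clusters with the point farthest from its centroid
    for (attempt in seq_len(k)) {
      counts <- tabulate(new_labels, nbins = k)
      if (all(counts > 0L)) break
      j <- which(counts == 0L)[1]
      own_d2 <- d2[cbind(seq_len(n), new_labels)]
      far <- which.max(own_d2)
      centers[j, ] <- profiles[far, ]
      d2[, j] <- pt_sq + sum(centers[j, ]^2) -
        2 * drop(profiles %*% centers[j, ])
      new_labels <- max.col(-d2, ties.method = "first")
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    counts <- tabulate(labels, nbins = k)
    nonempty <- counts > 0L
    sums <- rowsum(profiles, labels)
    centers[nonempty, ] <- sums / counts[nonempty]
  }
  stats::setNames(labels, rownames(profiles))
}

#' Figure-of-merit analysis for cluster-number selection
#'
#' Leave-one-timepoint-out homogeneity: for each held-out timepoint the
#' profiles are clustered on the remaining timepoints and the figure of
#' merit is the root-mean-square deviation of the held-out values from
#' their cluster means, multiplied by the adjustment factor
#' `sqrt(n / (n - k))` that removes the trivial decrease with growing k.
#' Each fit uses `n_starts` random k-means starts and keeps the solution
#' with the lowest within-cluster sum of squares on the training
#' timepoints (selection never looks at the held-out values), so the
#' curve reflects the clustering structure rather than k-means local
#' optima. The aggregate FOM for a k is the sum over held-out timepoints;
#' lower is more homogeneous, and the curve's elbow estimates the number
#' of clusters present.
#'
#' @param profiles numeric matrix, profiles x timepoints (>= 2 columns).
#' @param k_range integer vector of cluster counts to evaluate; values
#'   must not exceed `nrow(profiles)`.
#' @param n_starts random k-means starts per fit, best kept; default 10.
#' @param seed master seed.
#' @return object of class `"fom_result"`: data frame with columns `k`
#'   and `fom`, plus attribute `"components"` (k x timepoint matrix of
#'   per-held-out-timepoint FOMs).
#' @export
fom_analysis <- function(profiles, k_range = 2:15, n_starts = 10L,
                         seed = 1L) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  d <- ncol(profiles)
  if (d < 2) stop_format("FOM needs >= 2 timepoints")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range > n)) stop_format("k in k_range exceeds profile count %d", n)
  if (any(k_range < 1L)) stop_format("k must be >= 1")

  comp <- matrix(0, length(k_range), d,
                 dimnames = list(paste0("k", k_range), colnames(profiles)))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    adj <- if (k < n) sqrt(n / (n - k)) else NA_real_
    for (t in seq_len(d)) {
      train <- profiles[, -t, drop = FALSE]
      best_lab <- NULL
      best_ss <- Inf
      for (s in seq_len(n_starts)) {
        lab <- kmeans_partition(train, k,
                                seed = derive_seed(seed, ki * 100L + t, s))
        mu <- rowsum(train, lab) / as.vector(table(lab))
        ss <- sum((train - mu[as.character(lab), , drop = FALSE])^2)
        if (ss < best_ss) {
          best_ss <- ss
          best_lab <- lab
        }
      }
      mu_t <- tapply(profiles[, t], best_lab, mean)
      raw <- sqrt(mean((profiles[, t] - mu_t[as.character(best_lab)])^2))
      # each profile its own cluster => exact fit; skip the (infinite)
      # adjustment instead of producing 0 * Inf
      comp[ki, t] <- if (raw == 0) 0 else raw * adj
    }
  }
  out <- data.frame(k = k_range, fom = rowSums(comp))
  attr(out, "components") <- comp
  class(out) <- c("fom_result", "data.frame")
  out
}

#' Pick the cluster number at the FOM elbow
#'
#' Returns the k with the largest second difference of the aggregate FOM
#' curve (the point where the steep decrease turns into a plateau). The
#' endpoints of the curve cannot be selected.
#'
#' @param fom a `"fom_result"` from [fom_analysis()].
#' @return the selected integer k.
#' @export
fom_pick_k <- function(fom) {
  stopifnot(inherits(fom, "fom_result"))
  f <- fom$fom
  k <- fom$k
  if (length(k) < 3) return(k[which.min(f)])
  i <- 2:(length(k) - 1)
  curvature <- (f[i - 1] - f[i]) - (f[i] - f[i + 1])
  k[i][which.max(curvature)]
}

#' Threshold a co-clustering fraction matrix into consensus clusters
#'
#' Edges join probe pairs whose co-clustering fraction is at or above the
#' threshold; consensus clusters are the connected components (found by
#' depth-first search) with two or more members, and size-1 components are
#' singletons.
#'
#' @param co_fraction symmetric numeric matrix with unit diagonal and
#'   entries in `[0, 1]`, dimnames = probe ids.
#' @param threshold inclusive edge threshold in `(0, 1]`.
#' @return list with `clusters` (list of probe-id vectors, largest first)
#'   and `singletons` (probe-id vector).
#' @export
consensus_components <- function(co_fraction, threshold) {
  co_fraction <- as.matrix(co_fraction)
  n <- nrow(co_fraction)
  stopifnot(n == ncol(co_fraction))
  ids <- rownames(co_fraction) %||% as.character(seq_len(n))
  adj <- co_fraction >= threshold
  diag(adj) <- FALSE
  membership <- integer(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (membership[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    membership[start] <- comp
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(adj[v, ] & membership == 0L)
      membership[nb] <- comp
      stack <- c(stack, nb)
    }
  }
  comps <- split(ids, membership)
  sizes <- lengths(comps)
  clusters <- comps[sizes >= 2]
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, function(cl) match(cl[1], ids),
                                    integer(1)))]
  names(clusters) <- NULL
  list(clusters = clusters,
       singletons = unlist(comps[sizes == 1], use.names = FALSE) %||%
         character(0))
}

#' Consensus clustering over replicate datasets
#'
#' Runs `runs_per_replicate` seeded k-means partitions on each replicate
#' dataset (each in its own dimension: a replicate with a masked timepoint
#' is clustered on its reduced profile), accumulates the co-clustering
#' fraction over all runs, and resolves clusters at the threshold via
#' [consensus_components()].
#'
#' @param datasets list of numeric matrices (profiles x timepoints) with
#'   identical rownames — one per replicate.
#' @param params a `"consensus_params"`.
#' @return object of class `"consensus_result"`: list with `co_fraction`,
#'   `clusters`, `singletons`, `n_runs_total` and `params`.
#' @export
consensus_cluster <- function(datasets, params = consensus_params()) {
  stopifnot(inherits(params, "consensus_params"))
  if (!is.list(datasets) || length(datasets) < 1) {
    stop_format("datasets must be a non-empty list of matrices")
  }
  ids <- rownames(datasets[[1]])
  if (is.null(ids)) stop_format("datasets must carry probe ids as rownames")
  for (d in datasets) {
    if (!identical(rownames(d), ids)) {
      stop_format("all replicate datasets must share the same probe universe")
    }
  }
  n <- length(ids)
  n_runs <- length(datasets) * params$runs_per_replicate
  co <- matrix(0, n, n, dimnames = list(ids, ids))
  for (di in seq_along(datasets)) {
    for (r in seq_len(params$runs_per_replicate)) {
      lab <- kmeans_partition(datasets[[di]], params$k,
                              seed = derive_seed(params$seed, di, r))
      co <- co + outer(lab, lab, "==")
    }
  }
  co_fraction <- co / n_runs
  parts <- consensus_components(co_fraction, params$threshold)
  structure(
    list(co_fraction = co_fraction, clusters = parts$clusters,
         singletons = parts$singletons, n_runs_total = n_runs,
         params = params),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d clusters (size >= 2), %d singletons, %d runs, threshold %.2f\n",
              length(x$clusters), length(x$singletons), x$n_runs_total,
              x$params$threshold))
  if (length(x$clusters) > 0) {
    cat("cluster sizes:", paste(lengths(x$clusters), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flat cluster labels from a consensus result
#'
#' Clusters are numbered 1..m (largest first); each singleton gets its own
#' label beyond m, so the labeling is a full partition.
#'
#' @param x a `"consensus_result"`.
#' @return named integer vector over all probes in the result.
#' @export
cluster_labels <- function(x) {
  stopifnot(inherits(x, "consensus_result"))
  lab <- integer(0)
  for (i in seq_along(x$clusters)) {
    lab <- c(lab, stats::setNames(rep(i, length(x$clusters[[i]])),
                                  x$clusters[[i]]))
  }
  m <- length(x$clusters)
  if (length(x$singletons) > 0) {
    lab <- c(lab, stats::setNames(m + seq_along(x$singletons), x$singletons))
  }
  lab[rownames(x$co_fraction)]
}

#' Hierarchical ordering of profiles for heat-map display
#'
#' Agglomerative clustering (average linkage) under Euclidean distance;
#' ties are resolved by the deterministic first-seen merge order, so a
#' permuted input yields the same tree topology.
#'
#' @param profiles numeric matrix (>= 2 rows).
#' @return list with `order` (rownames in leaf order) and `hclust` (the
#'   merge tree).
#' @export
hierarchical_order <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop_format("need >= 2 profiles to order")
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = "average")
  list(order = rownames(profiles)[hc$order], hclust = hc)
}

#' Write consensus membership and co-fraction matrix as TSV
#'
#' @param x a `"consensus_result"`.
#' @param membership_path path for the probe_id / cluster table
#'   (singletons are labelled `"singleton"`).
#' @param co_fraction_path optional path for the full co-clustering
#'   fraction matrix.
#' @return invisibly, the membership data frame.
#' @export
write_consensus <- function(x, membership_path, co_fraction_path = NULL) {
  stopifnot(inherits(x, "consensus_result"))
  lab <- cluster_labels(x)
  m <- length(x$clusters)
  member <- data.frame(
    probe_id = names(lab),
    cluster = ifelse(lab <= m, paste0("cluster_", lab), "singleton"),
    stringsAsFactors = FALSE
  )
  utils::write.table(member, membership_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(co_fraction_path)) {
    utils::write.table(
      data.frame(probe_id = rownames(x$co_fraction), x$co_fraction,
                 check.names = FALSE),
      co_fraction_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(member)
}
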