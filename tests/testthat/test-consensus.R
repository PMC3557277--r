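test_that("k-means partition honors degenerate and separable cases", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(letters[1:10], NULL))
  expect_equal(unname(kmeans_partition(X, 1)), rep(1L, 10))
  # k = n with distinct profiles: every profile its own cluster
  expect_equal(sort(unname(kmeans_partition(X, 10, seed = 2))), 1:10)
  # two well-separated blobs are recovered from any start
  blob <- rbind(matrix(rnorm(20, 0, 0.1), 5, 4),
                matrix(rnorm(20, 5, 0.1), 5, 4))
  rownames(blob) <- letters[1:10]
  for (s in 1:10) {
    lab <- kmeans_partition(blob, 2, seed = s)
    expect_equal(length(unique(lab[1:5])), 1)
    expect_equal(length(unique(lab[6:10])), 1)
    expect_false(lab[1] == lab[6])
  }
  # same seed, same labeling; different seed may differ
  expect_identical(kmeans_partition(X, 3, seed = 5),
                   kmeans_partition(X, 3, seed = 5))
  expect_error(kmeans_partition(X, 11), "fewer profiles")
})

test_that("thresholded consensus matrix resolves components as specified", {
  ids <- c("a", "b", "c")
  cf <- function(ab, bc, ac) {
    m <- diag(3); m[1, 2] <- m[2, 1] <- ab; m[2, 3] <- m[3, 2] <- bc
    m[1, 3] <- m[3, 1] <- ac; dimnames(m) <- list(ids, ids); m
  }
  # trio together in 30/30 runs
  parts <- consensus_components(cf(1, 1, 1), 0.83)
  expect_equal(parts$clusters, list(c("a", "b", "c")))
  expect_equal(parts$singletons, character(0))
  # 24/30 = 0.80 < 0.83: no edge (inclusive threshold, 25/30 passes)
  parts <- consensus_components(cf(24 / 30, 0, 0), 0.83)
  expect_equal(parts$clusters, list())
  expect_setequal(parts$singletons, ids)
  expect_equal(consensus_components(cf(25 / 30, 0, 0), 0.83)$clusters,
               list(c("a", "b")))
  # transitivity through components: a-b and b-c edges join a with c
  parts <- consensus_components(cf(0.9, 0.9, 0.5), 0.83)
  expect_equal(parts$clusters, list(c("a", "b", "c")))
})

test_that("components match brute-force transitive closure and partition the input", {
  set.seed(10)
  for (trial in 1:25) {
    n <- sample(5:60, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- sample(c(0, 0.5, 0.85, 1), n * (n - 1) / 2,
                              replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
    m <- m + t(m); diag(m) <- 1
    dimnames(m) <- list(paste0("g", 1:n), paste0("g", 1:n))
    parts <- consensus_components(m, 0.83)
    got <- c(parts$clusters, as.list(parts$singletons))
    member <- rep(seq_along(got), lengths(got))
    names(member) <- unlist(got)
    oracle <- canonical_partition(closure_components(m, 0.83), rownames(m))
    expect_equal(canonical_partition(member[rownames(m)], rownames(m)),
                 oracle)
    # conservation: clusters + singletons partition the probe universe
    expect_setequal(unlist(got), rownames(m))
    expect_equal(anyDuplicated(unlist(got)), 0)
    # raising the threshold only refines components
    finer <- consensus_components(m, 0.95)
    finer_all <- c(finer$clusters, as.list(finer$singletons))
    coarse_member <- rep(seq_along(got), lengths(got))
    names(coarse_member) <- unlist(got)
    for (cl in finer_all) {
      expect_equal(length(unique(coarse_member[cl])), 1)
    }
  }
})

test_that("consensus over replicate datasets recovers planted structure", {
  ds <- generate_dataset(synthetic_spec(seed = 21))
  truth <- ds$truth
  keep <- truth$probe_id[truth$is_de & truth$is_consistent %in% TRUE]
  tcs <- build_time_course_set(ds$matrix, "dmm_vs_sham")
  datasets <- lapply(1:3, function(r) replicate_profiles(tcs, r, keep))
  cr <- consensus_cluster(datasets, consensus_params(k = 5, seed = 21))
  # co-fraction invariants
  expect_true(isSymmetric(cr$co_fraction))
  expect_equal(unname(diag(cr$co_fraction)), rep(1, length(keep)))
  expect_true(all(cr$co_fraction >= 0 & cr$co_fraction <= 1))
  expect_equal(cr$n_runs_total, 30)
  # clusters + singletons = input universe
  expect_setequal(c(unlist(cr$clusters), cr$singletons), keep)
  # one consensus cluster per planted template
  lab <- cluster_labels(cr)
  ref <- truth$template_id[match(names(lab), truth$probe_id)]
  expect_gte(mclust::adjustedRandIndex(lab, ref), 0.9)
  # reruns with one seed are identical
  cr2 <- consensus_cluster(datasets, consensus_params(k = 5, seed = 21))
  expect_identical(cr$co_fraction, cr2$co_fraction)
  expect_error(consensus_cluster(list(datasets[[1]],
                                      datasets[[2]][rev(keep), ]),
                                 consensus_params(k = 5)),
               "same probe universe")
})

test_that("figure of merit vanishes for exactly fit structure", {
  X <- matrix(rnorm(40), 10, 4)
  rownames(X) <- paste0("p", 1:10)
  # identical profiles: zero deviation at every k
  const <- matrix(1, 8, 4, dimnames = list(paste0("p", 1:8), NULL))
  fconst <- fom_analysis(const, k_range = c(2, 4, 8))
  expect_equal(fconst$fom, rep(0, 3))
  # every profile its own cluster: FOM exactly 0 (no 0 * Inf artifact)
  f <- fom_analysis(X, k_range = c(2, 9, 10))
  expect_equal(f$fom[f$k == 10], 0)
  expect_true(is.finite(f$fom[f$k == 9]))
  expect_true(all(f$fom >= 0))
  expect_error(fom_analysis(X, k_range = 2:11), "exceeds")
  expect_error(fom_analysis(X[, 1, drop = FALSE], 2), ">= 2 timepoints")
})

test_that("hierarchical ordering is deterministic and permutation-invariant", {
  X <- rbind(a = c(0, 0, 0, 0), b = c(0.01, 0, 0, 0),
             c = c(0.02, 0.01, 0, 0), out = c(5, 5, 5, 5))
  ho <- hierarchical_order(X)
  # identical profiles merge at height 0
  same <- hierarchical_order(rbind(x = 1:4, y = 1:4))
  expect_equal(same$hclust$height, 0)
  # the distant outlier merges last
  expect_equal(max(ho$hclust$height), ho$hclust$height[3])
  expect_true(which(ho$order == "out") %in% c(1, 4))
  # permuted input: same topology (equal cophenetic distances)
  perm <- X[c(3, 1, 4, 2), ]
  co1 <- as.matrix(stats::cophenetic(ho$hclust))
  co2 <- as.matrix(stats::cophenetic(hierarchical_order(perm)$hclust))
  expect_equal(co2[rownames(co1), colnames(co1)], co1)
  expect_error(hierarchical_order(X[1, , drop = FALSE]), ">= 2")
})

test_that("adjusted Rand index agrees with a hand-computed contingency case", {
  # two partitions of 6 items: {1,2,3|4,5,6} vs {1,2|3,4,5,6};
  # pair counts: index 4, expected 14/5, max 13/2, so
  # ARI = (4 - 14/5) / (13/2 - 14/5) = 12/37
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  expect_equal(mclust::adjustedRandIndex(a, b), 12 / 37)
  expect_equal(mclust::adjustedRandIndex(a, a), 1)
})
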