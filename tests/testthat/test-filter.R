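test_that("detection filter is inclusive at the bound and respects the mask", {
  em <- toy_em(n_probes = 3, missing_dmm_2wk_rep = 1)
  # probe 1 sits exactly at the bound everywhere; probe 2 fails one array
  em$detection_p[1, ] <- 0.06
  em$detection_p[2, "d_4wk_r2"] <- 0.061
  # probe 3 fails only in arrays feeding 2-week SLRs (dmm numerator +
  # sham denominator); the replicate missing its 2-week arrays never
  # consults them
  em$detection_p[3, c("d_2wk_r2", "d_2wk_r3",
                      sprintf("s_2wk_r%d", 1:3))] <- 0.5
  tc <- build_time_course_set(em, "dmm_vs_sham")
  det <- detection_filter(em, tc, filter_params())
  expect_true("p01" %in% det$rep1 && "p01" %in% det$rep2)
  expect_false("p02" %in% det$rep2)
  expect_true("p02" %in% det$rep1 && "p02" %in% det$rep3)
  expect_true("p03" %in% det$rep1)   # masked timepoint: arrays absent
  expect_false("p03" %in% det$rep2)
  expect_false("p03" %in% det$rep3)
})

test_that("detection control arrays are the SLR denominators", {
  em <- toy_em(n_probes = 2)
  # probe 2 undetected in the time-0 baseline arrays only
  em$detection_p[2, sprintf("b_r%d", 1:3)] <- 0.9
  tc_sham <- build_time_course_set(em, "sham_vs_baseline")
  det <- detection_filter(em, tc_sham, filter_params())
  expect_false(any(vapply(det, function(s) "p02" %in% s, TRUE)))
  # the DMM comparison never consults baseline arrays
  tc_dmm <- build_time_course_set(em, "dmm_vs_sham")
  det_dmm <- detection_filter(em, tc_dmm, filter_params())
  expect_true(all(vapply(det_dmm, function(s) "p02" %in% s, TRUE)))
})

test_that("SLR filter keeps a probe with |SLR| at the bound at any timepoint", {
  slr <- array(0, c(3, 3, 4))
  slr[1, 1, ] <- c(0.2, 0.5, 0.1, -0.3)     # one point at the bound
  slr[2, 1, ] <- c(0.49, -0.49, 0, 0.3)     # just below everywhere
  slr[3, 1, ] <- c(9, 0.5, 0.1, 0)          # strong at a masked timepoint
  em <- toy_em(n_probes = 3, dmm_slr = slr, missing_dmm_2wk_rep = 1)
  tc <- build_time_course_set(em, "dmm_vs_sham")
  kept <- slr_filter(tc, filter_params())
  expect_true("p01" %in% kept$rep1)
  expect_false("p02" %in% kept$rep1)
  # the 2-week value of the masked replicate does not exist; 0.5 at 4
  # weeks carries probe 3
  expect_true("p03" %in% kept$rep1)
  expect_equal(kept$rep2, character(0))
  expect_equal(
    slr_filter(tc, filter_params(slr_abs_min = 1e9))$rep1, character(0))
})

test_that("overlap filter is plain intersection over all replicates", {
  expect_setequal(overlap_filter(list(c("a", "b", "c"), c("b", "c", "d"),
                                      c("b", "c"))), c("b", "c"))
  expect_equal(overlap_filter(list("a", "b", "c")), character(0))
  expect_setequal(overlap_filter(list(c("a", "b"), c("a", "b"))), c("a", "b"))
  expect_error(overlap_filter(list("a")), ">= 2")
})

test_that("pairwise scores give exact PCC/ED on constructed profiles", {
  slr <- array(0, c(4, 3, 4))
  slr[1, 1, ] <- slr[1, 2, ] <- slr[1, 3, ] <- c(1, 2, 0.5, 1) # identical
  slr[2, 1, ] <- c(1, 2, 0.5, 1); slr[2, 2, ] <- -c(1, 2, 0.5, 1)
  slr[3, 1, ] <- c(1, 1, 1, 1);   slr[3, 2, ] <- c(1, 1, 1, 0.4)
  slr[4, 1, ] <- c(2, 2, 2, 2);   slr[4, 2, ] <- c(1, 2, 3, 4) # zero variance
  em <- toy_em(n_probes = 4, dmm_slr = slr)
  sc <- pairwise_scores(build_time_course_set(em, "dmm_vs_sham"))
  expect_equal(unname(sc$pcc[1, ]), c(1, 1, 1))
  expect_equal(unname(sc$ed[1, ]), c(0, 0, 0))
  expect_equal(unname(sc$pcc[2, "rep1-rep2"]), -1)
  expect_equal(unname(sc$ed[3, "rep1-rep2"]), 0.6)
  expect_true(is.na(sc$pcc[4, "rep1-rep2"]))   # undefined, not fabricated
  expect_false(is.na(sc$ed[4, "rep1-rep2"]))
  expect_equal(unname(sc$n_shared_timepoints), c(4L, 4L, 4L))
})

test_that("pairs with a masked replicate are scored on shared timepoints only", {
  slr <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  em <- toy_em(n_probes = 2, dmm_slr = slr, missing_dmm_2wk_rep = 1)
  sc <- pairwise_scores(build_time_course_set(em, "dmm_vs_sham"))
  expect_equal(unname(sc$n_shared_timepoints),
               c(3L, 3L, 4L))
  # ED over the 3 shared points, no length rescaling
  expect_equal(unname(sc$ed[1, "rep1-rep2"]),
               sqrt(sum((slr[1, 1, 2:4] - slr[1, 2, 2:4])^2)))
  # scores are symmetric in replicate order: relabeling replicates
  # permutes pairs but preserves values
  em2 <- toy_em(n_probes = 2, dmm_slr = slr[, c(2, 1, 3), , drop = FALSE],
                missing_dmm_2wk_rep = 2)
  sc2 <- pairwise_scores(build_time_course_set(em2, "dmm_vs_sham"))
  expect_equal(unname(sc2$ed[1, "rep1-rep2"]), unname(sc$ed[1, "rep1-rep2"]))
  expect_equal(sort(round(as.numeric(sc2$ed[1, ]), 10)),
               sort(round(as.numeric(sc$ed[1, ]), 10)))
})

test_that("PCC ignores positive affine rescaling; ED scales linearly", {
  set.seed(7)
  for (i in 1:10) {
    slr <- array(rnorm(1 * 3 * 4), c(1, 3, 4))
    em <- toy_em(n_probes = 1, dmm_slr = slr)
    sc <- pairwise_scores(build_time_course_set(em, "dmm_vs_sham"))
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    slr2 <- slr; slr2[1, 1, ] <- a * slr[1, 1, ] + b
    sc2 <- pairwise_scores(build_time_course_set(
      toy_em(n_probes = 1, dmm_slr = slr2), "dmm_vs_sham"))
    expect_equal(sc2$pcc[1, "rep1-rep2"], sc$pcc[1, "rep1-rep2"])
    slr3 <- slr * a
    sc3 <- pairwise_scores(build_time_course_set(
      toy_em(n_probes = 1, dmm_slr = slr3), "dmm_vs_sham"))
    expect_equal(unname(sc3$ed[1, ]), unname(a * sc$ed[1, ]))
  }
})

test_that("median ED cutoff follows the sort-based median convention", {
  expect_equal(median_ed_cutoff(c(0.2, 0.6, 1.0)), 0.6)
  expect_equal(median_ed_cutoff(c(0.2, 0.4)), 0.3)
  expect_error(median_ed_cutoff(numeric(0)), "no ED scores")
  sc <- make_scores(pcc = rbind(c(1, 1, 1), c(1, 1, 1)),
                    ed = rbind(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)))
  expect_equal(median_ed_cutoff(sc), 0.35)
})

test_that("consistency filter applies the 2-of-3 rule on both score types", {
  par <- filter_params(pcc_min = 0.70, ed_max = 0.60)
  keep1 <- consistency_filter(make_scores(c(0.9, 0.8, 0.1),
                                          c(0.2, 0.3, 0.9)), par)
  expect_equal(keep1$probes, "p01")
  keep2 <- consistency_filter(make_scores(c(0.9, 0.1, 0.1),
                                          c(0.2, 0.3, 0.4)), par)
  expect_equal(keep2$probes, character(0))
  keep3 <- consistency_filter(make_scores(c(0.8, 0.75, 0.7),
                                          c(0.1, 0.2, 0.6)), par)
  expect_equal(keep3$probes, "p01")
  # undefined PCC counts as a failing pair
  keep4 <- consistency_filter(make_scores(c(NA, 0.9, 0.1),
                                          c(0.1, 0.1, 0.1)), par)
  expect_equal(keep4$probes, character(0))
  # requiring all 3 pairs is a subset of requiring 2
  set.seed(3)
  sc <- make_scores(matrix(runif(60, -1, 1), 20),
                    matrix(runif(60, 0, 1.2), 20))
  k2 <- consistency_filter(sc, filter_params(ed_max = 0.6))$probes
  k3 <- consistency_filter(sc, filter_params(ed_max = 0.6,
                                             min_passing_pairs = 3))$probes
  expect_true(all(k3 %in% k2))
})

test_that("filter cascade is monotone and reports every intermediate count", {
  ds <- generate_dataset(synthetic_spec(n_probes = 300, n_de = 30, seed = 9))
  res <- run_filter_pipeline(ds$matrix, "dmm_vs_sham",
                             filter_params(ed_max = 0.60))
  counts <- res$report$counts
  # per replicate: detection+slr <= each of its inputs
  for (r in paste0("rep", 1:3)) {
    cc <- counts[counts$replicate == r, ]
    expect_true(cc$n_probes[cc$step == "detection+slr"] <=
                  min(cc$n_probes[cc$step %in% c("detection", "slr")]))
  }
  expect_true(counts$n_probes[counts$step == "overlap"] <=
                min(counts$n_probes[counts$step == "detection+slr"]))
  expect_true(counts$n_probes[counts$step == "consistency"] <=
                counts$n_probes[counts$step == "overlap"])
  expect_setequal(res$probes, intersect(res$probes, res$overlap))
  # detection and SLR predicates commute within a replicate
  tc <- res$tcs
  det <- detection_filter(ds$matrix, tc)
  slr <- slr_filter(tc)
  for (i in 1:3) {
    expect_setequal(intersect(det[[i]], slr[[i]]),
                    intersect(slr[[i]], det[[i]]))
  }
})

test_that("filter parameter validation rejects out-of-range settings", {
  expect_error(filter_params(detection_p_max = 0), "\\(0, 1\\)")
  expect_error(filter_params(slr_abs_min = -1), "> 0")
  expect_error(filter_params(pcc_min = 1.5), "\\[-1, 1\\]")
  expect_error(filter_params(ed_max = "mean"), "median")
  expect_error(filter_params(ed_max = -0.1), ">= 0")
  expect_error(filter_params(min_passing_pairs = 0), ">= 1")
})
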