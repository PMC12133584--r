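# Small lesioning testbed: 12 networks, all planted edges inside DMN at a
# strong coupling, so the DMN carries the entire signal.
lesion_testbed <- function(seed = 4, n_subjects = 60L) {
  generate_synthetic(synthetic_preset(
    "lesion", seed = seed, n_subjects = n_subjects,
    atlas = c(AUD = 3L, CO = 3L, CP = 3L, DAN = 3L, DMN = 4L, FPN = 3L,
              RSP = 3L, SAL = 3L, SM = 3L, SML = 3L, VAN = 3L, VIS = 3L),
    planted_positive = list(networks = "DMN", n = 3L),
    planted_negative = list(networks = "DMN", n = 3L)))
}

test_that("lesioning the signal-bearing network collapses accuracy", {
  ds <- lesion_testbed()
  at <- ds$ground_truth$config$atlas
  sch <- split_scheme(30, 0.7, 4)
  sw <- suppressWarnings(lesion_sweep(ds$connectomes$edges, ds$behavior$total,
                                      at, sch, n_flips = 500))
  expect_equal(nrow(sw), 12L)
  expect_equal(sw$network[which.min(sw$mean_delta)], "DMN")
  dmn <- sw[sw$network == "DMN", ]
  expect_lt(dmn$mean_delta, -0.3)
  expect_lt(dmn$p_corrected, 0.05)
  # matched-split accounting and the documented summary statistics
  res <- attr(sw, "results")[[which(sw$network == "DMN")]]
  expect_lte(res$n_matched, sch$n_splits)
  expect_equal(res$mean_delta, mean(res$delta_r))
  expect_equal(res$se_delta, sd(res$delta_r) / sqrt(res$n_matched))
  expect_true(all(sw$p_corrected >= sw$p_value))
})

test_that("a signal-free network leaves selection unchanged at a strict threshold", {
  ds <- lesion_testbed(seed = 6)
  at <- ds$ground_truth$config$atlas
  res <- suppressWarnings(
    lesion_and_rerun(ds$connectomes$edges, ds$behavior$total, at, "AUD",
                     split_scheme(30, 0.7, 6), p_threshold = 1e-6,
                     n_flips = 500))
  expect_lte(abs(res$mean_delta), 2 * res$se_delta + 1e-12)
})

test_that("reselect and prune modes coincide for edge-wise selection", {
  ds <- lesion_testbed(seed = 5)
  at <- ds$ground_truth$config$atlas
  sch <- split_scheme(20, 0.7, 5)
  a <- suppressWarnings(lesion_and_rerun(ds$connectomes$edges, ds$behavior$total,
                                         at, "VIS", sch, mode = "reselect",
                                         n_flips = 200))
  b <- suppressWarnings(lesion_and_rerun(ds$connectomes$edges, ds$behavior$total,
                                         at, "VIS", sch, mode = "prune",
                                         n_flips = 200))
  expect_equal(a$delta_r, b$delta_r, tolerance = 1e-12)
})

test_that("lesioning is deterministic and idempotent on the edge set", {
  ds <- lesion_testbed(seed = 5)
  at <- ds$ground_truth$config$atlas
  sch <- split_scheme(20, 0.7, 5)
  a <- suppressWarnings(lesion_and_rerun(ds$connectomes$edges, ds$behavior$total,
                                         at, "SM", sch, n_flips = 300))
  b <- suppressWarnings(lesion_and_rerun(ds$connectomes$edges, ds$behavior$total,
                                         at, "SM", sch, n_flips = 300))
  expect_identical(a$delta_r, b$delta_r)
  expect_identical(a$p_value, b$p_value)
  # removing a network's edges twice removes nothing more
  idx <- edges_of_network(at, "SM")
  kept <- setdiff(seq_len(ncol(ds$connectomes$edges)), idx)
  expect_identical(setdiff(kept, idx), kept)
  # the stored full-model accuracy matches a fresh run under the same seed
  full <- suppressWarnings(run_cpm(ds$connectomes$edges, ds$behavior$total, sch))
  expect_identical(a$full_mean_r, full$mean_r)
})

test_that("lesioning everything or an absent network is refused", {
  atlas_all <- network_atlas(0:4, rep("DMN", 5))
  set.seed(1)
  x <- matrix(rnorm(20 * 10), 20, 10)
  expect_error(lesion_and_rerun(x, rnorm(20), atlas_all, "DMN",
                                split_scheme(5, 0.7, 1)),
               "every edge")
  expect_error(edges_of_network(atlas_all, "VIS"), "no parcel")
})

test_that("selection fractions concentrate where the signal is planted", {
  ds <- lesion_testbed(seed = 7)
  at <- ds$ground_truth$config$atlas
  res <- suppressWarnings(run_cpm(ds$connectomes$edges, ds$behavior$total,
                                  split_scheme(20, 0.7, 7), return_masks = TRUE))
  sf <- selection_fraction_matrix(res, at)
  expect_true(isSymmetric(sf$positive))
  expect_true(all(sf$positive >= 0 & sf$positive <= 1))
  # planted edges live within DMN: the DMN-DMN cell dominates both sets
  top_pos <- arrayInd(which.max(sf$positive), dim(sf$positive))
  expect_identical(rownames(sf$positive)[top_pos[1]], "DMN")
  expect_identical(colnames(sf$positive)[top_pos[2]], "DMN")
  # 3 of the 6 within-DMN edges are planted negative
  expect_gt(sf$negative["DMN", "DMN"], 0.4)
})

test_that("fully selected and never-selected pairs hit the matrix bounds", {
  # two networks; all DMN-VIS edges equal the outcome, within-network edges noise
  atlas <- network_atlas(0:3, c("DMN", "DMN", "VIS", "VIS"))
  set.seed(9)
  n <- 40L
  y <- rnorm(n)
  edges <- orthogonalized_edges(n, 6L, y, seed = 10)
  # pairs: (0,1) DMN-DMN, (0,2),(0,3),(1,2),(1,3) DMN-VIS, (2,3) VIS-VIS
  for (e in 2:5) edges[, e] <- y + rnorm(n, sd = 1e-3)
  res <- run_cpm(edges, y, split_scheme(10, 0.7, 11), score_mode = "positive_only",
                 return_masks = TRUE)
  sf <- selection_fraction_matrix(res, atlas)
  expect_equal(sf$positive["DMN", "VIS"], 1)
  expect_equal(sf$positive["DMN", "DMN"], 0)
  expect_equal(sf$negative, sf$negative * 0)
})
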