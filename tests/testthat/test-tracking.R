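mk_counts <- function(...) {
  tibble::tribble(~variant, ~timepoint, ~day, ~alt, ~depth, ...)
}

test_that("VAF matrices apply the detection rule and union semantics", {
  counts <- mk_counts(
    "v1", "t1", 0L, 5L, 100L,
    "v1", "t2", 30L, 0L, 5000L,
    "v2", "t1", 0L, 200L, 4000L)
  vm <- build_vaf_matrix(counts)
  expect_equal(vm$vaf["v1", "t1"], 0.05)
  expect_true(vm$detected["v1", "t1"])
  # alt 0 of 5000: undetected, vaf stored as 0, depth retained
  expect_false(vm$detected["v1", "t2"])
  expect_equal(vm$vaf["v1", "t2"], 0)
  expect_equal(vm$depth["v1", "t2"], 5000)
  # v2 absent from t2's calls: kept as an undetected row entry
  expect_false(vm$detected["v2", "t2"])
  expect_equal(vm$depth["v2", "t2"], 0)

  # 2 alt reads of 1000 fails the 3-read floor even though vaf > min_vaf
  vm2 <- build_vaf_matrix(mk_counts("v1", "t1", 0L, 2L, 1000L))
  expect_false(vm2$detected["v1", "t1"])

  # duplicate labels with conflicting days are rejected
  expect_error(build_vaf_matrix(mk_counts("v1", "t1", 0L, 5L, 100L,
                                          "v2", "t1", 9L, 5L, 100L)),
               "duplicate")
})

test_that("hand-computed pair structure is recovered by clustering", {
  counts <- dplyr::bind_rows(
    mk_counts("a1", "t1", 0L, 100L, 1000L, "a1", "t2", 10L, 110L, 1000L,
              "a1", "t3", 20L, 100L, 1000L),
    mk_counts("a2", "t1", 0L, 105L, 1000L, "a2", "t2", 10L, 105L, 1000L,
              "a2", "t3", 20L, 105L, 1000L),
    mk_counts("b1", "t1", 0L, 300L, 1000L, "b1", "t2", 10L, 300L, 1000L,
              "b1", "t3", 20L, 310L, 1000L),
    mk_counts("b2", "t1", 0L, 305L, 1000L, "b2", "t2", 10L, 300L, 1000L,
              "b2", "t3", 20L, 300L, 1000L))
  vm <- build_vaf_matrix(counts)
  cl <- cluster_trajectories(vm, k = 2)
  a <- tidy(cl)
  expect_equal(a$cluster[a$variant == "a1"], a$cluster[a$variant == "a2"])
  expect_equal(a$cluster[a$variant == "b1"], a$cluster[a$variant == "b2"])
  expect_false(a$cluster[a$variant == "a1"] == a$cluster[a$variant == "b1"])
  # tight pairs merge first: the first two merge heights are the within-pair
  # distances, far below the between-pair separation
  expect_true(all(cl$hclust$height[1:2] < 0.05))
  expect_true(all(diff(cl$hclust$height) >= -1e-12))

  # identical rows collapse at height zero
  vm_id <- build_vaf_matrix(dplyr::bind_rows(
    mk_counts("x1", "t1", 0L, 100L, 1000L, "x1", "t2", 10L, 50L, 1000L),
    mk_counts("x2", "t1", 0L, 100L, 1000L, "x2", "t2", 10L, 50L, 1000L)))
  cl_id <- cluster_trajectories(vm_id, h = 1e-9)
  expect_equal(cl_id$n_clusters, 1)

  expect_error(cluster_trajectories(vm_id <- build_vaf_matrix(
    mk_counts("x1", "t1", 0L, 100L, 1000L)), k = 2), "at least 2")
})

test_that("clustering is invariant to variant input order", {
  cfg <- sim_config()
  tc <- simulate_timecourse(cfg)
  counts <- timecourse_counts(tc, depth = 3000, noise = TRUE, seed = 5)
  vm1 <- cluster_trajectories(build_vaf_matrix(counts), k = 2)
  counts_perm <- counts[withr::with_seed(1, sample(nrow(counts))), ]
  vm2 <- cluster_trajectories(build_vaf_matrix(counts_perm), k = 2)
  expect_identical(tidy(vm1), tidy(vm2))
})

test_that("progression detection fires on re-emergence, not on decline", {
  # monotone decline: never called
  dec <- purrr::map_dfr(1:5, function(j) {
    tibble::tibble(variant = c("v1", "v2"), timepoint = sprintf("t%d", j),
                   day = j * 30L, alt = c(60L, 50L) - 10L * j, depth = 1000L)
  })
  pc <- detect_progression(build_vaf_matrix(dec))
  expect_true(is.na(pc$call_day))

  # all-undetected matrix: never called
  und <- purrr::map_dfr(1:4, function(j) {
    tibble::tibble(variant = c("v1", "v2"), timepoint = sprintf("t%d", j),
                   day = j * 30L, alt = 0L, depth = 1000L)
  })
  expect_true(is.na(detect_progression(build_vaf_matrix(und))$call_day))

  # days must strictly increase
  bad <- mk_counts("v1", "t1", 10L, 5L, 100L, "v1", "t2", 10L, 5L, 100L)
  expect_error(detect_progression(build_vaf_matrix(bad)), "strictly increasing")

  # re-emergence after r undetected timepoints triggers at the right day,
  # and never earlier than the first post-nadir detection
  rise <- purrr::map_dfr(seq_along(c(0, 30, 60, 90, 120)), function(j) {
    day <- c(0L, 30L, 60L, 90L, 120L)[j]
    alt <- c(150L, 0L, 0L, 40L, 80L)[j]
    tibble::tibble(variant = c("v1", "v2"), timepoint = sprintf("t%d", j),
                   day = day, alt = alt, depth = 1000L)
  })
  pc2 <- detect_progression(build_vaf_matrix(rise), imaging_day = 150)
  expect_equal(pc2$call_day, 90L)
  expect_equal(pc2$lead_time_days, 60L)
  trace <- tidy(pc2)
  first_new <- min(trace$day[trace$n_new > 0])
  expect_gte(pc2$call_day, first_new)
})

test_that("the default relapse scenario is called at day 119 with 88-day lead", {
  tc <- simulate_timecourse(sim_config())
  vm <- build_vaf_matrix(timecourse_counts(tc, depth = 3000))
  pc <- detect_progression(vm, imaging_day = attr(tc, "imaging_day"))
  expect_equal(pc$call_day, 119L)
  expect_equal(pc$lead_time_days, 88L)
  g <- glance(pc)
  expect_equal(g$imaging_day, 207L)
})

test_that("sample similarity is Pearson correlation with shared-variant guards", {
  counts <- dplyr::bind_rows(
    mk_counts("v1", "t1", 0L, 100L, 1000L, "v1", "t2", 10L, 300L, 1000L),
    mk_counts("v2", "t1", 0L, 200L, 1000L, "v2", "t2", 10L, 200L, 1000L),
    mk_counts("v3", "t1", 0L, 300L, 1000L, "v3", "t2", 10L, 100L, 1000L))
  vm <- build_vaf_matrix(counts)
  ss <- sample_similarity(vm)
  expect_equal(diag(ss$similarity), c(t1 = 1, t2 = 1))
  # hand example: (0.1, 0.2, 0.3) vs (0.3, 0.2, 0.1) -> -1
  expect_equal(ss$similarity["t1", "t2"], -1)

  # a scaled copy correlates perfectly
  extra <- tibble::tibble(variant = c("v1", "v2", "v3"), sample = "tumor",
                          vaf = c(0.2, 0.4, 0.6))
  ss2 <- sample_similarity(vm, extra = extra)
  expect_equal(ss2$similarity["t1", "tumor"], 1)

  # fewer than two shared variants: flagged undefined, not silently 0
  extra1 <- tibble::tibble(variant = "v1", sample = "sparse", vaf = 0.5)
  ss3 <- sample_similarity(vm, extra = extra1)
  expect_true(is.na(ss3$similarity["t1", "sparse"]))
  expect_true("sparse" %in% c(ss3$undefined$sample_1, ss3$undefined$sample_2))
})

test_that("the depth planner implements X = kappa / (alpha * f) exactly", {
  expect_equal(required_depth(0.01, 1, 1), 100)
  expect_equal(required_depth(0.001, 0.5, 2.5), 5000)
  # linear in kappa
  expect_equal(required_depth(0.01, 0.8, 4), 2 * required_depth(0.01, 0.8, 2))
  # round trip recovers f to machine precision
  X <- required_depth(0.0037, 0.62, 3.1)
  expect_equal(3.1 / (0.62 * X), 0.0037, tolerance = 1e-15)
  expect_error(required_depth(0, 1, 1), "f must")
  expect_error(required_depth(0.1, 0, 1), "alpha")
  expect_error(required_depth(0.1, 1, 0.5), "kappa")
})
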