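test_that("simulated references have the requested length, GC and determinism", {
  r <- simulate_reference(10000, 0.41, seed = 7)
  expect_equal(nchar(r), 10000)
  gc <- sum(strsplit(r, "")[[1]] %in% c("G", "C")) / 10000
  expect_lt(abs(gc - 0.41), 0.02)

  expect_identical(simulate_reference(1000, 0.5, seed = 1),
                   simulate_reference(1000, 0.5, seed = 1))

  r99 <- simulate_reference(10000, 0.99, seed = 3)
  gc99 <- sum(strsplit(r99, "")[[1]] %in% c("G", "C")) / 10000
  expect_gt(gc99, 0.95)

  expect_error(simulate_reference(0, 0.5, seed = 1), "positive")
})

test_that("fragment lengths follow the periodic nucleosome model", {
  cfg <- sim_config()
  expect_identical(sample_fragment_lengths(0, cfg), integer(0))
  expect_error(sample_fragment_lengths(-1, cfg), "non-negative")

  len <- sample_fragment_lengths(200000, cfg)
  expect_true(all(len >= 30))
  st <- fragment_length_modes(len)
  expect_equal(st$mode, 167)
  expect_equal(st$peak_spacing, 10)
  # determinism under the config seed
  expect_identical(len, sample_fragment_lengths(200000, cfg))
})

test_that("somatic planting follows the signature weights", {
  ref <- simulate_reference(200000, 0.41, seed = 5)
  cfg <- sim_config(somatic_count = 1000, seed = 5)
  truth <- plant_variants(ref, cfg)
  expect_equal(nrow(truth$somatic), 1000)
  frac_ct <- mean(grepl("C>T", truth$somatic$class96, fixed = TRUE))
  expect_lt(abs(frac_ct - 0.8), 0.04)
  # germline and somatic positions are disjoint
  expect_length(intersect(truth$somatic$pos, truth$germline$pos), 0)
  # planted alleles differ from the reference
  refv <- strsplit(ref, "")[[1]]
  expect_true(all(truth$somatic$ref == refv[truth$somatic$pos]))
  expect_true(all(truth$somatic$ref != truth$somatic$alt))

  # chi-square goodness of fit of planted classes vs the weights (classes
  # with non-trivial expectation, 10000 events)
  cfg2 <- sim_config(somatic_count = 10000, reference_length = 500000, seed = 6)
  ref2 <- simulate_reference(500000, 0.41, seed = 6)
  t2 <- plant_variants(ref2, cfg2)
  w <- cfg2$signature_weights
  obs <- table(factor(t2$somatic$class96, levels = names(w)))
  keep <- 10000 * w >= 5
  obs_v <- as.vector(obs[keep])
  p_v <- w[keep]
  if (any(!keep)) {
    obs_v <- c(obs_v, sum(obs[!keep]))
    p_v <- c(p_v, sum(w[!keep]))
  }
  chi <- suppressWarnings(stats::chisq.test(obs_v, p = p_v))
  expect_gt(chi$p.value, 0.01)
})

test_that("degenerate planting configurations behave exactly", {
  ref <- simulate_reference(50000, 0.41, seed = 9)
  t0 <- plant_variants(ref, sim_config(reference_length = 50000,
                                       somatic_count = 0, seed = 9))
  expect_equal(nrow(t0$somatic), 0)
  expect_gt(nrow(t0$germline), 0)

  t1 <- plant_variants(ref, sim_config(reference_length = 50000,
                                       germline_het_rate = 0,
                                       somatic_count = 10, seed = 9))
  expect_equal(nrow(t1$germline), 0)
  expect_equal(nrow(t1$somatic), 10)
})

test_that("simulated alignments carry the expected alleles, depth and errors", {
  cfg <- sim_config(reference_length = 100000, somatic_count = 50,
                    mean_depth = 60, germline_depth = 20, seed = 13,
                    error_matrix = uniform_confusion_matrix(0))
  ds <- simulate_dataset(cfg, cfdna_days = c(-7), samples = c("cfdna", "germline"))
  reads <- ds$reads$reads

  # identity error matrix: zero injected errors, every mismatch is a variant
  expect_equal(nrow(ds$reads$error_log), 0)
  truth_pos <- sort(c(ds$truth$germline$pos, ds$truth$somatic$pos))
  cf <- dplyr::filter(reads, sample == "cfdna_d-7")
  refv <- strsplit(ds$reference, "")[[1]]
  mism <- unlist(lapply(seq_len(nrow(cf)), function(i) {
    obs <- strsplit(cf$seq[i], "")[[1]]
    p <- cf$pos[i]:(cf$pos[i] + length(obs) - 1L)
    p[obs != refv[p]]
  }))
  expect_true(all(unique(mism) %in% truth_pos))

  # mean observed depth within 5% of the target on a 100 kb genome
  obs_depth <- sum(nchar(cf$seq)) / cfg$reference_length
  expect_lt(abs(obs_depth - 60) / 60, 0.05)

  # byte-identical regeneration from an identical config
  ds2 <- simulate_dataset(cfg, cfdna_days = c(-7), samples = c("cfdna", "germline"))
  expect_identical(ds$reads$reads, ds2$reads$reads)
  expect_identical(ds$truth$somatic, ds2$truth$somatic)
})

test_that("somatic alt fraction in reads matches the binomial expectation", {
  # single clone at tumour fraction 0.10 -> expected VAF 0.05, depth 1000
  dyn <- default_subclone_dynamics()
  dyn$A[] <- 0.10
  dyn$B[] <- 0
  cfg <- sim_config(reference_length = 20000, somatic_count = 5,
                    germline_het_rate = 0, mean_depth = 1000,
                    clone_weights = c(AB = 0, A = 1, B = 0),
                    subclone_dynamics = dyn,
                    error_matrix = uniform_confusion_matrix(0), seed = 21)
  ds <- simulate_dataset(cfg, cfdna_days = c(-7), samples = "cfdna")
  cf <- ds$reads$reads
  for (j in seq_len(nrow(ds$truth$somatic))) {
    p <- ds$truth$somatic$pos[j]
    covers <- cf$pos <= p & cf$end >= p
    base_at <- substr(cf$seq[covers], p - cf$pos[covers] + 1L,
                      p - cf$pos[covers] + 1L)
    n <- sum(covers)
    k <- sum(base_at == ds$truth$somatic$alt[j])
    ci <- stats::qbinom(c(0.005, 0.995), n, 0.05)
    expect_gte(k, ci[1])
    expect_lte(k, ci[2])
  }

  # tumour fraction 0 everywhere: no somatic alt reads at all (error-free)
  dyn0 <- dyn
  dyn0$A[] <- 0
  cfg0 <- sim_config(reference_length = 20000, somatic_count = 5,
                     germline_het_rate = 0, mean_depth = 200,
                     clone_weights = c(AB = 0, A = 1, B = 0),
                     subclone_dynamics = dyn0,
                     error_matrix = uniform_confusion_matrix(0), seed = 22)
  ds0 <- simulate_dataset(cfg0, cfdna_days = c(-7), samples = "cfdna")
  cf0 <- ds0$reads$reads
  for (j in seq_len(nrow(ds0$truth$somatic))) {
    p <- ds0$truth$somatic$pos[j]
    covers <- cf0$pos <= p & cf0$end >= p
    base_at <- substr(cf0$seq[covers], p - cf0$pos[covers] + 1L,
                      p - cf0$pos[covers] + 1L)
    expect_equal(sum(base_at == ds0$truth$somatic$alt[j]), 0)
  }
})

test_that("the expected-VAF time course reproduces the relapse scenario", {
  tc <- simulate_timecourse(sim_config())
  expect_s3_class(tc, "timecourse")
  a1 <- dplyr::filter(tc, subclone == "A", variant == "var_A01")
  expect_equal(a1$day, c(-7, 0, 17, 42, 70, 100, 119, 150, 280, 343))
  # pre-treatment driver VAF 5%, relapse VAF 8% at the final timepoint
  expect_equal(a1$expected_vaf[1], 0.05)
  expect_equal(a1$expected_vaf[10], 0.08)
  # suppressed to zero on therapy
  expect_true(all(a1$expected_vaf[3:6] == 0))
  expect_equal(attr(tc, "imaging_day"), 207L)

  # single constant subclone: flat VAF at half the fraction
  dyn <- default_subclone_dynamics()
  dyn$A[] <- 0.1
  dyn$B[] <- 0
  tc2 <- simulate_timecourse(sim_config(subclone_dynamics = dyn,
                                        tracked_per_subclone = 3))
  expect_true(all(dplyr::filter(tc2, subclone == "A")$expected_vaf == 0.05))

  # fractions summing above 1 are rejected
  dyn_bad <- default_subclone_dynamics()
  dyn_bad$A[] <- 0.7
  dyn_bad$B[] <- 0.6
  expect_error(sim_config(subclone_dynamics = dyn_bad), "sum")
})
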