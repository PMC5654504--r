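test_that("background haplotype is the reference with the alt substituted", {
  ref <- simulate_reference(1000, 0.5, seed = 1)
  pos <- 500L
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, pos, pos))[1]
  read_seq <- substr(ref, 420, 580)
  substr(read_seq, pos - 420L + 1L, pos - 420L + 1L) <- alt
  hap <- build_background_haplotype(pos, alt, make_reads(420L, read_seq), ref,
                                    w = 30)
  expected <- substr(ref, 470, 530)
  substr(expected, 31, 31) <- alt
  expect_equal(as.character(hap), expected)
  expect_equal(attr(hap, "start"), 470L)
  expect_equal(attr(hap, "centre"), 31L)

  expect_error(build_background_haplotype(pos, alt, make_reads(integer(0),
                                                               character(0)),
                                          ref),
               "no alternate-supporting reads")
})

test_that("phased neighbouring variation is carried into the haplotype", {
  ref <- strrep("ACGT", 250)
  pos <- 400L
  het_pos <- 405L  # phased germline het 5 bp away
  alt <- "T"  # ref at 400 is T? positions: 400 mod 4 = 0 -> T; pick alt C
  ref_base <- substr(ref, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  het_alt <- setdiff(c("A", "C", "G", "T"), substr(ref, het_pos, het_pos))[1]
  mk <- function(start) {
    s <- substr(ref, start, start + 100L)
    substr(s, pos - start + 1L, pos - start + 1L) <- alt
    substr(s, het_pos - start + 1L, het_pos - start + 1L) <- het_alt
    s
  }
  alt_reads <- make_reads(c(350L, 360L, 370L), c(mk(350L), mk(360L), mk(370L)))
  hap <- as.character(build_background_haplotype(pos, alt, alt_reads, ref,
                                                 w = 30))
  expect_equal(substr(hap, 31, 31), alt)
  expect_equal(substr(hap, 31 + 5, 31 + 5), het_alt)
  # everything else matches the reference window
  expected <- substr(ref, 370, 430)
  substr(expected, 31, 31) <- alt
  substr(expected, 36, 36) <- het_alt
  expect_equal(as.character(hap), expected)
})

test_that("a single clean haplotype assembles into one contig containing it", {
  hap <- simulate_reference(120, 0.5, seed = 2)
  contigs <- local_assemble(rep(hap, 3), k = 31)
  expect_equal(nrow(contigs), 1)
  expect_true(grepl(hap, contigs$contig[1], fixed = TRUE))
})

test_that("a heterozygous site forms a four-contig bubble with both alleles", {
  h1 <- simulate_reference(80, 0.5, seed = 5)
  snv_pos <- 40L
  h2 <- h1
  substr(h2, snv_pos, snv_pos) <- setdiff(c("A", "C", "G", "T"),
                                          substr(h1, snv_pos, snv_pos))[1]
  contigs <- local_assemble(c(rep(h1, 2), rep(h2, 2)), k = 21)
  # shared prefix, two allele paths, shared suffix
  expect_equal(nrow(contigs), 4)
  # both allele paths recoverable: each haplotype's variant-spanning 21-mer
  # occurs in some contig
  span1 <- substr(h1, snv_pos - 10L, snv_pos + 10L)
  span2 <- substr(h2, snv_pos - 10L, snv_pos + 10L)
  expect_true(any(grepl(span1, contigs$contig, fixed = TRUE)))
  expect_true(any(grepl(span2, contigs$contig, fixed = TRUE)))
  # prefix/suffix contigs reconstruct the shared sequence
  expect_true(any(grepl(substr(h1, 1, 39), contigs$contig, fixed = TRUE)))
  expect_true(any(grepl(substr(h1, 41, 80), contigs$contig, fixed = TRUE)))
})

test_that("the k-mer abundance floor silences singleton input", {
  hap <- simulate_reference(100, 0.5, seed = 6)
  expect_equal(nrow(local_assemble(hap, k = 31, min_kmer_count = 2)), 0)
  expect_equal(nrow(local_assemble(rep(hap, 2), k = 31, min_kmer_count = 2)), 1)
})

test_that("k-mer verification counts spanning k-mers and read support", {
  ref <- simulate_reference(1000, 0.5, seed = 7)
  pos <- 500L
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, pos, pos))[1]
  hap <- substr(ref, 470, 530)
  substr(hap, 31, 31) <- alt
  attr(hap, "start") <- 470L
  attr(hap, "centre") <- 31L

  mk_read <- function(start, carry_alt) {
    s <- substr(ref, start, start + 120L)
    if (carry_alt) substr(s, pos - start + 1L, pos - start + 1L) <- alt
    s
  }
  cf <- c(vapply(c(430L, 440L, 450L, 455L, 460L), mk_read, "", carry_alt = TRUE),
          vapply(seq(400L, 580L, by = 10L), mk_read, "", carry_alt = FALSE))
  gl <- vapply(seq(400L, 580L, by = 10L), mk_read, "", carry_alt = FALSE)

  ev <- kmer_verify(hap, cf, gl, k = 31, min_support = 3,
                    germline_tolerance = 0)
  expect_equal(ev$n_spanning, 31)  # min(k, w+1, |hap|-k+1) for the 61-mer
  expect_equal(ev$cfdna_support, 5)
  expect_equal(ev$germline_support, 0)
  expect_equal(ev$verdict, "verified")
  expect_true(ev$assembly_confirmed)

  # haplotype present in germline reads -> germline_contaminated
  gl2 <- c(gl, vapply(c(430L, 440L, 450L), mk_read, "", carry_alt = TRUE))
  expect_equal(kmer_verify(hap, cf, gl2, k = 31)$verdict,
               "germline_contaminated")

  # too few supporting fragments -> insufficient
  cf2 <- c(vapply(c(430L, 440L), mk_read, "", carry_alt = TRUE),
           vapply(seq(400L, 580L, by = 10L), mk_read, "", carry_alt = FALSE))
  expect_equal(kmer_verify(hap, cf2, gl, k = 31)$verdict, "insufficient")

  expect_error(kmer_verify(substr(hap, 1, 20), cf, gl, k = 31), "shorter")
})

test_that("verification is invariant under reverse-complemented reads", {
  ref <- simulate_reference(1000, 0.5, seed = 9)
  pos <- 500L
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, pos, pos))[1]
  hap <- substr(ref, 470, 530)
  substr(hap, 31, 31) <- alt
  attr(hap, "start") <- 470L
  attr(hap, "centre") <- 31L
  mk_read <- function(start, carry_alt) {
    s <- substr(ref, start, start + 120L)
    if (carry_alt) substr(s, pos - start + 1L, pos - start + 1L) <- alt
    s
  }
  cf <- c(vapply(c(430L, 440L, 450L, 460L), mk_read, "", carry_alt = TRUE),
          vapply(seq(400L, 580L, by = 15L), mk_read, "", carry_alt = FALSE))
  gl <- vapply(seq(400L, 580L, by = 15L), mk_read, "", carry_alt = FALSE)
  ev_fwd <- kmer_verify(hap, cf, gl, k = 31)
  ev_rc <- kmer_verify(hap, revcomp(cf), revcomp(gl), k = 31)
  expect_equal(ev_fwd$cfdna_support, ev_rc$cfdna_support)
  expect_equal(ev_fwd$germline_support, ev_rc$germline_support)
  expect_equal(ev_fwd$verdict, ev_rc$verdict)
})

test_that("true somatic variants verify and germline hets are rejected", {
  cfg <- sim_config(reference_length = 60000, somatic_count = 30,
                    mean_depth = 80, germline_depth = 30, seed = 19,
                    clone_weights = c(AB = 1, A = 0, B = 0),
                    error_matrix = uniform_confusion_matrix(0))
  ds <- simulate_dataset(cfg, cfdna_days = c(-7), samples = c("cfdna", "germline"))
  cf <- dplyr::filter(ds$reads$reads, sample == "cfdna_d-7")
  gl <- dplyr::filter(ds$reads$reads, sample == "germline")

  # count alt-supporting fragments per somatic variant
  support <- vapply(seq_len(nrow(ds$truth$somatic)), function(j) {
    p <- ds$truth$somatic$pos[j]
    covers <- cf$pos <= p & cf$end >= p
    sum(substr(cf$seq[covers], p - cf$pos[covers] + 1L,
               p - cf$pos[covers] + 1L) == ds$truth$somatic$alt[j])
  }, integer(1))
  som <- ds$truth$somatic[support >= 3, ]
  cand_som <- tibble::tibble(
    chrom = "ref1", pos = som$pos, ref = som$ref, alt = som$alt,
    depth = 80L, n_hq = 80L, k = support[support >= 3],
    vaf = 0.08, filter = "PASS", called = TRUE)
  v_som <- verify_candidates(cand_som, cf, gl, ds$reference,
                             germline_genotypes = ds$truth$germline)
  expect_true(all(v_som$verdict == "verified"))

  # germline hets presented as candidates are flagged as contamination
  het <- utils::head(ds$truth$germline[order(ds$truth$germline$pos), ], 10)
  cand_het <- tibble::tibble(
    chrom = "ref1", pos = het$pos, ref = het$ref, alt = het$alt,
    depth = 80L, n_hq = 80L, k = 30L, vaf = 0.4, filter = "PASS",
    called = TRUE)
  v_het <- verify_candidates(cand_het, cf, gl, ds$reference,
                             germline_genotypes = ds$truth$germline)
  expect_true(all(v_het$verdict == "germline_contaminated"))
})
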