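#' Default base-quality bins
#'
#' Three Phred-quality strata used when estimating and querying confusion
#' matrices: 0-19, 20-29, and 30 upwards.
#'
#' @return Tibble with columns `lo`, `hi` (inclusive bounds; `hi` may be
#'   `Inf`).
#' @export
default_quality_bins <- function() {
  tibble(lo = c(0, 20, 30), hi = c(19, 29, Inf))
}

new_confusion_matrix <- function(matrices, bins, sample_id, site_count,
                                 pseudocount) {
  for (M in matrices) {
    stopifnot(all(dim(M) == c(4, 4)), all(M >= 0),
              all(abs(rowSums(M) - 1) < 1e-9))
  }
  structure(list(sample_id = sample_id, bins = bins, matrices = matrices,
                 site_count = site_count, pseudocount = pseudocount),
            class = "confusion_matrix")
}

#' Uniform substitution-error confusion matrix
#'
#' Builds a confusion matrix in which every base is misread at total rate
#' `rate`, split equally over the three wrong bases (each off-diagonal entry
#' is `rate/3`). `rate = 0` gives the identity matrix. Used as the simulator's
#' default error process and as a convenient analytic reference.
#'
#' @param rate Total per-base substitution-error probability, in `[0, 1)`.
#' @param bins Quality bins (the same matrix is used in every bin).
#' @param sample_id Label stored on the object.
#' @return A `"confusion_matrix"` object.
#' @export
#' @examples
#' cm <- uniform_confusion_matrix(0.01)
#' error_rate(cm, "C", "T", 30)  # 0.01/3
uniform_confusion_matrix <- function(rate, bins = default_quality_bins(),
                                     sample_id = "uniform") {
  stopifnot(rate >= 0, rate < 1)
  M <- matrix(rate / 3, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(M) <- 1 - rate
  new_confusion_matrix(rep(list(M), nrow(bins)), bins, sample_id,
                       site_count = 0L, pseudocount = 0)
}

# index of the quality bin containing `quality`; errors if none does
quality_bin_index <- function(cm, quality) {
  i <- which(cm$bins$lo <= quality & quality <= cm$bins$hi)
  if (length(i) != 1) {
    abort(sprintf("quality %s falls outside all configured bins", quality))
  }
  i
}

#' Estimate an empirical confusion matrix from alignments
#'
#' Tallies observed versus true base at reference positions, taking the
#' reference base as the truth proxy. Sites listed in `excluded_sites` (known
#' germline variants and somatic candidates) are skipped, as are sites where
#' more than one distinct non-reference base is seen in two or more reads
#' (likely real variation rather than error). Reads below `min_mapq` are
#' dropped and the `end_trim` outermost bases of every read are ignored,
#' suppressing alignment-end artefacts. Tallies are stratified by the read's
#' base-quality bin and row-normalised with an additive pseudocount.
#'
#' @param reads Tibble of aligned reads (`pos`, `seq`, `mapq`, `base_qual`),
#'   as produced by [generate_alignments()] or [read_alignments()]. Ungapped
#'   alignments are assumed.
#' @param reference Reference sequence string.
#' @param excluded_sites Integer vector of 1-based positions to exclude.
#' @param quality_bins Quality strata, see [default_quality_bins()].
#' @param pseudocount Additive count per cell before normalisation.
#' @param sample_id Label stored on the result.
#' @param min_mapq Minimum mapping quality.
#' @param end_trim Bases ignored at each read end.
#' @return A `"confusion_matrix"` object; `site_count` records the number of
#'   reference sites that contributed tallies.
#' @export
estimate_confusion_matrix <- function(reads, reference,
                                      excluded_sites = integer(0),
                                      quality_bins = default_quality_bins(),
                                      pseudocount = 1,
                                      sample_id = "sample",
                                      min_mapq = 20, end_trim = 5) {
  L <- nchar(reference)
  ref_idx <- seq_to_index(reference)
  reads <- reads[reads$mapq >= min_mapq, ]
  lens <- nchar(reads$seq) - 2L * end_trim
  keep <- lens >= 1L
  reads <- reads[keep, ]
  lens <- lens[keep]
  if (nrow(reads) == 0) abort("no usable reads after filtering")

  trimmed <- substr(reads$seq, end_trim + 1L, end_trim + lens)
  starts <- reads$pos + end_trim
  gpos <- sequence(lens) - 1L + rep(starts, lens)
  obs_idx <- .base_byte_index[as.integer(charToRaw(paste(trimmed, collapse = ""))) + 1L]
  true_idx <- ref_idx[gpos]

  included <- rep(TRUE, L)
  included[excluded_sites[excluded_sites >= 1 & excluded_sites <= L]] <- FALSE

  # per-site base counts, to spot multi-allelic (likely variant) sites
  site_counts <- matrix(tabulate((gpos - 1L) * 4L + obs_idx, nbins = 4L * L),
                        nrow = L, ncol = 4, byrow = TRUE)
  nonref <- site_counts
  nonref[cbind(seq_len(L), ref_idx)] <- 0L
  multi <- rowSums(nonref >= 2L) >= 2L
  included[multi] <- FALSE

  use <- included[gpos]
  if (!any(use)) abort("no usable sites: everything is excluded")

  qbin <- vapply(reads$base_qual, function(q) quality_bin_index(
    list(bins = quality_bins), q), integer(1))
  bin_of_base <- rep(qbin, lens)

  matrices <- vector("list", nrow(quality_bins))
  for (b in seq_len(nrow(quality_bins))) {
    sel <- use & bin_of_base == b
    tab <- matrix(tabulate((true_idx[sel] - 1L) * 4L + obs_idx[sel], nbins = 16L),
                  nrow = 4, ncol = 4, byrow = TRUE,
                  dimnames = list(DNA_BASES, DNA_BASES))
    tab <- tab + pseudocount
    matrices[[b]] <- tab / rowSums(tab)
  }
  new_confusion_matrix(matrices, quality_bins, sample_id,
                       site_count = sum(included & tabulate(gpos, L) > 0),
                       pseudocount = pseudocount)
}

#' Look up a substitution-error probability
#'
#' Returns P(observed base | true base) from the quality bin containing
#' `quality`.
#'
#' @param cm A `"confusion_matrix"`.
#' @param true_base,observed_base Single bases in A/C/G/T.
#' @param quality Phred base quality; must fall inside a configured bin.
#' @return A probability.
#' @export
error_rate <- function(cm, true_base, observed_base, quality) {
  assert_bases(c(true_base, observed_base))
  cm$matrices[[quality_bin_index(cm, quality)]][true_base, observed_base]
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> sample '%s', %d quality bin(s), %d sites, pseudocount %g\n",
              x$sample_id, length(x$matrices), x$site_count, x$pseudocount))
  for (b in seq_along(x$matrices)) {
    cat(sprintf("  Q[%g, %g]:\n", x$bins$lo[b], x$bins$hi[b]))
    print(round(x$matrices[[b]], 5))
  }
  invisible(x)
}

#' Tidy a confusion matrix into a long tibble
#'
#' @param x A `"confusion_matrix"`.
#' @param ... Unused.
#' @return Tibble with columns `bin_lo`, `bin_hi`, `true_base`,
#'   `observed_base`, `probability`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  purrr::map_dfr(seq_along(x$matrices), function(b) {
    M <- x$matrices[[b]]
    tidyr::crossing(true_base = DNA_BASES, observed_base = DNA_BASES) |>
      mutate(bin_lo = x$bins$lo[b], bin_hi = x$bins$hi[b],
             probability = M[cbind(.data$true_base, .data$observed_base)]) |>
      select("bin_lo", "bin_hi", "true_base", "observed_base", "probability")
  })
}
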