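#' Pileup base counts from ungapped alignments
#'
#' Computes, for every reference position, the total read depth plus
#' high-quality counts of each observed base. "High quality" means mapping
#' quality at least `min_mapq`, read base quality at least
#' `min_base_quality`, and more than `end_trim` bases from either read end —
#' the same read filters used throughout the caller. Alignments are assumed
#' ungapped (match-only), which holds for the simulator's reads and for the
#' SNV-only scope of this package.
#'
#' @param reads Tibble of aligned reads (`pos`, `seq`, `mapq`, `base_qual`).
#' @param reference Reference sequence string.
#' @param min_base_quality,min_mapq,end_trim High-quality read/base filters.
#' @return Tibble with columns `pos`, `ref`, `depth` (total coverage, no
#'   filters), `n_hq` (high-quality depth) and high-quality counts `A`, `C`,
#'   `G`, `T`.
#' @export
pileup_counts <- function(reads, reference, min_base_quality = 20,
                          min_mapq = 20, end_trim = 5) {
  L <- nchar(reference)
  refv <- strsplit(reference, "", fixed = TRUE)[[1]]
  lens_all <- nchar(reads$seq)
  depth <- as.integer(IRanges::coverage(
    IRanges::IRanges(start = reads$pos, width = lens_all), width = L))

  hq <- reads[reads$mapq >= min_mapq & reads$base_qual >= min_base_quality, ]
  counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, DNA_BASES))
  if (nrow(hq) > 0) {
    lens <- nchar(hq$seq) - 2L * end_trim
    keep <- lens >= 1L
    hq <- hq[keep, ]
    lens <- lens[keep]
    if (nrow(hq) > 0) {
      trimmed <- substr(hq$seq, end_trim + 1L, end_trim + lens)
      gpos <- sequence(lens) - 1L + rep(hq$pos + end_trim, lens)
      obs <- .base_byte_index[as.integer(charToRaw(paste(trimmed, collapse = ""))) + 1L]
      counts <- matrix(tabulate((gpos - 1L) * 4L + obs, nbins = 4L * L),
                       nrow = L, ncol = 4, byrow = TRUE,
                       dimnames = list(NULL, DNA_BASES))
    }
  }
  tibble(pos = seq_len(L), ref = refv, depth = depth,
         n_hq = as.integer(rowSums(counts)),
         A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4])
}

#' Scan a pileup for candidate somatic SNVs
#'
#' A position becomes a candidate when at least `min_alt` high-quality reads
#' carry a single non-genomic base (a base absent from the germline genotype
#' at that position) and the total depth lies within `coverage_bounds` times
#' the genome-wide median depth. Positions with anomalous coverage are never
#' emitted, whatever their alt count; they are recorded in the `"ignored"`
#' attribute of the result. At multi-allelic sites only the non-genomic base
#' with the highest count is considered (ties resolve in A<C<G<T order) and a
#' `multiallelic` filter label is attached when a second non-genomic base also
#' reaches `min_alt`.
#'
#' @param pileup A [pileup_counts()] tibble.
#' @param germline_genotypes Tibble of heterozygous germline sites (`pos`,
#'   `ref`, `alt`); positions absent from it are treated as homozygous
#'   reference.
#' @param min_alt Minimum high-quality non-genomic read count (default 3).
#' @param coverage_bounds Multiples of the median depth accepted as normal
#'   coverage, default `c(0.25, 2)`.
#' @return Tibble of candidates: `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `n_hq`, `k` (high-quality alt count), `vaf` (`k / n_hq`), `filter`.
#'   Attribute `"ignored"` holds positions suppressed by the coverage rule;
#'   attribute `"median_depth"` the median used.
#' @export
scan_candidates <- function(pileup, germline_genotypes = NULL, min_alt = 3,
                            coverage_bounds = c(0.25, 2)) {
  L <- nrow(pileup)
  counts <- as.matrix(pileup[, DNA_BASES])
  genomic <- matrix(FALSE, nrow = L, ncol = 4, dimnames = list(NULL, DNA_BASES))
  genomic[cbind(seq_len(L), match(pileup$ref, DNA_BASES))] <- TRUE
  if (!is.null(germline_genotypes) && nrow(germline_genotypes) > 0) {
    gg <- germline_genotypes[germline_genotypes$pos >= 1 &
                               germline_genotypes$pos <= L, ]
    if (any(pileup$ref[gg$pos] != gg$ref)) {
      abort("germline genotype reference bases disagree with the pileup")
    }
    genomic[cbind(gg$pos, match(gg$alt, DNA_BASES))] <- TRUE
  }
  nong <- counts
  nong[genomic] <- 0L

  # best (and second-best) non-genomic base per position, ties to A<C<G<T
  top_idx <- max.col(nong, ties.method = "first")
  k <- nong[cbind(seq_len(L), top_idx)]
  nong2 <- nong
  nong2[cbind(seq_len(L), top_idx)] <- 0L
  k2 <- nong2[cbind(seq_len(L), max.col(nong2, ties.method = "first"))]

  med <- stats::median(pileup$depth[pileup$depth > 0])
  in_bounds <- pileup$depth >= coverage_bounds[1] * med &
    pileup$depth <= coverage_bounds[2] * med

  hit <- k >= min_alt
  cand_rows <- which(hit & in_bounds)
  ignored_rows <- which(hit & !in_bounds)

  kk <- as.integer(k[cand_rows])
  nhq <- pileup$n_hq[cand_rows]
  out <- tibble(
    chrom = "ref1",
    pos = cand_rows,
    ref = pileup$ref[cand_rows],
    alt = DNA_BASES[top_idx[cand_rows]],
    depth = pileup$depth[cand_rows],
    n_hq = nhq,
    k = kk,
    vaf = ifelse(nhq > 0, kk / nhq, 0),
    filter = ifelse(k2[cand_rows] >= min_alt, "multiallelic", "PASS")
  )
  attr(out, "ignored") <- tibble(pos = ignored_rows,
                                 depth = pileup$depth[ignored_rows],
                                 k = as.integer(k[ignored_rows]))
  attr(out, "median_depth") <- med
  out
}

# exact upper binomial tail P(K >= k | n, e); vectorised
binom_upper_tail <- function(k, n, e) {
  p <- ifelse(k <= 0, 1, stats::pbinom(k - 1, n, e, lower.tail = FALSE))
  # e = 0 with k > 0 is an impossible observation under the null
  p[e == 0 & k > 0] <- 0
  p
}

#' Frequentist evidence for non-genomic alleles
#'
#' For each candidate, computes the exact upper binomial tail
#' `P(K >= k | n_hq, e)` where `e` is the confusion-matrix probability of
#' misreading the reference base as the alternate base in the candidates'
#' quality bin. The tail is an exact summation (via [stats::pbinom()]), not a
#' normal approximation. Candidates whose error rate sits below `e_floor` are
#' flagged `error_model_floor`: their p-values are dominated by the
#' pseudocount structure of the error model rather than by data.
#'
#' @param candidates A [scan_candidates()] tibble.
#' @param cm A `"confusion_matrix"` for the cfDNA sample.
#' @param quality Base quality at which to query the error model (the modal
#'   read quality; simulated reads are constant-quality).
#' @param e_floor Error-rate floor below which the flag is attached.
#' @return `candidates` with columns `e_ref_alt` and `p_freq` added.
#' @export
score_frequentist <- function(candidates, cm, quality = 30, e_floor = 1e-6) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, e_ref_alt = numeric(0), p_freq = numeric(0)))
  }
  e <- purrr::map2_dbl(candidates$ref, candidates$alt,
                       function(r, a) error_rate(cm, r, a, quality))
  out <- mutate(candidates, e_ref_alt = e,
                p_freq = binom_upper_tail(.data$k, .data$n_hq, e))
  floored <- e < e_floor
  out$filter <- ifelse(floored, paste_filters(out$filter, "error_model_floor"),
                       out$filter)
  out
}

# combine VCF-style filter labels ("PASS" is the empty element)
paste_filters <- function(existing, new) {
  ifelse(existing == "PASS", new, paste(existing, new, sep = ";"))
}

#' Bayesian scoring of candidate somatic SNVs
#'
#' Compares two per-read generative models at each candidate site. Under the
#' null, every high-quality read shows the alternate base with the sequencing
#' error probability `e_ra = P(alt | ref)`. Under the alternative, a somatic
#' allele at fraction `f` is present, so a read shows the alternate base with
#' probability `f * (1 - e_ar) + (1 - f) * e_ra` (a true alt read survives
#' unless misread back, a reference read appears alt by error); `f` is
#' marginalised uniformly over `f_grid`. The posterior combines the two
#' marginal likelihoods with the prior probability `prior_somatic` that a site
#' carries a somatic variant; `f_hat` is the grid argmax of the alternative
#' likelihood.
#'
#' @param candidates A [scan_candidates()] tibble.
#' @param cm A `"confusion_matrix"`.
#' @param prior_somatic Prior probability of a somatic SNV at a site; the
#'   default 1e-4 reflects a high-burden (melanoma-like) genome.
#' @param f_grid Somatic-fraction grid in (0, 1]; default 0.01 to 0.50 by
#'   0.01.
#' @param quality Base quality at which to query the error model.
#' @return `candidates` with columns `posterior` and `f_hat` added.
#' @export
score_bayesian <- function(candidates, cm, prior_somatic = 1e-4,
                           f_grid = seq(0.01, 0.5, by = 0.01), quality = 30) {
  if (length(f_grid) == 0) abort("f_grid must be non-empty")
  stopifnot(all(f_grid > 0), all(f_grid <= 1),
            prior_somatic > 0, prior_somatic < 1)
  if (nrow(candidates) == 0) {
    return(mutate(candidates, posterior = numeric(0), f_hat = numeric(0)))
  }
  res <- purrr::pmap_dfr(
    list(candidates$ref, candidates$alt, candidates$k, candidates$n_hq),
    function(r, a, k, n) {
      e_ra <- error_rate(cm, r, a, quality)
      e_ar <- error_rate(cm, a, r, quality)
      p1 <- f_grid * (1 - e_ar) + (1 - f_grid) * e_ra
      l1_grid <- stats::dbinom(k, n, p1)
      l1 <- mean(l1_grid)
      l0 <- stats::dbinom(k, n, e_ra)
      tibble(posterior = prior_somatic * l1 /
               (prior_somatic * l1 + (1 - prior_somatic) * l0),
             f_hat = f_grid[which.max(l1_grid)])
    })
  dplyr::bind_cols(candidates, res)
}

#' Score candidates with both statistics
#'
#' Convenience wrapper applying [score_frequentist()] then [score_bayesian()].
#'
#' @inheritParams score_frequentist
#' @inheritParams score_bayesian
#' @return Scored candidate tibble.
#' @export
score_candidates <- function(candidates, cm, quality = 30,
                             prior_somatic = 1e-4,
                             f_grid = seq(0.01, 0.5, by = 0.01)) {
  candidates |>
    score_frequentist(cm, quality = quality) |>
    score_bayesian(cm, prior_somatic = prior_somatic, f_grid = f_grid,
                   quality = quality)
}

#' Filter scored candidates into somatic calls
#'
#' A candidate is retained when its exact binomial p-value is at most `alpha`,
#' its posterior is at least `min_posterior`, and no blocking filter label is
#' already attached. Failing candidates are kept in the output with the
#' responsible filter labels recorded in `filter`; retained rows carry
#' `"PASS"`. The result is deterministic in the input.
#'
#' @param candidates A [score_candidates()] tibble.
#' @param alpha Per-site significance threshold for `p_freq` (default 1e-6).
#' @param min_posterior Minimum posterior probability (default 0.95).
#' @return The candidate tibble with updated `filter` and a logical `called`
#'   column; `dplyr::filter(x, called)` gives the call set.
#' @export
call_somatic <- function(candidates, alpha = 1e-6, min_posterior = 0.95) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, called = logical(0)))
  }
  out <- candidates
  fail_p <- out$p_freq > alpha
  fail_post <- out$posterior < min_posterior
  out$filter <- ifelse(fail_p, paste_filters(out$filter, "p_value"), out$filter)
  out$filter <- ifelse(fail_post, paste_filters(out$filter, "posterior"),
                       out$filter)
  out$called <- out$filter == "PASS"
  out
}

#' Call somatic SNVs in one cfDNA sample
#'
#' End-to-end stage 1: pileup, candidate scan against the germline genotype,
#' error-model scoring, and threshold filtering.
#'
#' @param reads Tibble of aligned cfDNA reads for one sample.
#' @param reference Reference sequence string.
#' @param germline_genotypes Tibble of heterozygous germline sites (`pos`,
#'   `ref`, `alt`).
#' @param cm A `"confusion_matrix"` for this sample.
#' @param min_alt,coverage_bounds Passed to [scan_candidates()].
#' @param alpha,min_posterior Passed to [call_somatic()].
#' @param prior_somatic,f_grid,quality Passed to the scoring functions.
#' @return Scored candidate tibble with `called` column.
#' @export
call_sample <- function(reads, reference, germline_genotypes, cm,
                        min_alt = 3, coverage_bounds = c(0.25, 2),
                        alpha = 1e-6, min_posterior = 0.95,
                        prior_somatic = 1e-4,
                        f_grid = seq(0.01, 0.5, by = 0.01), quality = 30) {
  pileup_counts(reads, reference) |>
    scan_candidates(germline_genotypes, min_alt = min_alt,
                    coverage_bounds = coverage_bounds) |>
    score_candidates(cm, quality = quality, prior_somatic = prior_somatic,
                     f_grid = f_grid) |>
    call_somatic(alpha = alpha, min_posterior = min_posterior)
}
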