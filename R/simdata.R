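#' The 96 trinucleotide substitution classes
#'
#' Classes follow the pyrimidine convention used for mutational-signature
#' analysis: every SNV is represented on the strand where the mutated base is
#' C or T, giving 6 substitution types x 16 flanking contexts. Ordering is the
#' conventional one (types C>A, C>G, C>T, T>A, T>C, T>G; within a type the 5'
#' then 3' base cycle through A, C, G, T).
#'
#' @return Character vector of length 96 with labels such as `"T[C>T]A"`.
#' @export
signature_classes <- function() {
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (ty in types) {
    ref <- substr(ty, 1, 1)
    for (p5 in DNA_BASES) {
      for (p3 in DNA_BASES) {
        out <- c(out, sprintf("%s[%s]%s", p5, ty, p3))
      }
    }
  }
  out
}

#' UV-dominated signature weights
#'
#' Default somatic substitution-class probabilities emulating the ultraviolet
#' damage signature of cutaneous melanoma: a fixed total mass on C>T
#' transitions (default 0.8), concentrated at dipyrimidine contexts (5'
#' pyrimidine contexts receive three times the weight of 5' purine contexts,
#' reflecting the pyrimidine-dimer mechanism), with the remaining mass uniform
#' over all other classes.
#'
#' @param ct_mass Total probability assigned to the 16 C>T classes.
#' @return Named numeric vector over [signature_classes()], summing to 1.
#' @export
#' @examples
#' w <- uv_signature_weights()
#' sum(w[grepl("C>T", names(w))])
uv_signature_weights <- function(ct_mass = 0.8) {
  stopifnot(ct_mass > 0, ct_mass < 1)
  cls <- signature_classes()
  w <- numeric(96)
  names(w) <- cls
  is_ct <- grepl("C>T", cls, fixed = TRUE)
  p5 <- substr(cls, 1, 1)
  rel <- ifelse(p5 %in% c("C", "T"), 3, 1)
  w[is_ct] <- ct_mass * rel[is_ct] / sum(rel[is_ct])
  w[!is_ct] <- (1 - ct_mass) / sum(!is_ct)
  w
}

#' Default subclone dynamics for the relapse-monitoring scenario
#'
#' Tumour-fraction trajectories for two subclones over ten sampling days
#' spanning a course of targeted therapy followed by immunotherapy:
#' subclone A (driver-bearing) sits at fraction 0.10 before treatment, is
#' suppressed to 0 while therapy is effective, re-emerges at 0.02 on day 119
#' and rises linearly to 0.16 at day 343; subclone B follows the same shape
#' scaled by 0.7 but declines after day 280 (halved by day 343). The scenario
#' carries a fixed radiological-progression date of day 207, so molecular
#' re-emergence precedes imaging by 88 days.
#'
#' @return Tibble with columns `day`, `A`, `B` (tumour fraction per subclone)
#'   and attribute `imaging_day` (207).
#' @export
default_subclone_dynamics <- function() {
  days <- c(-7L, 0L, 17L, 42L, 70L, 100L, 119L, 150L, 280L, 343L)
  a_of <- function(d) {
    if (d <= 0) return(0.10)
    if (d < 119) return(0)
    0.02 + (0.16 - 0.02) * (d - 119) / (343 - 119)
  }
  a <- vapply(days, a_of, numeric(1))
  b <- 0.7 * a
  # relapse decline of the second subclone after day 280
  b[days == 343] <- 0.5 * b[days == 280]
  out <- tibble(day = days, A = a, B = b)
  attr(out, "imaging_day") <- 207L
  out
}

#' Simulation configuration
#'
#' Bundles every parameter of the cfDNA simulator. Defaults encode the study
#' conditions the rest of the package assumes: a 200 kb reference at 41% GC,
#' heterozygous germline variants at 1e-3 per base, 600 somatic SNVs drawn
#' under a UV-dominated signature, fragment lengths modal at 167 bp with 10 bp
#' nucleosome periodicity, 100x cfDNA / 34x germline coverage, and a uniform
#' 0.1% substitution-error process (Q30-scale). The single `seed` fully
#' determines all outputs; stage-specific sub-streams are derived from it by
#' fixed offsets.
#'
#' @param reference_length Reference length in bases.
#' @param gc_fraction Expected G+C fraction of the simulated reference.
#' @param germline_het_rate Per-base probability of a heterozygous germline SNV.
#' @param somatic_count Number of somatic SNVs to plant.
#' @param signature_weights Named probability vector over the 96 substitution
#'   classes used to draw somatic variants; must sum to 1.
#' @param clone_weights Named probabilities assigning each somatic variant to a
#'   clone: `"AB"` (truncal, carried by both subclones), `"A"`, or `"B"`.
#'   Melanoma burdens are predominantly truncal, hence the 0.7/0.15/0.15 split.
#' @param subclone_dynamics Tibble of per-day tumour fractions for subclones A
#'   and B (see [default_subclone_dynamics()]).
#' @param tracked_per_subclone Number of variants per subclone followed by
#'   [simulate_timecourse()].
#' @param mean_depth Mean fold-coverage of each cfDNA sample.
#' @param germline_depth Mean fold-coverage of the germline sample.
#' @param tumor_depth,tumor_purity Coverage and tumour-cell fraction of the
#'   simulated tumour-biopsy sample.
#' @param fragment_mode,fragment_sd Mode and spread (bases) of the underlying
#'   fragment-length distribution before periodic modulation.
#' @param periodicity,periodicity_amplitude Period (bases) and relative
#'   amplitude of the cosine modulation producing sub-peaks below the mode.
#' @param min_fragment Smallest fragment length emitted.
#' @param panel_depth Read depth used when converting expected trajectories to
#'   amplicon-panel-like counts.
#' @param error_matrix A [confusion_matrix] describing the substitution-error
#'   process injected into reads.
#' @param base_quality,mapping_quality Constant Phred base quality and mapping
#'   quality attached to simulated reads.
#' @param seed Integer master seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(reference_length = 200000,
                       gc_fraction = 0.41,
                       germline_het_rate = 1e-3,
                       somatic_count = 600,
                       signature_weights = uv_signature_weights(),
                       clone_weights = c(AB = 0.7, A = 0.15, B = 0.15),
                       subclone_dynamics = default_subclone_dynamics(),
                       tracked_per_subclone = 20,
                       mean_depth = 100,
                       germline_depth = 34,
                       tumor_depth = 40,
                       tumor_purity = 0.8,
                       fragment_mode = 167,
                       fragment_sd = 25,
                       periodicity = 10,
                       periodicity_amplitude = 0.3,
                       min_fragment = 30,
                       panel_depth = 3000,
                       error_matrix = uniform_confusion_matrix(0.001),
                       base_quality = 30,
                       mapping_quality = 60,
                       seed = 11) {
  stopifnot(reference_length >= 1, gc_fraction > 0, gc_fraction < 1,
            germline_het_rate >= 0, somatic_count >= 0,
            fragment_mode > 0, fragment_sd > 0, periodicity > 0,
            periodicity_amplitude >= 0, periodicity_amplitude < 1,
            mean_depth > 0)
  if (!setequal(names(signature_weights), signature_classes())) {
    abort("signature_weights must be named by the 96 substitution classes")
  }
  if (abs(sum(signature_weights) - 1) > 1e-8) {
    abort("signature_weights must sum to 1")
  }
  frac <- subclone_dynamics$A + subclone_dynamics$B
  if (any(frac > 1 + 1e-12) || any(subclone_dynamics$A < 0) ||
      any(subclone_dynamics$B < 0)) {
    abort("subclone tumour fractions must lie in [0, 1] and sum to <= 1 at every timepoint")
  }
  structure(list(
    reference_length = as.integer(reference_length),
    gc_fraction = gc_fraction,
    germline_het_rate = germline_het_rate,
    somatic_count = as.integer(somatic_count),
    signature_weights = signature_weights[signature_classes()],
    clone_weights = clone_weights / sum(clone_weights),
    subclone_dynamics = subclone_dynamics,
    tracked_per_subclone = as.integer(tracked_per_subclone),
    mean_depth = mean_depth,
    germline_depth = germline_depth,
    tumor_depth = tumor_depth,
    tumor_purity = tumor_purity,
    fragment_mode = fragment_mode,
    fragment_sd = fragment_sd,
    periodicity = periodicity,
    periodicity_amplitude = periodicity_amplitude,
    min_fragment = as.integer(min_fragment),
    panel_depth = as.integer(panel_depth),
    error_matrix = error_matrix,
    base_quality = as.integer(base_quality),
    mapping_quality = as.integer(mapping_quality),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  reference: %d bp, GC %.2f | germline het rate %.2g | %d somatic SNVs\n",
              x$reference_length, x$gc_fraction, x$germline_het_rate, x$somatic_count))
  cat(sprintf("  fragments: mode %g bp, sd %g, period %g (amplitude %.2f)\n",
              x$fragment_mode, x$fragment_sd, x$periodicity, x$periodicity_amplitude))
  cat(sprintf("  depth: cfDNA %gx, germline %gx, tumour %gx (purity %.2f) | seed %d\n",
              x$mean_depth, x$germline_depth, x$tumor_depth, x$tumor_purity, x$seed))
  invisible(x)
}

#' Simulate a random reference sequence
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = `gc`/2, so the realised G+C
#' fraction converges to `gc`.
#'
#' @param length Sequence length in bases (>= 1).
#' @param gc Target G+C fraction, in (0, 1).
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return A single character string over A/C/G/T.
#' @export
#' @examples
#' r <- simulate_reference(1000, 0.41, seed = 7)
#' nchar(r)
simulate_reference <- function(length, gc, seed) {
  if (length < 1) abort("reference length must be positive")
  stopifnot(gc > 0, gc < 1)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  withr::with_seed(as.integer(seed), {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = "")
  })
}

# discrete fragment-length distribution: truncated-normal backbone centred at
# the mode, multiplicatively modulated by a cosine of the given period so that
# sub-peaks appear at mode - period, mode - 2*period, ...
fragment_length_weights <- function(config) {
  grid <- seq.int(config$min_fragment,
                  ceiling(config$fragment_mode + 8 * config$fragment_sd))
  w <- stats::dnorm(grid, mean = config$fragment_mode, sd = config$fragment_sd) *
    (1 + config$periodicity_amplitude *
       cos(2 * pi * (grid - config$fragment_mode) / config$periodicity))
  w[w < 0] <- 0
  tibble(length = grid, weight = w / sum(w))
}

# draw from the fragment-length distribution using the current RNG state
draw_fragment_lengths <- function(n, config) {
  if (n == 0) return(integer(0))
  fl <- fragment_length_weights(config)
  sample(fl$length, n, replace = TRUE, prob = fl$weight)
}

#' Sample cfDNA fragment lengths
#'
#' Draws fragment lengths from the simulator's nucleosome-footprint model: a
#' discretised normal centred on `fragment_mode` (default 167 bp, the
#' canonical cfDNA mode) multiplied by `1 + amplitude * cos(2*pi*(L - mode) /
#' period)`, renormalised, so that sub-modal peaks appear every `periodicity`
#' bases (default 10 bp) below the mode. No length below `min_fragment`
#' (default 30 bp) is emitted.
#'
#' @param n Number of lengths to draw (>= 0).
#' @param config A [sim_config()].
#' @param seed Seed for this draw; defaults to a fixed sub-stream of
#'   `config$seed`.
#' @return Integer vector of `n` fragment lengths.
#' @export
#' @examples
#' len <- sample_fragment_lengths(5000, sim_config())
#' which.max(tabulate(len))  # modal length
sample_fragment_lengths <- function(n, config = sim_config(),
                                    seed = sub_seed(config$seed, 101)) {
  if (n < 0) abort("n must be non-negative")
  withr::with_seed(as.integer(seed), draw_fragment_lengths(n, config))
}

#' Summarise the modal structure of a fragment-length sample
#'
#' Builds an integer histogram of fragment lengths, reports the modal length,
#' and locates the sub-modal peaks that give cfDNA its nucleosome fingerprint:
#' after 3-bin moving-average smoothing, local maxima below the global mode
#' (with smoothed counts above `floor_frac` of the maximum, suppressing
#' sparse-tail noise) are identified and the median spacing between
#' consecutive peaks is reported.
#'
#' @param lengths Integer vector of fragment lengths.
#' @param floor_frac Minimum smoothed count, as a fraction of the histogram
#'   maximum, for a sub-peak to be counted.
#' @return List with `mode` (modal length), `peaks` (sub-modal peak
#'   positions) and `peak_spacing` (median distance between consecutive
#'   sub-peaks, `NA` when fewer than two).
#' @export
#' @examples
#' len <- sample_fragment_lengths(50000, sim_config())
#' fragment_length_modes(len)$mode
fragment_length_modes <- function(lengths, floor_frac = 0.01) {
  h <- tabulate(lengths, nbins = max(lengths))
  mode_len <- which.max(h)
  sm <- as.numeric(stats::filter(h, rep(1 / 3, 3)))
  sm[is.na(sm)] <- 0
  pk <- which(diff(sign(diff(sm))) == -2) + 1L
  pk <- pk[pk < mode_len & sm[pk] > floor_frac * max(sm)]
  list(mode = mode_len, peaks = pk,
       peak_spacing = if (length(pk) >= 2) stats::median(diff(pk)) else NA_real_)
}

#' Plant germline and somatic variants into a reference
#'
#' Heterozygous germline SNVs are placed uniformly at `germline_het_rate` per
#' base. Somatic SNVs are drawn with trinucleotide-context probabilities
#' proportional to `signature_weights`: class counts come from a multinomial
#' draw, and each event is placed uniformly among reference positions whose
#' pyrimidine-strand context matches the class (positions already used, or
#' holding a germline het, are excluded, keeping the two truth sets disjoint).
#' Each somatic variant is assigned to a clone (`AB` truncal, `A`, or `B`)
#' with probabilities `clone_weights`.
#'
#' @param reference Reference sequence (character scalar).
#' @param config A [sim_config()].
#' @return A list of class `"truth_set"` with tibbles `germline`
#'   (`pos`, `ref`, `alt`) and `somatic` (`pos`, `ref`, `alt`, `clone`,
#'   `class96`), plus `reference_length`.
#' @export
plant_variants <- function(reference, config = sim_config()) {
  L <- nchar(reference)
  refv <- strsplit(reference, "", fixed = TRUE)[[1]]
  withr::with_seed(sub_seed(config$seed, 202), {
    # interior positions only: trinucleotide context must exist
    interior <- 2:(L - 1)
    het_pos <- interior[stats::runif(length(interior)) < config$germline_het_rate]
    het_ref <- refv[het_pos]
    het_alt <- vapply(het_ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                      character(1), USE.NAMES = FALSE)

    somatic <- tibble(pos = integer(0), ref = character(0), alt = character(0),
                      clone = character(0), class96 = character(0))
    if (config$somatic_count > 0) {
      ctx <- paste0(refv[interior - 1L], refv[interior], refv[interior + 1L])
      centre_pyr <- refv[interior] %in% c("C", "T")
      pyr_ctx <- ifelse(centre_pyr, ctx, revcomp(ctx))
      cls <- signature_classes()
      cls_ctx <- paste0(substr(cls, 1, 1), substr(cls, 3, 3), substr(cls, 7, 7))
      counts <- as.vector(stats::rmultinom(1, config$somatic_count,
                                           config$signature_weights))
      used <- rep(FALSE, length(interior))
      used[match(het_pos, interior)] <- TRUE
      pos_by_ctx <- split(seq_along(interior), pyr_ctx)
      rows <- vector("list", length(cls))
      for (i in seq_along(cls)) {
        m <- counts[i]
        if (m == 0) next
        cand <- pos_by_ctx[[cls_ctx[i]]]
        cand <- cand[!used[cand]]
        if (length(cand) < m) {
          abort(sprintf("not enough eligible '%s' contexts (%d needed, %d available)",
                        cls[i], m, length(cand)))
        }
        pick <- if (length(cand) == 1) cand else sample(cand, m)
        used[pick] <- TRUE
        alt_pyr <- substr(cls[i], 5, 5)
        p <- interior[pick]
        is_pyr <- centre_pyr[pick]
        rows[[i]] <- tibble(
          pos = p,
          ref = refv[p],
          alt = ifelse(is_pyr, alt_pyr, complement_base(alt_pyr)),
          class96 = cls[i]
        )
      }
      somatic <- bind_rows(rows)
      somatic$clone <- sample(names(config$clone_weights), nrow(somatic),
                              replace = TRUE, prob = config$clone_weights)
      somatic <- arrange(somatic, .data$pos)[, c("pos", "ref", "alt", "clone", "class96")]
    }
    structure(list(
      germline = tibble(pos = het_pos, ref = het_ref, alt = het_alt),
      somatic = somatic,
      reference_length = L
    ), class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d germline hets, %d somatic SNVs over %d bp\n",
              nrow(x$germline), nrow(x$somatic), x$reference_length))
  invisible(x)
}

#' Expected somatic VAF per variant and sampling day
#'
#' For a heterozygous somatic event, expected VAF is half the summed tumour
#' fraction of the subclones that carry it (truncal variants are carried by
#' both A and B).
#'
#' @param truth A [plant_variants()] truth set.
#' @param config A [sim_config()] supplying `subclone_dynamics`.
#' @return Tibble with one row per variant x day: `pos`, `ref`, `alt`,
#'   `clone`, `day`, `expected_vaf`.
#' @export
expected_somatic_vaf <- function(truth, config = sim_config()) {
  dyn <- config$subclone_dynamics
  tidyr::crossing(truth$somatic[, c("pos", "ref", "alt", "clone")],
                  dyn) |>
    mutate(expected_vaf = 0.5 * dplyr::case_when(
      .data$clone == "AB" ~ .data$A + .data$B,
      .data$clone == "A" ~ .data$A,
      .data$clone == "B" ~ .data$B
    )) |>
    select("pos", "ref", "alt", "clone", "day", "expected_vaf")
}

# substitute `alt` into reads covering `pos` with per-read probability p;
# reads given as (starts, ends, seqs); returns modified seqs
.substitute_allele <- function(seqs, starts, ends, pos, alt, p) {
  hit <- which(starts <= pos & ends >= pos)
  if (length(hit) == 0) return(seqs)
  take <- hit[stats::runif(length(hit)) < p]
  for (i in take) {
    off <- pos - starts[i] + 1L
    substr(seqs[i], off, off) <- alt
  }
  seqs
}

# one sample's reads: place fragments, apply germline hets (per-fragment coin
# flip), somatic alleles at the supplied per-variant probabilities, then
# inject substitution errors per the confusion-matrix row of the true base.
.simulate_sample_reads <- function(reference, truth, config, depth,
                                   somatic_p, sample_label, day = NA_integer_) {
  L <- nchar(reference)
  mean_len <- with(fragment_length_weights(config), sum(length * weight))
  n_frag <- max(1L, as.integer(round(depth * L / mean_len)))
  lens <- draw_fragment_lengths(n_frag, config)
  lens <- pmin(lens, L)
  starts <- 1L + as.integer(floor(stats::runif(n_frag) * (L - lens + 1)))
  ends <- starts + lens - 1L
  seqs <- substring(reference, starts, ends)

  if (nrow(truth$germline) > 0) {
    for (j in seq_len(nrow(truth$germline))) {
      seqs <- .substitute_allele(seqs, starts, ends, truth$germline$pos[j],
                                 truth$germline$alt[j], 0.5)
    }
  }
  if (nrow(truth$somatic) > 0 && any(somatic_p > 0)) {
    for (j in which(somatic_p > 0)) {
      seqs <- .substitute_allele(seqs, starts, ends, truth$somatic$pos[j],
                                 truth$somatic$alt[j], somatic_p[j])
    }
  }

  # substitution errors: per-base probability 1 - diagonal of the confusion
  # row for the true base, replacement drawn from the off-diagonal entries
  bin <- quality_bin_index(config$error_matrix, config$base_quality)
  M <- config$error_matrix$matrices[[bin]]
  err_log <- tibble(read = integer(0), offset = integer(0),
                    true = character(0), observed = character(0))
  err_prob <- 1 - diag(M)
  if (any(err_prob > 0)) {
    big <- paste(seqs, collapse = "")
    bases <- .base_byte_index[as.integer(charToRaw(big)) + 1L]
    is_err <- stats::runif(length(bases)) < err_prob[bases]
    err_at <- which(is_err)
    if (length(err_at) > 0) {
      true_idx <- bases[err_at]
      new_idx <- integer(length(err_at))
      for (b in 1:4) {
        sel <- which(true_idx == b)
        if (length(sel) == 0) next
        off <- M[b, ]
        off[b] <- 0
        new_idx[sel] <- sample.int(4, length(sel), replace = TRUE, prob = off)
      }
      raw_big <- charToRaw(big)
      raw_big[err_at] <- charToRaw(paste(DNA_BASES[new_idx], collapse = ""))
      big <- rawToChar(raw_big)
      cum_end <- cumsum(lens)
      cum_start <- cum_end - lens + 1L
      rd <- findInterval(err_at, cum_start)
      err_log <- tibble(read = rd, offset = err_at - cum_start[rd] + 1L,
                        true = DNA_BASES[true_idx], observed = DNA_BASES[new_idx])
    }
    cum_end <- cumsum(lens)
    seqs <- substring(big, cum_end - lens + 1L, cum_end)
  }

  reads <- tibble(
    read_id = sprintf("%s_%06d", sample_label, seq_len(n_frag)),
    sample = sample_label,
    day = day,
    chrom = "ref1",
    pos = starts,
    end = ends,
    strand = sample(c("+", "-"), n_frag, replace = TRUE),
    mapq = config$mapping_quality,
    base_qual = config$base_quality,
    seq = seqs
  )
  err_log$sample <- rep(sample_label, nrow(err_log))
  list(reads = reads, error_log = err_log)
}

#' Generate aligned cfDNA, tumour and germline reads
#'
#' Fragments are placed uniformly on the reference with lengths from the
#' periodic fragment model and are emitted as single aligned records spanning
#' the whole fragment (cfDNA fragments are short enough that a sequenced pair
#' covers the full insert; no aligner is simulated). Germline heterozygous
#' alleles are drawn per fragment with probability 0.5, somatic alternate
#' alleles with probability equal to the variant's expected VAF at the
#' sample's day, and substitution errors are injected according to the
#' configured confusion matrix. Base and mapping qualities are constant.
#'
#' @param reference Reference sequence string.
#' @param truth A [plant_variants()] truth set.
#' @param config A [sim_config()].
#' @param cfdna_days Sampling days at which whole-genome cfDNA samples are
#'   generated (default: first and last day of the subclone dynamics).
#' @param samples Which samples to generate, any of `"cfdna"`, `"germline"`,
#'   `"tumor"`.
#' @return List of class `"sim_reads"`: `reads` (one tibble of aligned reads,
#'   columns `read_id`, `sample`, `day`, `chrom`, `pos`, `end`, `strand`,
#'   `mapq`, `base_qual`, `seq`) and `error_log` (injected sequencing errors:
#'   `read`, `offset`, `true`, `observed`, `sample`).
#' @export
generate_alignments <- function(reference, truth, config = sim_config(),
                                cfdna_days = NULL,
                                samples = c("cfdna", "germline", "tumor")) {
  if (config$mean_depth <= 0) abort("mean_depth must be positive")
  dyn <- config$subclone_dynamics
  if (is.null(cfdna_days)) cfdna_days <- range(dyn$day)
  if (!all(cfdna_days %in% dyn$day)) {
    abort("cfdna_days must be sampling days of the subclone dynamics")
  }
  ev <- expected_somatic_vaf(truth, config)
  withr::with_seed(sub_seed(config$seed, 303), {
    parts <- list()
    if ("germline" %in% samples) {
      parts$germline <- .simulate_sample_reads(
        reference, truth, config, config$germline_depth,
        somatic_p = rep(0, nrow(truth$somatic)), sample_label = "germline")
    }
    if ("tumor" %in% samples) {
      parts$tumor <- .simulate_sample_reads(
        reference, truth, config, config$tumor_depth,
        somatic_p = rep(0.5 * config$tumor_purity, nrow(truth$somatic)),
        sample_label = "tumor")
    }
    if ("cfdna" %in% samples) {
      for (d in cfdna_days) {
        p <- if (nrow(truth$somatic) > 0) {
          left_join(truth$somatic["pos"],
                    filter(ev, .data$day == d)[, c("pos", "expected_vaf")],
                    by = "pos")$expected_vaf
        } else numeric(0)
        lab <- sprintf("cfdna_d%d", d)
        parts[[lab]] <- .simulate_sample_reads(
          reference, truth, config, config$mean_depth, somatic_p = p,
          sample_label = lab, day = as.integer(d))
      }
    }
    structure(list(
      reads = bind_rows(lapply(parts, `[[`, "reads")),
      error_log = bind_rows(lapply(parts, `[[`, "error_log"))
    ), class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  s <- dplyr::count(x$reads, .data$sample)
  cat("<sim_reads>\n")
  for (i in seq_len(nrow(s))) cat(sprintf("  %s: %d reads\n", s$sample[i], s$n[i]))
  cat(sprintf("  injected errors: %d\n", nrow(x$error_log)))
  invisible(x)
}

#' Simulate an expected-VAF time course
#'
#' Builds the deterministic variant x timepoint expected-VAF table implied by
#' the configured subclone dynamics: `tracked_per_subclone` variants are
#' assigned to each of subclones A and B, and each variant's expected VAF at a
#' sampling day is half its subclone's tumour fraction on that day. The
#' default dynamics place the pre-treatment driver VAF at 5%, suppress it
#' during response, and return it at 8% by the final timepoint.
#'
#' @param config A [sim_config()].
#' @return Tibble of class `"timecourse"` with columns `variant`, `subclone`,
#'   `timepoint`, `day`, `expected_vaf`; attribute `imaging_day` carries the
#'   scenario's radiological progression date.
#' @export
#' @examples
#' tc <- simulate_timecourse(sim_config())
#' dplyr::filter(tc, timepoint == "t01", subclone == "A")$expected_vaf
simulate_timecourse <- function(config = sim_config()) {
  dyn <- config$subclone_dynamics
  if (nrow(dyn) < 1) abort("at least one timepoint required")
  if (any(dyn$A + dyn$B > 1 + 1e-12)) {
    abort("tumour fractions must not sum above 1 at any timepoint")
  }
  n <- config$tracked_per_subclone
  if (n < 1) abort("at least one tracked variant per subclone required")
  vars <- tibble(
    variant = sprintf("var_%s%02d", rep(c("A", "B"), each = n), rep(seq_len(n), 2)),
    subclone = rep(c("A", "B"), each = n)
  )
  tps <- tibble(timepoint = sprintf("t%02d", seq_len(nrow(dyn))), day = dyn$day,
                A = dyn$A, B = dyn$B)
  out <- tidyr::crossing(vars, tps) |>
    mutate(expected_vaf = 0.5 * ifelse(.data$subclone == "A", .data$A, .data$B)) |>
    select("variant", "subclone", "timepoint", "day", "expected_vaf") |>
    arrange(.data$variant, .data$day)
  attr(out, "imaging_day") <- attr(dyn, "imaging_day", exact = TRUE)
  class(out) <- c("timecourse", class(out))
  out
}

#' Convert a time course to per-timepoint read counts
#'
#' Turns expected VAF trajectories into panel-like alt/depth counts, either
#' deterministically (`alt = round(vaf * depth)`) or with binomial sampling
#' noise.
#'
#' @param tc A [simulate_timecourse()] tibble.
#' @param depth Read depth per variant per timepoint.
#' @param noise If `TRUE`, draw `alt ~ Binomial(depth, expected_vaf)`;
#'   otherwise round the expectation.
#' @param seed Seed used when `noise = TRUE`.
#' @return Tibble with columns `variant`, `timepoint`, `day`, `alt`, `depth`,
#'   ready for [build_vaf_matrix()].
#' @export
timecourse_counts <- function(tc, depth = 3000, noise = FALSE, seed = 1) {
  out <- tibble(variant = tc$variant, timepoint = tc$timepoint, day = tc$day,
                depth = as.integer(depth))
  if (noise) {
    out$alt <- withr::with_seed(as.integer(seed), {
      stats::rbinom(nrow(tc), out$depth, tc$expected_vaf)
    })
  } else {
    out$alt <- as.integer(round(tc$expected_vaf * out$depth))
  }
  out[, c("variant", "timepoint", "day", "alt", "depth")]
}

#' One-call desk-scale simulation
#'
#' Convenience wrapper running [simulate_reference()], [plant_variants()],
#' [generate_alignments()] and [simulate_timecourse()] from a single config.
#'
#' @param config A [sim_config()].
#' @param cfdna_days,samples Passed to [generate_alignments()].
#' @return List with `reference`, `truth`, `reads` (a `sim_reads` object) and
#'   `timecourse`.
#' @export
simulate_dataset <- function(config = sim_config(), cfdna_days = NULL,
                             samples = c("cfdna", "germline", "tumor")) {
  reference <- simulate_reference(config$reference_length, config$gc_fraction,
                                  seed = sub_seed(config$seed, 1))
  truth <- plant_variants(reference, config)
  reads <- generate_alignments(reference, truth, config,
                               cfdna_days = cfdna_days, samples = samples)
  list(reference = reference, truth = truth, reads = reads,
       timecourse = simulate_timecourse(config))
}
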