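#' Classify an SNV into its 96-context class
#'
#' Maps a reference trinucleotide and alternate base to the pyrimidine-
#' convention class label: when the central base is a purine, the triplet and
#' the alternate base are reverse-complemented first, so every substitution is
#' expressed with a C or T reference. Vectorised.
#'
#' @param ref_triplet Character vector of trinucleotides over A/C/G/T.
#' @param alt_base Alternate base(s), distinct from each triplet's centre.
#' @return Character vector of class labels such as `"T[C>T]A"`.
#' @export
#' @examples
#' classify_substitution("TCA", "T")  # "T[C>T]A"
#' classify_substitution("TGG", "A")  # "C[C>T]A" via reverse complement
classify_substitution <- function(ref_triplet, alt_base) {
  if (length(alt_base) == 1 && length(ref_triplet) > 1) {
    alt_base <- rep(alt_base, length(ref_triplet))
  }
  stopifnot(length(ref_triplet) == length(alt_base))
  if (any(nchar(ref_triplet) != 3)) abort("ref_triplet must be trinucleotides")
  bad <- grepl("[^ACGT]", ref_triplet) | !(alt_base %in% DNA_BASES)
  if (any(bad)) abort("ambiguous base in triplet or alternate")
  centre <- substr(ref_triplet, 2, 2)
  if (any(centre == alt_base)) {
    abort("alternate base equals the reference base at the centre")
  }
  purine <- centre %in% c("A", "G")
  trip <- ref_triplet
  alt <- alt_base
  if (any(purine)) {
    trip[purine] <- revcomp(ref_triplet[purine])
    alt[purine] <- complement_base(alt_base[purine])
  }
  sprintf("%s[%s>%s]%s", substr(trip, 1, 1), substr(trip, 2, 2), alt,
          substr(trip, 3, 3))
}

# pyrimidine-strand of a variant: "+" when the reference base is C/T
pyrimidine_strand <- function(ref_base) {
  ifelse(ref_base %in% c("C", "T"), "+", "-")
}

# strand category per variant given a gene annotation tibble
assign_strand <- function(pos, ref_base, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0) {
    return(rep("intergenic", length(pos)))
  }
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(start = pos, width = 1L),
    IRanges::IRanges(start = annotation$start, end = annotation$end))
  res <- rep("intergenic", length(pos))
  if (length(ov) > 0) {
    hit_strands <- split(annotation$strand[S4Vectors::subjectHits(ov)],
                         S4Vectors::queryHits(ov))
    pyr <- pyrimidine_strand(ref_base)
    for (q in names(hit_strands)) {
      qi <- as.integer(q)
      s <- unique(hit_strands[[q]])
      if (length(s) > 1) {
        res[qi] <- "ambiguous"
      } else if (s == pyr[qi]) {
        # pyrimidine on the coding (sense) strand: mutation sits on the
        # untranscribed strand
        res[qi] <- "untranscribed"
      } else {
        res[qi] <- "transcribed"
      }
    }
  }
  res
}

#' Build a 96-context mutation spectrum
#'
#' Classifies each SNV into one of the 96 trinucleotide classes using the
#' reference context, and — when a gene annotation is supplied — assigns a
#' transcriptional strand: a mutation whose pyrimidine lies on the coding
#' (sense) strand of the overlapping gene is counted as `untranscribed`, on
#' the template strand as `transcribed`; variants outside genes are
#' `intergenic` and variants under genes on both strands are `ambiguous`
#' (kept in the 96-class counts but excluded from strand-bias totals).
#'
#' @param variants Tibble of SNVs with columns `pos`, `ref`, `alt`.
#' @param reference Reference sequence string.
#' @param annotation Optional gene tibble (`start`, `end`, `strand` with
#'   values `"+"`/`"-"`).
#' @param sample_id Label stored on the spectrum.
#' @return A `"mutation_spectrum"` object: named `counts96` vector, tibble
#'   `stranded` (class x strand counts), `total`, `sample_id`.
#' @export
build_spectrum <- function(variants, reference, annotation = NULL,
                           sample_id = "sample") {
  cls <- signature_classes()
  counts <- stats::setNames(integer(96), cls)
  stranded <- tibble(class96 = character(0), strand = character(0),
                     n = integer(0))
  if (nrow(variants) > 0) {
    L <- nchar(reference)
    if (any(variants$pos < 2 | variants$pos > L - 1)) {
      abort("variant outside reference bounds (no trinucleotide context)")
    }
    trip <- substring(reference, variants$pos - 1L, variants$pos + 1L)
    centre <- substr(trip, 2, 2)
    if (any(centre != variants$ref)) {
      abort("variant ref base disagrees with the reference sequence")
    }
    lab <- classify_substitution(trip, variants$alt)
    tab <- table(factor(lab, levels = cls))
    counts <- stats::setNames(as.integer(tab), cls)
    strand <- assign_strand(variants$pos, variants$ref, annotation)
    stranded <- tibble(class96 = lab, strand = strand) |>
      dplyr::count(.data$class96, .data$strand, name = "n")
  }
  structure(list(sample_id = sample_id, counts96 = counts,
                 stranded = stranded, total = sum(counts)),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  ty <- spectrum_by_type(x)
  cat(sprintf("<mutation_spectrum> sample '%s', %d SNVs\n", x$sample_id, x$total))
  for (i in seq_len(nrow(ty))) {
    cat(sprintf("  %s: %5d (%.1f%%)\n", ty$type[i], ty$n[i],
                100 * ty$n[i] / max(1, x$total)))
  }
  invisible(x)
}

#' Tidy a mutation spectrum
#'
#' @param x A `"mutation_spectrum"`.
#' @param ... Unused.
#' @return Tibble with `class96`, `type`, `context`, `count`, `fraction`.
#' @export
tidy.mutation_spectrum <- function(x, ...) {
  cls <- names(x$counts96)
  tibble(class96 = cls,
         type = substr(cls, 3, 5),
         context = paste0(substr(cls, 1, 1), substr(cls, 3, 3), substr(cls, 7, 7)),
         count = as.integer(x$counts96),
         fraction = if (x$total > 0) x$counts96 / x$total else 0)
}

# counts collapsed to the 6 pyrimidine substitution types
spectrum_by_type <- function(x) {
  tidy.mutation_spectrum(x) |>
    group_by(.data$type) |>
    summarise(n = sum(.data$count), .groups = "drop")
}

#' Transcriptional strand bias per substitution type
#'
#' Aggregates the stranded spectrum counts to the six substitution types and
#' applies a two-sided exact binomial test of untranscribed versus
#' transcribed counts against 0.5. Types with no stranded observations return
#' p = 1.
#'
#' @param spectrum A `"mutation_spectrum"` built with a gene annotation.
#' @return Tibble with columns `type`, `untranscribed`, `transcribed`,
#'   `p_value`.
#' @export
strand_bias_test <- function(spectrum) {
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  st <- spectrum$stranded |>
    mutate(type = substr(.data$class96, 3, 5)) |>
    group_by(.data$type, .data$strand) |>
    summarise(n = sum(.data$n), .groups = "drop")
  get_n <- function(ty, s) {
    v <- st$n[st$type == ty & st$strand == s]
    if (length(v) == 0) 0L else v
  }
  purrr::map_dfr(types, function(ty) {
    u <- get_n(ty, "untranscribed")
    t2 <- get_n(ty, "transcribed")
    p <- if (u + t2 == 0) 1 else stats::binom.test(u, u + t2, 0.5)$p.value
    tibble(type = ty, untranscribed = u, transcribed = t2, p_value = p)
  })
}

#' Compare two mutation spectra type by type
#'
#' For each of the six substitution types, forms the 2x2 table of type count
#' versus remaining count in each spectrum, applies a two-sided Fisher exact
#' test, and corrects the six p-values with Benjamini-Hochberg. The relative
#' change is `(prop2 - prop1) / prop1`.
#'
#' @param s1,s2 `"mutation_spectrum"` objects with positive totals.
#' @return Tibble with `type`, `count_1`, `total_1`, `count_2`, `total_2`,
#'   `prop_1`, `prop_2`, `relative_change`, `p_value`, `q_value`.
#' @export
compare_spectra <- function(s1, s2) {
  if (s1$total == 0 || s2$total == 0) abort("cannot compare a zero-total spectrum")
  t1 <- spectrum_by_type(s1)
  t2 <- spectrum_by_type(s2)
  out <- tibble(type = t1$type, count_1 = t1$n, total_1 = s1$total,
                count_2 = t2$n, total_2 = s2$total) |>
    mutate(prop_1 = .data$count_1 / .data$total_1,
           prop_2 = .data$count_2 / .data$total_2,
           relative_change = (.data$prop_2 - .data$prop_1) / .data$prop_1,
           p_value = purrr::pmap_dbl(
             list(.data$count_1, .data$total_1, .data$count_2, .data$total_2),
             function(x1, n1, x2, n2) {
               stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2))$p.value
             }))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
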