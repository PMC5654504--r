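#' @importFrom rlang .data abort %||%
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows left_join distinct n
#' @importFrom tibble tibble as_tibble
NULL

# fixed base alphabet; all sequence code indexes into this order
DNA_BASES <- c("A", "C", "G", "T")

# raw-byte lookup: byte value -> base index (A=1, C=2, G=3, T=4), NA otherwise
.base_byte_index <- local({
  idx <- rep(NA_integer_, 256)
  idx[as.integer(charToRaw("A")) + 1L] <- 1L
  idx[as.integer(charToRaw("C")) + 1L] <- 2L
  idx[as.integer(charToRaw("G")) + 1L] <- 3L
  idx[as.integer(charToRaw("T")) + 1L] <- 4L
  idx
})

# vector of base indices for a single sequence string
seq_to_index <- function(x) {
  .base_byte_index[as.integer(charToRaw(x)) + 1L]
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors.
#'
#' @param x Character vector of DNA sequences over A/C/G/T.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTG"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# derive a reproducible sub-stream seed from a master seed and a fixed offset
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483629)
}

assert_bases <- function(x, what = "base") {
  bad <- !(x %in% DNA_BASES)
  if (any(bad)) {
    abort(sprintf("%s outside A/C/G/T alphabet: %s", what,
                  paste(utils::head(unique(x[bad]), 5), collapse = ", ")))
  }
  invisible(x)
}

# all k-mers of one sequence (character scalar); empty if too short
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1), k:n)
}

# canonical form: lexicographic min of a k-mer and its reverse complement
canonical_kmers <- function(kmers) {
  if (length(kmers) == 0) return(character(0))
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}
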