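#' Read and write FASTA references
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] exchanging plain named character vectors.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs) %||% sprintf("seq%d", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write simulated reads as SAM
#'
#' Serialises a read tibble to a coordinate-sorted single-end SAM file with
#' one read group per sample. Simulated reads are ungapped, so every record
#' carries a match-only CIGAR; base qualities are constant per read.
#'
#' @param reads Read tibble (`read_id`, `sample`, `chrom`, `pos`, `strand`,
#'   `mapq`, `base_qual`, `seq`).
#' @param path Output path (`.sam`).
#' @param ref_name,ref_len Reference sequence name and length for the header.
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, path, ref_name = "ref1", ref_len) {
  reads <- arrange(reads, .data$pos)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_len)),
              sprintf("@RG\tID:%s\tSM:%s", unique(reads$sample),
                      unique(reads$sample)))
  lens <- nchar(reads$seq)
  qual <- vapply(seq_len(nrow(reads)), function(i) {
    strrep(rawToChar(as.raw(reads$base_qual[i] + 33L)), lens[i])
  }, character(1))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tRG:Z:%s",
                  reads$read_id, ifelse(reads$strand == "-", 16L, 0L),
                  ref_name, reads$pos, reads$mapq, lens, reads$seq, qual,
                  reads$sample)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read alignments from SAM/BAM into the package's read tibble
#'
#' Uses [Rsamtools] to parse the file (SAM input is converted to BAM
#' on the fly). Only ungapped (match-only CIGAR) records are supported, the
#' package's SNV-only scope; others raise an error. Base quality is
#' summarised as the per-read minimum Phred score.
#'
#' @param path A `.sam` or `.bam` file.
#' @return Read tibble (`read_id`, `sample`, `chrom`, `pos`, `end`, `strand`,
#'   `mapq`, `base_qual`, `seq`).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "RG")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(x$pos) == 0) {
    return(tibble(read_id = character(0), sample = character(0),
                  chrom = character(0), pos = integer(0), end = integer(0),
                  strand = character(0), mapq = integer(0),
                  base_qual = integer(0), seq = character(0)))
  }
  if (any(!grepl("^[0-9]+M$", x$cigar))) {
    abort("only ungapped (match-only) alignments are supported")
  }
  seqs <- as.character(x$seq)
  quals <- as.character(x$qual)
  minq <- vapply(quals, function(q) {
    min(as.integer(charToRaw(q))) - 33L
  }, integer(1), USE.NAMES = FALSE)
  tibble(read_id = x$qname,
         sample = x$tag$RG %||% rep(NA_character_, length(x$qname)),
         chrom = as.character(x$rname),
         pos = x$pos,
         end = x$pos + nchar(seqs) - 1L,
         strand = ifelse(bitwAnd(x$flag, 16L) > 0, "-", "+"),
         mapq = x$mapq,
         base_qual = minq,
         seq = seqs)
}

#' Write somatic calls as VCF
#'
#' Serialises a candidate/call tibble to a minimal VCF 4.2 file (1-based
#' coordinates) with the caller's statistics in INFO (`K`, `DP`, `NHQ`,
#' `VAF`, `PF`, `POST`, `FHAT`, and the stage-2 `VERDICT` when present) and
#' filter labels in FILTER.
#'
#' @param calls Candidate tibble from [call_somatic()] or
#'   [verify_candidates()].
#' @param path Output path.
#' @param ref_name,ref_len Contig name and length for the header.
#' @return The path, invisibly.
#' @export
write_variants_vcf <- function(calls, path, ref_name = "ref1", ref_len = NA) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s%s>", ref_name,
            if (is.na(ref_len)) "" else sprintf(",length=%d", as.integer(ref_len))),
    "##INFO=<ID=K,Number=1,Type=Integer,Description=\"High-quality alternate read count\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=NHQ,Number=1,Type=Integer,Description=\"High-quality depth\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=PF,Number=1,Type=Float,Description=\"Exact binomial tail p-value\">",
    "##INFO=<ID=POST,Number=1,Type=Float,Description=\"Posterior probability of a somatic variant\">",
    "##INFO=<ID=FHAT,Number=1,Type=Float,Description=\"Grid estimate of the somatic fraction\">",
    "##INFO=<ID=VERDICT,Number=1,Type=String,Description=\"Haplotype verification verdict\">",
    "##FILTER=<ID=p_value,Description=\"Binomial tail above alpha\">",
    "##FILTER=<ID=posterior,Description=\"Posterior below threshold\">",
    "##FILTER=<ID=multiallelic,Description=\"Second non-genomic allele at the site\">",
    "##FILTER=<ID=error_model_floor,Description=\"Error rate below the model floor\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_num <- function(x) ifelse(is.na(x), ".", formatC(x, digits = 6, format = "g"))
  info <- sprintf("K=%d;DP=%d;NHQ=%d;VAF=%s;PF=%s;POST=%s;FHAT=%s",
                  calls$k, calls$depth, calls$n_hq, fmt_num(calls$vaf),
                  fmt_num(calls$p_freq %||% rep(NA_real_, nrow(calls))),
                  fmt_num(calls$posterior %||% rep(NA_real_, nrow(calls))),
                  fmt_num(calls$f_hat %||% rep(NA_real_, nrow(calls))))
  if (!is.null(calls$verdict)) {
    info <- paste0(info, ifelse(is.na(calls$verdict), "",
                                sprintf(";VERDICT=%s", calls$verdict)))
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt,
                  calls$filter, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variant calls from VCF
#'
#' Imports a VCF (such as one written by [write_variants_vcf()], or external
#' caller output) into the candidate-tibble shape via [vcfR].
#'
#' @param path VCF file path.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `filter` and any of
#'   `k`, `depth`, `n_hq`, `vaf`, `p_freq`, `posterior`, `f_hat`, `verdict`
#'   present in INFO.
#' @export
read_variant_calls <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexpr(sprintf("(?:^|;)%s=[^;]+", key), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(sprintf("(?:^|;)%s=", key), fix$INFO)
    out[hit] <- sub(sprintf("^;?%s=", key), "", m)
    out
  }
  tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
         alt = fix$ALT, filter = fix$FILTER,
         k = as.integer(info_field("K")),
         depth = as.integer(info_field("DP")),
         n_hq = as.integer(info_field("NHQ")),
         vaf = as.numeric(info_field("VAF")),
         p_freq = as.numeric(info_field("PF")),
         posterior = as.numeric(info_field("POST")),
         f_hat = as.numeric(info_field("FHAT")),
         verdict = info_field("VERDICT"))
}

#' Read a gene annotation for strand assignment
#'
#' Imports GFF/GTF or BED via [rtracklayer] and returns the minimal gene
#' tibble used by [build_spectrum()]. BED input is consumed 0-based
#' half-open and converted to 1-based inclusive coordinates.
#'
#' @param path Annotation file path (`.gff`, `.gff3`, `.gtf`, or `.bed`).
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `gene`.
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading annotations requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  nm <- if (!is.null(gr$gene_id)) gr$gene_id else if (!is.null(gr$name)) {
    gr$name
  } else sprintf("gene%d", seq_along(gr))
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)), gene = nm)
}
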