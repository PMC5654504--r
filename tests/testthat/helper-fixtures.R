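# Shared fixtures: constructed read sets and independent oracles.

# a read tibble from explicit (pos, seq) pairs with constant qualities
make_reads <- function(pos, seq, sample = "s", mapq = 60L, base_qual = 30L) {
  tibble::tibble(
    read_id = sprintf("%s_%04d", sample, seq_along(pos)),
    sample = sample, day = NA_integer_, chrom = "ref1",
    pos = as.integer(pos), end = as.integer(pos) + nchar(seq) - 1L,
    strand = "+", mapq = as.integer(mapq), base_qual = as.integer(base_qual),
    seq = seq
  )
}

# fragments copied verbatim from a source sequence laid out on the reference
# at `src_offset`; used to fake reads from a reference or from a paralog
fragments_from <- function(src, src_offset, n, lo, hi, len = 167L,
                           sample = "s") {
  starts <- sample(lo:(hi - len + 1L), n, replace = TRUE)
  make_reads(starts,
             substring(src, starts - src_offset + 1L, starts - src_offset + len),
             sample = sample)
}

# --- independent oracles (kept brute-force on purpose) ---

# upper binomial tail by direct summation over the support
oracle_binom_tail <- function(k, n, e) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(vapply(k:n, function(i) choose(n, i) * e^i * (1 - e)^(n - i), 0))
}

# two-sided Fisher exact p by hypergeometric enumeration of all tables with
# the same margins, summing probabilities not exceeding the observed one
oracle_fisher_p <- function(x1, n1, x2, n2) {
  m <- x1 + x2          # white balls: type counts
  nn <- (n1 - x1) + (n2 - x2)
  kk <- n1              # draws: sample-1 total
  support <- max(0, kk - nn):min(kk, m)
  probs <- stats::dhyper(support, m, nn, kk)
  obs <- stats::dhyper(x1, m, nn, kk)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-sided exact binomial p (equal-or-smaller point-probability rule)
oracle_binom_two_sided <- function(x, n, p = 0.5) {
  probs <- stats::dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, written out literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
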