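---
title: "Methods: somatic SNV calling and longitudinal monitoring in cfDNA WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic SNV calling and longitudinal monitoring in cfDNA WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftrace)
library(dplyr)
```

# The problem

Circulating tumour DNA (ctDNA) is a minority fraction of the cell-free DNA
(cfDNA) in plasma. In a patient with advanced cancer, whole-genome sequencing
of cfDNA at moderate depth (on the order of 100x) can reveal somatic single
nucleotide variants at variant allele frequencies (VAF) of roughly 5% and
above, and deep targeted re-sequencing of those positions can then track the
tumour's subclonal dynamics through treatment, often ahead of radiological
imaging. The difficulty is statistical: at 100x, a 5%-VAF variant is
supported by about five reads, uncomfortably close to what sequencing error
alone produces, and cfDNA alignments harbour systematic artefacts — notably
reads mis-assigned from paralogous sequence diverged from the reference —
that mimic low-frequency variants.

`cftrace` implements a two-stage caller built for this regime, together with
the downstream analyses that make the calls clinically interpretable:
96-context mutational signatures with transcriptional strand bias, and
longitudinal VAF tracking with subclone clustering and molecular-progression
detection. A seeded simulator generates cfDNA-like data with known truth so
that every stage is testable at desk scale.

# Stage 1: error-model-based candidate scoring

## Empirical confusion matrices

All calling statistics are conditioned on an empirically estimated
substitution-error model: a row-stochastic 4x4 matrix of
P(observed base | true base) per base-quality bin
(`estimate_confusion_matrix()`). The estimation protocol takes the reference
base as the truth proxy at sites that are plausibly invariant, which requires
three guards:

* sites listed as germline variants or somatic candidates are excluded by
  the caller (`excluded_sites`);
* sites where two or more distinct non-reference bases each appear in two or
  more reads are skipped — a single recurrent non-reference base is what a
  real variant looks like, and leaving such sites in would inflate the error
  estimate;
* reads below mapping quality 20, duplicate-like artefact-prone positions
  within 5 bp of read ends, are ignored (standard artefact suppression).

Rows are normalised with an additive pseudocount (default 1), and the
estimator refuses to normalise when no usable site remains: an
all-pseudocount "error model" would silently behave like a uniform matrix.
Default quality bins are 0–19, 20–29, 30+; the simulator emits constant Q30
reads, so in practice the top bin carries the data.

## Candidate scan

A position becomes a candidate when at least **three** high-quality reads
carry a single non-genomic base — a base absent from the germline genotype at
that position — and total coverage is unexceptional. "High quality" is pinned
as: base quality >= 20, mapping quality >= 20, more than 5 bp from the read
end. Coverage is deemed anomalous outside [0.25, 2.0] times the genome-wide
median; such positions are recorded but never emitted, whatever their alt
count, since both repeats (high coverage) and mapping deserts (low coverage)
generate unreliable pileups. At multi-allelic sites only the strongest
non-genomic base is scored and a `multiallelic` filter is attached when a
second base also reaches the floor; ties between equally supported bases
resolve in A<C<G<T order so results are deterministic.

## Two statistics per candidate

With `n` high-quality reads, `k` of them alt, and confusion-matrix entries
`e_ra = P(alt | ref)` and `e_ar = P(ref | alt)` from the candidate's quality
bin:

* **Exact binomial tail** (`score_frequentist()`):
  `p = P(K >= k | n, e_ra)`, summed exactly — no normal approximation. When
  `e_ra` is below a floor of 1e-6 the p-value degenerates (anything looks
  significant) and an `error_model_floor` flag is attached.
* **Bayesian posterior** (`score_bayesian()`): under H0 a read is alt with
  probability `e_ra`; under H1 a somatic allele at fraction `f` makes a read
  alt with probability `f (1 - e_ar) + (1 - f) e_ra`, and `f` is
  marginalised uniformly over a grid (default 0.01–0.50 by 0.01, covering
  subclonal fractions up to a heterozygous clonal variant in pure tumour).
  The posterior combines the marginal likelihoods with a prior somatic
  probability of 1e-4 per site, reflecting a high-burden, melanoma-like
  genome (tens of thousands of somatic SNVs in 3 Gb). `f_hat` is the grid
  argmax.

Calls require `p <= 1e-6` (per-site), posterior `>= 0.95`, and no blocking
filter. With a 0.1% error process the per-site threshold makes four alt
reads the effective floor; at 100x this places the detection limit at
roughly 5% VAF, which is the operating point the whole design targets —
variants below it are expected to be recovered later by deep targeted
re-sequencing, not by WGS.

# Stage 2: haplotype verification

Stage 1 is deliberately permissive about *why* reads carry a non-genomic
base. Stage 2 asks whether the candidate lives on a coherent local haplotype
that is present in the cfDNA and absent from the germline.

1. **Background haplotype** (`build_background_haplotype()`): a per-position
   majority consensus of the alt-supporting reads over a +-30 bp window,
   reference-filled where uncovered, centre forced to the alt. Ties resolve
   to the reference base. Phased germline hets riding on the somatic
   haplotype are intentionally captured.
2. **k-mer support** (`kmer_verify()`): the haplotype's 31-mers overlapping
   the variant (31 of them for an interior SNV) are canonicalised (a k-mer
   and its reverse complement are equivalent, making the statistic
   orientation-invariant) and support is counted at the *read* level — the
   number of reads containing at least one spanning k-mer — rather than by
   raw k-mer multiplicity, which would double-count overlapping k-mers
   within one fragment. Verification needs >= 3 supporting cfDNA reads
   (mirroring the candidate floor) and tolerates 0 germline reads by
   default; any germline support yields `germline_contaminated`.
3. **Assembly support** (`local_assemble()`): a de Bruijn graph over the
   window's read 31-mers with abundance >= 2 (singleton k-mers are treated
   as error noise). Contigs are maximal unbranched paths, reported in
   deterministic lexicographic order. A heterozygous background splits the
   graph into a bubble, so the *confirmation* criterion is that the
   haplotype is spelled by the abundance-filtered graph (every haplotype
   k-mer is an edge) rather than contained in a single unbranched contig —
   the latter is impossible across a bubble even for a perfectly real
   variant.
4. **Divergence guard**: reads mis-assigned from a paralog a few percent
   diverged from the reference produce candidates whose alt-supporting reads
   carry *multiple* clustered non-reference bases. The guard builds the
   consensus of the alt-supporting reads over their full span (~300 bp for
   167 bp fragments) and counts non-reference positions that are neither the
   candidate nor a known germline variant; more than one extra mismatch
   yields `assembly_artefact`. The wide span matters: at 3% divergence a
   61 bp window contains a second divergent site only ~84% of the time,
   while the full fragment span essentially always does.

# The simulator

The simulator is first-class, tested code; its defaults define the study
conditions the caller and tracker are validated under.

* **Reference**: i.i.d. bases at 41% GC, 200 kb by default — large enough
  for ~600 somatic events and a stable coverage median, small enough for
  test-suite turnaround. The test suite and examples use 20–200 kb
  references and 20x–1000x depths; these sizes are the package's desk-scale
  operating points.
* **Fragment lengths**: a discretised normal (mode 167 bp, sd 25 bp)
  multiplied by `1 + 0.3 cos(2*pi*(L - 167)/10)` and renormalised — two
  parameters reproduce both the canonical 167 bp cfDNA mode (the
  chromatosome footprint) and the 10 bp sub-peak periodicity left by
  nucleosome-protected cleavage. The sd and amplitude are pinned choices:
  published insert-size traces constrain the mode and periodicity tightly
  but not these two, and no attempt is made to infer them from data.
  `fragment_length_modes()` measures the structure back from a sample
  (3-bin smoothing, local maxima below the mode, median spacing); peak
  locations in the far tail jitter by +-1 base at 200,000 draws, so the
  spacing estimate occasionally lands at 9.5 rather than 10.
* **Variants**: germline hets uniformly at 1e-3 per base; somatic SNVs drawn
  by trinucleotide context in proportion to a UV-dominated signature — 80%
  of mass on C>T, concentrated 3:1 at 5'-pyrimidine (dipyrimidine) contexts,
  the photodimer mechanism's fingerprint. Each somatic variant belongs to a
  clone: truncal (`AB`, carried by both subclones, weight 0.7) or private to
  subclone A or B (0.15 each). The truncal majority reflects the
  predominantly early, UV-driven mutagenesis of cutaneous melanoma.
* **Reads**: fragments are placed uniformly and emitted as single aligned
  records spanning the whole fragment. With 167 bp fragments, a sequenced
  pair covers essentially the full insert, and no aligner is in scope, so
  paired-end bookkeeping would add complexity without exercising any code
  path differently. Germline het alleles are drawn per fragment at 0.5
  (sites are unphased and independent — adequate for consensus and k-mer
  tests, not a phasing model), somatic alleles at the variant's expected
  VAF, and substitution errors per the configured confusion matrix (default
  uniform 0.1%, the Q30 operating point). Base and mapping qualities are
  constant (Q30/60): quality modelling is not this package's contribution.
  An error log records every injected substitution, which is what lets the
  error-model tests compare estimates against injected truth.
* **Time course**: ten sampling days {-7, 0, 17, 42, 70, 100, 119, 150, 280,
  343} relative to treatment start. Subclone A holds tumour fraction 0.10
  pre-treatment (heterozygous VAF 5%), is suppressed to zero during
  response, re-emerges at 0.02 on day 119 and climbs linearly to 0.16
  (VAF 8%) at day 343; subclone B follows at 0.7x with a decline after day
  280 (halved by day 343 — the "decline" is otherwise unconstrained, and a
  factor of two is large enough to separate the clusters without zeroing
  the clone). The scenario's radiological progression date is fixed at day
  207, so the molecular call at day 119 leads imaging by 88 days.
* **Determinism**: one master seed; each stage draws from a sub-stream at a
  fixed offset, so regenerating any stage with the same config is
  byte-identical.

What the generator does **not** emulate: indels, structural variants and
copy number; GC- and mappability-driven coverage waves; FFPE deamination
damage; PCR duplicates; quality-score miscalibration; real repeat structure
(the reference is i.i.d., so genuine multi-mapping does not arise — the
divergence guard is instead exercised by explicitly mis-assigned paralog
reads). Passing tests therefore demonstrate correctness of the statistical
machinery under the stated error model, not robustness to every artefact of
production WGS.

# Signatures

`classify_substitution()` maps each SNV to the 96 pyrimidine-convention
classes; reverse-complement invariance is enforced by construction and
tested by exhaustive enumeration of all 288 (triplet, alt) inputs.
Transcriptional strand assignment follows the repair logic: a mutation whose
pyrimidine representation lies on the coding (sense) strand of the
overlapping gene is "untranscribed", on the template strand "transcribed";
variants under genes on both strands are "ambiguous" and excluded from
strand totals (but kept in the 96-class counts), variants outside genes are
"intergenic". Strand bias is a two-sided exact binomial test per collapsed
substitution type, and between-timepoint spectrum changes use a two-sided
Fisher exact test per type with Benjamini–Hochberg correction across the six
types — the granularity at which a treatment-driven depletion of one base
change (e.g. T>G, equivalently A.T>C.G) is the object of interest. The
comparison uses raw counts against totals; depth normalisation between
timepoints is deliberately not attempted, as both spectra are conditioned on
their own call sets.

# Tracking

`build_vaf_matrix()` assembles the union-of-variants VAF matrix with an
explicit detection rule: alt count >= 3 (the candidate floor again) and
VAF >= 0.002 at panel-like depth; undetected entries are stored as VAF 0
with depth retained, mirroring how amplicon assays report "not detectable"
rather than a noisy small number.

Subclone structure comes from agglomerative hierarchical clustering of the
variant rows (Euclidean distance, average linkage, cut at k = 2 by default
— the method is standard for this task, and the metric/linkage/cut are
pinned choices exposed as arguments). Rows are sorted lexicographically by
variant key before clustering, which makes the result invariant to input
order.

`detect_progression()` operationalises "re-emergence": a variant qualifies
at a timepoint when it is detected with VAF >= 0.01 after being undetected
at both of the two preceding timepoints, and progression is called at the
earliest day where at least 25% of tracked variants qualify together. The
defaults are intentionally loose-fitting: requiring two preceding undetected
timepoints rejects single-timepoint blips, the 1% rise threshold sits well
above panel noise at 3000x, and the 25% quorum requires a subclone-sized
group rather than one variant, without being tuned to any particular
dataset. The full rule trace is returned so a call can be audited.
`sample_similarity()` is Pearson correlation of per-variant VAFs between
samples, with pairs sharing fewer than two variants flagged undefined rather
than silently zeroed. `required_depth()` implements the planning identity
`X = kappa / (alpha * f)` for choosing coverage given a target mutation
frequency `f`, library efficiency `alpha`, and read-count scaling
efficiency `kappa`.

# Numerical and degenerate-input choices

* Binomial tails use exact summation (`pbinom`); oracle tests compare
  against literal term-by-term enumeration at 1e-12 tolerance.
* `e = 0` with `k > 0` returns p = 0 (an impossible observation under the
  null) plus the floor flag; `k = 0` returns p = 1.
* Zero-total spectra cannot be compared; zero-count strand classes give
  p = 1.
* Empty candidate sets, empty fragment draws (`n = 0`) and empty somatic
  truth sets flow through every stage as empty tibbles.
* Coordinates are 1-based inclusive everywhere user-facing (VCF
  convention); BED input is converted from 0-based half-open on read.

# A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- validate_config(list(
  seed = 7L,
  simulate = list(reference_length = 60000L, somatic_count = 120L,
                  mean_depth = 50, germline_depth = 20, tumor_depth = 0)))
manifest <- run_pipeline(cfg, out_dir = tempfile("cftrace_run"))
```

This writes the reference, per-sample SAM, truth tables, error-model JSON,
candidate and verified-call VCF/TSV per cfDNA timepoint, spectrum tables, the
VAF matrix, cluster assignments and the progression report, plus a manifest
of MD5 checksums; re-running with the same config yields identical checksums.

# Limitations

SNVs only — no indels, SVs, or copy number; single-sample calling per
timepoint (cross-timepoint evidence enters only at the tracking layer);
ungapped alignments are assumed by the pileup and consensus code;
confusion matrices are quality-binned but not context-stratified
(trinucleotide-dependent error, e.g. oxidation artefacts, would need the
context extension); and the tumour-biopsy sample is simulated as uniformly
clonal at a given purity, which is a simplification of real intratumour
heterogeneity.
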