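#' Assemble a variant-by-timepoint VAF matrix
#'
#' Takes per-timepoint observations (alt and total read counts per variant)
#' and builds the union-of-variants matrix the tracking layer works on. A
#' variant counts as detected at a timepoint when its alt count reaches
#' `min_alt` (mirroring the caller's 3-read candidate floor) and its raw VAF
#' reaches `min_vaf`; undetected entries store VAF 0 with the depth retained.
#' Variants absent from a timepoint's observations are kept as undetected
#' rows (union semantics).
#'
#' @param counts Tibble with columns `variant`, `timepoint`, `day`, `alt`,
#'   `depth` (one row per variant per timepoint observed).
#' @param min_alt Minimum alt reads for detection (default 3).
#' @param min_vaf Minimum VAF for detection (default 0.002).
#' @return A `"vaf_matrix"` object: matrices `vaf`, `detected`, `depth`
#'   (variants x timepoints), `variants` (lexicographically ordered keys) and
#'   `timepoints` (tibble `timepoint`, `day`, ordered by day).
#' @export
build_vaf_matrix <- function(counts, min_alt = 3, min_vaf = 0.002) {
  tp <- distinct(counts, .data$timepoint, .data$day) |> arrange(.data$day)
  if (anyDuplicated(tp$timepoint)) {
    abort("duplicate timepoint labels with conflicting days")
  }
  if (nrow(tp) < 1) abort("at least one timepoint required")
  vars <- sort(unique(counts$variant))
  nv <- length(vars)
  nt <- nrow(tp)
  vaf <- detected <- depth <- matrix(0, nv, nt,
                                     dimnames = list(vars, tp$timepoint))
  i <- match(counts$variant, vars)
  j <- match(counts$timepoint, tp$timepoint)
  depth[cbind(i, j)] <- counts$depth
  raw_vaf <- ifelse(counts$depth > 0, counts$alt / counts$depth, 0)
  det <- counts$alt >= min_alt & raw_vaf >= min_vaf
  detected[cbind(i, j)] <- det
  vaf[cbind(i, j)] <- ifelse(det, raw_vaf, 0)
  structure(list(vaf = vaf, detected = detected == 1, depth = depth,
                 variants = vars, timepoints = tp,
                 detection = list(min_alt = min_alt, min_vaf = min_vaf)),
            class = "vaf_matrix")
}

#' @export
print.vaf_matrix <- function(x, ...) {
  cat(sprintf("<vaf_matrix> %d variants x %d timepoints (days %s)\n",
              length(x$variants), nrow(x$timepoints),
              paste(x$timepoints$day, collapse = ", ")))
  invisible(x)
}

#' Tidy a VAF matrix into long form
#'
#' @param x A `"vaf_matrix"`.
#' @param ... Unused.
#' @return Tibble with `variant`, `timepoint`, `day`, `vaf`, `detected`,
#'   `depth`.
#' @export
tidy.vaf_matrix <- function(x, ...) {
  tidyr::crossing(variant = x$variants, timepoint = x$timepoints$timepoint) |>
    left_join(x$timepoints, by = "timepoint") |>
    mutate(vaf = x$vaf[cbind(.data$variant, .data$timepoint)],
           detected = x$detected[cbind(.data$variant, .data$timepoint)],
           depth = x$depth[cbind(.data$variant, .data$timepoint)]) |>
    arrange(.data$variant, .data$day)
}

#' Cluster variant trajectories into subclones
#'
#' Agglomerative hierarchical clustering of the variant rows of a VAF matrix.
#' Rows are taken in lexicographic variant order, making the result invariant
#' to input permutation. The dendrogram is cut either at a fixed number of
#' clusters `k` or at height `h`.
#'
#' @param vm A `"vaf_matrix"` with at least two variants and two timepoints.
#' @param metric Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param k Number of clusters to cut (default 2, the two major subclone
#'   groups typical of relapse dynamics); ignored when `h` is given.
#' @param h Optional cut height.
#' @return A `"subclone_clusters"` object: named `assignments`, the `hclust`
#'   merge record, and `n_clusters`.
#' @export
cluster_trajectories <- function(vm, metric = "euclidean",
                                 linkage = "average", k = 2, h = NULL) {
  if (length(vm$variants) < 2) abort("need at least 2 variants to cluster")
  if (nrow(vm$timepoints) < 2) abort("need at least 2 timepoints to cluster")
  d <- stats::dist(vm$vaf, method = metric)
  hc <- stats::hclust(d, method = linkage)
  assignments <- if (is.null(h)) {
    stats::cutree(hc, k = k)
  } else {
    stats::cutree(hc, h = h)
  }
  structure(list(assignments = assignments, hclust = hc,
                 n_clusters = length(unique(assignments)),
                 metric = metric, linkage = linkage),
            class = "subclone_clusters")
}

#' @export
print.subclone_clusters <- function(x, ...) {
  cat(sprintf("<subclone_clusters> %d variants in %d clusters (%s distance, %s linkage)\n",
              length(x$assignments), x$n_clusters, x$metric, x$linkage))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' @export
tidy.subclone_clusters <- function(x, ...) {
  tibble(variant = names(x$assignments), cluster = as.integer(x$assignments))
}

#' @export
glance.subclone_clusters <- function(x, ...) {
  tibble(n_variants = length(x$assignments), n_clusters = x$n_clusters,
         max_height = max(x$hclust$height), metric = x$metric,
         linkage = x$linkage)
}

#' Detect molecular progression from VAF trajectories
#'
#' Scans timepoints in chronological order for the re-emergence of tracked
#' variants: a variant qualifies at timepoint `j` when it is detected there
#' with VAF at least `rise_threshold` after being undetected at all of the
#' `r` immediately preceding timepoints. Progression is called at the
#' earliest sampling day where at least `min_frac` of the tracked variants
#' qualify. When an imaging (radiological progression) day is supplied, the
#' lead time `imaging_day - call_day` is reported.
#'
#' @param vm A `"vaf_matrix"`; its timepoint days must be strictly
#'   increasing.
#' @param driver_set Optional character vector restricting the tracked
#'   variants (default: all variants).
#' @param r Number of preceding undetected timepoints required (default 2).
#' @param rise_threshold Minimum VAF at re-emergence (default 0.01).
#' @param min_frac Fraction of tracked variants that must re-emerge together
#'   (default 0.25).
#' @param imaging_day Optional radiological progression day.
#' @return A `"progression_call"` object with `call_day` (or `NA`),
#'   `lead_time_days`, `imaging_day`, the per-timepoint `rule_trace`, and the
#'   rule parameters.
#' @export
detect_progression <- function(vm, driver_set = NULL, r = 2,
                               rise_threshold = 0.01, min_frac = 0.25,
                               imaging_day = NULL) {
  days <- vm$timepoints$day
  if (any(diff(days) <= 0)) abort("timepoint days must be strictly increasing")
  vars <- vm$variants
  if (!is.null(driver_set) && length(driver_set) > 0) {
    missing_v <- setdiff(driver_set, vars)
    if (length(missing_v) > 0) {
      abort(sprintf("driver_set variants not in matrix: %s",
                    paste(utils::head(missing_v, 3), collapse = ", ")))
    }
    vars <- intersect(vars, driver_set)
  }
  V <- vm$vaf[vars, , drop = FALSE]
  D <- vm$detected[vars, , drop = FALSE]
  nt <- length(days)
  trace <- tibble(timepoint = vm$timepoints$timepoint, day = days,
                  eligible = seq_len(nt) > r, n_new = 0L,
                  n_tracked = length(vars), frac = 0, triggered = FALSE)
  call_day <- NA_integer_
  for (j in seq_len(nt)) {
    if (j <= r) next
    prev_undetected <- rowSums(D[, (j - r):(j - 1), drop = FALSE]) == 0
    qual <- D[, j] & V[, j] >= rise_threshold & prev_undetected
    trace$n_new[j] <- sum(qual)
    trace$frac[j] <- sum(qual) / length(vars)
    if (is.na(call_day) && trace$frac[j] >= min_frac) {
      trace$triggered[j] <- TRUE
      call_day <- days[j]
    }
  }
  lead <- if (!is.na(call_day) && !is.null(imaging_day)) {
    as.integer(imaging_day) - call_day
  } else {
    NA_integer_
  }
  structure(list(call_day = call_day, lead_time_days = lead,
                 imaging_day = if (is.null(imaging_day)) NA_integer_ else as.integer(imaging_day),
                 rule_trace = trace,
                 params = list(r = r, rise_threshold = rise_threshold,
                               min_frac = min_frac)),
            class = "progression_call")
}

#' @export
print.progression_call <- function(x, ...) {
  if (is.na(x$call_day)) {
    cat("<progression_call> no molecular progression detected\n")
  } else {
    cat(sprintf("<progression_call> progression called at day %d", x$call_day))
    if (!is.na(x$lead_time_days)) {
      cat(sprintf(" (%d days before imaging at day %d)",
                  x$lead_time_days, x$imaging_day))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
tidy.progression_call <- function(x, ...) {
  x$rule_trace
}

#' @export
glance.progression_call <- function(x, ...) {
  tibble(call_day = x$call_day, imaging_day = x$imaging_day,
         lead_time_days = x$lead_time_days,
         r = x$params$r, rise_threshold = x$params$rise_threshold,
         min_frac = x$params$min_frac)
}

#' Pairwise sample similarity from VAF profiles
#'
#' Pearson correlation of per-variant VAFs between every pair of samples
#' (the matrix's timepoints plus any extra samples such as a tumour biopsy).
#' Pairs sharing fewer than two variants, or with zero variance, yield `NA`
#' and are flagged rather than silently reported as 0.
#'
#' @param vm A `"vaf_matrix"`.
#' @param extra Optional tibble of additional samples (`variant`, `sample`,
#'   `vaf`); variants absent from a sample are treated as unshared.
#' @return A `"sample_similarity"` object: `similarity` (symmetric matrix,
#'   unit diagonal), `n_shared` (variants per pair), and a tibble of
#'   `undefined` pairs.
#' @export
sample_similarity <- function(vm, extra = NULL) {
  prof <- vm$vaf
  if (!is.null(extra) && nrow(extra) > 0) {
    wide <- tidyr::pivot_wider(extra, id_cols = "variant",
                               names_from = "sample", values_from = "vaf")
    add <- matrix(NA_real_, nrow(prof), ncol(wide) - 1,
                  dimnames = list(rownames(prof), names(wide)[-1]))
    hit <- match(wide$variant, rownames(prof))
    ok <- !is.na(hit)
    add[hit[ok], ] <- as.matrix(wide[ok, -1])
    prof <- cbind(prof, add)
  }
  ns <- ncol(prof)
  if (ns < 2) abort("need at least 2 samples")
  sim <- matrix(NA_real_, ns, ns, dimnames = list(colnames(prof), colnames(prof)))
  nsh <- matrix(0L, ns, ns, dimnames = dimnames(sim))
  diag(sim) <- 1
  for (a in seq_len(ns)) {
    for (b in seq_len(ns)) {
      if (b <= a) next
      shared <- !is.na(prof[, a]) & !is.na(prof[, b])
      nsh[a, b] <- nsh[b, a] <- sum(shared)
      if (sum(shared) >= 2) {
        sim[a, b] <- sim[b, a] <-
          suppressWarnings(stats::cor(prof[shared, a], prof[shared, b]))
      }
    }
  }
  diag(nsh) <- colSums(!is.na(prof))
  und <- which(is.na(sim) & upper.tri(sim), arr.ind = TRUE)
  structure(list(similarity = sim, n_shared = nsh,
                 undefined = tibble(sample_1 = rownames(sim)[und[, 1]],
                                    sample_2 = colnames(sim)[und[, 2]])),
            class = "sample_similarity")
}

#' @export
print.sample_similarity <- function(x, ...) {
  cat(sprintf("<sample_similarity> %d samples\n", ncol(x$similarity)))
  print(round(x$similarity, 3))
  if (nrow(x$undefined) > 0) {
    cat(sprintf("  %d pair(s) undefined (too few shared variants or zero variance)\n",
                nrow(x$undefined)))
  }
  invisible(x)
}

#' @export
tidy.sample_similarity <- function(x, ...) {
  s <- x$similarity
  tidyr::crossing(sample_1 = rownames(s), sample_2 = colnames(s)) |>
    mutate(similarity = s[cbind(.data$sample_1, .data$sample_2)],
           n_shared = x$n_shared[cbind(.data$sample_1, .data$sample_2)]) |>
    filter(.data$sample_1 < .data$sample_2)
}

#' Required sequencing depth for a target mutation frequency
#'
#' Depth-of-coverage planner for low-frequency variant detection: to detect
#' mutations at frequency `f`, the depth must scale as
#' `X = kappa / (alpha * f)`, where `alpha` is the library efficiency (the
#' usable fraction of input molecules) and `kappa` is the read-count scaling
#' efficiency, a dimensionless factor (>= 1) absorbing PCR duplication and
#' coverage variability.
#'
#' @param f Target mutation frequency, in (0, 1]. Vectorised.
#' @param alpha Library efficiency, in (0, 1].
#' @param kappa Read-count scaling efficiency, >= 1.
#' @return Required fold-coverage `X` (numeric, recycled over inputs).
#' @export
#' @examples
#' required_depth(0.01, 1, 1)      # 100
#' required_depth(0.001, 0.5, 2.5) # 5000
required_depth <- function(f, alpha = 1, kappa = 1) {
  if (any(f <= 0) || any(f > 1)) abort("f must lie in (0, 1]")
  if (any(alpha <= 0) || any(alpha > 1)) abort("alpha must lie in (0, 1]")
  if (any(kappa < 1)) abort("kappa must be >= 1")
  kappa / (alpha * f)
}
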