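#' Default end-to-end run configuration
#'
#' Nested parameter blocks mirroring each stage's defaults. The configuration
#' is YAML-serialisable; a copy is written into every output directory so a
#' run can be reproduced from its artefacts alone.
#'
#' @param seed Master seed for the run.
#' @return Nested named list.
#' @export
default_config <- function(seed = 11) {
  list(
    seed = as.integer(seed),
    log_level = "info",
    simulate = list(
      reference_length = 200000L, gc_fraction = 0.41,
      germline_het_rate = 1e-3, somatic_count = 600L, ct_mass = 0.8,
      mean_depth = 100, germline_depth = 34, tumor_depth = 40,
      tumor_purity = 0.8, fragment_mode = 167, fragment_sd = 25,
      periodicity = 10, periodicity_amplitude = 0.3,
      tracked_per_subclone = 20L, panel_depth = 3000L, error_rate = 0.001
    ),
    error_model = list(pseudocount = 1, min_mapq = 20, end_trim = 5),
    caller = list(min_alt = 3L, coverage_lo = 0.25, coverage_hi = 2,
                  alpha = 1e-6, min_posterior = 0.95, prior_somatic = 1e-4,
                  quality = 30),
    verify = list(w = 30L, k = 31L, min_support = 3L, germline_tolerance = 0L,
                  min_kmer_count = 2L, max_extra_mismatches = 1L),
    signature = list(ct_check = TRUE),
    tracking = list(min_alt = 3L, min_vaf = 0.002, k = 2L, r = 2L,
                    rise_threshold = 0.01, min_frac = 0.25,
                    panel_noise = TRUE)
  )
}

#' Validate a run configuration
#'
#' Recursively checks a configuration against [default_config()]: unknown
#' keys are rejected (catching typos before a long run), missing keys fall
#' back to the defaults.
#'
#' @param config Nested list (e.g. from [yaml::read_yaml()]).
#' @param template Reference structure.
#' @return The merged, validated configuration.
#' @export
validate_config <- function(config, template = default_config()) {
  merge_block <- function(cfg, tpl, path) {
    unknown <- setdiff(names(cfg), names(tpl))
    if (length(unknown) > 0) {
      abort(sprintf("unknown configuration key%s: %s",
                    if (length(unknown) > 1) "s" else "",
                    paste0(path, unknown, collapse = ", ")))
    }
    for (key in names(tpl)) {
      if (is.list(tpl[[key]])) {
        cfg[[key]] <- merge_block(cfg[[key]] %||% list(), tpl[[key]],
                                  paste0(path, key, "."))
      } else if (is.null(cfg[[key]])) {
        cfg[[key]] <- tpl[[key]]
      }
    }
    cfg
  }
  merge_block(config, template, "")
}

config_to_sim <- function(config) {
  s <- config$simulate
  sim_config(
    reference_length = s$reference_length, gc_fraction = s$gc_fraction,
    germline_het_rate = s$germline_het_rate, somatic_count = s$somatic_count,
    signature_weights = uv_signature_weights(s$ct_mass),
    mean_depth = s$mean_depth, germline_depth = s$germline_depth,
    tumor_depth = s$tumor_depth, tumor_purity = s$tumor_purity,
    fragment_mode = s$fragment_mode, fragment_sd = s$fragment_sd,
    periodicity = s$periodicity,
    periodicity_amplitude = s$periodicity_amplitude,
    tracked_per_subclone = s$tracked_per_subclone,
    panel_depth = s$panel_depth,
    error_matrix = uniform_confusion_matrix(s$error_rate),
    seed = config$seed
  )
}

#' Run the full cfDNA analysis pipeline
#'
#' Executes simulate, error-model, call, verify, signature and track stages
#' in order on a simulated dataset, writing every artefact (FASTA, SAM, TSV,
#' VCF, JSON) plus the serialised configuration into `out_dir`, and returns a
#' manifest of files with MD5 checksums. The run is deterministic: the same
#' configuration and seed give byte-identical artefacts. A stage failure
#' aborts with the failing stage named; artefacts of completed stages are
#' retained.
#'
#' @param config Configuration list, validated against [default_config()].
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest (`file`, `md5`), invisibly classed
#'   `"pipeline_manifest"`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_line <- function(stage, msg) {
    if (identical(config$log_level, "quiet")) return(invisible())
    message(sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  outfile <- function(...) file.path(out_dir, ...)
  yaml::write_yaml(config, outfile("config.yaml"))

  sim <- stage("simulate", {
    sc <- config_to_sim(config)
    ds <- simulate_dataset(sc)
    write_fasta(c(ref1 = ds$reference), outfile("reference.fasta"))
    readr_write_tsv(ds$truth$germline, outfile("truth_germline.tsv"))
    readr_write_tsv(ds$truth$somatic, outfile("truth_somatic.tsv"))
    for (s in unique(ds$reads$reads$sample)) {
      write_sam(filter(ds$reads$reads, .data$sample == s),
                outfile(sprintf("%s.sam", s)), ref_len = sc$reference_length)
    }
    readr_write_tsv(as_tibble(ds$timecourse), outfile("timecourse_expected.tsv"))
    log_line("simulate", sprintf("%d reads, %d somatic variants",
                                 nrow(ds$reads$reads), nrow(ds$truth$somatic)))
    c(ds, list(config = sc))
  })

  cm <- stage("error-model", {
    germ <- filter(sim$reads$reads, .data$sample == "germline")
    excl <- sort(unique(c(sim$truth$germline$pos, sim$truth$somatic$pos)))
    m <- estimate_confusion_matrix(
      germ, sim$reference, excluded_sites = excl,
      pseudocount = config$error_model$pseudocount,
      sample_id = "germline", min_mapq = config$error_model$min_mapq,
      end_trim = config$error_model$end_trim)
    jsonlite::write_json(
      list(sample_id = m$sample_id, bins = m$bins, site_count = m$site_count,
           pseudocount = m$pseudocount,
           matrices = lapply(m$matrices, function(x) as.data.frame(x))),
      outfile("error_model.json"), auto_unbox = TRUE, digits = NA)
    log_line("error-model", sprintf("%d sites tallied", m$site_count))
    m
  })

  calls <- stage("call", {
    cf <- config$caller
    cfdna_samples <- sort(unique(filter(sim$reads$reads,
                                        grepl("^cfdna", .data$sample))$sample))
    out <- list()
    for (s in cfdna_samples) {
      res <- call_sample(
        filter(sim$reads$reads, .data$sample == s), sim$reference,
        sim$truth$germline, cm, min_alt = cf$min_alt,
        coverage_bounds = c(cf$coverage_lo, cf$coverage_hi),
        alpha = cf$alpha, min_posterior = cf$min_posterior,
        prior_somatic = cf$prior_somatic, quality = cf$quality)
      out[[s]] <- res
      log_line("call", sprintf("%s: %d candidates, %d called", s, nrow(res),
                               sum(res$called)))
    }
    out
  })

  verified <- stage("verify", {
    vf <- config$verify
    germ <- filter(sim$reads$reads, .data$sample == "germline")
    out <- list()
    for (s in names(calls)) {
      res <- verify_candidates(
        calls[[s]], filter(sim$reads$reads, .data$sample == s), germ,
        sim$reference, germline_genotypes = sim$truth$germline,
        w = vf$w, k = vf$k, min_support = vf$min_support,
        germline_tolerance = vf$germline_tolerance,
        min_kmer_count = vf$min_kmer_count,
        max_extra_mismatches = vf$max_extra_mismatches)
      write_variants_vcf(res, outfile(sprintf("calls_%s.vcf", s)),
                         ref_len = nchar(sim$reference))
      readr_write_tsv(res, outfile(sprintf("calls_%s.tsv", s)))
      out[[s]] <- res
      log_line("verify", sprintf("%s: %d verified", s,
                                 sum(res$verdict == "verified", na.rm = TRUE)))
    }
    out
  })

  spectra <- stage("signature", {
    out <- list()
    for (s in names(verified)) {
      vc <- filter(verified[[s]], .data$verdict == "verified")
      sp <- build_spectrum(vc, sim$reference, sample_id = s)
      readr_write_tsv(tidy.mutation_spectrum(sp),
                      outfile(sprintf("spectrum_%s.tsv", s)))
      out[[s]] <- sp
    }
    if (length(out) >= 2 && out[[1]]$total > 0 && out[[2]]$total > 0) {
      readr_write_tsv(compare_spectra(out[[1]], out[[2]]),
                      outfile("spectrum_comparison.tsv"))
    }
    log_line("signature", sprintf("%s", paste(
      vapply(out, function(z) sprintf("%s: %d SNVs", z$sample_id, z$total),
             character(1)), collapse = "; ")))
    out
  })

  stage("track", {
    tk <- config$tracking
    counts <- timecourse_counts(sim$timecourse,
                                depth = sim$config$panel_depth,
                                noise = tk$panel_noise,
                                seed = sub_seed(config$seed, 404))
    vm <- build_vaf_matrix(counts, min_alt = tk$min_alt, min_vaf = tk$min_vaf)
    readr_write_tsv(tidy.vaf_matrix(vm), outfile("vaf_matrix.tsv"))
    cl <- cluster_trajectories(vm, k = tk$k)
    readr_write_tsv(tidy.subclone_clusters(cl), outfile("subclone_clusters.tsv"))
    pc <- detect_progression(vm, r = tk$r, rise_threshold = tk$rise_threshold,
                             min_frac = tk$min_frac,
                             imaging_day = attr(sim$timecourse, "imaging_day"))
    jsonlite::write_json(
      list(call_day = pc$call_day, imaging_day = pc$imaging_day,
           lead_time_days = pc$lead_time_days, rule_trace = pc$rule_trace),
      outfile("progression.json"), auto_unbox = TRUE, digits = NA)
    log_line("track", if (is.na(pc$call_day)) "no progression" else
      sprintf("progression at day %d (lead %d days)", pc$call_day,
              pc$lead_time_days))
    pc
  })

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, outfile("manifest.json"), digits = NA)
  class(manifest) <- c("pipeline_manifest", class(manifest))
  invisible(manifest)
}

# TSV writer with stable formatting (no scientific-notation drift)
readr_write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tracking counts table
#'
#' Reads a TSV of per-timepoint variant observations (`variant`, `timepoint`,
#' `day`, `alt`, `depth`) for [build_vaf_matrix()].
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_tracking_counts <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
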