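# End-to-end pipeline: simulate (or ingest) each mixture, filter consensus
# reads, pile up, call, classify, validate, phase, and summarize the limit
# of detection — writing deterministic TSV/VCF-like reports.

#' Pipeline configuration
#'
#' Bundles thresholds, the mixture design and simulation parameters, and
#' validates them before any stage runs.
#'
#' @param seed Integer seed (mandatory; drives every simulation stage).
#' @param design A [mixture_design()].
#' @param reference A [circular_reference()].
#' @param panel An [amplicon_panel()].
#' @param haplotypes Documented haplotype pair (see [default_haplotypes()]).
#' @param coverage,coverage_model,error_rate Simulation parameters passed to
#'   [simulation_config()].
#' @param extension_length Extension for read placement and pileup folding.
#' @param min_base_quality,min_alt_depth Pileup/calling thresholds
#'   (defaults 30 and 5).
#' @param min_read_quality,min_passes Consensus read filters (defaults 0.99
#'   and 5).
#' @param homopolymer_min_run,proximity_window Artifact-flag parameters.
#' @param min_informative,concordance_min Phasing parameters.
#' @param out_dir Output directory for the report bundle.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            design = mixture_design(),
                            reference = synthetic_reference(),
                            panel = default_amplicon_panel(reference),
                            haplotypes = default_haplotypes(reference),
                            coverage = 2000,
                            coverage_model = "fixed",
                            error_rate = 0.001,
                            extension_length = 3000L,
                            min_base_quality = 30L,
                            min_alt_depth = 5L,
                            min_read_quality = 0.99,
                            min_passes = 5L,
                            homopolymer_min_run = 4L,
                            proximity_window = 5L,
                            min_informative = 5L,
                            concordance_min = 0.9,
                            out_dir = tempfile("mitodetect_run_")) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("an integer seed is mandatory for the pipeline")
  }
  if (min_alt_depth < 1L) stop("min_alt_depth must be >= 1")
  if (min_base_quality < 0L) stop("min_base_quality must be >= 0")
  if (min_passes < 1L) stop("min_passes must be >= 1")
  if (min_read_quality < 0 || min_read_quality > 1) {
    stop("min_read_quality must lie in [0, 1]")
  }
  if (concordance_min <= 0.5 || concordance_min > 1) {
    stop("concordance_min must lie in (0.5, 1]")
  }
  stopifnot(inherits(design, "mixture_design"))
  structure(list(
    seed = as.integer(seed), design = design, reference = reference,
    panel = panel, haplotypes = haplotypes, coverage = coverage,
    coverage_model = coverage_model, error_rate = error_rate,
    extension_length = as.integer(extension_length),
    min_base_quality = as.integer(min_base_quality),
    min_alt_depth = as.integer(min_alt_depth),
    min_read_quality = min_read_quality, min_passes = as.integer(min_passes),
    homopolymer_min_run = as.integer(homopolymer_min_run),
    proximity_window = as.integer(proximity_window),
    min_informative = as.integer(min_informative),
    concordance_min = concordance_min, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full detection pipeline on a simulated dilution series
#'
#' For every mixture of the design: simulate consensus amplicon reads,
#' apply the read-quality/pass filter, build the quality-filtered circular
#' pileup, call variants, then classify calls against the documented
#' haplotypes, flag artifacts, validate de novo calls across mixtures,
#' phase them, and derive the per-position limit of detection of the tracked
#' mutant alleles. Writes `calls.vcf`, `lod_table.tsv`, `denovo_report.tsv`
#' and `run_log.txt` into `out_dir`; identical configuration and seed give
#' byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`calls`,
#'   `lod_table`, `denovo_report`, `detections`) and output `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- extend_reference(cfg$reference, cfg$extension_length)
  anchors_truth <- haplotype_anchors(cfg$haplotypes$wildtype,
                                     cfg$haplotypes$mutant, cfg$reference)
  truth <- data.frame(position = anchors_truth$position,
                      mutant_allele = anchors_truth$mutant_allele)

  all_calls <- list()
  detections <- list()
  reads_by_mixture <- list()
  for (i in seq_along(cfg$design$fractions)) {
    f <- cfg$design$fractions[i]
    label <- cfg$design$labels[i]
    sim_cfg <- simulation_config(
      fraction = f, reference = cfg$reference, panel = cfg$panel,
      haplotypes = cfg$haplotypes, extension_length = cfg$extension_length,
      coverage = cfg$coverage, coverage_model = cfg$coverage_model,
      error_rate = cfg$error_rate, seed = cfg$seed + 97L * i,
      mixture_id = label
    )
    sim <- simulate_mixture_reads(sim_cfg)
    reads <- filter_ccs(sim$reads, cfg$min_read_quality, cfg$min_passes)
    pileup <- build_pileup(reads, ext, cfg$min_base_quality)
    calls <- call_variants(pileup, min_alt_depth = cfg$min_alt_depth,
                           mixture_id = label)
    det <- allele_detections(
      pileup, data.frame(position = truth$position,
                         allele = truth$mutant_allele),
      min_depth = cfg$min_alt_depth)
    det$mixture_id <- label
    all_calls[[label]] <- calls
    detections[[label]] <- det
    reads_by_mixture[[label]] <- reads
  }

  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  calls <- classify_calls(calls, cfg$haplotypes)
  calls <- flag_artifacts(calls, cfg$reference, cfg$haplotypes,
                          cfg$homopolymer_min_run, cfg$proximity_window)
  calls <- validate_denovo(calls)
  calls <- phase_calls(calls, reads_by_mixture, cfg$haplotypes,
                       cfg$reference, min_informative = cfg$min_informative,
                       concordance_min = cfg$concordance_min)

  det_all <- do.call(rbind, detections)
  det_hits <- det_all[det_all$detected, c("mixture_id", "position", "allele")]
  lod_table <- lod_per_position(det_hits, truth, cfg$design)
  report <- denovo_report(calls, cfg$design)

  fp <- config_fingerprint(cfg[setdiff(names(cfg), "out_dir")])
  stamp <- sprintf("config=%s seed=%d", fp, cfg$seed)
  paths <- list(
    calls = file.path(cfg$out_dir, "calls.vcf"),
    lod = file.path(cfg$out_dir, "lod_table.tsv"),
    denovo = file.path(cfg$out_dir, "denovo_report.tsv"),
    log = file.path(cfg$out_dir, "run_log.txt")
  )
  write_calls_vcf(calls, cfg$reference, paths$calls, header_comments = stamp)
  write_lod_tsv(lod_table, paths$lod, header_comments = stamp)
  con <- file(paths$denovo, "w")
  writeLines(paste0("# ", stamp), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  writeLines(c(
    paste0("# ", stamp),
    sprintf("mixtures: %s", paste(cfg$design$labels, collapse = ", ")),
    sprintf("coverage: %s (%s)", cfg$coverage, cfg$coverage_model),
    sprintf("error_rate: %s", cfg$error_rate),
    sprintf("thresholds: min_base_quality=%d min_alt_depth=%d min_read_quality=%s min_passes=%d",
            cfg$min_base_quality, cfg$min_alt_depth, cfg$min_read_quality,
            cfg$min_passes),
    sprintf("calls: %d (%d documented, %d de novo keys)",
            nrow(calls), sum(calls$category == "documented_homoplasmic"),
            nrow(unique(calls[calls$category == "de_novo",
                              c("position", "alt")])))
  ), paths$log)

  invisible(list(calls = calls, lod_table = lod_table,
                 denovo_report = report, detections = det_all,
                 paths = paths))
}
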