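# Limit-of-detection analysis over a dilution series, sensitivity summaries,
# and copy-number detection models for the orthogonal methods.

#' Mixture design of a dilution series
#'
#' @param fractions Strictly increasing mutant fractions in `[0, 1]`;
#'   defaults to the six-step series 0, 0.001%, 0.01%, 0.1%, 1%, 10%.
#' @return Object of class `mixture_design` with `fractions` and percent
#'   `labels`.
#' @export
mixture_design <- function(fractions = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1)) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("mixture fractions must lie in [0, 1]")
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("mixture fractions must be strictly increasing")
  }
  structure(list(fractions = fractions,
                 labels = format_fraction_percent(fractions)),
            class = "mixture_design")
}

#' Empirical limit of detection per position
#'
#' Given per-mixture detections of the tracked mutant alleles, returns for
#' each truth position the smallest design fraction at which the mutant
#' allele was detected. The 0-fraction mixture never contributes to an LOD
#' (detections there are background, not a detection limit). Positions never
#' detected get `NA` and the label `"not detected"`.
#'
#' @param detections data.frame with columns `mixture_id` (a design label),
#'   `position`, `allele` — one row per detected (mixture, position, allele),
#'   e.g. filtered rows of [allele_detections()] output or of
#'   [call_variants()] output (with `alt` renamed `allele`).
#' @param truth data.frame with columns `position`, `mutant_allele`.
#' @param design A [mixture_design()] whose labels key `mixture_id`.
#' @return data.frame `position`, `mutant_allele`, `lod_fraction`,
#'   `lod_percent`, `lod_label` (e.g. `">=0.1%"` or `"not detected"`).
#' @export
lod_per_position <- function(detections, truth, design) {
  stopifnot(inherits(design, "mixture_design"))
  if ("alt" %in% names(detections) && !"allele" %in% names(detections)) {
    detections$allele <- detections$alt
  }
  unknown <- setdiff(unique(detections$mixture_id), design$labels)
  if (length(unknown)) {
    stop("unknown mixture label(s): ", paste(unknown, collapse = ", "))
  }
  frac <- design$fractions[match(detections$mixture_id, design$labels)]
  lod <- vapply(seq_len(nrow(truth)), function(i) {
    hit <- detections$position == truth$position[i] &
      detections$allele == truth$mutant_allele[i] & frac > 0
    if (any(hit)) min(frac[hit]) else NA_real_
  }, numeric(1))
  data.frame(
    position = truth$position,
    mutant_allele = truth$mutant_allele,
    lod_fraction = lod,
    lod_percent = lod * 100,
    lod_label = ifelse(is.na(lod), "not detected",
                       paste0(">=", format_fraction_percent(ifelse(is.na(lod), 0, lod)))),
    stringsAsFactors = FALSE
  )
}

#' Sensitivity of a method at a given allele-frequency level
#'
#' The percentage of analyzed positions whose limit of detection is at or
#' below `level`. `NA` entries denote positions analyzed but never detected;
#' they count in the denominator.
#'
#' @param lod_percent Numeric vector of per-position LODs in percent for one
#'   method (`NA` = not detected). Positions not analyzed by the method must
#'   be excluded before calling.
#' @param level Allele-frequency level in percent.
#' @return Sensitivity in percent.
#' @examples
#' fx <- load_lod_fixture()
#' sensitivity_at(fx$lod_smrt[!is.na(fx$lod_smrt)], 0.1)  # ~91
#' @export
sensitivity_at <- function(lod_percent, level) {
  if (!length(lod_percent)) {
    stop("no positions analyzed for this method")
  }
  100 * sum(!is.na(lod_percent) & lod_percent <= level) / length(lod_percent)
}

#' Copy-number detection model of a method
#'
#' Minimal number of variant copies (or reads) a method needs for a
#' detection: 2 positive partitions for digital PCR (within its ~20,000-copy
#' partition capacity), 3 variant copies for the single-base-extension mass
#' spectrometry assay, 5 alternative reads for the sequencing approach.
#'
#' @param method One of `"dPCR"`, `"UltraSEEK"`, `"SMRT"`.
#' @return List with `method`, `min_variant_copies`, `capacity` (`NA` when
#'   not applicable).
#' @export
detection_model <- function(method = c("dPCR", "UltraSEEK", "SMRT")) {
  method <- match.arg(method)
  switch(method,
    dPCR = list(method = method, min_variant_copies = 2L, capacity = 20000L),
    UltraSEEK = list(method = method, min_variant_copies = 3L, capacity = NA_integer_),
    SMRT = list(method = method, min_variant_copies = 5L, capacity = NA_integer_)
  )
}

#' Detection probability of a copy-counting method
#'
#' The number of variant copies among `total_copies` input molecules is
#' binomial with success probability `allele_fraction`; detection requires
#' at least the model's minimal copy number. The binomial tail is computed
#' exactly (no normal or Poisson approximation).
#'
#' @param model A [detection_model()] (or a list with
#'   `min_variant_copies` and optional `capacity`).
#' @param allele_fraction Variant allele fraction in `[0, 1]`.
#' @param total_copies Total input molecules; must not exceed the model's
#'   capacity when one applies.
#' @return Detection probability in `[0, 1]`.
#' @examples
#' detection_probability(detection_model("dPCR"), 1e-4, 20000)  # ~0.594
#' @export
detection_probability <- function(model, allele_fraction, total_copies) {
  if (any(allele_fraction < 0 | allele_fraction > 1)) {
    stop("allele_fraction must lie in [0, 1]")
  }
  if (!is.na(model$capacity) && any(total_copies > model$capacity)) {
    stop("total_copies exceeds the ", model$method, " capacity of ",
         model$capacity)
  }
  stopifnot(model$min_variant_copies >= 1L)
  stats::pbinom(model$min_variant_copies - 1L, total_copies,
                allele_fraction, lower.tail = FALSE)
}

#' Write a per-position LOD table as TSV
#'
#' @param lod_table data.frame from [lod_per_position()].
#' @param path Output path.
#' @param header_comments Optional `#`-prefixed comment lines.
#' @export
write_lod_tsv <- function(lod_table, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments)) writeLines(paste0("# ", header_comments), con)
  utils::write.table(lod_table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
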