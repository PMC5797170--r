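#' mtDNA:nDNA molecule ratio from qPCR quantification cycles
#'
#' Relative quantitation: the ratio of mitochondrial to nuclear target
#' molecules is `2^(Cq_nuc - Cq_mt)`. When the nuclear target yields no
#' amplification signal (`cq_nuc = NA`), the ratio is set to a fixed cap
#' rather than infinity, reflecting that the nuclear template is below the
#' assay's detection limit.
#'
#' @param cq_mt Quantification cycle of the mitochondrial target (finite, > 0).
#' @param cq_nuc Quantification cycle of the nuclear target, or `NA` for no
#'   signal. Vectorized with `cq_mt`.
#' @param no_signal_cap Ratio assigned when `cq_nuc` is absent
#'   (default 2e7, corresponding to ~99% mtDNA by mass).
#' @return Numeric vector of mtDNA:nDNA molecule ratios.
#' @examples
#' mt_nuc_ratio(15, 25)   # 2^10 = 1024
#' mt_nuc_ratio(15, NA)   # capped at 2e7
#' @export
mt_nuc_ratio <- function(cq_mt, cq_nuc, no_signal_cap = 2e7) {
  if (any(is.na(cq_mt))) {
    stop("cq_mt must be present (no mitochondrial signal cannot be quantified)")
  }
  if (any(!is.finite(cq_mt)) || any(cq_mt <= 0)) {
    stop("cq_mt must be finite and > 0")
  }
  if (any(!is.na(cq_nuc) & (!is.finite(cq_nuc) | cq_nuc <= 0))) {
    stop("cq_nuc, when present, must be finite and > 0")
  }
  ifelse(is.na(cq_nuc), no_signal_cap, 2^(cq_nuc - cq_mt))
}

#' Percentage of dsDNA mass that is mitochondrial
#'
#' Converts a molecule ratio into a mass percentage using the genome sizes:
#' `100 * r * S_mt / (r * S_mt + S_nuc)`. Strictly increasing in `r` and
#' saturating below 100%.
#'
#' @param ratio mtDNA:nDNA molecule ratio(s), >= 0.
#' @param mt_genome_size Mitochondrial genome size in bases (default 16,569,
#'   NC_012920).
#' @param nuclear_genome_size Haploid nuclear genome size in bases (default
#'   3,088,269,805, GRCh38).
#' @return Percentage(s) in `[0, 100)`.
#' @examples
#' round(mtdna_percentage(2e7))  # 99
#' @export
mtdna_percentage <- function(ratio, mt_genome_size = 16569,
                             nuclear_genome_size = 3088269805) {
  if (any(is.na(ratio)) || any(ratio < 0)) {
    stop("ratio must be non-negative")
  }
  stopifnot(mt_genome_size > 0, nuclear_genome_size > 0)
  100 * (ratio * mt_genome_size) /
    (ratio * mt_genome_size + nuclear_genome_size)
}

#' Percentage of aligned reads of mitochondrial origin
#'
#' @param aligned_mt Reads aligned to the mitochondrial contig.
#' @param aligned_total Reads aligned to the whole genome (> 0).
#' @return `100 * aligned_mt / aligned_total`.
#' @export
percent_reads_mitochondrial <- function(aligned_mt, aligned_total) {
  if (any(aligned_total == 0)) stop("aligned_total must be > 0")
  if (any(aligned_mt < 0) || any(aligned_mt > aligned_total)) {
    stop("aligned_mt must lie in [0, aligned_total]")
  }
  100 * aligned_mt / aligned_total
}

#' Fold enrichment between two mtDNA percentages
#'
#' A ratio of percentages (e.g. 27% after enrichment vs 0.1% before gives
#' 270-fold), matching how enrichment folds are conventionally reported for
#' extraction protocols; not an odds or copy ratio.
#'
#' @param pct_after,pct_before mtDNA percentages in `[0, 100]`;
#'   `pct_before > 0`.
#' @return `pct_after / pct_before`.
#' @examples
#' enrichment_fold(27, 0.1)  # 270
#' @export
enrichment_fold <- function(pct_after, pct_before) {
  if (any(pct_before <= 0)) stop("pct_before must be > 0")
  if (any(pct_after < 0 | pct_after > 100) || any(pct_before > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  pct_after / pct_before
}

#' Apparent heteroplasmy caused by a NUMT
#'
#' A nuclear insertion of mitochondrial origin (NUMT) present at
#' `numt_copies_per_haploid_genome` copies contributes
#' `ploidy_factor * numt_copies` NUMT molecules per cell against
#' `enrichment_fold * mt_copies_per_cell` effective mtDNA molecules, and can
#' therefore masquerade as an mtDNA variant at the returned allele frequency.
#' Enriching the extract for mtDNA suppresses the artifact proportionally:
#' doubling the fold halves the apparent heteroplasmy.
#'
#' @param numt_copies_per_haploid_genome NUMT copies per haploid nuclear
#'   genome (>= 0).
#' @param mt_copies_per_cell mtDNA molecules per cell (> 0).
#' @param ploidy_factor Nuclear ploidy (default 2, diploid).
#' @param enrichment_fold mtDNA enrichment fold of the extract (>= 1; 1 for a
#'   total cellular DNA extract).
#' @return Apparent heteroplasmy in percent.
#' @examples
#' numt_apparent_heteroplasmy(20, 500)                       # 8
#' numt_apparent_heteroplasmy(20, 500, enrichment_fold = 270) # ~0.03
#' @export
numt_apparent_heteroplasmy <- function(numt_copies_per_haploid_genome,
                                       mt_copies_per_cell,
                                       ploidy_factor = 2,
                                       enrichment_fold = 1) {
  if (any(mt_copies_per_cell <= 0)) stop("mt_copies_per_cell must be > 0")
  if (any(numt_copies_per_haploid_genome < 0)) {
    stop("NUMT copy number must be >= 0")
  }
  if (any(enrichment_fold < 1)) stop("enrichment_fold must be >= 1")
  100 * (ploidy_factor * numt_copies_per_haploid_genome) /
    (enrichment_fold * mt_copies_per_cell)
}

#' Expected duplicate-read fraction for a small genome
#'
#' Single-end reads from a genome offering only `n_start_positions` distinct
#' start positions must collide once more reads than start positions are
#' drawn: at least `1 - n_start_positions / n_reads` of reads appear as
#' duplicates even when every read is error-free.
#'
#' @param n_reads Number of generated reads (> 0).
#' @param n_start_positions Number of distinct start positions (> 0); for a
#'   circular genome read on one strand this is the genome length.
#' @param strand_aware If `TRUE`, double the start positions to account for
#'   both strands (not the convention used for the single-strand expectation).
#' @return Minimum expected duplicate fraction in percent.
#' @examples
#' round(expected_duplicate_fraction(776959, 16569), 1)  # 97.9
#' @export
expected_duplicate_fraction <- function(n_reads, n_start_positions,
                                        strand_aware = FALSE) {
  if (any(n_reads <= 0)) stop("n_reads must be > 0")
  if (any(n_start_positions <= 0)) stop("n_start_positions must be > 0")
  starts <- n_start_positions * (1L + as.integer(strand_aware))
  100 * pmax(0, 1 - starts / n_reads)
}

#' Read a qPCR Cq plate from TSV
#'
#' Expected columns: `sample_id`, `replicate`, `cq_mt`, `cq_nuc`; an empty
#' `cq_nuc` cell denotes no amplification signal for the nuclear target.
#'
#' @param path TSV path.
#' @return data.frame with one row per replicate measurement.
#' @export
read_cq_plate <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "na"))
  need <- c("sample_id", "replicate", "cq_mt", "cq_nuc")
  if (!all(need %in% names(df))) {
    stop("Cq plate must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Summarize mtDNA purity per sample from a Cq plate
#'
#' Replicate runs are averaged on the Cq scale before the delta is taken
#' (duplicate runs of the same multiplex assay); a sample whose nuclear
#' target never amplified gets the no-signal ratio cap.
#'
#' @param plate data.frame as returned by [read_cq_plate()].
#' @param no_signal_cap See [mt_nuc_ratio()].
#' @param ... Passed to [mtdna_percentage()] (genome sizes).
#' @return data.frame with columns `sample_id`, `ratio`, `percentage`.
#' @export
assess_purity <- function(plate, no_signal_cap = 2e7, ...) {
  if (any(is.na(plate$cq_mt))) {
    stop("cq_mt absent for sample(s): ",
         paste(unique(plate$sample_id[is.na(plate$cq_mt)]), collapse = ", "))
  }
  samples <- unique(plate$sample_id)
  res <- lapply(samples, function(s) {
    rows <- plate[plate$sample_id == s, , drop = FALSE]
    cq_mt <- mean(rows$cq_mt)
    cq_nuc <- if (all(is.na(rows$cq_nuc))) NA_real_ else
      mean(rows$cq_nuc, na.rm = TRUE)
    r <- mt_nuc_ratio(cq_mt, cq_nuc, no_signal_cap = no_signal_cap)
    data.frame(sample_id = s, ratio = r,
               percentage = mtdna_percentage(r, ...))
  })
  do.call(rbind, res)
}

#' Write per-sample purity results to TSV
#'
#' @param purity data.frame from [assess_purity()].
#' @param path Output path.
#' @export
write_purity_tsv <- function(purity, path) {
  utils::write.table(purity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
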