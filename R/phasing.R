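# Read-backed allelic phasing: assign a detected variant to the wildtype or
# mutant haplotype by inspecting, on every read that carries the variant
# allele, the alleles observed at positions where the two haplotypes are
# documented to differ (the anchors).

#' Phase one variant against the two documented haplotypes
#'
#' For each read carrying the variant allele, the bases at anchor positions
#' (documented differing positions) falling within the read span are compared
#' with the two haplotypes. A read is informative when it covers at least one
#' anchor whose base matches exactly one haplotype; bases matching neither
#' haplotype (sequencing error at the anchor) are ignored rather than counted
#' as discordant. A read is concordant with the haplotype matching the
#' majority of its informative anchors. The variant is assigned a genotype
#' when at least `min_informative` reads are informative and the concordant
#' fraction reaches `concordance_min`; otherwise it is `ambiguous`.
#'
#' @param position,allele The variant to phase (1-based circle position and
#'   its allele).
#' @param reads Read data.frame (`start` on the extended reference, `seq`);
#'   typically the consensus reads of the mixture where the variant was seen.
#' @param anchors Anchor table from [haplotype_anchors()]: `position`,
#'   `wildtype_allele`, `mutant_allele`.
#' @param ref The [circular_reference()] (supplies the circle length).
#' @param min_informative Minimum informative carrier reads (default 5,
#'   mirroring the calling module's evidence standard).
#' @param concordance_min Minimum concordant fraction among informative
#'   reads (default 0.9).
#' @return List of class `phasing_result`: `position`, `allele`,
#'   `n_variant_reads`, `n_informative_reads`, `n_wildtype_concordant`,
#'   `n_mutant_concordant`, `genotype` (one of `"wildtype"`, `"mutant"`,
#'   `"ambiguous"`).
#' @export
phase_variant <- function(position, allele, reads, anchors, ref,
                          min_informative = 5L, concordance_min = 0.9) {
  L <- ref$length
  anchors <- anchors[anchors$position != position, , drop = FALSE]
  lens <- nchar(reads$seq)

  # offset of a circle position within each read (NA when not covered);
  # works for body and extension placements alike because the extension
  # replicates the start of the circle
  offset_of <- function(p) {
    off <- ((p - reads$start) %% L) + 1L
    ifelse(off >= 1L & off <= lens, off, NA_integer_)
  }

  var_off <- offset_of(position)
  covered <- !is.na(var_off)
  carrier <- covered & substr(reads$seq, var_off, var_off) == allele
  carrier[is.na(carrier)] <- FALSE
  idx <- which(carrier)
  n_var <- length(idx)

  wt_n <- integer(n_var)
  mt_n <- integer(n_var)
  if (n_var && nrow(anchors)) {
    sub <- reads[idx, , drop = FALSE]
    sub_lens <- lens[idx]
    for (k in seq_len(nrow(anchors))) {
      off <- ((anchors$position[k] - sub$start) %% L) + 1L
      inside <- off >= 1L & off <= sub_lens
      if (!any(inside)) next
      base <- rep(NA_character_, n_var)
      base[inside] <- substr(sub$seq[inside], off[inside], off[inside])
      wt_n <- wt_n + as.integer(!is.na(base) &
                                  base == anchors$wildtype_allele[k])
      mt_n <- mt_n + as.integer(!is.na(base) &
                                  base == anchors$mutant_allele[k])
    }
  }
  informative <- (wt_n + mt_n) >= 1L
  n_inf <- sum(informative)
  n_wt <- sum(informative & wt_n > mt_n)
  n_mt <- sum(informative & mt_n > wt_n)

  genotype <- "ambiguous"
  if (n_inf >= min_informative) {
    if (n_wt / n_inf >= concordance_min) genotype <- "wildtype"
    else if (n_mt / n_inf >= concordance_min) genotype <- "mutant"
  }
  structure(list(position = position, allele = allele,
                 n_variant_reads = n_var, n_informative_reads = n_inf,
                 n_wildtype_concordant = n_wt, n_mutant_concordant = n_mt,
                 genotype = genotype),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf(
    "<phasing_result> %d%s: %s (%d carrier reads, %d informative; wt %d / mut %d)\n",
    x$position, x$allele, x$genotype, x$n_variant_reads,
    x$n_informative_reads, x$n_wildtype_concordant, x$n_mutant_concordant))
  invisible(x)
}

#' Phase every de novo call in a call table
#'
#' Each de novo (position, allele) is phased in the mixture where it was
#' observed with the greatest alternative read depth (the richest carrier
#' set); documented homoplasmic calls keep their haplotype assignment from
#' the truth set.
#'
#' @param calls Classified call data.frame (with `mixture_id`).
#' @param reads_by_mixture Named list of read data.frames keyed by mixture
#'   label (post-filter reads of each mixture).
#' @param haplotypes Documented haplotype pair.
#' @param ref The [circular_reference()].
#' @param ... Passed to [phase_variant()].
#' @return `calls` with added columns `phased_genotype`,
#'   `phasing_informative_reads`.
#' @export
phase_calls <- function(calls, reads_by_mixture, haplotypes, ref, ...) {
  anchors <- haplotype_anchors(haplotypes$wildtype, haplotypes$mutant, ref)
  calls$phased_genotype <- NA_character_
  calls$phasing_informative_reads <- NA_integer_
  dn_keys <- unique(calls[calls$category == "de_novo", c("position", "alt")])
  for (i in seq_len(nrow(dn_keys))) {
    p <- dn_keys$position[i]
    a <- dn_keys$alt[i]
    rows <- which(calls$position == p & calls$alt == a)
    best <- rows[which.max(calls$alt_depth[rows])]
    mix <- calls$mixture_id[best]
    if (!mix %in% names(reads_by_mixture)) next
    res <- phase_variant(p, a, reads_by_mixture[[mix]], anchors, ref, ...)
    calls$phased_genotype[rows] <- res$genotype
    calls$phasing_informative_reads[rows] <- res$n_informative_reads
  }
  doc <- calls$category == "documented_homoplasmic"
  if (any(doc)) {
    key <- function(v) paste(v$position, v$alt, sep = ":")
    mut_k <- key(haplotypes$mutant$variants)
    wt_k <- key(haplotypes$wildtype$variants)
    ck <- paste(calls$position, calls$alt, sep = ":")
    calls$phased_genotype[doc & ck %in% mut_k & !ck %in% wt_k] <- "mutant"
    calls$phased_genotype[doc & ck %in% wt_k & !ck %in% mut_k] <- "wildtype"
    calls$phased_genotype[doc & ck %in% wt_k & ck %in% mut_k] <- "concordant"
  }
  calls
}
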