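# Classification of calls against the documented haplotypes, artifact
# screening rules, and validation of de novo variants by independent
# observations (multiple mixtures or overlapping amplicons).

#' Classify calls against the documented haplotype pair
#'
#' A call matching a documented homoplasmic variant (same position AND same
#' alternative allele in either haplotype) is `documented_homoplasmic`; every
#' other call is `de_novo`. The two categories partition the calls.
#'
#' @param calls Call data.frame from [call_variants()] (possibly several
#'   mixtures row-bound together).
#' @param haplotypes Named list with `mutant` and `wildtype`
#'   [haplotype_definition()]s sharing the calls' reference.
#' @return `calls` with an added `category` column.
#' @export
classify_calls <- function(calls, haplotypes) {
  doc <- rbind(haplotypes$mutant$variants[, c("position", "alt")],
               haplotypes$wildtype$variants[, c("position", "alt")])
  key <- function(p, a) paste(p, a, sep = ":")
  documented <- unique(key(doc$position, doc$alt))
  calls$category <- ifelse(key(calls$position, calls$alt) %in% documented,
                           "documented_homoplasmic", "de_novo")
  calls
}

# Circle positions lying in, or immediately bordering, a reference
# homopolymer run of at least `min_run` identical bases. Runs wrapping
# across the origin are merged.
homopolymer_positions <- function(ref, min_run = 4L) {
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_len <- r$lengths
  n_runs <- length(run_len)
  # merge the first and last run when they carry the same base (circular)
  merged_len <- run_len
  if (n_runs > 1L && r$values[1L] == r$values[n_runs]) {
    merged_len[1L] <- merged_len[n_runs] <- run_len[1L] + run_len[n_runs]
  }
  flag <- logical(L)
  for (i in which(merged_len >= min_run)) {
    span <- (starts[i] - 1L):(ends[i] + 1L)  # run plus adjacent bases
    flag[((span - 1L) %% L) + 1L] <- TRUE
  }
  which(flag)
}

# Minimum circular distance from each position to any position in `targets`.
min_circular_distance <- function(positions, targets, L) {
  if (!length(targets)) return(rep(Inf, length(positions)))
  vapply(positions, function(p) {
    d <- abs(p - targets)
    min(pmin(d, L - d))
  }, numeric(1))
}

#' Flag likely artifact calls
#'
#' Encodes the two visual-inspection artifact categories as explicit rules:
#' `homopolymer_adjacent` marks calls lying inside or immediately bordering
#' a reference homopolymer run of at least `homopolymer_min_run` bases;
#' `near_homoplasmic_variant` marks calls within `proximity_window` bases
#' (circular distance) of a documented homoplasmic variant.
#'
#' @param calls Classified call data.frame (see [classify_calls()]).
#' @param ref The [circular_reference()].
#' @param haplotypes Documented haplotype pair.
#' @param homopolymer_min_run Minimum identical-base run length (default 4).
#' @param proximity_window Distance window in bases (default 5).
#' @return `calls` with added logical columns `homopolymer_adjacent` and
#'   `near_homoplasmic_variant`.
#' @export
flag_artifacts <- function(calls, ref, haplotypes, homopolymer_min_run = 4L,
                           proximity_window = 5L) {
  hp <- homopolymer_positions(ref, homopolymer_min_run)
  doc_pos <- unique(c(haplotypes$mutant$variants$position,
                      haplotypes$wildtype$variants$position))
  calls$homopolymer_adjacent <- calls$position %in% hp
  d <- min_circular_distance(calls$position, doc_pos, ref$length)
  calls$near_homoplasmic_variant <- d <= proximity_window
  calls
}

#' Validate de novo calls by independent observations
#'
#' A de novo (position, allele) observed in two or more mixtures is
#' `validated_multi_mixture`; one observed in a single mixture but in two or
#' more overlapping amplicons is `validated_overlap`; anything else is
#' `unvalidated`. Calls that cannot be validated pass the conservative
#' reporting rule only at or above 1% allele frequency
#' (`passes_conservative_threshold`). Documented homoplasmic calls are left
#' with `NA` validation.
#'
#' @param calls Classified call data.frame (rows from all mixtures, with
#'   `mixture_id`, `category`, `n_amplicons`, `allele_frequency`).
#' @param conservative_af Allele-frequency floor for unvalidated de novo
#'   calls (default 0.01, i.e. 1%).
#' @return `calls` with added `validation` and
#'   `passes_conservative_threshold` columns.
#' @export
validate_denovo <- function(calls, conservative_af = 0.01) {
  stopifnot(all(c("mixture_id", "category", "n_amplicons") %in% names(calls)))
  key <- paste(calls$position, calls$alt, sep = ":")
  dn <- calls$category == "de_novo"
  n_mix <- tapply(calls$mixture_id[dn], key[dn],
                  function(m) length(unique(m)))
  max_amp <- tapply(calls$n_amplicons[dn], key[dn], max)
  validation <- rep(NA_character_, nrow(calls))
  v <- ifelse(n_mix[key[dn]] >= 2L, "validated_multi_mixture",
              ifelse(max_amp[key[dn]] >= 2L, "validated_overlap",
                     "unvalidated"))
  validation[dn] <- v
  calls$validation <- validation
  calls$passes_conservative_threshold <- ifelse(
    dn,
    validation != "unvalidated" | calls$allele_frequency >= conservative_af,
    NA
  )
  calls
}

#' Mixture-wide de novo variant report
#'
#' Reshapes validated (and optionally phased) calls into one row per
#' (position, allele) with the allele frequency observed in each mixture,
#' the observing amplicons, validation status and artifact flags — the shape
#' used to report heteroplasmic de novo variants across a dilution series.
#' Allele frequencies are displayed at 2 significant figures.
#'
#' @param calls Validated call data.frame (see [validate_denovo()]; a
#'   `phased_genotype` column, if present, is carried through).
#' @param design A [mixture_design()] giving the column order.
#' @return data.frame with one row per de novo (position, allele).
#' @export
denovo_report <- function(calls, design) {
  dn <- calls[calls$category == "de_novo", , drop = FALSE]
  labels <- design$labels
  if (!nrow(dn)) {
    out <- data.frame(position = integer(), allele = character(),
                      amplicons = character(), phased_genotype = character(),
                      stringsAsFactors = FALSE)
    for (l in labels) out[[paste0("af_", l)]] <- numeric()
    return(out)
  }
  keys <- unique(dn[, c("position", "alt")])
  keys <- keys[order(keys$position, keys$alt), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- dn[dn$position == keys$position[i] & dn$alt == keys$alt[i], ,
              drop = FALSE]
    afs <- stats::setNames(rep(NA_real_, length(labels)), labels)
    got <- sub$mixture_id %in% labels
    afs[sub$mixture_id[got]] <- signif(sub$allele_frequency[got], 2)
    amps <- sort(unique(unlist(strsplit(sub$amplicons[!is.na(sub$amplicons)],
                                        ",", fixed = TRUE))))
    out <- data.frame(
      position = keys$position[i], allele = keys$alt[i],
      amplicons = if (length(amps)) paste(amps, collapse = ",") else NA_character_,
      phased_genotype = if ("phased_genotype" %in% names(sub))
        sub$phased_genotype[1] else NA_character_,
      validation = sub$validation[1],
      homopolymer_adjacent = if ("homopolymer_adjacent" %in% names(sub))
        any(sub$homopolymer_adjacent) else NA,
      near_homoplasmic_variant = if ("near_homoplasmic_variant" %in% names(sub))
        any(sub$near_homoplasmic_variant) else NA,
      stringsAsFactors = FALSE
    )
    for (j in seq_along(labels)) out[[paste0("af_", labels[j])]] <- afs[[j]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
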