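# Pileup construction over the extended reference and threshold-based
# single-nucleotide variant calling. Bases below the quality threshold are
# excluded before counting; extension positions are folded back onto circle
# coordinates so a position covered both in the genome body and in the
# extension accumulates into a single column. Deletions and insertions do not
# exist in the supported read dialect.

#' Build a quality-filtered pileup on circle coordinates
#'
#' Counts, for every circle position, the A/C/G/T read bases at or above
#' `min_base_quality`; bases below the threshold and `N` bases are never
#' counted. Reads placed on the extension are folded back via
#' [to_circle_position()] and their counts summed with body placements.
#' Per-amplicon allele counts are kept alongside the totals to support
#' overlap-based validation.
#'
#' @param reads Read data.frame (`read_id`, `start`, `seq`, `qual`,
#'   optionally `amplicon_id`); `start` is 1-based on the extended reference.
#' @param ext_ref The [extend_reference()] result the reads are placed on.
#' @param min_base_quality Minimum phred base quality to count (default 30).
#' @return Object of class `mt_pileup`: list with `columns` (data.frame
#'   `position`, `A`, `C`, `G`, `T`, `depth`; depth-0 positions omitted),
#'   `by_amplicon` (long data.frame `amplicon`, `position`, `A`, `C`, `G`,
#'   `T`), `min_base_quality`, and `reference` (the base
#'   [circular_reference()]).
#' @export
build_pileup <- function(reads, ext_ref, min_base_quality = 30L) {
  stopifnot(inherits(ext_ref, "extended_reference"))
  L <- ext_ref$base$length
  if (!nrow(reads)) {
    empty <- data.frame(position = integer(), A = integer(), C = integer(),
                        G = integer(), T = integer(), depth = integer())
    return(structure(list(columns = empty,
                          by_amplicon = cbind(amplicon = character(), empty[1:5]),
                          min_base_quality = min_base_quality,
                          reference = ext_ref$base),
                     class = "mt_pileup"))
  }
  lens <- nchar(reads$seq)
  if (any(nchar(reads$qual) != lens)) {
    bad <- reads$read_id[which(nchar(reads$qual) != lens)[1]]
    stop("sequence/quality length mismatch for read ", bad)
  }
  if (any(reads$start < 1L) || any(reads$start + lens - 1L > ext_ref$length)) {
    bad <- reads$read_id[which(reads$start < 1L |
                                 reads$start + lens - 1L > ext_ref$length)[1]]
    stop("read ", bad, " extends beyond the extended reference")
  }
  amp_ids <- reads$amplicon_id %||% rep(NA_character_, nrow(reads))
  amp_key <- ifelse(is.na(amp_ids), ".", amp_ids)

  totals <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  per_amp <- list()

  groups <- split(seq_len(nrow(reads)),
                  paste(amp_key, reads$start, lens, sep = "\r"))
  for (g in groups) {
    n <- length(g)
    len <- lens[g[1]]
    start <- reads$start[g[1]]
    akey <- amp_key[g[1]]
    bytes <- charToRaw(paste(reads$seq[g], collapse = ""))
    qual <- as.integer(charToRaw(paste(reads$qual[g], collapse = ""))) - 33L
    bytes[qual < min_base_quality] <- as.raw(78L)  # 'N': never counted
    m <- matrix(bytes, nrow = len, ncol = n)
    pos <- to_circle_position(start:(start + len - 1L), L)
    cnt <- matrix(0L, nrow = 4L, ncol = len,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    for (b in c("A", "C", "G", "T")) {
      cnt[b, ] <- as.integer(rowSums(m == charToRaw(b)))
    }
    totals[, pos] <- totals[, pos] + cnt
    if (is.null(per_amp[[akey]])) {
      per_amp[[akey]] <- matrix(0L, nrow = 4L, ncol = L,
                                dimnames = list(c("A", "C", "G", "T"), NULL))
    }
    per_amp[[akey]][, pos] <- per_amp[[akey]][, pos] + cnt
  }

  depth <- colSums(totals)
  keep <- which(depth > 0L)
  columns <- data.frame(position = keep,
                        A = totals["A", keep], C = totals["C", keep],
                        G = totals["G", keep], T = totals["T", keep],
                        depth = as.integer(depth[keep]))
  rownames(columns) <- NULL

  by_amp <- do.call(rbind, lapply(names(per_amp), function(a) {
    d <- colSums(per_amp[[a]])
    k <- which(d > 0L)
    if (!length(k)) return(NULL)
    data.frame(amplicon = a, position = k,
               A = per_amp[[a]]["A", k], C = per_amp[[a]]["C", k],
               G = per_amp[[a]]["G", k], T = per_amp[[a]]["T", k],
               stringsAsFactors = FALSE)
  }))
  if (is.null(by_amp)) {
    by_amp <- data.frame(amplicon = character(), position = integer(),
                         A = integer(), C = integer(), G = integer(),
                         T = integer(), stringsAsFactors = FALSE)
  }
  rownames(by_amp) <- NULL

  structure(list(columns = columns, by_amplicon = by_amp,
                 min_base_quality = min_base_quality,
                 reference = ext_ref$base),
            class = "mt_pileup")
}

#' @export
print.mt_pileup <- function(x, ...) {
  cat(sprintf("<mt_pileup> %d covered positions on %s (min base quality %d)\n",
              nrow(x$columns), x$reference$name, x$min_base_quality))
  invisible(x)
}

#' Call single-nucleotide variants from a pileup
#'
#' Emits one call per (position, non-reference allele) whose filtered read
#' count reaches `min_alt_depth`; multiple alternative alleles at one
#' position yield multiple calls. The allele frequency is the alternative
#' count over the filtered depth at the position. The set of amplicons in
#' which the allele was observed (count >= 1) is recorded for overlap-based
#' validation.
#'
#' @param pileup An `mt_pileup` from [build_pileup()].
#' @param ref Reference; defaults to the pileup's own.
#' @param min_alt_depth Minimum alternative-allele read count (default 5
#'   independent high-quality reads).
#' @param mixture_id Optional sample label stamped on the calls.
#' @return data.frame with columns `position`, `ref`, `alt`, `alt_depth`,
#'   `depth`, `allele_frequency`, `amplicons` (comma-separated ids or `NA`),
#'   `n_amplicons`, `mixture_id`.
#' @export
call_variants <- function(pileup, ref = pileup$reference, min_alt_depth = 5L,
                          mixture_id = NA_character_) {
  stopifnot(inherits(pileup, "mt_pileup"))
  if (min_alt_depth < 1L) stop("min_alt_depth must be >= 1")
  df <- pileup$columns
  empty <- data.frame(position = integer(), ref = character(),
                      alt = character(), alt_depth = integer(),
                      depth = integer(), allele_frequency = numeric(),
                      amplicons = character(), n_amplicons = integer(),
                      mixture_id = character(), stringsAsFactors = FALSE)
  if (!nrow(df)) return(empty)
  refb <- ref_base(ref, df$position)
  rows <- lapply(c("A", "C", "G", "T"), function(b) {
    hit <- refb != b & df[[b]] >= min_alt_depth
    if (!any(hit)) return(NULL)
    data.frame(position = df$position[hit], ref = refb[hit], alt = b,
               alt_depth = df[[b]][hit], depth = df$depth[hit],
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(calls) || !nrow(calls)) return(empty)
  calls <- calls[order(calls$position, calls$alt), , drop = FALSE]
  calls$allele_frequency <- calls$alt_depth / calls$depth

  ba <- pileup$by_amplicon
  obs <- vapply(seq_len(nrow(calls)), function(i) {
    r <- ba[ba$position == calls$position[i] & ba$amplicon != ".", ,
            drop = FALSE]
    amps <- sort(r$amplicon[r[[calls$alt[i]]] >= 1L])
    if (length(amps)) paste(amps, collapse = ",") else NA_character_
  }, character(1))
  calls$amplicons <- obs
  calls$n_amplicons <- ifelse(is.na(obs), 0L,
                              lengths(strsplit(obs, ",", fixed = TRUE)))
  calls$mixture_id <- mixture_id
  rownames(calls) <- NULL
  calls
}

#' Per-target allele detection in a pileup
#'
#' Reports, for each (position, allele) target, the filtered read count and
#' whether it reaches `min_depth`. Unlike [call_variants()] this does not
#' require the allele to differ from the reference, which matters for
#' limit-of-detection analysis at positions where the tracked (mutant)
#' allele equals the reference base.
#'
#' @param pileup An `mt_pileup`.
#' @param targets data.frame with columns `position`, `allele`.
#' @param min_depth Detection threshold on the allele read count (default 5).
#' @return `targets` with added `count`, `depth` and `detected` columns.
#' @export
allele_detections <- function(pileup, targets, min_depth = 5L) {
  stopifnot(inherits(pileup, "mt_pileup"),
            all(c("position", "allele") %in% names(targets)))
  df <- pileup$columns
  i <- match(targets$position, df$position)
  cnt <- integer(nrow(targets))
  dep <- integer(nrow(targets))
  for (b in c("A", "C", "G", "T")) {
    sel <- which(targets$allele == b & !is.na(i))
    cnt[sel] <- df[[b]][i[sel]]
    dep[sel] <- df$depth[i[sel]]
  }
  out <- targets
  out$count <- cnt
  out$depth <- dep
  out$detected <- cnt >= min_depth
  out
}

#' Write a pileup as TSV
#'
#' @param pileup An `mt_pileup`.
#' @param path Output path.
#' @param header_comments Optional `#`-prefixed comment lines.
#' @export
write_pileup_tsv <- function(pileup, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments)) writeLines(paste0("# ", header_comments), con)
  utils::write.table(pileup$columns, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
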