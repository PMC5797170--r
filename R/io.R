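# Text-format plumbing: SAM-dialect reader/writer for aligned consensus
# reads, FASTQ export, VCF-like call export. The SAM dialect is deliberately
# restricted: single contig (the extended reference), match-only CIGARs (no
# indels), per-base qualities required. Reverse-strand records are
# reverse-complemented on ingest so all downstream logic sees forward-strand
# reads.

#' Write aligned reads as a SAM-dialect file
#'
#' One `@SQ` line for the extended reference; reads are written mapped on the
#' forward strand with match-only CIGARs. Amplicon id, pass count and
#' predicted read accuracy travel in the `XC:Z`, `np:i` and `rq:f` tags (the
#' latter two follow long-read consensus conventions).
#'
#' @param reads Read data.frame (see [simulate_mixture_reads()]).
#' @param ext_ref An [extend_reference()] result the reads are placed on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ext_ref, path) {
  stopifnot(inherits(ext_ref, "extended_reference"))
  rname <- paste0(ext_ref$base$name, "_extended")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", rname, ext_ref$length),
    "@PG\tID:mitodetect\tPN:mitodetect"
  ), con)
  if (nrow(reads)) {
    amp <- reads$amplicon_id %||% rep(".", nrow(reads))
    amp[is.na(amp)] <- "."
    np <- reads$n_passes %||% rep(1L, nrow(reads))
    np[is.na(np)] <- 1L
    rq <- reads$read_quality %||% rep(1, nrow(reads))
    rq[is.na(rq)] <- 1
    tags <- sprintf("XC:Z:%s\tnp:i:%d\trq:f:%.6f", amp, as.integer(np), rq)
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\t%s",
                       reads$read_id, rname, reads$start,
                       nchar(reads$seq), reads$seq, reads$qual, tags), con)
  }
  invisible(path)
}

#' Read aligned reads from a SAM-dialect file
#'
#' Accepts the restricted dialect written by [write_sam()] (or equivalent):
#' mapped single-segment records with match-only CIGARs (`<n>M`, optionally
#' with soft clips rejected) and per-base qualities. Reverse-strand records
#' (flag bit 0x10) are reverse-complemented, their qualities reversed, so the
#' returned table is forward-strand throughout. Unmapped records are dropped.
#'
#' @param path SAM path.
#' @return Read data.frame with columns `read_id`, `amplicon_id`, `start`,
#'   `seq`, `qual`, `n_passes`, `read_quality`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(), amplicon_id = character(),
                      start = integer(), seq = character(),
                      qual = character(), n_passes = integer(),
                      read_quality = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_one <- function(f) {
    if (length(f) < 11L) stop("malformed SAM record: ", f[1])
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) return(NULL)  # unmapped
    cigar <- f[6]
    if (!grepl("^[0-9]+M$", cigar)) {
      stop("unsupported CIGAR '", cigar, "' in read ", f[1],
           " (dialect allows match-only alignments)")
    }
    seq <- f[10]
    qual <- f[11]
    if (qual == "*") stop("per-base qualities required (read ", f[1], ")")
    if (nchar(seq) != nchar(qual)) {
      stop("sequence/quality length mismatch in read ", f[1])
    }
    if (bitwAnd(flag, 16L) != 0L) {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
    }
    tags <- if (length(f) > 11L) f[12:length(f)] else character()
    tag_value <- function(prefix) {
      hit <- tags[startsWith(tags, prefix)]
      if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE) else NA_character_
    }
    amp <- tag_value("XC:Z:")
    np <- tag_value("np:i:")
    rq <- tag_value("rq:f:")
    data.frame(read_id = f[1], amplicon_id = amp,
               start = as.integer(f[4]), seq = seq, qual = qual,
               n_passes = if (is.na(np)) NA_integer_ else as.integer(np),
               read_quality = if (is.na(rq)) NA_real_ else as.numeric(rq),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Filter(Negate(is.null), lapply(fields, parse_one)))
  rownames(out) <- NULL
  out
}

#' Write reads as FASTQ
#'
#' @param reads Read data.frame with `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n",
                      reads$qual), con)
  }
  invisible(path)
}

#' Write a read-truth sidecar table as TSV
#'
#' @param truth data.frame with `read_id`, `true_origin` (and optionally
#'   `amplicon_id`).
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write variant calls as a VCF-like file
#'
#' Single contig (the circular reference), positions on the circle, depth /
#' allele frequency / observing amplicons / mixture label in INFO.
#'
#' @param calls Call data.frame from [call_variants()].
#' @param ref The [circular_reference()].
#' @param path Output path.
#' @param header_comments Optional character vector written as extra `##`
#'   lines (e.g. seed and configuration fingerprint).
#' @export
write_calls_vcf <- function(calls, ref, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.3",
    if (!is.null(header_comments)) paste0("##", header_comments),
    sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Filtered read depth">',
    '##INFO=<ID=AD,Number=1,Type=Integer,Description="Alternative allele read depth">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternative allele frequency">',
    '##INFO=<ID=AMP,Number=.,Type=String,Description="Amplicons observing the allele">',
    '##INFO=<ID=MIX,Number=1,Type=String,Description="Mixture sample label">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  ), con)
  if (nrow(calls)) {
    o <- order(calls$position, calls$alt)
    calls <- calls[o, , drop = FALSE]
    info <- sprintf("DP=%d;AD=%d;AF=%s;AMP=%s;MIX=%s",
                    calls$depth, calls$alt_depth,
                    signif(calls$allele_frequency, 2),
                    ifelse(is.na(calls$amplicons) | calls$amplicons == "",
                           ".", calls$amplicons),
                    calls$mixture_id)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", ref$name,
                       calls$position, calls$ref, calls$alt, info), con)
  }
  invisible(path)
}
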