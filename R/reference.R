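#' Circular mitochondrial reference genome
#'
#' Container for a circular reference sequence such as the ~16,569 bp human
#' mitochondrial genome. Positions are 1-based and intervals on the circle are
#' closed, following rCRS convention.
#'
#' @param sequence Single character string over the alphabet A, C, G, T, N.
#' @param name Contig name used in FASTA/SAM/VCF output.
#' @return An object of class `circular_reference` with fields `name`,
#'   `sequence` and `length`.
#' @examples
#' ref <- circular_reference("ACGTACGTAC", name = "miniM")
#' ref$length
#' @export
circular_reference <- function(sequence, name = "chrM") {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("reference sequence must be non-empty")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference alphabet is restricted to A, C, G, T, N")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "circular_reference"
  )
}

#' @export
print.circular_reference <- function(x, ...) {
  cat(sprintf("<circular_reference> %s: %d bp (circular)\n", x$name, x$length))
  invisible(x)
}

#' Read a circular reference from a FASTA file
#'
#' The first record of the file is used.
#'
#' @param path Path to a FASTA file.
#' @param name Optional contig name overriding the FASTA header.
#' @return A [circular_reference()].
#' @export
read_reference_fasta <- function(path, name = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences found in ", path)
  nm <- if (is.null(name)) sub("\\s.*$", "", names(ss)[1]) else name
  circular_reference(as.character(ss[[1]]), name = nm)
}

#' Write a reference (circular or extended) to FASTA
#'
#' @param ref A [circular_reference()] or [extend_reference()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  nm <- if (inherits(ref, "extended_reference")) {
    paste0(ref$base$name, "_extended")
  } else {
    ref$name
  }
  x <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, nm))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reference base(s) at circle positions
#'
#' @param ref A [circular_reference()].
#' @param positions Vector of 1-based circle positions.
#' @return Character vector of single bases.
#' @export
ref_base <- function(ref, positions) {
  if (any(positions < 1L | positions > ref$length)) {
    stop("positions must lie in [1, ", ref$length, "]")
  }
  substring(ref$sequence, positions, positions)
}

# Circular substring starting at `start` (1-based) of length `length`,
# wrapping across the origin when needed.
circ_substr <- function(ref, start, length) {
  L <- ref$length
  stopifnot(start >= 1L, start <= L, length >= 1L)
  end <- start + length - 1L
  if (end <= L) {
    substr(ref$sequence, start, end)
  } else {
    n_wraps <- (end - 1L) %/% L  # full extra copies needed beyond the first
    s <- paste(rep(ref$sequence, n_wraps + 1L), collapse = "")
    substr(s, start, end)
  }
}

#' Extend a circular reference past the origin
#'
#' Alignment of reads to a linearized circular genome biases coverage at the
#' origin: a read spanning the junction cannot be placed. Appending the first
#' `extension_length` bases of the circle to its end produces a linear
#' reference on which every read that fits on the circle has a contiguous
#' placement; positions beyond the circle length are folded back with
#' [to_circle_position()].
#'
#' @param ref A [circular_reference()].
#' @param extension_length Number of bases to replicate past the origin; must
#'   be in (0, circle length] and at least the longest expected read/amplicon.
#' @return An object of class `extended_reference` with fields `base`,
#'   `extension_length`, `sequence`, `length`.
#' @examples
#' ref <- circular_reference(strrep("ACGT", 25))
#' ext <- extend_reference(ref, 10)
#' ext$length  # 110
#' @export
extend_reference <- function(ref, extension_length = 3000L) {
  stopifnot(inherits(ref, "circular_reference"))
  extension_length <- as.integer(extension_length)
  if (is.na(extension_length) || extension_length <= 0L ||
      extension_length > ref$length) {
    stop("extension_length must be in (0, ", ref$length,
         "]; got ", extension_length)
  }
  structure(
    list(
      base = ref,
      extension_length = extension_length,
      sequence = paste0(ref$sequence, substr(ref$sequence, 1L, extension_length)),
      length = ref$length + extension_length
    ),
    class = "extended_reference"
  )
}

#' @export
print.extended_reference <- function(x, ...) {
  cat(sprintf("<extended_reference> %s: %d bp circle + %d bp extension\n",
              x$base$name, x$base$length, x$extension_length))
  invisible(x)
}

#' Fold an extended-reference position back onto the circle
#'
#' @param pos_extended Vector of 1-based positions on the extended (or further
#'   wrapped) reference.
#' @param ref_length Length of the circular reference.
#' @return Integer vector of 1-based circle positions in `[1, ref_length]`.
#' @examples
#' to_circle_position(16570, 16569)  # 1
#' to_circle_position(17069, 16569)  # 500
#' @export
to_circle_position <- function(pos_extended, ref_length) {
  if (any(pos_extended < 1L)) {
    stop("extended positions must be >= 1")
  }
  as.integer((pos_extended - 1L) %% as.integer(ref_length) + 1L)
}

# Circular span length of [start, end] (closed, 1-based); end < start means
# the interval wraps across the origin.
amplicon_span_length <- function(start, end, ref_length) {
  ifelse(end >= start, end - start + 1L, ref_length - start + 1L + end)
}

# TRUE where circle position `pos` lies inside the closed circular interval.
in_circular_interval <- function(pos, start, end) {
  ifelse(end >= start, pos >= start & pos <= end, pos >= start | pos <= end)
}

#' Amplicon panel over a circular reference
#'
#' A tiling set of PCR amplicons; consecutive amplicons overlap so that
#' positions in overlap regions are observed independently by two amplicons.
#'
#' @param amplicons data.frame with columns `id` (unique labels, e.g. letters
#'   A-I), `start`, `end` (1-based inclusive circle positions; `end < start`
#'   denotes an origin-spanning amplicon).
#' @param reference A [circular_reference()].
#' @param require_coverage If `TRUE` (default) the union of amplicon intervals
#'   must cover every position of the circle; set `FALSE` for partial panels
#'   (e.g. to simulate a single amplicon).
#' @return An object of class `amplicon_panel`.
#' @export
amplicon_panel <- function(amplicons, reference, require_coverage = TRUE) {
  stopifnot(inherits(reference, "circular_reference"),
            is.data.frame(amplicons),
            all(c("id", "start", "end") %in% names(amplicons)))
  amplicons$id <- as.character(amplicons$id)
  amplicons$start <- as.integer(amplicons$start)
  amplicons$end <- as.integer(amplicons$end)
  if (anyDuplicated(amplicons$id)) stop("amplicon ids must be unique")
  L <- reference$length
  if (any(amplicons$start < 1L | amplicons$start > L |
          amplicons$end < 1L | amplicons$end > L)) {
    stop("amplicon coordinates must lie in [1, ", L, "]")
  }
  amplicons$length <- amplicon_span_length(amplicons$start, amplicons$end, L)
  panel <- structure(list(amplicons = amplicons, reference = reference),
                     class = "amplicon_panel")
  if (require_coverage) {
    cov <- panel_coverage_counts(panel)
    if (any(cov == 0L)) {
      stop("amplicon panel does not cover the circle (first uncovered ",
           "position: ", which(cov == 0L)[1], ")")
    }
  }
  panel
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("<amplicon_panel> %d amplicons on %s (%d bp)\n",
              nrow(x$amplicons), x$reference$name, x$reference$length))
  print(x$amplicons, row.names = FALSE)
  invisible(x)
}

#' Per-position amplicon coverage counts
#'
#' @param panel An [amplicon_panel()].
#' @return Integer vector of length `reference$length`: number of amplicons
#'   whose interval contains each circle position.
#' @export
panel_coverage_counts <- function(panel) {
  L <- panel$reference$length
  cov <- integer(L)
  for (i in seq_len(nrow(panel$amplicons))) {
    s <- panel$amplicons$start[i]
    e <- panel$amplicons$end[i]
    if (e >= s) {
      cov[s:e] <- cov[s:e] + 1L
    } else {
      cov[s:L] <- cov[s:L] + 1L
      cov[1:e] <- cov[1:e] + 1L
    }
  }
  cov
}

#' Amplicons covering a circle position
#'
#' Positions inside overlap regions return two (or more) amplicon ids; such
#' positions are observed by independent PCR products, which the de novo
#' validation logic exploits.
#'
#' @param panel An [amplicon_panel()].
#' @param pos Single 1-based circle position.
#' @return Character vector of amplicon ids (possibly empty for partial
#'   panels).
#' @export
amplicons_covering <- function(panel, pos) {
  stopifnot(length(pos) == 1L)
  L <- panel$reference$length
  if (is.na(pos) || pos < 1L || pos > L) {
    stop("position must lie in [1, ", L, "]")
  }
  a <- panel$amplicons
  a$id[in_circular_interval(pos, a$start, a$end)]
}

#' Default nine-amplicon panel
#'
#' Nine amplicons of ~2 kb evenly spaced around the circle with fixed-length
#' overlaps between consecutive amplicons; the last amplicon spans the origin.
#' This synthesizes the structural properties of a whole-mtDNA tiling design
#' (complete coverage, pairwise overlaps, one junction-spanning product)
#' without a published primer table.
#'
#' @param reference A [circular_reference()]; typically 16,569 bp.
#' @param n_amplicons Number of amplicons (default 9, labelled A, B, C, ...).
#' @param overlap Overlap between consecutive amplicons in bases (default 150).
#' @return An [amplicon_panel()].
#' @export
default_amplicon_panel <- function(reference, n_amplicons = 9L, overlap = 150L) {
  L <- reference$length
  starts <- 1L + as.integer(round((seq_len(n_amplicons) - 1L) * L / n_amplicons))
  nxt <- c(starts[-1L], starts[1L] + L)  # next start, unwrapped
  ends <- to_circle_position(nxt + overlap - 1L, L)
  amp <- data.frame(id = LETTERS[seq_len(n_amplicons)],
                    start = starts, end = ends)
  panel <- amplicon_panel(amp, reference)
  len <- panel$amplicons$length
  if (L > 10000L && (any(len < 1700L) || any(len > 3000L))) {
    stop("default panel amplicon lengths fall outside [1700, 3000] bp; ",
         "adjust n_amplicons/overlap")
  }
  panel
}

#' Read/write an amplicon panel as TSV
#'
#' Columns: `id`, `start`, `end` (1-based inclusive circle coordinates).
#'
#' @param path TSV path.
#' @param reference A [circular_reference()] the panel is defined on.
#' @param ... Passed to [amplicon_panel()] (e.g. `require_coverage`).
#' @return An [amplicon_panel()].
#' @export
read_panel_tsv <- function(path, reference, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  amplicon_panel(df[, c("id", "start", "end")], reference, ...)
}

#' @rdname read_panel_tsv
#' @param panel An [amplicon_panel()] to write.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(panel$amplicons[, c("id", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
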