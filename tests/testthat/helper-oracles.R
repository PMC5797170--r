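# Independent brute-force oracles kept deliberately naive: per-read,
# per-base loops with none of the vectorization used by the implementation.

# 4 x L allele-count matrix tallied read by read, base by base.
brute_pileup_counts <- function(reads, ext_ref, min_base_quality = 30L) {
  L <- ext_ref$base$length
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(reads))) {
    b <- strsplit(reads$seq[i], "")[[1]]
    q <- as.integer(charToRaw(reads$qual[i])) - 33L
    for (j in seq_along(b)) {
      if (q[j] < min_base_quality) next
      if (!b[j] %in% rownames(counts)) next
      p <- ((reads$start[i] + j - 2L) %% L) + 1L
      counts[b[j], p] <- counts[b[j], p] + 1L
    }
  }
  counts
}

# Per-position effective allele sequence of a haplotype, built by character
# substitution over the full genome.
brute_effective_sequence <- function(h, ref) {
  chars <- strsplit(ref$sequence, "")[[1]]
  v <- h$variants
  for (i in seq_len(nrow(v))) chars[v$position[i]] <- v$alt[i]
  chars
}
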