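# Small in-code fixtures shared across test files.

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# Deterministic random circular reference of a given length.
tiny_reference <- function(length = 120L, seed = 5L, name = "miniM") {
  withr::with_seed(seed, {
    circular_reference(paste(sample(c("A", "C", "G", "T"), length,
                                    replace = TRUE), collapse = ""),
                       name = name)
  })
}

# Two-amplicon covering panel; amplicon B spans the origin.
tiny_panel <- function(ref, overlap = 10L) {
  L <- ref$length
  half <- L %/% 2L
  amplicon_panel(data.frame(id = c("A", "B"),
                            start = c(1L, half + 1L),
                            end = c(half + overlap, overlap)),
                 ref)
}

# Haplotype whose alternative alleles are transitions of the reference base.
make_haplotype <- function(ref, name, positions, bg_positions = NULL,
                           bg_fractions = NULL) {
  variants <- if (length(positions)) {
    rb <- ref_base(ref, positions)
    data.frame(position = positions, ref = rb,
               alt = unname(TRANSITION[rb]))
  } else {
    data.frame(position = integer(), ref = character(), alt = character())
  }
  background <- if (length(bg_positions)) {
    rb <- ref_base(ref, bg_positions)
    data.frame(position = bg_positions, ref = rb,
               alt = unname(TRANSITION[rb]), fraction = bg_fractions)
  } else NULL
  haplotype_definition(name, variants, background)
}

# Mutant/wildtype pair on a tiny reference with disjoint variant positions.
tiny_haplotypes <- function(ref, mut_pos, wt_pos = integer(),
                            mut_bg = NULL, wt_bg = NULL,
                            mut_bg_frac = NULL, wt_bg_frac = NULL) {
  list(mutant = make_haplotype(ref, "mutant", mut_pos, mut_bg, mut_bg_frac),
       wildtype = make_haplotype(ref, "wildtype", wt_pos, wt_bg, wt_bg_frac))
}

# A read data.frame row with uniformly high base qualities.
make_read <- function(id, start, seq, qual = NULL, amplicon = "A") {
  data.frame(read_id = id, amplicon_id = amplicon, start = start,
             seq = seq,
             qual = if (is.null(qual)) strrep("]", nchar(seq)) else qual,
             n_passes = 10L, read_quality = 0.999,
             stringsAsFactors = FALSE)
}
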