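# Truth sets: the two documented cell-line haplotypes, packaged LOD fixture,
# and the synthetic reference/haplotype defaults used by the simulator.

# Transition partner of each base; used when a synthetic alternative allele is
# needed (transitions dominate mtDNA substitution spectra).
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# Positions invented for the default simulation truth sets. They avoid every
# fixture position and each other.
.EXTRA_DIFFERING_POS <- c(3107L, 5186L, 8869L, 11335L, 14953L)
.SHARED_ALT_POS <- c(742L, 2356L, 4216L, 7598L, 9540L, 12372L, 15607L)
.WT_BACKGROUND <- data.frame(
  position = c(1294L, 3644L, 6082L, 9722L, 13534L, 16383L),
  fraction = c(0.24, 0.072, 0.013, 0.006, 0.0045, 0.003)
)
.MT_BACKGROUND <- data.frame(
  position = c(2088L, 7815L, 14223L),
  fraction = c(0.08, 0.061, 0.009)
)
# Fixture position modeled with the alternative allele on the wildtype side
# (see default_haplotypes details).
.WT_SIDE_FIXTURE_POS <- 6371L

#' Haplotype truth set
#'
#' A named set of homoplasmic single-nucleotide variants relative to the
#' circular reference, optionally with low-level background heteroplasmies
#' that every molecule of this haplotype carries with the stated fraction.
#'
#' @param name Haplotype label, e.g. `"mutant"` or `"wildtype"`.
#' @param variants data.frame with columns `position`, `ref`, `alt`
#'   (single bases, `ref != alt`, unique positions).
#' @param background Optional data.frame with columns `position`, `ref`,
#'   `alt`, `fraction` (allele fraction in (0, 0.5] by default convention).
#' @return Object of class `haplotype_definition`.
#' @export
haplotype_definition <- function(name, variants, background = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  variants <- as.data.frame(variants)
  need <- c("position", "ref", "alt")
  stopifnot(all(need %in% names(variants)))
  variants$position <- as.integer(variants$position)
  if (nrow(variants)) {
    if (anyDuplicated(variants$position)) {
      stop("at most one homoplasmic alternative allele per position")
    }
    if (any(variants$ref == variants$alt)) {
      stop("ref and alt alleles must differ")
    }
    if (!all(c(variants$ref, variants$alt) %in% c("A", "C", "G", "T"))) {
      stop("alleles must be A, C, G or T")
    }
    variants <- variants[order(variants$position), , drop = FALSE]
    rownames(variants) <- NULL
  }
  if (is.null(background)) {
    background <- data.frame(position = integer(), ref = character(),
                             alt = character(), fraction = numeric())
  } else {
    background <- as.data.frame(background)
    stopifnot(all(c("position", "ref", "alt", "fraction") %in% names(background)))
    if (any(background$fraction <= 0 | background$fraction >= 1)) {
      stop("background fractions must lie in (0, 1)")
    }
  }
  structure(list(name = name, variants = variants, background = background),
            class = "haplotype_definition")
}

#' @export
print.haplotype_definition <- function(x, ...) {
  cat(sprintf("<haplotype_definition> %s: %d homoplasmic variants, %d background heteroplasmies\n",
              x$name, nrow(x$variants), nrow(x$background)))
  invisible(x)
}

# Effective (homoplasmic) allele of haplotype `h` at given circle positions:
# the alternative allele where defined, the reference base elsewhere.
effective_allele <- function(h, positions, ref) {
  out <- ref_base(ref, positions)
  i <- match(positions, h$variants$position)
  hit <- !is.na(i)
  out[hit] <- h$variants$alt[i[hit]]
  out
}

#' Positions where two haplotypes carry different alleles
#'
#' Compares the effective allele (alternative where documented, reference
#' base elsewhere) of the two haplotypes at every position where either
#' carries a variant. Symmetric in its arguments.
#'
#' @param h1,h2 [haplotype_definition()] objects on the same reference.
#' @param ref The shared [circular_reference()].
#' @return Sorted integer vector of differing circle positions.
#' @export
differing_positions <- function(h1, h2, ref) {
  cand <- sort(unique(c(h1$variants$position, h2$variants$position)))
  if (!length(cand)) return(integer())
  a1 <- effective_allele(h1, cand, ref)
  a2 <- effective_allele(h2, cand, ref)
  cand[a1 != a2]
}

#' Anchor table for phasing: differing positions with per-haplotype alleles
#'
#' @inheritParams differing_positions
#' @param wildtype,mutant [haplotype_definition()] objects.
#' @return data.frame with columns `position`, `wildtype_allele`,
#'   `mutant_allele`.
#' @export
haplotype_anchors <- function(wildtype, mutant, ref) {
  pos <- differing_positions(wildtype, mutant, ref)
  data.frame(position = pos,
             wildtype_allele = effective_allele(wildtype, pos, ref),
             mutant_allele = effective_allele(mutant, pos, ref))
}

#' Load the packaged per-position limit-of-detection fixture
#'
#' Twenty-three positions at which the two cell-line haplotypes differ, with
#' the mutant and wildtype alleles and the empirically determined limit of
#' detection (lowest mixture fraction at which the mutant allele was
#' detected, in percent) for each of three methods. `na` marks positions not
#' analyzed by a method (the single-base-extension and digital PCR assays
#' require dedicated primers and covered 7 and 2 positions respectively).
#'
#' @param path Fixture path; defaults to the copy installed with the package.
#' @return data.frame with columns `position`, `mutant_allele`,
#'   `wildtype_allele`, `lod_smrt`, `lod_ultraseek`, `lod_dpcr` (numeric
#'   percent, `NA` = not analyzed).
#' @export
load_lod_fixture <- function(path = system.file("extdata", "lod_fixture.tsv",
                                           package = "mitodetect")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("position", "mutant_allele", "wildtype_allele",
            "lod_smrt", "lod_ultraseek", "lod_dpcr")
  if (!all(need %in% names(df))) {
    stop("LOD fixture must have columns: ", paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  for (i in seq_len(nrow(df))) {
    ok <- !is.na(df$position[i]) &&
      all(c(df$mutant_allele[i], df$wildtype_allele[i]) %in% c("A", "C", "G", "T"))
    if (!ok) stop("malformed LOD fixture at row ", i)
  }
  for (col in c("lod_smrt", "lod_ultraseek", "lod_dpcr")) {
    v <- df[[col]]
    v[v == "na"] <- NA
    df[[col]] <- as.numeric(v)
  }
  if (anyDuplicated(df$position)) stop("duplicate positions in LOD fixture")
  df
}

#' Synthetic circular reference genome
#'
#' A deterministic synthetic 16,569 bp random sequence standing in for an
#' rCRS-like mitochondrial genome, patched so that the packaged truth-table
#' alleles are consistent: at each fixture position the reference base equals
#' the wildtype allele (the mutant allele is the alternative), except position
#' 6371 where the reference equals the mutant allele (the wildtype carries
#' the alternative; see [default_haplotypes()]). The sequence is synthetic: it
#' reproduces the coordinate system, length and truth-set structure of the
#' real genome, not its base composition at other positions.
#'
#' @param length Genome length (default 16,569).
#' @param name Contig name.
#' @return A [circular_reference()].
#' @export
synthetic_reference <- function(length = 16569L, name = "chrM") {
  bases <- with_rng_seed(16569L, {
    sample(c("A", "C", "G", "T"), length, replace = TRUE)
  })
  fx <- load_lod_fixture()
  fx <- fx[fx$position <= length, , drop = FALSE]
  refb <- ifelse(fx$position == .WT_SIDE_FIXTURE_POS,
                 fx$mutant_allele, fx$wildtype_allele)
  bases[fx$position] <- refb
  circular_reference(paste(bases, collapse = ""), name = name)
}

#' Default mutant/wildtype haplotype pair for simulation
#'
#' Builds the two truth sets emulating the documented cell-line haplotypes:
#'
#' * 28 positions with a different effective allele between the haplotypes:
#'   the 23 fixture positions plus 5 synthetic extra differing positions
#'   (standing in for positions omitted from the fixture because they are
#'   heteroplasmic in every mixture).
#' * 7 concordant positions where both haplotypes carry the same synthetic
#'   alternative allele.
#' * The mutant haplotype therefore carries 29 alternative alleles and the
#'   wildtype 13. Those counts force 6 of the 28 differing positions to carry
#'   the alternative allele on the wildtype side; the 5 synthetic extras and
#'   fixture position 6371 play that role, so at those positions the mutant
#'   allele equals the reference base.
#' * Background heteroplasmies follow the documented pattern: a ~24% and a
#'   ~7% variant plus several at or below ~1% on the wildtype, and a few
#'   low-level variants on the mutant.
#'
#' @param reference A [circular_reference()] from [synthetic_reference()].
#' @return Named list with elements `mutant` and `wildtype`
#'   ([haplotype_definition()] objects).
#' @export
default_haplotypes <- function(reference = synthetic_reference()) {
  fx <- load_lod_fixture()
  wt_side <- fx$position == .WT_SIDE_FIXTURE_POS

  mut_var <- data.frame(position = fx$position[!wt_side],
                        ref = fx$wildtype_allele[!wt_side],
                        alt = fx$mutant_allele[!wt_side])
  wt_var <- data.frame(position = fx$position[wt_side],
                       ref = fx$mutant_allele[wt_side],
                       alt = fx$wildtype_allele[wt_side])

  extra_ref <- ref_base(reference, .EXTRA_DIFFERING_POS)
  wt_var <- rbind(wt_var, data.frame(position = .EXTRA_DIFFERING_POS,
                                     ref = extra_ref,
                                     alt = unname(.TRANSITION[extra_ref])))

  shared_ref <- ref_base(reference, .SHARED_ALT_POS)
  shared <- data.frame(position = .SHARED_ALT_POS, ref = shared_ref,
                       alt = unname(.TRANSITION[shared_ref]))

  bg <- function(tab) {
    rb <- ref_base(reference, tab$position)
    data.frame(position = tab$position, ref = rb,
               alt = unname(.TRANSITION[rb]), fraction = tab$fraction)
  }

  list(
    mutant = haplotype_definition("mutant", rbind(mut_var, shared),
                                  background = bg(.MT_BACKGROUND)),
    wildtype = haplotype_definition("wildtype", rbind(wt_var, shared),
                                    background = bg(.WT_BACKGROUND))
  )
}

#' Export a haplotype truth set as a minimal VCF-like file
#'
#' Single-sample, genotype-only records for the homoplasmic variants.
#'
#' @param h A [haplotype_definition()].
#' @param ref The [circular_reference()].
#' @param path Output path.
#' @export
write_haplotype_vcf <- function(h, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.3",
    sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", h$name, sep = "\t")
  ), con)
  v <- h$variants
  if (nrow(v)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\fx", ref$name,
                       v$position, v$ref, v$alt), con)
  }
  invisible(path)
}
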