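make_call <- function(position, alt, af = 0.5, mixture = "1%",
                      n_amplicons = 1L, ref = "A") {
  data.frame(position = position, ref = ref, alt = alt,
             alt_depth = as.integer(round(af * 1000)), depth = 1000L,
             allele_frequency = af,
             amplicons = paste(LETTERS[seq_len(n_amplicons)], collapse = ","),
             n_amplicons = n_amplicons, mixture_id = mixture,
             stringsAsFactors = FALSE)
}

test_that("calls are partitioned into documented and de novo", {
  ref <- tiny_reference(100L)
  haps <- tiny_haplotypes(ref, mut_pos = c(20L, 80L), wt_pos = 50L)
  calls <- rbind(
    make_call(20L, haps$mutant$variants$alt[1]),       # documented (mutant)
    make_call(50L, haps$wildtype$variants$alt[1]),     # documented (wildtype)
    make_call(20L, setdiff(c("A", "C", "G", "T"),
                           c(haps$mutant$variants$alt[1],
                             ref_base(ref, 20L)))[1]), # same pos, other allele
    make_call(33L, "T", ref = ref_base(ref, 33L))      # untouched position
  )
  cls <- classify_calls(calls, haps)
  expect_equal(cls$category,
               c("documented_homoplasmic", "documented_homoplasmic",
                 "de_novo", "de_novo"))
  expect_true(all(cls$category %in% c("documented_homoplasmic", "de_novo")))
})

test_that("de novo count on clean simulation equals the injected background", {
  ref <- tiny_reference(100L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = c(20L, 80L),
                          wt_bg = c(40L, 65L), wt_bg_frac = c(0.3, 0.2))
  cfg <- simulation_config(0, ref, panel, haps, extension_length = 60L,
                           coverage = 400, coverage_model = "fixed",
                           error_rate = 0, p_low_quality = 0, seed = 31)
  sim <- simulate_mixture_reads(cfg)
  pu <- build_pileup(sim$reads, extend_reference(ref, 60L))
  calls <- classify_calls(call_variants(pu, mixture_id = "0%"), haps)
  dn <- calls[calls$category == "de_novo", ]
  expect_equal(sort(dn$position), c(40L, 65L))
  expect_equal(nrow(dn), 2L)
})

test_that("homopolymer adjacency follows the run-length rule", {
  ref <- circular_reference(paste0("ACGT", strrep("A", 6L), "CGTCG",
                                   "TTT", "CGACGACG"))
  haps <- tiny_haplotypes(ref, mut_pos = integer())
  calls <- rbind(
    make_call(7L, "G", ref = "A"),    # inside the 6-base A run (5..10)
    make_call(11L, "A", ref = "C"),   # immediately bordering the run
    make_call(16L, "C", ref = "T"),   # inside the TTT run: length 3 < 4
    make_call(20L, "T", ref = "G")    # far from any run
  )
  flagged <- flag_artifacts(calls, ref, haps, homopolymer_min_run = 4L)
  expect_equal(flagged$homopolymer_adjacent, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("homopolymer runs merge across the origin", {
  ref <- circular_reference(paste0("AA", strrep("CGT", 6L), "AA"))
  haps <- tiny_haplotypes(ref, mut_pos = integer())
  calls <- make_call(1L, "G", ref = "A")  # in a wrapped run of 4 A's
  flagged <- flag_artifacts(calls, ref, haps, homopolymer_min_run = 4L)
  expect_true(flagged$homopolymer_adjacent)
})

test_that("proximity to documented variants uses circular distance", {
  ref <- tiny_reference(100L)
  haps <- tiny_haplotypes(ref, mut_pos = c(50L, 2L))
  calls <- rbind(
    make_call(47L, "T", ref = ref_base(ref, 47L)),  # 3 bp from 50
    make_call(56L, "T", ref = ref_base(ref, 56L)),  # 6 bp from 50
    make_call(99L, "T", ref = ref_base(ref, 99L))   # 3 bp from 2, wrapping
  )
  flagged <- flag_artifacts(calls, ref, haps, proximity_window = 5L)
  expect_equal(flagged$near_homoplasmic_variant, c(TRUE, FALSE, TRUE))
})

test_that("de novo validation distinguishes multi-mixture, overlap and neither", {
  ref <- tiny_reference(100L)
  haps <- tiny_haplotypes(ref, mut_pos = 20L)
  calls <- rbind(
    make_call(33L, "T", af = 0.002, mixture = "0.1%"),  # seen twice ...
    make_call(33L, "T", af = 0.004, mixture = "1%"),    # ... across mixtures
    make_call(41L, "T", af = 0.003, mixture = "1%", n_amplicons = 2L),
    make_call(55L, "T", af = 0.002, mixture = "1%"),    # single obs, low AF
    make_call(60L, "T", af = 0.02, mixture = "1%")      # single obs, 2% AF
  )
  calls$ref <- "C"
  cls <- validate_denovo(classify_calls(calls, haps))
  v <- stats::setNames(cls$validation, cls$position)
  expect_equal(unname(v[c("33", "41", "55", "60")][1]), "validated_multi_mixture")
  expect_equal(unname(v["41"]), "validated_overlap")
  expect_equal(unname(v["55"]), "unvalidated")
  expect_equal(unname(v["60"]), "unvalidated")
  p <- stats::setNames(cls$passes_conservative_threshold, cls$position)
  expect_true(p[["33"]])   # validated -> passes regardless of AF
  expect_true(p[["41"]])
  expect_false(p[["55"]])  # unvalidated below 1%
  expect_true(p[["60"]])   # unvalidated but >= 1% AF
})

test_that("observing a variant in an extra mixture never invalidates it", {
  ref <- tiny_reference(100L)
  haps <- tiny_haplotypes(ref, mut_pos = 20L)
  base <- rbind(make_call(41L, "T", af = 0.003, mixture = "1%",
                          n_amplicons = 2L))
  base$ref <- "C"
  v1 <- validate_denovo(classify_calls(base, haps))
  expect_equal(v1$validation, "validated_overlap")
  more <- rbind(base, transform(base, mixture_id = "10%", n_amplicons = 1L))
  v2 <- validate_denovo(classify_calls(more, haps))
  expect_true(all(v2$validation != "unvalidated"))
})

test_that("the mixture-wide report has one row per de novo allele", {
  ref <- tiny_reference(100L)
  haps <- tiny_haplotypes(ref, mut_pos = 20L)
  design <- mixture_design(c(0, 0.01, 0.1))
  calls <- rbind(
    make_call(33L, "T", af = 0.0021, mixture = "1%"),
    make_call(33L, "T", af = 0.0043, mixture = "10%"),
    make_call(20L, haps$mutant$variants$alt[1], af = 0.1, mixture = "10%")
  )
  calls$ref <- "C"
  cls <- validate_denovo(classify_calls(calls, haps))
  rep <- denovo_report(cls, design)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$position, 33L)
  expect_equal(rep[["af_1%"]], 0.0021)
  expect_equal(rep[["af_10%"]], 0.0043)
  expect_true(is.na(rep[["af_0%"]]))
})
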