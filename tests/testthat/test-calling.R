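test_that("pileup counts equal a brute-force per-read tally", {
  ref <- tiny_reference(90L, seed = 21L)
  ext <- extend_reference(ref, 40L)
  withr::with_seed(13, {
    n <- 60L
    reads <- do.call(rbind, lapply(seq_len(n), function(i) {
      len <- sample(5:30, 1)
      start <- sample.int(ext$length - len + 1L, 1)
      seq <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                          prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                   collapse = "")
      qual <- phred <- sample(c(20L, 35L, 60L), len, replace = TRUE)
      make_read(sprintf("r%02d", i), start, seq,
                qual = rawToChar(as.raw(qual + 33L)),
                amplicon = sample(c("A", "B"), 1))
    }))
    pu <- build_pileup(reads, ext, min_base_quality = 30L)
    oracle <- brute_pileup_counts(reads, ext, min_base_quality = 30L)
    got <- matrix(0L, nrow = 4L, ncol = ref$length,
                  dimnames = dimnames(oracle))
    for (b in c("A", "C", "G", "T")) {
      got[b, pu$columns$position] <- pu$columns[[b]]
    }
    expect_identical(got, oracle)
    # per-amplicon counts sum to the totals
    ba <- pu$by_amplicon
    for (b in c("A", "C", "G", "T")) {
      sums <- tapply(ba[[b]], ba$position, sum)
      expect_equal(as.integer(sums[as.character(pu$columns$position)]),
                   pu$columns[[b]])
    }
  })
})

test_that("bases below the quality threshold are never counted", {
  ref <- tiny_reference(50L)
  ext <- extend_reference(ref, 20L)
  q29 <- rawToChar(as.raw(29L + 33L))
  q30 <- rawToChar(as.raw(30L + 33L))
  reads <- rbind(make_read("lo", 10L, "A", qual = q29),
                 make_read("hi", 10L, "A", qual = q30))
  pu <- build_pileup(reads, ext, min_base_quality = 30L)
  col <- pu$columns[pu$columns$position == 10L, ]
  expect_equal(col$A, 1L)   # only the quality-30 base counts
  expect_equal(col$depth, 1L)
})

test_that("body and extension placements fold into one circle column", {
  ref <- tiny_reference(50L)
  ext <- extend_reference(ref, 20L)
  # read 1 covers circle positions 2..6 in the body; read 2 starts at 45 and
  # wraps through the extension, covering 45..50 then 1..4
  reads <- rbind(make_read("body", 2L, strrep("A", 5L)),
                 make_read("wrap", 45L, strrep("A", 10L)))
  pu <- build_pileup(reads, ext)
  expect_equal(pu$columns$depth[pu$columns$position == 2L], 2L)
  expect_equal(pu$columns$depth[pu$columns$position == 4L], 2L)
  expect_equal(pu$columns$depth[pu$columns$position == 5L], 1L)
  expect_equal(pu$columns$depth[pu$columns$position == 50L], 1L)
  expect_false(any(pu$columns$position > ref$length))
  expect_false(any(pu$columns$position < 1L))
})

test_that("reads beyond the extended reference are rejected by id", {
  ref <- tiny_reference(50L)
  ext <- extend_reference(ref, 10L)
  reads <- make_read("overhang", 58L, "ACGTA")
  expect_error(build_pileup(reads, ext), "overhang")
})

test_that("calls require the minimum alternative read depth", {
  ref <- circular_reference(strrep("A", 40L))
  ext <- extend_reference(ref, 10L)
  # 4 reads with G at position 5 -> no call; a 5th read tips it over
  alt4 <- do.call(rbind, lapply(1:4, function(i) {
    make_read(paste0("alt", i), 5L, "G")
  }))
  refr <- do.call(rbind, lapply(1:20, function(i) {
    make_read(paste0("ref", i), 5L, "A")
  }))
  pu4 <- build_pileup(rbind(alt4, refr), ext)
  expect_equal(nrow(call_variants(pu4)), 0L)
  pu5 <- build_pileup(rbind(alt4, make_read("alt5", 5L, "G"), refr), ext)
  calls <- call_variants(pu5)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 5L)
  expect_equal(calls$ref, "A")
  expect_equal(calls$alt, "G")
  expect_equal(calls$alt_depth, 5L)
  expect_equal(calls$depth, 25L)
  expect_equal(calls$allele_frequency, 0.2)
  expect_error(call_variants(pu5, min_alt_depth = 0L), "min_alt_depth")
})

test_that("an allele in 5 of 5000 reads is called at 0.1% frequency", {
  ref <- circular_reference(strrep("C", 30L))
  ext <- extend_reference(ref, 10L)
  n_ref <- 4995L
  reads <- data.frame(
    read_id = sprintf("r%04d", seq_len(5000L)), amplicon_id = "A",
    start = 7L, seq = c(rep("T", 5L), rep("C", n_ref)),
    qual = "]", n_passes = 10L, read_quality = 0.999,
    stringsAsFactors = FALSE)
  calls <- call_variants(build_pileup(reads, ext))
  expect_equal(calls$alt, "T")
  expect_equal(calls$allele_frequency, 0.001)
})

test_that("multiple alternative alleles at one position yield separate calls", {
  ref <- circular_reference(strrep("A", 40L))
  ext <- extend_reference(ref, 10L)
  reads <- do.call(rbind, lapply(1:18, function(i) {
    b <- c(rep("G", 6L), rep("T", 5L), rep("A", 7L))[i]
    make_read(paste0("r", i), 9L, b)
  }))
  calls <- call_variants(build_pileup(reads, ext))
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$alt, c("G", "T"))
  expect_true(all(calls$alt_depth <= calls$depth))
  expect_true(all(calls$allele_frequency > 0 & calls$allele_frequency <= 1))
})

test_that("homoplasmic differing positions are called above 99% at fraction 1", {
  ref <- tiny_reference(100L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = c(20L, 80L))
  cfg <- simulation_config(1, ref, panel, haps, extension_length = 60L,
                           coverage = 600, coverage_model = "fixed",
                           error_rate = 0.001, seed = 12)
  sim <- simulate_mixture_reads(cfg)
  pu <- build_pileup(filter_ccs(sim$reads), extend_reference(ref, 60L))
  calls <- call_variants(pu)
  for (p in c(20L, 80L)) {
    af <- calls$allele_frequency[calls$position == p]
    expect_length(af, 1L)
    expect_gt(af, 0.99)
  }
})

test_that("allele detection works where the tracked allele equals the reference", {
  ref <- circular_reference(strrep("G", 30L))
  ext <- extend_reference(ref, 10L)
  reads <- do.call(rbind, lapply(1:10, function(i) {
    make_read(paste0("r", i), 4L, if (i <= 6) "G" else "A")
  }))
  pu <- build_pileup(reads, ext)
  det <- allele_detections(pu, data.frame(position = 4L, allele = "G"))
  expect_true(det$detected)
  expect_equal(det$count, 6L)
  det2 <- allele_detections(pu, data.frame(position = 4L, allele = "A"),
                            min_depth = 5L)
  expect_false(det2$detected)  # 4 reads only
  expect_equal(det2$count, 4L)
})

test_that("amplicon attribution of calls reflects the observing amplicons", {
  ref <- circular_reference(strrep("A", 60L))
  ext <- extend_reference(ref, 20L)
  reads <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      make_read(paste0("a", i), 10L, "T", amplicon = "A"))),
    do.call(rbind, lapply(1:3, function(i)
      make_read(paste0("b", i), 10L, "T", amplicon = "B"))),
    do.call(rbind, lapply(1:10, function(i)
      make_read(paste0("c", i), 10L, ref_base(ref, 10L), amplicon = "A")))
  )
  pu <- build_pileup(reads, ext)
  calls <- call_variants(pu)
  call_t <- calls[calls$alt == "T", ]
  expect_equal(call_t$amplicons, "A,B")
  expect_equal(call_t$n_amplicons, 2L)
})
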