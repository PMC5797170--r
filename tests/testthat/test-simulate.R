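test_that("mixture fraction controls the haplotype of origin", {
  ref <- tiny_reference(100L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = c(20L, 80L))
  cfg0 <- simulation_config(0, ref, panel, haps, extension_length = 60L,
                            coverage = 50, coverage_model = "fixed", seed = 1)
  sim0 <- simulate_mixture_reads(cfg0)
  expect_true(all(sim0$truth$true_origin == "wildtype"))

  # 10,000 reads at fraction 0.1: mutant count within 3 sigma of binomial
  cfg <- simulation_config(0.1, ref, panel, haps, extension_length = 60L,
                           coverage = 5000, coverage_model = "fixed", seed = 2)
  sim <- simulate_mixture_reads(cfg)
  n <- nrow(sim$truth)
  expect_equal(n, 10000L)
  k <- sum(sim$truth$true_origin == "mutant")
  expect_lt(abs(k - n * 0.1), 3 * sqrt(n * 0.1 * 0.9))
})

test_that("error-free wildtype-only reads show only wildtype alleles", {
  ref <- tiny_reference(100L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = c(20L, 80L), wt_pos = 50L)
  cfg <- simulation_config(0, ref, panel, haps, extension_length = 60L,
                           coverage = 40, coverage_model = "fixed",
                           error_rate = 0, p_low_quality = 0, seed = 3)
  sim <- simulate_mixture_reads(cfg)
  pu <- build_pileup(sim$reads, extend_reference(ref, 60L))
  wt_eff <- brute_effective_sequence(haps$wildtype, ref)
  for (p in c(20L, 50L, 80L)) {
    col <- pu$columns[pu$columns$position == p, ]
    expect_equal(col[[wt_eff[p]]], col$depth)  # every read carries it
  }
})

test_that("identical seeds give identical simulations", {
  ref <- tiny_reference(100L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = 20L)
  cfg <- simulation_config(0.2, ref, panel, haps, extension_length = 60L,
                           coverage = 30, seed = 99)
  expect_identical(simulate_mixture_reads(cfg), simulate_mixture_reads(cfg))
})

test_that("the consensus-read filter applies both thresholds and keeps order", {
  reads <- rbind(
    make_read("r1", 1, "ACGT"), make_read("r2", 1, "ACGT"),
    make_read("r3", 1, "ACGT"), make_read("r4", 1, "ACGT"))
  reads$n_passes <- c(10L, 4L, 7L, 5L)
  reads$read_quality <- c(0.999, 0.999, 0.995, 0.985)
  kept <- filter_ccs(reads)
  expect_identical(kept$read_id, c("r1", "r3"))  # r2: passes, r4: quality
  expect_identical(filter_ccs(reads, min_passes = 4, min_quality = 0.98)$read_id,
                   c("r1", "r2", "r3", "r4"))
  empty <- reads[0, ]
  expect_equal(nrow(filter_ccs(empty)), 0L)
})

test_that("simulated reads respect the filter thresholds after filtering", {
  ref <- tiny_reference(100L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = 20L)
  cfg <- simulation_config(0, ref, panel, haps, extension_length = 60L,
                           coverage = 300, coverage_model = "fixed", seed = 4)
  sim <- simulate_mixture_reads(cfg)
  kept <- filter_ccs(sim$reads)
  expect_true(all(kept$n_passes >= 5L))
  expect_true(all(kept$read_quality >= 0.99))
  expect_gt(nrow(kept), 0L)
  expect_lt(nrow(kept), nrow(sim$reads))  # some reads fail the thresholds
})

test_that("mutant-origin read fraction concentrates on the mixture fraction", {
  ref <- tiny_reference(100L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = 20L)
  for (f in c(0.01, 0.1)) {
    cfg <- simulation_config(f, ref, panel, haps, extension_length = 60L,
                             coverage = 3000, coverage_model = "fixed",
                             seed = 7)
    sim <- simulate_mixture_reads(cfg)
    k <- sum(sim$truth$true_origin == "mutant")
    n <- nrow(sim$truth)
    ci <- qbinom(c(0.005, 0.995), n, f)
    expect_gte(k, ci[1])
    expect_lte(k, ci[2])
  }
})

test_that("at fraction zero, off-truth allele frequencies stay at the error floor", {
  ref <- tiny_reference(150L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = 30L)
  eps <- 0.005
  coverage <- 1000
  cfg <- simulation_config(0, ref, panel, haps, extension_length = 90L,
                           coverage = coverage, coverage_model = "fixed",
                           error_rate = eps, p_low_quality = 0, seed = 8)
  sim <- simulate_mixture_reads(cfg)
  pu <- build_pileup(sim$reads, extend_reference(ref, 90L))
  cols <- pu$columns[pu$columns$position != 30L, ]
  rb <- ref_base(ref, cols$position)
  nonref <- cols$depth -
    vapply(seq_len(nrow(cols)), function(i) cols[[rb[i]]][i], integer(1))
  bound <- eps * (1 + 5 / sqrt(eps * coverage))
  expect_true(all(nonref / cols$depth <= bound))
})

test_that("qPCR plate simulation is exact at zero noise and seeded", {
  p1 <- simulate_qpcr_plate(1, cq_noise_sd = 0, seed = 1)
  expect_equal(p1$cq_nuc - p1$cq_mt, c(0, 0))
  p2 <- simulate_qpcr_plate(1024, cq_noise_sd = 0, seed = 1)
  expect_equal(p2$cq_nuc - p2$cq_mt, c(10, 10))
  expect_identical(simulate_qpcr_plate(50, seed = 5),
                   simulate_qpcr_plate(50, seed = 5))
  p0 <- simulate_qpcr_plate(0, seed = 2)
  expect_true(all(is.na(p0$cq_mt)))   # no mitochondrial signal
  expect_true(all(!is.na(p0$cq_nuc)))
  expect_error(simulate_qpcr_plate(-1), "true_ratio")
})

test_that("reads survive a SAM round trip with identical pileups", {
  ref <- tiny_reference(100L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = c(20L, 80L))
  cfg <- simulation_config(0.3, ref, panel, haps, extension_length = 60L,
                           coverage = 25, coverage_model = "fixed", seed = 6)
  sim <- simulate_mixture_reads(cfg)
  ext <- extend_reference(ref, 60L)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim$reads, ext, sam)
  back <- read_sam(sam)
  expect_equal(nrow(back), nrow(sim$reads))
  expect_equal(back$seq, sim$reads$seq)
  expect_equal(back$n_passes, sim$reads$n_passes)
  pu1 <- build_pileup(sim$reads, ext)
  pu2 <- build_pileup(back, ext)
  expect_equal(pu2$columns, pu1$columns)
  expect_equal(pu2$by_amplicon, pu1$by_amplicon)

  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  expect_equal(length(readLines(fq)), 4L * nrow(sim$reads))
})

test_that("reverse-strand SAM records are reverse-complemented on ingest", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:miniM_extended\tLN:160",
    "fwd\t0\tminiM_extended\t5\t60\t4M\t*\t0\t0\tACGT\tIIII\tXC:Z:A",
    "rev\t16\tminiM_extended\t5\t60\t4M\t*\t0\t0\tACGT\tIIIH\tXC:Z:A"
  ), sam)
  reads <- read_sam(sam)
  expect_equal(reads$seq[reads$read_id == "rev"], "ACGT")  # rc of ACGT
  expect_equal(reads$qual[reads$read_id == "rev"], "HIII")
})

test_that("unsupported SAM records are rejected with the read name", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:x\tLN:160",
    "indel\t0\tx\t5\t60\t2M1I1M\t*\t0\t0\tACGT\tIIII"
  ), sam)
  expect_error(read_sam(sam), "indel")
})

test_that("simulation config validates its study parameters", {
  ref <- tiny_reference(100L)
  panel <- tiny_panel(ref)
  haps <- tiny_haplotypes(ref, mut_pos = 20L)
  expect_error(simulation_config(-0.1, ref, panel, haps,
                                 extension_length = 60L), "fraction")
  expect_error(simulation_config(1.5, ref, panel, haps,
                                 extension_length = 60L), "fraction")
  expect_error(simulation_config(0.1, ref, panel, haps,
                                 extension_length = 60L, error_rate = 0.2),
               "error_rate")
  expect_error(simulation_config(0.1, ref, panel, haps,
                                 extension_length = 10L), "extension_length")
})
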