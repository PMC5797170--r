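# Seeded simulator of circular-consensus amplicon reads from two-haplotype
# cell-line mixtures, with known ground truth kept in a sidecar table.

.BASES <- c("A", "C", "G", "T")
.BASE_RAW <- charToRaw("ACGT")
# .OTHER_RAW[i, ] = the three bases different from .BASES[i]
.OTHER_RAW <- matrix(charToRaw("CGTAGTACTACG"), nrow = 4L, byrow = TRUE)

#' Simulation configuration for mixture amplicon reads
#'
#' Defines the study conditions for one mixture sample: the mutant fraction,
#' the panel and haplotype pair, the per-amplicon coverage model, the
#' post-consensus substitution error rate and the consensus-read pass/quality
#' model. All randomness flows from the single `seed`.
#'
#' @param fraction Mutant mixture fraction in `[0, 1]` (probability that a
#'   molecule, hence a read, originates from the mutant haplotype).
#' @param reference A [circular_reference()].
#' @param panel An [amplicon_panel()] on `reference`.
#' @param haplotypes Named list with [haplotype_definition()] elements
#'   `mutant` and `wildtype`.
#' @param extension_length Extension used for read placement; must be at
#'   least the longest amplicon so no simulated read straddles the extension
#'   boundary.
#' @param coverage Reads per amplicon: the exact count under
#'   `coverage_model = "fixed"`, the median of a log-normal under
#'   `"lognormal"`.
#' @param coverage_model `"lognormal"` (default; emulates the wide
#'   per-amplicon spread seen in targeted long-read runs) or `"fixed"`.
#' @param coverage_sdlog Log-scale SD of the log-normal coverage draw
#'   (default 0.84, giving an interquartile range comparable to the median).
#' @param coverage_range Clipping bounds for the coverage draw.
#' @param error_rate Post-consensus per-base substitution probability,
#'   i.i.d., uniform over the three non-template bases; in `[0, 0.05]`.
#' @param pass_mean Mean of the shifted-Poisson pass-count model
#'   (`passes = 1 + Poisson(pass_mean - 1)`).
#' @param consensus_error_scale Scale of the phenomenological consensus-error
#'   model: predicted read accuracy is
#'   `1 - consensus_error_scale / sqrt(passes) * jitter` with lognormal
#'   jitter, so that accuracy improves with passes and the 99%-accuracy and
#'   5-pass filters are both active.
#' @param quality_high,quality_low,p_low_quality Per-base quality model:
#'   each base independently receives `quality_low` with probability
#'   `p_low_quality` and `quality_high` otherwise.
#' @param seed Integer seed; mandatory for reproducible simulation.
#' @param mixture_id Label attached to reads (default derived from
#'   `fraction`, e.g. `"0.1%"`).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(fraction,
                              reference = synthetic_reference(),
                              panel = default_amplicon_panel(reference),
                              haplotypes = default_haplotypes(reference),
                              extension_length = 3000L,
                              coverage = 4060,
                              coverage_model = c("lognormal", "fixed"),
                              coverage_sdlog = 0.84,
                              coverage_range = c(648, 34263),
                              error_rate = 0.001,
                              pass_mean = 9,
                              consensus_error_scale = 0.02,
                              quality_high = 60L,
                              quality_low = 20L,
                              p_low_quality = 0.1,
                              seed = NULL,
                              mixture_id = NULL) {
  coverage_model <- match.arg(coverage_model)
  if (is.na(fraction) || fraction < 0 || fraction > 1) {
    stop("mixture fraction must lie in [0, 1]")
  }
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error_rate must lie in [0, 0.05]")
  }
  if (coverage <= 0) stop("coverage must be > 0")
  max_amp <- max(panel$amplicons$length)
  if (extension_length < max_amp) {
    stop("extension_length (", extension_length, ") must be >= the longest ",
         "amplicon (", max_amp, ")")
  }
  if (extension_length > reference$length) {
    stop("extension_length must not exceed the reference length")
  }
  stopifnot(is.list(haplotypes),
            inherits(haplotypes$mutant, "haplotype_definition"),
            inherits(haplotypes$wildtype, "haplotype_definition"))
  structure(list(
    fraction = fraction, reference = reference, panel = panel,
    haplotypes = haplotypes, extension_length = as.integer(extension_length),
    coverage = coverage, coverage_model = coverage_model,
    coverage_sdlog = coverage_sdlog, coverage_range = coverage_range,
    error_rate = error_rate, pass_mean = pass_mean,
    consensus_error_scale = consensus_error_scale,
    quality_high = as.integer(quality_high),
    quality_low = as.integer(quality_low),
    p_low_quality = p_low_quality,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    mixture_id = mixture_id %||% format_fraction_percent(fraction)
  ), class = "simulation_config")
}

# Amplicon template sequence of one haplotype as raw bytes: reference
# substring with the haplotype's homoplasmic variants applied.
haplotype_amplicon_bytes <- function(ref, start, len, h) {
  bytes <- charToRaw(circ_substr(ref, start, len))
  if (nrow(h$variants)) {
    off <- ((h$variants$position - start) %% ref$length) + 1L
    hit <- off <= len
    if (any(hit)) {
      bytes[off[hit]] <- charToRaw(paste(h$variants$alt[hit], collapse = ""))
    }
  }
  bytes
}

#' Simulate consensus amplicon reads from a two-haplotype mixture
#'
#' Each read's haplotype of origin is drawn independently with
#' `P(mutant) = fraction`; its sequence is the haplotype-consistent amplicon
#' template (homoplasmic variants always applied, background heteroplasmies
#' applied per read with their fraction) with i.i.d. substitution errors at
#' the configured rate. Reads span their full amplicon and are placed on the
#' extended reference at the amplicon start, so origin-spanning amplicons map
#' contiguously. Truth labels (haplotype of origin) are returned only in a
#' sidecar table keyed by read id, never in the read table or any export.
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `reads` (data.frame: `read_id`, `amplicon_id`,
#'   `start`, `seq`, `qual`, `n_passes`, `read_quality`, `mixture_id`),
#'   `truth` (data.frame: `read_id`, `true_origin`, `amplicon_id`) and
#'   `config`.
#' @export
simulate_mixture_reads <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_rng_seed(cfg$seed, {
    ref <- cfg$reference
    amp <- cfg$panel$amplicons
    reads_list <- vector("list", nrow(amp))
    truth_list <- vector("list", nrow(amp))
    for (i in seq_len(nrow(amp))) {
      a_id <- amp$id[i]
      start <- amp$start[i]
      len <- amp$length[i]
      n <- switch(cfg$coverage_model,
        fixed = as.integer(round(cfg$coverage)),
        lognormal = as.integer(round(min(max(
          stats::rlnorm(1, meanlog = log(cfg$coverage),
                        sdlog = cfg$coverage_sdlog),
          cfg$coverage_range[1]), cfg$coverage_range[2])))
      )
      if (n < 1L) n <- 1L

      origin_mut <- stats::runif(n) < cfg$fraction
      wt_bytes <- haplotype_amplicon_bytes(ref, start, len, cfg$haplotypes$wildtype)
      mut_bytes <- haplotype_amplicon_bytes(ref, start, len, cfg$haplotypes$mutant)
      m <- matrix(rep(wt_bytes, n), nrow = len, ncol = n)
      if (any(origin_mut)) m[, origin_mut] <- mut_bytes

      # background heteroplasmies: per-read Bernoulli draw on the carrier
      # haplotype's reads only
      for (hap in c("wildtype", "mutant")) {
        bgs <- cfg$haplotypes[[hap]]$background
        if (!nrow(bgs)) next
        cols <- if (hap == "mutant") which(origin_mut) else which(!origin_mut)
        if (!length(cols)) next
        off <- ((bgs$position - start) %% ref$length) + 1L
        for (j in which(off <= len)) {
          carrier <- cols[stats::runif(length(cols)) < bgs$fraction[j]]
          if (length(carrier)) m[off[j], carrier] <- charToRaw(bgs$alt[j])
        }
      }

      # i.i.d. substitution errors, uniform over the three non-template bases
      n_bases <- len * n
      if (cfg$error_rate > 0) {
        n_err <- stats::rbinom(1L, n_bases, cfg$error_rate)
        if (n_err > 0L) {
          idx <- sample.int(n_bases, n_err)
          cur <- match(as.integer(m[idx]), as.integer(.BASE_RAW))
          pick <- sample.int(3L, n_err, replace = TRUE)
          m[idx] <- .OTHER_RAW[cbind(cur, pick)]
        }
      }

      # per-base qualities: binary high/low mixture
      qraw <- rep(as.raw(cfg$quality_high + 33L), n_bases)
      if (cfg$p_low_quality > 0) {
        n_low <- stats::rbinom(1L, n_bases, cfg$p_low_quality)
        if (n_low > 0L) {
          qraw[sample.int(n_bases, n_low)] <- as.raw(cfg$quality_low + 33L)
        }
      }

      full_seq <- rawToChar(as.vector(m))
      full_qual <- rawToChar(qraw)
      starts <- (seq_len(n) - 1L) * len + 1L
      seqs <- substring(full_seq, starts, starts + len - 1L)
      quals <- substring(full_qual, starts, starts + len - 1L)

      n_passes <- 1L + stats::rpois(n, cfg$pass_mean - 1)
      acc_err <- cfg$consensus_error_scale / sqrt(n_passes) *
        exp(stats::rnorm(n, 0, 0.5))
      read_quality <- pmax(0, pmin(1 - 1e-6, 1 - acc_err))

      ids <- sprintf("%s/%s/%05d", cfg$mixture_id, a_id, seq_len(n))
      reads_list[[i]] <- data.frame(
        read_id = ids, amplicon_id = a_id, start = start,
        seq = seqs, qual = quals, n_passes = n_passes,
        read_quality = read_quality, mixture_id = cfg$mixture_id,
        stringsAsFactors = FALSE
      )
      truth_list[[i]] <- data.frame(
        read_id = ids,
        true_origin = ifelse(origin_mut, "mutant", "wildtype"),
        amplicon_id = a_id, stringsAsFactors = FALSE
      )
    }
    list(reads = do.call(rbind, reads_list),
         truth = do.call(rbind, truth_list),
         config = cfg)
  })
}

#' Filter consensus reads on predicted accuracy and pass count
#'
#' Keeps reads with predicted consensus accuracy at or above `min_quality`
#' and at least `min_passes` passes of the circular template, the selection
#' applied to single-molecule consensus reads before alignment. Order is
#' preserved.
#'
#' @param reads Read data.frame with `read_quality` and `n_passes` columns.
#' @param min_quality Minimum predicted accuracy (default 0.99).
#' @param min_passes Minimum pass count (default 5).
#' @return The filtered data.frame.
#' @export
filter_ccs <- function(reads, min_quality = 0.99, min_passes = 5L) {
  if (!nrow(reads)) return(reads)
  stopifnot(all(c("read_quality", "n_passes") %in% names(reads)))
  keep <- reads$read_quality >= min_quality & reads$n_passes >= min_passes
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR Cq plate for a known mtDNA:nDNA ratio
#'
#' Replicate Cq pairs whose difference `cq_nuc - cq_mt` is centered on
#' `log2(true_ratio)` with Gaussian noise on each Cq. A ratio of 0 (no
#' mitochondrial template) yields an absent mitochondrial signal
#' (`cq_mt = NA`).
#'
#' @param true_ratio True mtDNA:nDNA molecule ratio (>= 0).
#' @param n_replicates Number of replicate runs (default 2).
#' @param cq_noise_sd Gaussian SD on each Cq value in cycles (0 for exact).
#' @param seed Integer seed.
#' @param base_cq_mt Center of the mitochondrial Cq (default 18 cycles).
#' @param sample_id Sample label.
#' @return data.frame with columns `sample_id`, `replicate`, `cq_mt`,
#'   `cq_nuc`.
#' @export
simulate_qpcr_plate <- function(true_ratio, n_replicates = 2L,
                                cq_noise_sd = 0.1, seed = NULL,
                                base_cq_mt = 18, sample_id = "S1") {
  if (is.na(true_ratio) || true_ratio < 0) {
    stop("true_ratio must be >= 0")
  }
  with_rng_seed(seed, {
    reps <- seq_len(n_replicates)
    if (true_ratio == 0) {
      cq_mt <- rep(NA_real_, n_replicates)
      cq_nuc <- base_cq_mt + stats::rnorm(n_replicates, 0, cq_noise_sd)
    } else {
      cq_mt <- base_cq_mt + stats::rnorm(n_replicates, 0, cq_noise_sd)
      cq_nuc <- base_cq_mt + log2(true_ratio) +
        stats::rnorm(n_replicates, 0, cq_noise_sd)
    }
    data.frame(sample_id = sample_id, replicate = reps,
               cq_mt = cq_mt, cq_nuc = cq_nuc, stringsAsFactors = FALSE)
  })
}

#' Format a mixture fraction as a percent label
#'
#' @param fraction Fraction(s) in `[0, 1]`.
#' @return Character labels such as `"0%"`, `"0.001%"`, `"10%"`.
#' @export
format_fraction_percent <- function(fraction) {
  paste0(vapply(fraction * 100, function(x) {
    format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1)), "%")
}
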