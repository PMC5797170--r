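---
title: "Models and methods behind mitodetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitodetect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodetect)
```

# Scope

`mitodetect` models the detection of low-frequency single-nucleotide
variants on the circular human mitochondrial genome from long-read amplicon
consensus sequencing, together with the closed-form quantitation that
surrounds such an assay: mtDNA purity from qPCR, enrichment folds, the
apparent heteroplasmy contributed by nuclear insertions of mitochondrial
origin (NUMTs), duplicate-read expectations for short-read data, and
copy-number detection models for orthogonal confirmation methods. This
vignette explains the models, the tunable parameters and their defaults,
what the simulator does and does not emulate, and the numerical choices
made where the design was genuinely open.

# Circular coordinates and the extended reference

All genomic positions are 1-based on a closed circle of length $L$
(16,569 bp for the default genome). Aligning reads to a linearized circle
biases the origin: a read spanning the junction has no contiguous
placement. The standard remedy, implemented in `extend_reference()`, is to
append the first $E$ bases of the circle to its end and align against the
$L + E$ bp linear sequence; any position $x$ on the extension folds back as
$((x - 1) \bmod L) + 1$ (`to_circle_position()`). The default $E = 3000$
exceeds the longest amplicon, so every amplicon — including the
origin-spanning one — maps contiguously and no simulated read straddles the
extension boundary. The pileup sums counts from body and extension
placements into a single circular column, which the tests verify against a
hand tally on junction-spanning reads.

# The amplicon panel

The panel abstraction (`amplicon_panel()`) is a set of closed circular
intervals whose union must cover the circle; consecutive amplicons overlap
so that positions in overlap regions are observed by two independent PCR
products. The published primer coordinates for whole-mtDNA tiling designs
live in supplements that are not machine-readable here, so
`default_amplicon_panel()` synthesizes the structural properties instead:
nine amplicons of 1,991 bp evenly spaced with 150 bp overlaps, the last one
spanning the origin. Amplicon lengths are kept inside the 1,700–3,000 bp
window that makes single-pass consensus reads practical while excluding
most NUMTs (the large majority of known NUMTs are shorter fragments). For
small test genomes the general constructor accepts arbitrary lengths and,
with `require_coverage = FALSE`, partial panels.

# Truth sets

The two haplotypes emulate a documented pair of breast-cancer cell lines:
29 homoplasmic variants on the mutant line and 13 on the wildtype line
relative to the reference, 7 of them concordant, leaving 28 positions with
different effective alleles. Twenty-three of those positions, with their
alleles and per-method empirical detection limits, ship as a plain-text
fixture (`load_lod_fixture()`); the remaining five differing positions are
synthetic placeholders (their published identities are heteroplasmic in
every mixture and were omitted from the fixture's source).

Those counts pin down the structure: with 29 and 13 alternative alleles and
7 concordant ones, exactly 6 of the 28 differing positions must carry the
alternative allele on the *wildtype* side. The five synthetic extras plus
fixture position 6371 play that role, so at those six positions the mutant
allele equals the reference base. Two consequences follow:

* variant calling against the reference sees those positions as
  near-homoplasmic wildtype alternatives, and
* limit-of-detection analysis must count *mutant-allele reads* in the
  pileup rather than require a non-reference call —
  `allele_detections()` exists for exactly this, and `lod_per_position()`
  consumes either detections or calls.

The reference itself (`synthetic_reference()`) is a deterministic random
16,569 bp sequence patched so the fixture alleles are consistent. It
reproduces the coordinate system and truth-set structure of the real
genome, not its composition: base-composition-dependent artifacts (e.g.
the true homopolymer landscape) are therefore only generically
represented.

# The simulator

`simulate_mixture_reads()` generates consensus amplicon reads for one
mixture:

* **Origin.** Each read's haplotype of origin is an independent Bernoulli
  draw with $P(\text{mutant}) = f$, the mixture fraction. The dilution
  design defaults to $f \in \{0, 10^{-5}, 10^{-4}, 10^{-3}, 10^{-2},
  10^{-1}\}$.
* **Template.** The read spans its whole amplicon; homoplasmic variants of
  the origin haplotype are always applied, background heteroplasmies
  per read with their population fraction. The default background pattern
  follows the documented wildtype-phased spectrum (one ~24% variant, one
  ~7%, several at or below ~1%) plus a few low-level mutant-phased
  variants.
* **Errors.** Post-consensus substitutions are i.i.d. at rate
  $\varepsilon$, uniform over the three non-template bases. The default
  $\varepsilon = 0.001$ is chosen so the 0.1%-allele-frequency regime is
  realistically marginal under the five-read rule: at that rate detection
  at 0.1% succeeds or fails on depth, mirroring the empirically observed
  depth-limited detection limits. Indels are not simulated; the pileup
  ignores them by construction.
* **Coverage.** Per-amplicon read counts default to a log-normal with
  median 4,060 and log-SD 0.84 (interquartile range comparable to the
  median), clipped to [648, 34,263] — the documented spread of targeted
  long-read runs. Tests use `coverage_model = "fixed"` for exact depths.
* **Pass counts and accuracy.** Passes follow a shifted Poisson
  ($1 + \mathrm{Pois}(8)$). Predicted accuracy is a phenomenological
  $1 - c/\sqrt{\text{passes}} \cdot e^{\eta}$ with $c = 0.02$ and lognormal
  jitter $\eta \sim N(0, 0.5)$ — accuracy improves with passes but is not
  determined by them, so the two consensus-read filters (≥5 passes, ≥99%
  accuracy, `filter_ccs()`) are both active. A scale that made typical
  accuracies fall below 99% would silently empty the dataset through the
  quality filter; $c = 0.02$ places the typical read at ≈99.3% accuracy,
  with ~25% of reads failing one of the two filters.
* **Base qualities.** Each base independently receives quality 60 (90%)
  or 20 (10%), a stylized two-component model that gives the
  `min_base_quality = 30` pileup filter real work without modeling
  instrument physics.
* **Truth labels** (haplotype of origin) live only in a sidecar table keyed
  by read id — never in the read table, the SAM dialect or FASTQ output —
  so the pipeline cannot use them.

All randomness flows from a single integer seed; identical configurations
and seeds give identical outputs byte for byte.

What the simulator does **not** emulate: raw polymerase reads and the
consensus algorithm itself, PCR duplicate lineages and chimeras, primer
artifacts, indels, strand effects, and the true base composition of the
real genome. Passing tests therefore demonstrate the pipeline's statistical
behavior under the stated error model, not robustness to every artifact
class of real instruments.

# Pileup and calling thresholds

`build_pileup()` counts A/C/G/T bases with quality at or above
`min_base_quality = 30`; `N` bases and sub-threshold bases are never
counted, and allele-frequency denominators include only counted bases.
Mapping quality is accept-all by design (single-contig alignment).
`call_variants()` emits one call per (position, non-reference allele) with
at least `min_alt_depth = 5` reads — five independent high-quality
observations being the evidence standard that suppresses isolated PCR or
sequencing errors — and records the amplicons observing the allele.
Positions with zero filtered depth are omitted; multiple alternative
alleles at one position yield multiple calls. Reported allele frequencies
are displayed at two significant figures, full precision internally.

# De novo classification, artifact flags and validation

Calls matching a documented homoplasmic variant (position *and* allele)
are `documented_homoplasmic`; all others are `de_novo`. Two artifact
screens encode, as explicit rules, what is conventionally judged by visual
inspection: adjacency to a reference homopolymer run (run length ≥ 4,
including the bordering base on each side, with runs merged across the
origin) and proximity to a documented homoplasmic variant (circular
distance ≤ 5 bp). Both cutoffs are configurable; no published numeric
values exist for the visual screen, and these defaults reproduce its
intent.

A de novo allele observed in two or more mixtures is
`validated_multi_mixture`; observed in one mixture but in two overlapping
amplicons, `validated_overlap`; otherwise `unvalidated`. Allele-frequency
agreement across mixtures is deliberately not required — background
heteroplasmies drift across dilution points. Unvalidated calls pass the
conservative reporting rule only at ≥1% allele frequency, the threshold at
which single-observation calls become reliable without orthogonal
confirmation.

# Phasing

`phase_variant()` makes the manual long-read phasing procedure
algorithmic. For every read carrying the variant allele, the bases at
documented differing positions (anchors) inside the read span are compared
with both haplotypes. A read is informative if at least one anchor base
matches exactly one haplotype; anchor bases matching neither (sequencing
error at the anchor) are ignored rather than counted against — penalizing
phasing for independent errors would bias it toward `ambiguous`. A read
votes for the haplotype matching the majority of its informative anchors;
the variant is assigned when at least `min_informative = 5` reads are
informative and at least `concordance_min = 0.9` of them agree. Both
defaults mirror the calling module's five-read evidence standard; the
manual procedure states no numbers.

# Limit of detection and detection models

`lod_per_position()` reports, per tracked position, the smallest design
fraction at which the mutant allele was detected; the 0% mixture is
excluded (anything seen there is background, not a detection limit).
`sensitivity_at()` summarizes a method's LOD column as the percentage of
analyzed positions detectable at or below a level, counting
never-detected positions in the denominator.

The orthogonal methods are modeled at the molecule level:
`detection_probability()` evaluates $P(X \ge k)$, $X \sim
\mathrm{Binomial}(n, f)$ exactly, with $k = 2$ (digital PCR, within its
≈20,000-partition capacity), $k = 3$ (single-base extension mass
spectrometry) and $k = 5$ (sequencing reads). For digital PCR this equates
"≥2 variant copies" with "≥2 positive partitions", ignoring multi-copy
partitions — valid in the dilute regime (≤20,000 copies in 20,000
partitions) and increasingly conservative beyond it; no Poisson occupancy
correction is applied.

# Numerical and degenerate-input choices

* qPCR replicates are averaged on the Cq scale before the delta; a sample
  with no nuclear signal receives the ratio cap 2×10⁷ (≈99% mtDNA).
* Enrichment folds are ratios of percentages, matching how such folds are
  conventionally reported; `expected_duplicate_fraction()` counts
  single-strand start positions by default, with a strand-aware variant.
* Empty pileups yield empty call tables, not errors; reads extending past
  the extended reference are rejected with the offending read id.
* Reverse-strand SAM records are reverse-complemented on ingest so all
  internal logic is forward-strand; the SAM dialect forbids indel CIGARs.
* Ties in phasing (equal anchor votes) make a read non-concordant but
  still informative, so a 50/50 read weakens rather than flips an
  assignment.

# Problem sizes used by the test suite

The suite validates behavior at sizes chosen to keep the statistics
informative: end-to-end mixture-fraction recovery runs two dilution points
(1% and 10%) at 10,000× fixed coverage on the full 16,569 bp genome,
checking every differing position's alternative-read count against the
exact binomial 99% band at the error-model allele fraction — note that
with 56 simultaneous 99% bands, occasional single-position excursions are
expected behavior of a correct implementation, not evidence of bias.
Phasing fidelity uses 200 replicate simulations on a 400 bp test circle;
the calling stage's detection rate is compared with the closed-form
binomial tail over 500 replicates at 400× depth; zero-fraction
false-positive behavior uses 200 replicates of a single full-length
amplicon at 400× coverage. Unit tests run on 100–200 bp circles where
brute-force oracles (per-read, per-base tallies; character-level haplotype
comparison; term-by-term binomial summation) are cheap.

# Known limitations

* The reference and five of the 28 differing positions are synthetic;
  analyses tied to the real genome's sequence context (homopolymer
  landscape, NUMT homology) are only structurally representative.
* The error model is i.i.d. substitution; correlated errors (PCR jackpot
  events, context-dependent miscalls) are exactly what the multi-mixture /
  overlap validation is designed to catch in real data, but they are not
  simulated, so validation specificity against such artifacts is not
  measured here.
* Overlap validation accepts one supporting read in the second amplicon;
  with deep pileups and a nonzero error floor this is permissive, and the
  conservative ≥1% rule remains the effective guard for unvalidated
  calls.
* Phasing assumes exactly two haplotypes and anchor-rich amplicons;
  multi-clone deconvolution and cross-amplicon statistical phasing are out
  of scope.
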