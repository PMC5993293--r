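---
title: "Methods: accessibility, footprinting and co-association on synthetic regulatory genomics data"
author: "accessilate"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`accessilate` implements the bespoke computations behind a
regulatory-genomics study of how a transcription factor (the NF-κB
subunit p65, through its TA3 region and the co-factor Zbtb7a) controls
promoter accessibility: DNase-I cut-site coverage and normalization,
empirical-null differential accessibility, cleavage-bias-corrected
footprinting, peak co-occurrence statistics, label-swap SILAC screen
scoring, and rule-based expression target classification. Alignment,
peak calling, motif discovery and microarray preprocessing are upstream
of the package: mapped tags, peak calls, motif instances and normalized
log2 signals are its inputs. Because the real datasets are genome-scale,
every stage is exercised instead on synthetic data with planted ground
truth; the generators are first-class, tested code.

# Coverage, depth and DHS-anchored normalization

Read tags are width-1 stranded positions with fractional weights (a read
mapping to *k* ≤ 5 locations contributes 1/*k* at each; weights are
never rounded). Tags are extended 3′-ward to the sample's mean fragment
size — 300 bp for ChIP, 200 bp for DHS-recovered DNA, 1 bp to mark the
individual DNase cut site — and per-base coverage is the weight sum of
overlapping fragments, so window means are mean overlapping fragments
per bp. Coordinates are 0-based half-open on disk (BED/bedGraph dialect)
and 1-based closed inside R's `GRanges` containers.

Tracks are scaled to a nominal depth of 20 million reads. For
cross-sample accessibility comparisons a second, anchored normalization
equalizes the total cut-site weight under DHS peaks across samples, so
differences in the background read fraction do not distort accessibility
measurements. The common target is the geometric mean of the in-peak
totals, chosen (over, say, "match the first sample") to make the result
invariant to sample order. The approach assumes mean accessibility over
all DHS regions is approximately equal between samples; a coordinated
genome-wide accessibility shift would be partially absorbed by the
scaling and the resulting calls would be conservative.

Excess duplicate reads at a single (chromosome, position, strand) are
treated as likely PCR artefacts and capped. The count model is Poisson
with mean equal to the local per-position read density in a centred 1 kb
strand-specific window, and the cap is the largest count whose
upper-tail probability still reaches α = 10⁻³ (`qpois(1 - α, λ)`). The
Poisson law and the 1 kb window are package defaults: a duplicate filter
"based on the local level of coverage" needs a count law, and Poisson is
the minimal one; both parameters are exposed.

# Empirical-null differential accessibility

Per-promoter accessibility is the mean cut frequency in a window
anchored on the TSS: ±600 bp for summary statistics, or the 1 kb
interval upstream of the TSS (strand-oriented) for regulation calls.
Windows clipped at chromosome edges renormalize by realized width.

Rather than a parametric model, regulation calls use an empirical null:
thresholds are the 95th (loose) and 99th (strict) percentiles — linear
interpolation between order statistics, R's type-7 quantile — of the
signed delta distribution at factor-negative promoters, per tail. A
promoter is called increased only if its delta *strictly exceeds* the
upper threshold (mirrored for decreased), so a promoter exactly at the
threshold is unchanged and strict calls are nested inside loose calls.
Two percentiles are fitted independently per tail from the signed null;
the combined null call rate at the loose cutoff is therefore ~10% (5%
per tail), which matches reading the cutoff as a per-tail "P < 0.05".
The alternative two-sided reading is not implemented.

# Cleavage-bias-corrected footprinting

DNase-I cuts with a strong intrinsic sequence preference; uncorrected
cut profiles across motifs mostly reflect that bias. The package learns
an expected relative cut rate for each of the 4⁶ 6-bp contexts as the
mean cut frequency over all positions with that context inside DHS
regions. Registration is symmetric — 3 bases 5′ and 3 bases 3′ of the
cut base on the forward strand — and isolated in one function, since
"surrounding 6 bp" admits several alignments. A pseudocount of one
observation at the DHS-wide mean per context keeps all rates strictly
positive in sparse simulations. Dividing a track by its own learned
expectations averages to exactly 1 over the DHS positions as the
pseudocount vanishes, which the tests assert.

Footprint profiles aggregate across strand-oriented motif instances:
per aligned position, the ratio of the mean observed cut weight to the
mean expected rate from each instance's local context
(mean-of-observed over mean-of-expected, which is stabler at low counts
than averaging per-instance ratios). Minus-strand instances are
coordinate-reversed before aggregation. After correction, ratios can be
below *or* above 1 within a bound motif, depending on which nucleotides
binding exposes.

The footprint magnitude *M* is the mean ratio over the 10 bp around the
motif centre minus the mean over background positions, defined here as
21–50 bp from the centre on both sides (the background band is a
package default; it must not intersect the central window). The sign is
retained. *M* understates asymmetric or complex footprints; it is a
summary, not a per-instance binding predictor. Condition contrasts
report ΔM = M(control) − M(knockdown) with a seeded bootstrap SE over
motif instances (default 1,000 resamples).

One synthetic-data caveat: all planted instances share one consensus, so
the motif's central hexamers are heavily over-represented at protected
positions inside the DHS training set and the learned bias partially
absorbs the footprint, compressing |M| (in real data a single 6-mer's
motif occurrences are diluted across the genome). Ordering across
occupancies survives; tests that assert the closed-form central ratio
(e.g. 0.75 at 50% occupancy and half-depth protection) therefore supply
the generator's exact bias table as the expectation model, while tests
of the learning path use unbound simulations where no absorption exists.

# Peak co-occurrence and co-association

Overlap counting expands the reference set by a symmetric slop
(±500 bp for promoter windows), merges it so nested references are not
double-counted, and counts each query peak at most once on a ≥ 1 bp
half-open intersection. Two null models are available:

* **Binomial**: each of *n* query peaks hits with probability equal to
  the merged expanded-reference coverage fraction; significance is the
  upper tail P(X ≥ k).
* **Gap-retaining randomization**: the circular sequence of (peak
  width, following gap) pairs on each chromosome is rotated to a random
  first peak and re-laid from a uniform random origin; draws that would
  wrap a peak across the chromosome end are rejected and redrawn. This
  preserves the per-chromosome width and inter-peak distance multisets
  exactly — the strongest reading of "retaining interpeak distances" —
  whereas independent re-placement would destroy the clustering
  structure. The default 900 randomizations move the query set only
  (a flag randomizes both sets), and the empirical P uses the add-one
  estimator (1 + #{k_rand ≥ k_obs})/(N + 1), so 0 is unattainable and
  the smallest reportable value is 1/901.

Co-association of two datasets over a region universe uses the binary
indicator vectors: φ² from the 2×2 table, identical to the squared
Pearson correlation of the indicators (asserted to 10⁻¹² in tests), and
the Jaccard index a/(a+b+c). Dataset rankings sort by descending φ²,
ties by Jaccard then dataset name, so ranks are deterministic.

# SILAC label-swap screen scoring

Each pull-down replicate observes heavy/light ratios; in a label-swap
design the functional bait takes each label in half the replicates.
Ratios are re-oriented so the functional bait is in the numerator and
combined per protein as the mean of log2 ratios over detected
replicates — the geometric mean of ratios, symmetric between enrichment
and depletion (the arithmetic mean is available behind a flag). Any
multiplicative label bias applied antisymmetrically to swapped pairs
cancels exactly in the combination; this is an algebraic identity and is
tested as such. Each protein receives an upper-tail empirical P,
(1 + #{proteins ≥ it})/(n + 1) with ties counting as ≥, and
Benjamini–Hochberg q-values; with purely rank-based P values over one
screen the q-values are conservative by construction. Proteins flagged
as promiscuous binders (recovered with a control bait) are annotated,
never silently removed.

# Expression target rules

Differential expression between groups of 3 replicates uses the
unpaired two-tailed Student *t* (equal-variance, df = n₁+n₂−2),
vectorised over genes; Welch is available behind a flag since the
study's statistical-methods text and its dataset-analysis text disagree
on the variance assumption. Zero-variance degenerate cases return p = 1
at equal means and p = 0 otherwise.

Classification rules are applied verbatim with the printed comparison
operators: TA3-responsive promoters need (TA3 − ko) ≥ 0.5 and
(p65 − ko) ≥ 0.4; TA3-nonresponsive need (p65 − ko) ≥ 0.5 and
(TA3 − ko) < 0.4; both require a high-confidence peak
(−10log₁₀P strictly greater than 50) within 2 kb of the TSS, measured
TSS-to-summit by default (edge distance behind a flag; the prose is
ambiguous). Direct targets are the union. Zbtb7a-regulated expression
grades (TA3 − knockdown) deltas at ≥ 0.5 ("+++") and ≥ 0.2 ("+"),
mirrored for down-regulation, each gated at t-test P < 0.05; strong
labels are nested in weak ones. Top-N target lists keep the N largest
|delta| among P < 0.05 genes, ties broken by gene id for determinism.

# The synthetic study

One configuration object drives every generator; each generator is a
pure function of (config, seed). Defaults define the study conditions:

* Genome: 2 chromosomes × 2 Mb of uniform-random sequence; ~500
  promoters (TSS ± 1 kb, random strand), ~100 enhancers; open-chromatin
  windows of ±600 bp around each TSS/enhancer midpoint form the DHS set.
  This scale keeps the full suite and the end-to-end run in minutes on
  one CPU while leaving ≥ 100 factor-negative promoters for the
  empirical null.
* Cut-site tracks: per-base Poisson counts with rate = 0.05 cuts/bp ×
  a seeded log-normal (sdlog 0.3) per-hexamer factor × an accessibility
  factor of 10 inside open windows × occupancy protection
  (1 − occupancy × 0.5) over the central 10 bp of each planted motif.
  Occupancy is 0.8 in control and 0.2 after knockdown; at dependent
  promoters knockdown also shrinks the accessibility bump to 40%. The
  log-normal bias is strong enough that uncorrected profiles are
  visibly distorted, which the correction tests exploit.
* Peak pairs: set A uniform; each B peak co-located with a random A
  peak with probability ρ (default 0.5), realized co-locations reported
  as truth.
* Expression: four groups (p65ko, +p65, +p65 TA3, shZbtb7a +p65 TA3) ×
  3 replicates, signal = baseline + group effect + N(0, 0.1). Planted
  classes carry the rule-defining effects (0.6/0.5 for TA3-responsive,
  with a high-confidence peak planted within 2 kb; ±0.6/±0.3 for the
  strong/weak knockdown classes).
* SILAC: 700 proteins, 5 binders at log2 ratio 2, heavy-label bias
  factor 2, 4 label-swapped replicates with N(0, 0.5) log2 noise.

What the generators deliberately do not emulate: mappability and repeat
structure, fragment-length variation, replicate-level biological
variance in tracks, correlated gene-gene expression, and real motif
degeneracy. Passing tests therefore demonstrate the computations are
correct under their stated models, not that the models capture every
property of real chromatin data.

# Calibration of the recovery scorecard

The end-to-end scorecard checks that each stage recovers its planted
truth. Two recovery bands deserve explanation because the planted
margins are deliberately tight. The TA3 rule threshold (0.5) sits 0.1
below the planted effect (0.6); the delta of two 3-replicate means at
noise sd 0.1 has sd 0.1·√(2/3) ≈ 0.082, and the two qualifying deltas
share the p65ko mean (correlation 0.5), so the expected recall of
planted TA3-responsive labels is P(both deltas pass) ≈ 0.82, not ~1 —
recall approaching 1 would require per-replicate noise below ~0.06.
Precision, by contrast, is essentially 1, because null genes sit ~6 sd
below the threshold. The scorecard therefore asserts recall ≥ 0.65
(about 5 binomial sd below the 0.82 expectation at 60 planted genes)
and, by the same propagation, Zbtb7a strong-up recovery ≥ 0.75
(expectation ≈ 0.89). These bands were fixed from the noise model, not
tuned to runs.

# Numerical and degenerate-input choices

* Summits default to the interval midpoint with ties to the lower
  coordinate; an explicit summit column overrides.
* Intervals clipped at chromosome edges are truncated, not discarded;
  tags outside bounds are rejected with a warning.
* Percentile thresholds interpolate linearly between order statistics;
  at least 100 null regions are required.
* Peak randomization rejects layouts that wrap a peak across the
  chromosome end (bounded retries), and errors if peaks cover the whole
  chromosome.
* φ² on a constant indicator returns NaN with a warning rather than a
  silent 0.
* All randomized procedures take explicit seeds; the empirical overlap
  test records its randomization count in its result.

# Known limitations

* The bias-absorption effect above makes absolute |M| values on
  synthetic consensus plantings smaller than the generative protection
  depth; only orderings and oracle-bias ratios are interpreted.
* The empirical P of the SILAC screen is a within-screen rank statistic;
  it cannot reach below 2/(n+1) and its BH q-values are conservative.
* The duplicate-filter law (Poisson, 1 kb window) is a modelling default
  for a procedure whose source describes only "statistically excess
  reads"; alternatives (e.g. negative binomial for overdispersed
  libraries) are not implemented.
* The gap-retaining null randomizes the query set by default; moving
  both sets is available but the two choices answer slightly different
  questions about which set's positional structure is held fixed.
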