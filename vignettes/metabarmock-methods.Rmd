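---
title: "Methods: simulating and analysing a mock arthropod metabarcoding experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a mock arthropod metabarcoding experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabarmock)
```

## Scope and model

`metabarmock` models a benchmark that is common in metabarcoding method
work: a *mock community* — an assemblage of known species composition —
is pooled, amplified with degenerate COI primers, sequenced on several
platforms, and the reads are pushed through a standard
assignment/diversity pipeline. Because the truth is known, every failure
mode (pooling bias, PCR primer-mismatch bias, platform error, filtering
loss) is measurable. The package provides both halves: a generative
simulator with known ground truth, and the analysis chain whose behaviour
it is designed to probe.

The generative chain is, per sample:

1. **Community.** `generate_community()` builds `n` species records.
   Barcodes are 658 bp sequences derived from a random ancestor by
   per-site substitution (default rate 0.08), with rejection sampling
   enforcing an uncorrected pairwise divergence above 2% — the rule used
   to select well-separated species proxies (BINs) in real mock
   communities. Real COI sequences are deliberately not downloaded; the
   analyses under test depend on the divergence structure, not on
   phylogenetic realism, and this keeps the package self-contained.
   Abdominal masses span a 7,500-fold range (log-uniform by default,
   extremes pinned so the realized ratio is exact). Primer-binding sites
   with known mismatch counts are spliced into fixed barcode coordinates;
   the counts are drawn from per-primer distributions whose defaults put
   ~17% of species at ≥4 forward mismatches for the short (407 bp)
   amplicon class and ~5% for the long (463 bp) class, mirroring the
   observed contrast between the two forward primers (62 vs 18 of 369
   species beyond 3 mismatches).
2. **Template pool.** Template share is proportional to
   mass^`b` times lognormal noise. `b` defaults to 0.66 for bulk-abdomen
   pools (the allometric exponent linking mitochondrial copy number to
   body mass), is smaller for leg-based bulk pools, and is 0 for the
   single-leg (equalized) regime. With noise off, the share ratio equals
   `mass_ratio^b` exactly — 7500^0.66 ≈ 360.
3. **PCR.** Amplicon share multiplies template share by
   `(1 + e · s^m)^c`, with per-cycle efficiency `e` (default 0.12),
   per-mismatch penalty `s` (default 0.85), `m` the species'
   primer--template mismatch count (best-of-cocktail forward plus
   reverse) and `c = 40` cycles (two rounds of 20). This is the simplest
   mechanism that makes read count decline smoothly with mismatch count;
   the defaults give roughly a 1.9-fold drop per mismatch, strong enough
   to reproduce the qualitative "decline after two mismatches" without
   erasing high-mismatch species entirely. The mechanism's parameters are
   free simulator knobs, not measured quantities.
4. **Reads.** Reads are drawn multinomially from the amplicon shares.
   Platform profiles are deliberate caricatures: `miseq_like` is paired,
   fixed-length, flat-quality, low-error; `s5_like` and `pgm_like` are
   single-end, variable-length, with linearly declining 3' quality and
   more indels. No published per-platform error rates were available to
   calibrate against, so the defaults are chosen to exercise the QC rules
   (the pgm-like profile loses a visible fraction of long reads to the
   Q20-fraction rule) rather than to mimic any instrument quantitatively.
   The source species is recorded in each read id, which is what makes
   planted-truth tests possible.

## Analysis chain

**QC** (`run_qc`) applies the filtering rules of the hosted pipeline the
simulation emulates, in printed order: mates merged at the best overlap
of ≥20 bp with ≤10% mismatches (higher-QV base kept at conflicts); reads
discarded on mean QV < 20, then >25% of bases below Q20, then >5% below
Q10 (strict comparisons, first failure reported); a 30 bp 5' trim
(forward primer) followed by truncation to the class target length
(407/463) and a class minimum length (300/350). "Mean QV" is the
arithmetic mean of Phred scores, the common reading. The head trim is by
definition not idempotent (it always removes 30 bp); the truncation step
is, and the tests pin that reading. The QC report conserves counts on any
input.

**Assignment** (`assign_reads`) matches each read to the
minimum-distance reference if that distance is < 3%, ties broken by
library order. Distance is computed on a semi-global alignment (end gaps
free — reads are truncated amplicon substrings), over aligned columns
where both sequences have an unambiguous base. Uncorrected p-distance is
the default for thresholding (conservative, fast); the Kimura
two-parameter correction is available where transition/transversion
structure matters, returning an `Inf` sentinel at saturation. The kernel
is a compiled banded aligner seeded by 12-mer diagonal voting (band ±16,
full-width fallback when no seed exists); `Biostrings::pairwiseAlignment`
with identical scoring serves as the independent oracle in the test
suite, not as the production path, because per-call S4 dispatch is two
orders of magnitude too slow at planted-truth scale. Candidate references
are shortlisted by shared 6-mer content (`top_n = 8`); with references
separated by >2% this shortlist effectively always contains the nearest
reference, and `prescreen = FALSE` restores the exhaustive contract.

**OTUs** (`cluster_unmatched`): unmatched reads are dereplicated, sorted
by descending abundance (ties lexicographic), and clustered greedily at
2%: a sequence joins the first (oldest) centroid within threshold, else
founds an OTU. Only a threshold is prescribed by the emulated pipeline;
greedy abundance-sorted clustering with fixed tie-breaks was chosen for
determinism and is validated against a brute-force oracle.

**Rarefaction** (`accumulation_curve`) subsamples without replacement —
the standard reading of random subsampling — at the depth grid
10^2 … 10^6 in half-decade steps (10,000 replicates by default), using
exact sequential-hypergeometric draws vectorized across replicates. The
mean curve is checked against the closed form
E[S] = Σᵢ (1 − C(N−nᵢ, d)/C(N, d)). An asymptote is declared at the left
endpoint of the first consecutive pair with slope < 0.01. The axis for
the slope denominator is not stated by the emulated protocol; the
default is the linear read axis (units: new taxa per read, which makes
the 0.01 threshold meaningful at these depths), with `slope_axis =
"log10"` available since accumulation plots are log-scaled.

**Diversity** (`diversity_report`): indices are computed on relative
abundances after a strict >0.01% floor (a row at exactly 0.01% is
excluded), per the sentence order of the emulated protocol; natural logs
throughout (vegan convention); Pielou returns an `NA` sentinel at S = 1;
the coefficient of variation uses the sample (n−1) standard deviation.
Recovery is reported under both criteria (≥1 read; >0.01% of reads) —
the second is never the larger. Bray–Curtis dissimilarities feed a
single-linkage dendrogram (`hclust`), serialized as Newick via `ape`.
Kendall tau is tau-b with tie-corrected normal-approximation p-values.

**Depth model** (`depth_model_table`): for PCR-free protocols, a random
genomic read covers the barcode with probability 0.05 × 0.01 = 1/2,000
(barcode share of the mitogenome × mitochondrial share of cellular DNA).
One retained read per species therefore costs 374 × 2,000 = 748,000 ≈
750,000 reads. Recovering 95% of 374 equally sampled species is a coupon
collector problem; the expectation Σ_{i=0}^{k−1} N/(N−i) with
k = ⌈0.95·374⌉ gives ≈3 draws per species, hence 2.25 million reads.
The printed source formula ("N∑ 1/(N−i−1)") has ill-defined index
bounds; the standard form above is implemented and reproduces every
printed number. Body-mass skew multiplies the requirement by the
template ratio `R^b` (nearest ten: 7500^0.66 → 360, giving 810 million;
178^0.66 → 30, giving 67.5 million after excluding the lightest 5% of
specimens). Headline values chain the *rounded* factors exactly as the
worked example does; raw values are always reported alongside. A
Monte-Carlo collector (`simulate_coupon`) with arbitrary weights serves
as the model's oracle and quantifies how unequal template shares inflate
the expectation.

## What a green test establishes (and what it does not)

The simulator reproduces the *statistical structure* the analyses
assume: divergence-separated references, mass- and mismatch-biased
abundances, platform-dependent quality/error. It does not model
phylogenetically realistic sequence evolution, chimeras, NUMTs,
contamination, quality-score miscalibration, or PCR saturation; a green
qualitative test (e.g. "single-leg pools are more even than bulk
pools") therefore validates the pipeline's behaviour under the stated
generative model, not any claim about a particular real instrument or
taxon. Real-data results that depend on the deposited sequencing runs
(per-platform recovery percentages, index values, dendrogram topologies)
are deliberately out of scope; seeded simulation properties cover their
qualitative direction only.

## Numerical choices and degenerate inputs

- Determinism: every generator takes a seed; identical seeds give
  byte-identical outputs.
- Rejection sampling failures (community too constrained) raise explicit
  errors naming the constraint rather than degrading silently.
- k2p saturation and single-species Pielou return sentinels (`Inf`,
  `NA`) instead of numbers that would be silently wrong.
- Rarefaction at depths beyond the sample total returns full-depth
  richness with a warning; depth grids are trimmed to the total.
- Assignment ties (exactly equal distances) resolve to the earliest
  library entry; OTU ties resolve by abundance then lexicographic order.
- Merging scans overlaps longest-first and keeps the lowest mismatch
  fraction, so a perfect long overlap short-circuits the scan.

## Worked example

```{r example, eval = FALSE}
cm <- generate_community(community_spec(n_species = 50, seed = 1))
smp <- simulate_sample(cm, treatment = "bulk_abdomen",
                       platform = "s5_like", amplicon_class = 407,
                       depth = 5000, seed = 7)
res <- analyze_sample(smp, cm)
rec <- recovery_rate(res$counts[cm$bin_id], cm$bin_id, "any_read")
curve <- accumulation_curve(res$counts,
                            rarefaction_config(n_replicates = 1000,
                                               seed = 1))
asymptote_depth(curve)
depth_model_table(depth_model_params())
```
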