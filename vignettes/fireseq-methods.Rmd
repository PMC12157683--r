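---
title: "Calling regulatory elements from m6A-stenciled fibers: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling regulatory elements from m6A-stenciled fibers: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireseq)
library(data.table)
```

## The measurement and the model

Fiber-seq stencils chromatin architecture onto single DNA molecules: a
non-specific adenine methyltransferase deposits m6A wherever DNA is not
protected by a nucleosome or another bound protein, and each multi-kilobase
read then reports, base by base, which parts of that one molecule were
accessible. `fireseq` turns those per-molecule m6A calls into regulatory
element calls in five stages.

**1. Segmentation.** Protected stretches (nucleosome footprints) are m6A
deserts. The caller is a four-phase heuristic over each fiber's sorted m6A
offsets: (i) every maximal m6A-free run of at least `n = 75` bases is a
candidate footprint; (ii) every stretch of at least `c = 100` bases
containing exactly one internal m6A — a putative false-positive call — is a
candidate; (iii) a candidate extends across one adjacent m6A whenever doing
so gains at least `e = 25` unmethylated bases, left side attempted before
right; (iv) phase (iii) repeats to a fixed point. A run between marks at
offsets $i < j$ is the open interval $(i, j)$ of length $j - i - 1$; read
ends count as boundaries, so a terminal extension is bounded by the read
end. When an extension leaves two candidates separated by only the spanned
m6A they merge, which keeps footprints disjoint. Everything between
footprints is a methyltransferase-sensitive patch (MSP) — the unit all later
stages classify. The three parameters are in units of bp; `n` sets the
smallest protected stretch believed to be a nucleosome rather than chance,
`c` the evidence needed to forgive one stray m6A, and `e` the evidence
needed to forgive one more at a footprint edge.

Two properties of this scheme are worth knowing. The fixed point is
order-independent (an extension's gain depends only on the mark positions,
never on other candidates), which the test suite exploits by checking
against a restart-from-scratch enumeration. And re-running the caller on a
fiber whose complement is fully methylated reproduces the segmentation
footprint-for-footprint but grows each boundary by one base — the single
m6A flanking a clean interior of at least 75 bases is always re-absorbed by
phase (ii). Exact idempotence is impossible under the phase rules
themselves; the property tests assert the 1-bp form.

**2. Features and labels.** Each MSP becomes a fixed-length vector: length,
internal m6A count and per-bp rate, log2 fold enrichment of the internal
rate over the whole-fiber rate (pseudocount 0.5 on numerator and
denominator, so an unmethylated fiber yields exactly 0), A/T fraction when
sequence is available, and m6A counts and rates in flanking windows of 30,
100 and 200 bp either side, truncated at read ends. Nothing in the vector
references the reference genome, so a trained model transfers to samples,
assemblies and organisms the labels never saw. Labels do use a reference:
MSPs overlapping (by one base or more) a set of putative-positive regions —
in real data, bulk accessibility peaks; in simulation, the planted truth —
are *mixed positives* (a blend of truly actuated elements and ordinary
linkers that happen to lie in accessible regions); MSPs clear of both the
positive and an optional exclusion set are *clean negatives*.

**3. Semi-supervised classification with estimated precision.** Because no
clean positive labels exist, precision is estimated on a held-out test
split: at a score threshold, $EP = 1 - (FP + 1)/TMP$, where $TMP$ counts
mixed-positives and $FP$ negatives at or above the threshold, with a
pseudocount of one on the false positives so small collections are never
scored liberally. Raw EP is not monotone; we scan thresholds from the
lowest score upward taking the running maximum, so equal scores receive
equal EP and confidence is non-decreasing in score. Training starts from
the single feature (either orientation) that captures the most
mixed-positives at 95% EP, fits a gradient-boosted tree ensemble (XGBoost)
on those positives against all clean negatives with five-fold
cross-validation, re-scores every training row out of fold, re-derives the
positive set at 95% EP, and repeats until the count of positives at 95% EP
stops increasing (cap 25 iterations; the iteration with the maximal count
is kept). Folds — and the train/test split itself — are assigned per fiber,
never per MSP, because MSPs on one molecule are correlated and row-level
splits would leak. An MSP is a FIRE element (Fiber-seq Inferred Regulatory
Element) when its EP reaches 0.90.

One design choice deliberately departs from a balanced-test-set EP: the
final curve uses the untouched test split *as is*. The test fibers are a
random sample of the input, so the split's label mix matches the population
the model is applied to. Downsampling the negatives to a balanced set makes
the EP-0.90 threshold admit roughly $TMP/10$ balanced false positives — a
fixed quantile of the background *regardless of classifier quality* — and
estimated precision stops tracking realized precision wherever negatives
dominate, as they do genome-wide. With raw counts, EP at 0.90 empirically
tracks truth-table precision on labelled simulations (the calibration
tests assert at least 0.85 among `ep >= 0.90` at n above 500).

**4. Aggregation, null, peaks.** Per base $g$, with $R_g$ covering reads
and $C_g$ covering FIRE elements of estimated precisions $EP_i$,

$$S_g = -\frac{50}{R_g}\sum_{i=1}^{C_g}\log_{10}\!\big(1 - \min(EP_i,\,0.99)\big),$$

so each element contributes at most $2 \cdot 50/R_g$ and the score lives in
$[0, 100]$; bases with $C_g < 4$ are unscored (sentinel $-1$). The null
distribution comes from relocating every read uniformly on its own
chromosome (length and internal structure preserved, seeded); reads whose
start base lies in unreliable-coverage territory — coverage deviating from
the genome-wide median by more than five Poisson standard deviations,
$5\sqrt{\mathrm{median}}$ — stay put, and relocated reads are
rejection-sampled off unreliable bases. The FDR at score $s$ is the number
of null bases scoring at least $s$ over the number of observed bases
scoring at least $s$, clamped to $[0,1]$ and made monotone by a running
minimum from the top score down ("at least" rather than "above", so the
top score is defined). Peaks are local maxima of $S_g$ with FDR below 5%
and actuation $C_g/R_g$ of at least 10% at the summit; adjacent maxima
sharing at least half the supporting elements (measured against the
smaller support) or overlapping reciprocally by 90% merge into the higher
summit; bounds are the lower-median start and upper-median end of the
supporting elements (even counts round outward so a peak never shrinks
past half its support). Wide peaks are the union of peaks and all sub-FDR
bases, merged across gaps smaller than one nucleosome (147 bp). On a
plateau of tied scores the *central* base is the summit: a leftmost-base
rule is equally deterministic but systematically biases summits toward the
upstream plateau edge, which at high coverage can sit outside the element
that generated the plateau.

The "median coverage by five standard deviations" rule mixes median and
mean in its source description; we center the band on the median and use
$\sqrt{\mathrm{median}}$ for the standard deviation, the conservative and
self-consistent reading. The 10%-actuation filter is evaluated at the
summit base, the single-base anchor every other peak statistic uses.

**5. Downstream statistics.** Haplotype-selective chromatin accessibility
(HSCA): for peaks with at least 10 phased reads on each haplotype at the
summit, a two-sided Fisher's exact test on (FIREs, non-FIRE reads) by
haplotype, BH-corrected across tested peaks; unphased reads are excluded.
Windows of 100 consecutive peaks (step 10, per chromosome, terminal
remainder dropped) are Fisher-tested for enrichment of nominally
significant (p < 0.05) HSCA peaks against the genome-wide q <= 0.05 count,
excluding the window itself from the background. Cosine similarity of
percent-actuation profiles over the same windows compares haplotype pairs
within and between samples. Permutation tests place same-sized windows
uniformly per chromosome (10,000 draws, `p = (1 + #null >= obs)/(1 + n)`,
never zero). Parent-of-origin consistency retains sites significant in at
least 10 samples with every *significant* sample skewed the same parental
direction — untested samples are neutral, since they carry no directional
information. X-inactivation classes follow the actuation decision table
(50-point difference for Xa/Xi-specific with the high side at 30% or more;
shared otherwise when either haplotype reaches 30%); when both rules could
fire the specific class wins, and an `intermediate` escape class covers Xi
at 30% or more with a difference between 25 and 50 points, making the
classification a total function. Escape-proximity profiles bin non-TSS
escaping peaks by absolute summit-to-summit distance (5-kb bins to 100 kb,
half-open edges). Protein occupancy at a motif on one fiber requires the
FIRE element to overlap the motif completely and at most one m6A inside
the motif.

## The simulator and what passing tests mean

`simulate_truth()` / `simulate_fibers()` generate the ground truth every
recovery test measures against: non-overlapping elements (150–250 bp,
minimum separation 3 kb, ~30 per Mb) with per-haplotype actuation
probabilities; reads (~20 kb, sd 2 kb) at uniform positions carrying a
nucleosome array (footprints ~N(147, 15) bp, linkers ~N(60, 15) bp, random
phase per molecule); per-base m6A at 0.15 in linkers and actuated
elements, 5e-4 in footprints (a "very low" false-call rate, ~0.07 marks
per nucleosome), all scaled by a per-sample multiplier emulating
experimental drift in methylation efficiency. With the default multiplier
the global m6A fraction lands near 4.5% of bases — roughly 9% of adenines,
inside the 6–13% range real training experiments span; the calibration
tests train across multipliers 0.6–1.35 (a 2.3-fold range) and check the
FIRE designation stays precise at both extremes. Simulated reads are
gapless relative to the reference and, by default, sequence-free (rates
are per bp; with `gen_seq = TRUE` marks land only on A/T at rescaled
rates).

What the simulator does *not* emulate: alignment gaps and clipping,
sequence-dependent methyltransferase preferences, fragmented or chimeric
reads, copy-number structure, unstable ("fragile") nucleosomes whose MSPs
genuinely straddle the linker/element boundary, and correlated actuation
between neighbouring elements. Passing recovery tests therefore shows the
*procedure* is correct and calibrated under its stated model — not that
real-data peak lists at any particular depth are reproduced.

Problem sizes used by the test suite and the acceptance script — chosen as
the smallest sizes at which every statistic is well-resolved: a 2-Mb
genome at 30-fold coverage (~3,000 reads, ~290k MSPs) for training and
evaluation; 20 seeded genomes for false-discovery control of peak calling
(planted actuation 0.5); a 90-fold genome down-sampled three-fold to
30-fold — the coverage the method is routinely run at — for score
stability; constructed per-locus read sets for the haplotype power and
null calibration checks.

## Numerical and degenerate-input choices

* EP of an empty threshold set, or of scores below the lowest tabulated
  threshold, is 0; `TMP = 0` gives EP 0 rather than NaN.
* Fisher tests use `stats::fisher.test` (verified against exhaustive
  hypergeometric enumeration to 1e-12 for all margins up to 12); BH uses
  `stats::p.adjust` (verified against the textbook step-up).
* A read longer than the reliable territory of its chromosome stays in
  place after 50 rejection draws and is counted, with a warning.
* Peaks with zero covering reads are reported untested by the haplotype
  test; windows with an all-zero actuation vector yield a missing cosine.
* CpG methylation differences need at least 5 calls per haplotype.
* Ties: initialization prefers the earlier feature and ascending
  orientation; peak merges keep the left of two equal summits.
* All coordinates are 0-based half-open everywhere, including all BED and
  bedGraph output.

## Known limitations

The aggregate-score null shares one shuffle realization by default (an
averaging option exists); at desk-scale simulation the shuffled null is
sparse wherever true FIREs are sparse, making the FDR estimate
conservative near zero. The per-base score depends on reads whose
boundaries fall inside a peak, so summit scores carry $O(1/\sqrt{R})$
noise — the reason score-stability is stated at 30-fold, not below.
Reference projection assumes gapless alignment; applying the package to
real spliced or clipped alignments requires projecting MSP offsets through
the CIGAR first, which is out of scope here.
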