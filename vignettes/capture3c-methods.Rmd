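---
title: "Statistical methods for multiplexed dCas9-capture 3C interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for multiplexed dCas9-capture 3C interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capture3c)
```

## The assay and the data model

Multiplexed dCas9-capture 3C sequencing profiles the long-range chromatin
contacts of a programmable set of cis-regulatory elements. Pooled sgRNAs
direct a biotinylated, catalytically dead Cas9 to tens or hundreds of bait
regions (enhancers, promoters, locus-control-region hypersensitive sites);
after restriction digestion (DpnII), proximity ligation and streptavidin
pull-down, paired-end sequencing reads out ligation products in which one
end anchors at a captured bait.

The computational model in this package treats the data at three levels:

* **Read pairs** — aligned ends with mapping qualities. Pairs are merged
  across replicates, filtered at MAPQ >= 30 by default (both ends),
  deduplicated on the exact unordered coordinate tuple of the two ends, and
  classified against the merged bait peaks.
* **PETs (pair-end tags)** — read pairs with exactly one end inside a bait
  peak. Pairs with both ends in the same bait peak are self-ligations
  (circularized fragments, not contacts) and are discarded; pairs spanning
  two distinct baits are bait-bait contacts and contribute one PET to each
  bait's profile, flagged so global totals are not double counted; pairs
  touching no bait are off-target and are retained only as part of the
  background contact library (below).
* **Interaction calls** — per bait, every chromosome is tiled at the bait's
  peak size L(i) and each bin (and each other bait region) with at least
  `min_count` PETs is tested against a sampled null.

Reads that failed to map are trimmed at the first GATC: sticky-end ligation
of DpnII fragments reconstitutes the recognition site at the ligation
junction, so the 5' fragment up to the first occurrence is the conservative
remappable unit (`trim_at_junction()`, minimum retained length 20 bp).

## The sampled negative-binomial null and the Bayes factor

For a pair of regions i, j with sizes L(i), L(j) at genomic distance d
(midpoint to midpoint), the null asks how many contacts a *random* region
pair of identical geometry would capture. Following the sampled-background
design, 10,000 placements of two intervals of sizes L(i) and L(j) at
distance d are drawn uniformly over all positions where both intervals fit
on one chromosome and neither touches any bait region; chromosomes are
weighted by their number of eligible start positions. The contacts captured
by each placement are counted from the **full deduplicated pair library**
(including off-target pairs). Strictly bait-anchored PETs can never land in
bait-avoiding placements — one of their ends is by definition inside a
bait — so the background is necessarily counted over the complete library;
this is what makes the null non-degenerate.

The 10,000 counts are fitted as a negative binomial by the method of
moments: with sample mean m and variance v, size r = m²/(v − m) and success
probability p = m/v when v > m; a Poisson with rate m when v <= m; a point
mass at zero when every sampled count is zero (reported with a `degenerate`
flag rather than suppressed). For an observed count x the Bayes factor is

$$\mathrm{BF} = \frac{\Pr(X < x)}{\Pr(X \ge x)} \cdot
\frac{\Pr(H_1)}{\Pr(H_0)},$$

with prior odds 0.001 chosen to control the false discovery rate; BF >= 20
defines a significant (high-confidence) interaction. Both tails are
evaluated directly (the upper tail via `lower.tail = FALSE`), never as
1 − CDF, so BF values remain exact far into the tail. BF is monotone
non-decreasing in x and linear in the prior odds.

Two details are decided here because the procedure leaves them open. First,
the significance cutoff is taken as BF **>= 20** (the high-confidence
definition), rather than strictly greater. Second, inter-chromosomal pairs
cannot match a distance, so their background places the two intervals
independently on two distinct random chromosomes — the only consistent
generalization — and the calls are flagged `inter`.

### Exact placement law instead of literal rejection sampling

Placement starts live on an integer axis; the number of library contacts
captured by a placement is a piecewise-constant function of its start, and
the bait-exclusion zones are themselves intervals. `sample_background()`
therefore sweeps the contact intervals once to obtain the exact run-length
distribution of capture counts over all eligible, bait-avoiding starts, and
draws its 10,000 placements i.i.d. from that distribution. This is
*distributionally identical* to drawing uniform placements with rejection
and counting each one — same law, same chromosome weighting, same exclusion
rule — but costs O(contacts in the matching distance window) per test
instead of O(placements × contacts). Determinism is preserved: each test
derives its seed from the configured base seed.

Bins equidistant to the left and right of a bait have identical (L(i),
L(j), d) and share one sampled background.

## Quantification

Interaction signal is depth- and length-normalized as PETs per kilobase of
bait region per million read pairs,

$$\mathrm{PPKM} = \frac{\mathrm{PETs} \times 10^9}
{\mathrm{Size_{bp}} \times \mathrm{TotalPairs}},$$

implemented with the single 10^9 factor exactly (no separate /1000 and
/10^6 roundings). FPKM for expression and chromatin signal uses the same
formula. The library total is the deduplicated, MAPQ-filtered pair count,
documented so cross-sample comparisons share a denominator. Time-course
signals are further normalized by the mean over all timepoints
(`normalize_timecourse()`), giving NPPKM/NFPKM series with mean 1.

## Super-enhancer hierarchy: H-score and hub enhancers

Within a super-enhancer (SE) of s constituent enhancers, enhancer i with
PET count EN(i) and peak size L(i) receives

$$H(i) = \frac{EN(i)}{L(i) \cdot \tfrac{1}{s}\sum_k EN(k)},$$

the mean-normalized, size-corrected interaction enrichment relative to its
SE siblings. The identity sum_i H(i) L(i) = s holds exactly and is asserted
in the tests. L is taken in kilobases so H-scores are O(1); hub calls are
invariant to that unit choice because a global rescaling of L rescales all
H equally and the classification is quantile-based.

H-scores of **all** enhancers are pooled and fitted as a gamma distribution
(maximum likelihood on the strictly positive scores; a moments fit is a
config switch). Each enhancer gets the upper-tail probability P(H >= h);
enhancers with P < 0.05 are hub enhancers, and an SE containing at least
one hub is hierarchical. Pooling across SEs (rather than per-SE fits) is
used because the per-SE normalization already removes SE-level scale;
the upper tail is the only sensible sidedness for an enrichment score.
Zero H-scores are excluded from the fit and can never be hubs; a
zero-variance score set yields no hubs with a warning.

SE-level interactions merge the PETs of all member enhancers (union,
deduplicated by read identity) before testing, with the SE span as the
pseudo-bait. SE calls are categorized by their partner region with
precedence SE-P (promoter window, TSS ± 2 kb by default) over SE-G (gene
body) over SE-O (elsewhere), and SE-gene links (high-confidence calls whose
partner overlaps a promoter window) form a bipartite graph whose connected
components yield the five SE-gene patterns (single/multiple SE ×
single/multiple gene, plus SEs with no significant gene). The distance from
a gene to its SE is measured from the TSS to the midpoint of the member
enhancer with the strongest interaction (highest PET count, ties broken by
Bayes factor then leftmost position).

## Promoter-centric dynamics

Enhancers are annotated as ATAC-seq peaks overlapping at least one H3K27ac
peak, with the ATAC peak taken as the enhancer footprint (the same genomic
region must carry both marks). For promoter baits, intra-chromosomal calls
within 200 kb (bait midpoint to partner midpoint, consistent with the PET
distance convention) whose partner overlaps an annotated enhancer are E-P
interactions; all remaining intra-chromosomal calls are "other";
inter-chromosomal calls belong to neither class. Over a differentiation
time course (0, 2, 6, 12, 24 h), per-promoter PPKM/FPKM series are
mean-normalized and summarized as cohort mean ± SEM, and the cohort-mean
interaction trajectory is correlated with the cohort-mean expression
trajectory: Pearson r with p-value from t = r·sqrt(n−2)/sqrt(1−r²) on n−2
degrees of freedom. With five timepoints n = 5; the test's sidedness is an
explicit argument (`two.sided` default) because it is not determined by the
procedure itself.

## The synthetic-data generator

`sim_config()` defines a complete, seeded simulation of everything the
pipeline consumes. Its defaults are the reference conditions used by the
test suite and the acceptance script:

* a 1.5-Mb, three-chromosome genome with 50 non-overlapping bait peaks of
  1.5–2.5 kb;
* a genome-wide ligation library of 10^6 pairs with anchors uniform over
  the genome and intra-chromosomal partner offsets following a shifted
  power law P(d) ∝ (1 + d/d0)^(−γ), γ = 1, d0 = 5 kb — the canonical
  contact-frequency decay — with 5% inter-chromosomal contacts; partners
  falling off the chromosome are discarded, so the local contact intensity
  at a given distance is identical for every anchor and for the sampled
  background;
* artifact injection at fixed rates: 10% PCR duplicates, 5% self-ligations,
  5% low-MAPQ ends, 20% GATC-junction reads.

This geometry yields roughly 10^5 bait-anchored PETs (about 2,000 per
bait), a realistic captured depth at which bait-size bins carry counts of
order one or more across testable distances. The compact genome is what
makes that density achievable with a desk-scale library; the alternative —
a chromosome-scale genome with a sparse library — produces far bins where
reaching the `min_count` test gate is itself already an extreme event, a
regime real capture libraries do not occupy.

Because the simulated baits have no capture bias by default
(`capture_enrichment = 1`), bait-anchored bin counts are exchangeable with
background placements: a null simulation is genuinely null, and the
fraction of tested pairs called at BF >= 20 is bounded by the analytic tail
probability implied by the threshold (≈ 5 × 10⁻⁵) plus sampling error.
Planted loops add (fold − 1) times the expected local decay baseline
between a bait and a target interval, with negative-binomial (or Poisson,
by switch) count noise; the truth table suffices to score recall and
precision without re-reading generator internals.

What the generator does **not** emulate: sequence-level realism (no
reference FASTA, no base errors), restriction-fragment boundaries,
chromatin-state covariates of contact frequency (A/B compartments, TADs),
capture-efficiency variation across sgRNAs, or replicate structure. Passing
tests therefore demonstrate the correctness and calibration of the
*statistics* under the stated generative assumptions, not performance on
any particular real library.

## Numerical and edge-case decisions

* Internal intervals are GRanges (1-based, closed); BED/BEDPE conversion
  happens only at the file boundary. Widths, midpoints and distances are
  convention-independent.
* PET distance and the 200-kb E-P rule use midpoints; bait midpoint is
  floor((start + end)/2).
* Degenerate backgrounds give BF = Inf for x >= 1, flagged, never dropped.
* A bait/bin pair whose geometry cannot be placed anywhere in the genome
  (no eligible bait-avoiding start) is reported untested (NA Bayes factor)
  with a warning rather than aborting the bait.
* `min_count = 2` keeps singleton bins out of testing.
* All randomness flows from explicit seeds; identical configuration gives
  byte-identical outputs, which the test suite asserts.

## Problem sizes used by the checks

The acceptance checks run the reference simulation (50 baits, 10^6-pair
library, ≈ 10^5 PETs, ≈ 10⁴ tested pairs at 10,000 background placements
each) twice — once null, once with twelve loops planted at 30-fold
enrichment at 50–150 kb — plus small closed-form checks. These sizes were
chosen so the whole suite exercises every stage at full statistical
fidelity while remaining a desk-scale computation.

## Known limitations

* The negative-binomial tail beyond the sampled range is an extrapolation
  of the moments fit; calls at extreme counts inherit that extrapolation.
* Background placements for very large distances are confined to the few
  chromosomal offsets that can host them, so their sampled counts are
  correlated; the fitted null remains unbiased in the mean but its
  dispersion estimate is noisier there.
* Bait-bait contacts contribute a PET to both baits' profiles; SE-level
  merging deduplicates by read identity, but cross-SE double counting of a
  single ligation event between two SEs is intentional (each SE sees the
  contact).
* The caller tests marginal bait-bin pairs; it does not model domain
  structure or polymer effects, and makes no multiple-testing correction
  beyond the FDR-motivated prior odds in the Bayes factor.
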