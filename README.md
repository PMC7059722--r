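# capture3c

Statistical analysis of multiplexed dCas9-capture proximity-ligation
(3C) sequencing data.

## The problem

CRISPR-affinity purification of chromatin (a biotinylated, catalytically
dead Cas9 directed by pooled sgRNAs) combined with 3C proximity ligation
reads out the long-range DNA contacts of tens to hundreds of
cis-regulatory elements — enhancers, promoters, locus-control-region
hypersensitive sites — in a single experiment. Each captured element is a
*bait*; sequencing yields read pairs in which (ideally) one end anchors in
a bait peak and the other end marks the interacting locus. This package
implements the computational side of that assay for analysts working with
such libraries:

* **PET extraction** — read pairs are merged across replicates, MAPQ
  filtered, deduplicated on exact coordinates, and classified per bait:
  self-ligations (both ends in one bait peak) are discarded, pairs with
  exactly one end in a bait become pair-end tags (PETs), pairs spanning
  two baits are flagged bait–bait contacts, and everything else is
  off-target. Unmapped reads can be trimmed at the first GATC, the DpnII
  ligation junction, for remapping.
* **Interaction calling** — per bait of peak size L, every chromosome is
  tiled into L-sized bins and each bin (and every other bait) with at
  least 2 PETs is tested against a sampled null: 10,000 random placements
  of a size- and distance-matched region pair avoiding all baits, contact
  counts fitted as a negative binomial. Significance is scored by the
  Bayes factor

  ```
  BF = [ Pr(X < x) / Pr(X >= x) ] * Pr(H1)/Pr(H0),
  ```

  with prior odds Pr(H1)/Pr(H0) = 0.001 for FDR control; BF >= 20 defines
  a high-confidence interaction.
* **Quantification** — PPKM (PETs per kilobase of bait region per million
  read pairs) = PETs x 1e9 / (Size_bp x TotalPairs), FPKM by the same
  formula, and mean-normalization across time-course points
  (NPPKM/NFPKM).
* **Super-enhancer hierarchy** — constituent enhancer i of an SE with s
  members gets H-score H(i) = EN(i) / (L(i) x mean(EN)); pooled H-scores
  are fitted as a gamma distribution, upper-tail P < 0.05 defines *hub
  enhancers*, and an SE with at least one hub is *hierarchical*. SE
  interactions are categorized SE-P / SE-G / SE-O, SE–gene links are
  classified into the five single/multiple SE x gene patterns, and
  SE-to-gene distances use the strongest interacting enhancer.
* **Promoter-centric dynamics** — promoter-bait interactions within
  200 kb that land on an annotated enhancer (ATAC peak overlapping
  H3K27ac) are E-P interactions, the remaining intra-chromosomal calls
  "other"; time-course signal tables are mean-normalized and correlated
  with expression (Pearson r, t-test p-value).
* **Synthetic data** — a fully seeded generator for genomes, baits,
  genome-wide contact libraries with power-law distance decay, planted
  loops, library artifacts (duplicates, self-ligations, low-MAPQ ends,
  junction reads) and coupled expression/interaction time courses, so the
  entire pipeline is testable without sequencing data.

## Worked example

Simulate a small experiment with one loop planted at 30-fold enrichment
60 kb from its bait, run the pipeline, and score it against the truth
table:

```r
library(capture3c)

cfg   <- sim_config(seed = 42, chrom_lengths = c(chr1 = 3e5, chr2 = 2e5),
                    n_baits = 10L, n_contacts = 200000L)
baits <- simulate_baits(cfg)
loops <- plant_loops(baits, simulate_genome(cfg), n_loops = 3L,
                     distance = 60000, width = 4000, fold = 30, seed = 42)
cfg   <- sim_config(seed = 42, chrom_lengths = c(chr1 = 3e5, chr2 = 2e5),
                    n_baits = 10L, n_contacts = 200000L, loops = loops)

sim   <- simulate_pets(cfg)
rp    <- simulate_read_pairs(cfg, sim$contacts, sim$baits)
pairs <- dedup_pairs(filter_mapq(rp$pairs))
px    <- extract_pets(pairs, sim$baits)
px$summary
#>           total       pet_pairs   self_ligation      off_target bait_bait_pairs
#>          155572           10945            7827          136609             191
#>    pets_emitted
#>           11327

contacts <- data.frame(chrom1 = pairs$chrom1, pos1 = pairs$pos1,
                       chrom2 = pairs$chrom2, pos2 = pairs$pos2)
calls <- call_all_interactions(px$pets, sim$baits, simulate_genome(cfg),
                               contacts, call_config(seed = 42))
calls[calls$significant, c("bait_id", "start", "end", "distance", "x", "bf")]
#>     bait_id  start    end distance   x           bf
#> 525 bait003 137105 138662    62226  35 5.204660e+19
#> 526 bait003 138663 140220    60668 102 2.234912e+91
#> 527 bait003 140221 141778    59110 100 5.840656e+96
#> 528 bait003 141779 143336    57552  23 3.056185e+07

score_calls(calls, sim$truth)[c("recall", "precision")]
#> $recall    [1] 1
#> $precision [1] 1
```

Of 155,572 simulated read pairs, 11,327 PETs anchor at the ten baits;
7,827 pairs are self-ligation circles and the bulk of the library is
genome-wide ligation background, which is exactly what the null model
samples from. The four significant bins (Bayes factors 3e7–6e96, all far
above the threshold of 20) tile the planted 4-kb target at ~60 kb from
bait003, and nothing else is called: the planted loop is recovered with
perfect precision at this scale.

A shell entry point wrapping the same functions ships in
`inst/scripts/capture3c`:

```sh
capture3c simulate --config sim.yaml --out simdir/
capture3c pets     --config pets.yaml
capture3c call     --config call.yaml
capture3c summary  --config summary.yaml
```

Each stage validates its configuration keys, writes its declared outputs
plus a `manifest.json` (inputs, parameters, package version), and returns
a non-zero exit status on error.

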