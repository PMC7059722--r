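## Shared fixtures: tiny deterministic inputs built in code.

gr <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
}

mc <- S4Vectors::mcols
`mc<-` <- S4Vectors::`mcols<-`

tiny_genome <- function() Genome(c(chr1 = 100000, chr2 = 80000))

tiny_baits <- function() {
  b <- gr(c("chr1", "chr1", "chr2"), c(10001, 50001, 20001),
          c(12000, 52000, 22000))
  mc(b)$bait_id <- c("B1", "B2", "B3")
  b
}

## small read-pair table touching every extraction category
tiny_pairs <- function() {
  data.frame(
    read_id = sprintf("r%02d", 1:8),
    chrom1 = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr1", "chr2", "chr1"),
    pos1   = c(10500,  10600,  11000,  51000,  21000,  30000,  60000,  10999),
    mapq1  = c(60, 60, 60, 60, 60, 60, 60, 60),
    chrom2 = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    pos2   = c(30000,  11500,  51500,  52000,  30700,  40000,  61000,  70000),
    mapq2  = c(60, 60, 60, 60, 60, 60, 60, 60),
    stringsAsFactors = FALSE)
  ## r1: B1 -> open sea (PET); r2: self-ligation in B1; r3: B1-B2 bait-bait;
  ## r4: self-ligation in B2; r5: B3 -> chr1 inter PET; r6: off-target;
  ## r7: off-target; r8: B1 -> chr2 inter PET
}

## exact NB pmf from first principles (lgamma), independent of dnbinom
nb_pmf <- function(x, r, p) {
  exp(lgamma(x + r) - lgamma(r) - lfactorial(x) + r * log(p) +
        x * log1p(-p))
}

## brute-force tail-sum Bayes factor oracle for a NB background
bf_oracle <- function(x, r, p, prior = 0.001, upto = 5000) {
  k <- 0:upto
  pmf <- nb_pmf(k, r, p)
  p_lt <- if (x == 0) 0 else sum(pmf[k < x])
  p_ge <- sum(pmf[k >= x])   # direct tail sum: no cancellation
  p_lt / p_ge * prior
}
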