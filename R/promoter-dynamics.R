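## Promoter-centric interaction dynamics: enhancer annotation, E-P vs other
## classification, time-course integration and correlation with expression.

#' Annotate enhancers as ATAC peaks supported by H3K27ac
#'
#' An enhancer is a genomic region carrying both open chromatin and the
#' active-enhancer mark: each ATAC peak overlapping at least one H3K27ac
#' peak is emitted, with the ATAC peak taken as the enhancer footprint.
#'
#' @param atac_peaks GRanges of ATAC-seq peaks.
#' @param k27ac_peaks GRanges of H3K27ac ChIP-seq peaks.
#' @return GRanges of annotated enhancers (subset of `atac_peaks`) with
#'   mcols `atac_id` and `k27ac_id` evidence indices.
#' @export
annotate_enhancers <- function(atac_peaks, k27ac_peaks) {
  hits <- findOverlaps(atac_peaks, k27ac_peaks, ignore.strand = TRUE)
  qi <- unique(queryHits(hits))
  enh <- atac_peaks[qi]
  first <- hits[!duplicated(queryHits(hits))]
  mcols(enh)$atac_id <- qi
  mcols(enh)$k27ac_id <- subjectHits(first)[match(qi, queryHits(first))]
  enh
}

#' Classify promoter-bait calls into E-P and other interactions
#'
#' An interaction between an anchor promoter and a neighboring enhancer
#' within `max_dist` is an E-P interaction: the call must be
#' intra-chromosomal, its bait-to-partner midpoint distance at most
#' `max_dist`, and its partner region must overlap an annotated enhancer.
#' All remaining intra-chromosomal calls are "other"; inter-chromosomal
#' calls are excluded from both classes.
#'
#' @param calls calls data.frame (needs chrom, start, end, distance, inter).
#' @param enhancers annotated enhancer GRanges from [annotate_enhancers()].
#' @param max_dist maximum bait-to-partner distance in bp (default 200,000).
#' @return `calls` subset to intra-chromosomal rows, with a `category`
#'   column in \{"E-P", "other"\}.
#' @export
classify_interactions <- function(calls, enhancers, max_dist = 200000L) {
  intra <- calls[!calls$inter, , drop = FALSE]
  if (nrow(intra) == 0L) {
    intra$category <- character(0)
    return(intra)
  }
  part <- GRanges(intra$chrom, IRanges(intra$start, intra$end))
  on_enh <- overlapsAny(part, enhancers, ignore.strand = TRUE)
  intra$category <- ifelse(on_enh & intra$distance <= max_dist, "E-P", "other")
  rownames(intra) <- NULL
  intra
}

#' Assemble normalized time-course signal tables
#'
#' Takes one raw-signal matrix per data type (rows = regions/promoters,
#' columns = ordered timepoints), normalizes every row by its own mean across
#' timepoints ([normalize_timecourse()]), and reports the cohort mean and
#' standard error per timepoint.
#'
#' @param signals named list of numeric matrices, one per signal type (e.g.
#'   RNA, ATAC, `3C-EP`); all must share the same timepoint columns.
#' @param timepoints expected timepoint labels (default `c(0, 2, 6, 12, 24)`
#'   hours); an error names any missing timepoint.
#' @return list per signal type: `normalized` (row-normalized matrix),
#'   `mean` and `sem` (cohort summaries per timepoint).
#' @export
timecourse_table <- function(signals, timepoints = c(0, 2, 6, 12, 24)) {
  want <- as.character(timepoints)
  out <- list()
  for (nm in names(signals)) {
    m <- signals[[nm]]
    miss <- setdiff(want, colnames(m))
    if (length(miss))
      stop(sprintf("signal '%s': missing timepoint(s) %s", nm,
                   paste(miss, collapse = ", ")))
    m <- m[, want, drop = FALSE]
    norm <- t(apply(m, 1, normalize_timecourse))
    colnames(norm) <- want
    mu <- colMeans(norm)
    sem <- apply(norm, 2, stats::sd) / sqrt(nrow(norm))
    out[[nm]] <- list(normalized = norm, mean = mu, sem = sem)
  }
  out
}

#' Pearson correlation between interaction and expression trajectories
#'
#' Pearson r between two equal-length trajectories (typically cohort-mean
#' normalized signals over the five timepoints), with a p-value from the t
#' statistic t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom.
#'
#' @param interaction,expression numeric vectors, length >= 3.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list: r, t, df, p_value, alternative.
#' @export
correlate_expression <- function(interaction, expression,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  n <- length(interaction)
  if (length(expression) != n) stop("trajectories must have equal length")
  if (n < 3L) stop("need at least 3 timepoints")
  if (stats::sd(interaction) == 0 || stats::sd(expression) == 0)
    stop("zero-variance trajectory")
  r <- stats::cor(interaction, expression)
  df <- n - 2L
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  list(r = r, t = t, df = df, p_value = p, alternative = alternative)
}
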