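## Bayes-factor interaction calling against a sampled negative-binomial
## background. For a bait pair (i, j) with peak sizes L(i), L(j) at genomic
## distance d, the null is built by placing 10,000 random size- and
## distance-matched region pairs avoiding all bait regions, counting contacts
## captured by each placement, and fitting a negative binomial. The Bayes
## factor is BF = [Pr(X < x) / Pr(X >= x)] * prior_ratio with prior_ratio
## 0.001; BF >= 20 defines a high-confidence interaction.

#' Interaction-calling configuration
#'
#' @param n_samples random background placements per test (default 10,000).
#' @param prior_ratio prior odds Pr(H1)/Pr(H0) in the Bayes factor
#'   (default 0.001, chosen to control the false discovery rate).
#' @param bf_threshold significance threshold on the Bayes factor (default 20).
#' @param min_count minimum observed PET count for a bin/bait pair to be
#'   tested (default 2; singleton bins are not tested).
#' @param seed base random seed; all background sampling derives from it.
#' @param n_min minimum accepted placements before erroring (default 1,000).
#' @param max_attempt_factor cap on redraws, as a multiple of `n_samples`.
#' @return list of class `call_config`.
#' @export
call_config <- function(n_samples = 10000L, prior_ratio = 0.001,
                        bf_threshold = 20, min_count = 2L, seed = 1234L,
                        n_min = 1000L, max_attempt_factor = 50L) {
  if (prior_ratio <= 0) stop("prior_ratio must be positive")
  structure(list(n_samples = as.integer(n_samples), prior_ratio = prior_ratio,
                 bf_threshold = bf_threshold, min_count = as.integer(min_count),
                 seed = as.integer(seed), n_min = as.integer(n_min),
                 max_attempt_factor = as.integer(max_attempt_factor)),
            class = "call_config")
}

#' Tile a genome into fixed-size bins
#'
#' Each chromosome of length M is cut into `ceiling(M / bin_size)` half-open
#' bins; the last bin may be short. For bait-centric calling the bin size is
#' the bait peak size.
#'
#' @param genome a [Genome()].
#' @param bin_size bin width in bp (> 0).
#' @return GRanges tiling every chromosome without gaps or overlaps, with an
#'   mcols column `bin` (0-based bin index within chromosome).
#' @export
bin_genome <- function(genome, bin_size) {
  if (bin_size <= 0) stop("bin_size must be positive")
  bin_size <- as.numeric(bin_size)
  chroms <- names(genome)
  nb <- ceiling(unclass(genome) / bin_size)
  chrom <- rep(chroms, nb)
  k <- unlist(lapply(nb, function(x) seq_len(x) - 1), use.names = FALSE)
  st <- k * bin_size + 1
  en <- pmin((k + 1) * bin_size, rep(unclass(genome), nb))
  gr <- GRanges(chrom, IRanges(st, en), bin = k)
  GenomeInfoDb::seqlevels(gr) <- chroms
  GenomeInfoDb::seqlengths(gr) <- unclass(genome)
  S4Vectors::metadata(gr)$bin_size <- bin_size
  gr
}

#' Count PET partner ends per bin
#'
#' @param pets PET data.frame (partner ends are counted).
#' @param grid bin GRanges from [bin_genome()].
#' @return integer vector parallel to `grid`; sums to `nrow(pets)`.
#' @export
count_pets <- function(pets, grid) {
  bs <- S4Vectors::metadata(grid)$bin_size
  genome <- GenomeInfoDb::seqlengths(grid)
  counts <- integer(length(grid))
  if (nrow(pets) == 0L) return(counts)
  bad <- !(pets$partner_chrom %in% names(genome)) |
    pets$partner_pos < 1 | pets$partner_pos > genome[pets$partner_chrom]
  if (any(bad))
    stop(sprintf("PET partner end outside genome (first at row %d)", which(bad)[1L]))
  offs <- cumsum(c(0, ceiling(genome / bs)))[seq_along(genome)]
  names(offs) <- names(genome)
  idx <- offs[pets$partner_chrom] + (pets$partner_pos - 1) %/% bs + 1
  tab <- tabulate(idx, nbins = length(grid))
  as.integer(tab)
}

#' Build a contact index for background sampling
#'
#' Pre-sorts the full deduplicated contact set (all read pairs surviving
#' preprocessing, including off-target pairs) for fast counting of contacts
#' captured by arbitrary region pairs, and records the bait intervals that
#' random placements must avoid.
#'
#' @param contacts data.frame with columns chrom1, pos1, chrom2, pos2.
#' @param baits merged bait GRanges.
#' @param genome a [Genome()].
#' @return object of class `contact_index`.
#' @export
contact_index <- function(contacts, baits, genome) {
  intra <- contacts$chrom1 == contacts$chrom2
  idx_intra <- list()
  for (c in unique(contacts$chrom1[intra])) {
    sel <- intra & contacts$chrom1 == c
    u <- pmin(contacts$pos1[sel], contacts$pos2[sel])
    v <- pmax(contacts$pos1[sel], contacts$pos2[sel])
    gap <- v - u
    o <- order(gap)
    idx_intra[[c]] <- list(u = u[o], v = v[o], gap = gap[o])
  }
  idx_inter <- list()
  if (any(!intra)) {
    c1 <- contacts$chrom1[!intra]; c2 <- contacts$chrom2[!intra]
    p1 <- contacts$pos1[!intra]; p2 <- contacts$pos2[!intra]
    swap <- c1 > c2
    tmp <- c1[swap]; c1[swap] <- c2[swap]; c2[swap] <- tmp
    tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
    key <- paste(c1, c2, sep = "|")
    for (k in unique(key)) {
      sel <- key == k
      o <- order(p1[sel])
      idx_inter[[k]] <- list(pA = p1[sel][o], pB = p2[sel][o])
    }
  }
  ## per-chromosome sorted, non-overlapping bait intervals for rejection
  avoid <- list()
  for (c in names(genome)) {
    b <- baits[as.character(seqnames(baits)) == c]
    o <- order(start(b))
    avoid[[c]] <- list(start = start(b)[o], end = end(b)[o])
  }
  structure(list(intra = idx_intra, inter = idx_inter, avoid = avoid,
                 genome = genome, n_contacts = nrow(contacts)),
            class = "contact_index")
}

## TRUE where [qs, qe] overlaps any avoided interval on chromosome c
.hits_avoid <- function(ci, c, qs, qe) {
  av <- ci$avoid[[c]]
  if (is.null(av) || length(av$start) == 0L) return(rep(FALSE, length(qs)))
  i <- .bisect_cpp(av$start, qe, TRUE)
  i >= 1L & av$end[pmax(i, 1L)] >= qs
}

## Run-length histogram of captured-contact counts over all placement starts
## a in [1, a_lim] on chromosome c, for the pair geometry (A = [a, a+Lleft),
## B = [a+o, a+o+Lright)). A contact (u, v) with u <= v is captured by the
## placements whose start falls in [max(u-Lleft+1, v-o-Lright+1),
## min(u, v-o)]; placement starts whose A or B interval touches a bait are
## excluded.
.cover_hist_intra <- function(ci, c, a_lim, Lleft, Lright, o) {
  ix <- ci$intra[[c]]
  av <- ci$avoid[[c]]
  excl_lo <- c(av$start - Lleft + 1, av$start - o - Lright + 1)
  excl_hi <- c(av$end, av$end - o)
  if (is.null(ix)) {
    return(.cover_hist_cpp(numeric(0), numeric(0), excl_lo, excl_hi, a_lim))
  }
  lo_gap <- o - Lright + 1; hi_gap <- o + Lleft - 1
  i1 <- .bisect_cpp(ix$gap, lo_gap - 1, TRUE) + 1L
  i2 <- .bisect_cpp(ix$gap, hi_gap, TRUE)
  if (i2 < i1) {
    return(.cover_hist_cpp(numeric(0), numeric(0), excl_lo, excl_hi, a_lim))
  }
  u <- ix$u[i1:i2]; v <- ix$v[i1:i2]
  lo <- pmax(u - Lleft + 1, v - o - Lright + 1)
  hi <- pmin(u, v - o)
  .cover_hist_cpp(lo, hi, excl_lo, excl_hi, a_lim)
}

## count inter-chromosomal contacts with one end in A = [a, a+L1-1] on cA and
## the other in B = [b, b+L2-1] on cB, per placement.
.count_inter <- function(ci, cA, cB, a, b, L1, L2) {
  swap <- cA > cB
  if (swap) { tmp <- cA; cA <- cB; cB <- tmp; tmp <- a; a <- b; b <- tmp
              tmp <- L1; L1 <- L2; L2 <- tmp }
  ix <- ci$inter[[paste(cA, cB, sep = "|")]]
  if (is.null(ix)) return(integer(length(a)))
  .count_pairs_cpp(ix$pA, ix$pB, a, b, L1, L2)
}

## draw seed-deterministic placements and per-placement contact counts
.sample_counts <- function(ci, L_i, L_j, distance, n, seed, n_min,
                           max_attempts) {
  genome <- ci$genome
  set.seed(seed)
  counts <- integer(0)
  attempts <- 0L
  intra <- !is.null(distance) && !is.na(distance)
  if (intra) {
    Lleft <- L_i; Lright <- L_j
    o <- round(distance + (Lleft - Lright) / 2)
    if (o < 0) { tmp <- Lleft; Lleft <- Lright; Lright <- tmp
                 o <- round(distance + (Lleft - Lright) / 2) }
    o <- max(o, 0)
    span <- o + Lright
    elig <- unclass(genome) - span + 1
    ok <- elig >= 1
    if (!any(ok)) stop("no chromosome long enough for background placement")
    ## exact count distribution over all eligible, bait-avoiding placement
    ## starts; drawing n i.i.d. placements from it is identical in law to
    ## rejection-sampling uniform placements and counting per placement
    vals <- integer(0); lens <- numeric(0)
    for (c in names(genome)[ok]) {
      h <- .cover_hist_intra(ci, c, elig[[c]], Lleft, Lright, o)
      vals <- c(vals, h$value); lens <- c(lens, h$length)
    }
    if (sum(lens) < 1)
      stop(paste("no eligible background placement avoids the bait regions;",
                 "use a larger genome or fewer/smaller bait regions"))
    draw <- sample.int(length(vals), n, replace = TRUE, prob = lens)
    counts <- vals[draw]
  } else {
    if (length(genome) < 2L)
      stop("inter-chromosomal background needs at least two chromosomes")
    eligA <- unclass(genome) - L_i + 1
    eligB <- unclass(genome) - L_j + 1
    okA <- eligA >= 1; okB <- eligB >= 1
    while (length(counts) < n && attempts < max_attempts) {
      nb <- min(ceiling(1.5 * (n - length(counts))) + 100L,
                max_attempts - attempts)
      attempts <- attempts + nb
      cA <- names(genome)[okA][sample.int(sum(okA), nb, replace = TRUE,
                                          prob = eligA[okA])]
      cB <- names(genome)[okB][sample.int(sum(okB), nb, replace = TRUE,
                                          prob = eligB[okB])]
      keep <- cA != cB
      cA <- cA[keep]; cB <- cB[keep]
      a <- floor(runif(length(cA)) * eligA[cA]) + 1
      b <- floor(runif(length(cB)) * eligB[cB]) + 1
      rej <- logical(length(cA))
      for (c in unique(cA)) { s <- cA == c
        rej[s] <- rej[s] | .hits_avoid(ci, c, a[s], a[s] + L_i - 1) }
      for (c in unique(cB)) { s <- cB == c
        rej[s] <- rej[s] | .hits_avoid(ci, c, b[s], b[s] + L_j - 1) }
      cA <- cA[!rej]; cB <- cB[!rej]; a <- a[!rej]; b <- b[!rej]
      need <- n - length(counts)
      if (length(a) > need) {
        cA <- cA[seq_len(need)]; cB <- cB[seq_len(need)]
        a <- a[seq_len(need)]; b <- b[seq_len(need)]
      }
      if (length(a)) {
        newc <- integer(length(a))
        keyv <- paste(cA, cB)
        for (k in unique(keyv)) {
          s <- keyv == k
          newc[s] <- .count_inter(ci, cA[s][1], cB[s][1], a[s], b[s], L_i, L_j)
        }
        counts <- c(counts, newc)
      }
    }
  }
  if (length(counts) < n_min)
    stop(sprintf(paste("only %d of %d background placements accepted;",
                       "use a larger genome or fewer/smaller bait regions"),
                 length(counts), n))
  counts[seq_len(min(length(counts), n))]
}

#' Sample a random matched background for a region pair
#'
#' Implements the sampled null: `n` random placements of two regions with the
#' same sizes L(i), L(j) and (for intra-chromosomal pairs) the same genomic
#' distance, avoiding all bait regions; contacts captured by each placement
#' are counted and the counts fitted as a negative binomial
#' (see [fit_negbin()]). Chromosomes are chosen with probability proportional
#' to the number of eligible start positions. Deterministic under `seed`.
#'
#' @param L_i,L_j region sizes in bp.
#' @param distance midpoint-to-midpoint distance in bp; `NULL` or `NA` for
#'   inter-chromosomal pairs (two independent regions on distinct
#'   chromosomes).
#' @param index [contact_index()] over the full contact set.
#' @param n number of accepted placements (default 10,000).
#' @param seed random seed.
#' @param n_min minimum accepted placements, else error.
#' @param max_attempts redraw cap.
#' @return a `negbin_background` (see [fit_negbin()]) with the raw sampled
#'   counts in `$counts`.
#' @export
sample_background <- function(L_i, L_j, distance, index, n = 10000L,
                              seed = 1234L, n_min = 1000L,
                              max_attempts = 50L * n) {
  stopifnot(inherits(index, "contact_index"))
  counts <- .sample_counts(index, L_i, L_j, distance, n, seed, n_min,
                           max_attempts)
  bg <- fit_negbin(counts)
  bg$provenance <- list(L_i = L_i, L_j = L_j, distance = distance, seed = seed)
  bg
}

#' Fit a negative-binomial null to sampled background counts
#'
#' Method-of-moments fit: with sample mean m and variance v, the size is
#' r = m^2 / (v - m) and the success probability p = m / v when v > m.
#' When v <= m (under- or equi-dispersed) a Poisson with rate m is used; when
#' every count is zero the null is a point mass at zero.
#'
#' @param counts non-negative integer vector.
#' @return list of class `negbin_background`: family ("negbin", "poisson" or
#'   "pointmass"), parameters, n_samples, and the input `counts`.
#' @export
fit_negbin <- function(counts) {
  if (length(counts) == 0L) stop("counts must be non-empty")
  m <- mean(counts); v <- stats::var(counts)
  if (length(counts) == 1L) v <- 0
  if (m == 0) {
    out <- list(family = "pointmass", r = NA_real_, p = NA_real_,
                lambda = 0, mean = 0, var = 0)
  } else if (v > m) {
    out <- list(family = "negbin", r = m^2 / (v - m), p = m / v,
                lambda = NA_real_, mean = m, var = v)
  } else {
    out <- list(family = "poisson", r = NA_real_, p = NA_real_,
                lambda = m, mean = m, var = v)
  }
  out$n_samples <- length(counts)
  out$counts <- counts
  structure(out, class = "negbin_background")
}

#' @export
print.negbin_background <- function(x, ...) {
  cat("Sampled background (", x$n_samples, " placements): ", x$family, sep = "")
  if (x$family == "negbin") cat(sprintf(" r = %.4g, p = %.4g", x$r, x$p))
  if (x$family == "poisson") cat(sprintf(" lambda = %.4g", x$lambda))
  cat("\n")
  invisible(x)
}

## Pr(X <= q) under a fitted background
.bg_ple <- function(bg, q) {
  if (bg$family == "pointmass") return(as.numeric(q >= 0))
  if (bg$family == "poisson") return(stats::ppois(q, bg$lambda))
  stats::pnbinom(q, size = bg$r, prob = bg$p)
}

## Pr(X > q), computed in the upper tail directly for numerical stability
.bg_pgt <- function(bg, q) {
  if (bg$family == "pointmass") return(as.numeric(q < 0))
  if (bg$family == "poisson")
    return(stats::ppois(q, bg$lambda, lower.tail = FALSE))
  stats::pnbinom(q, size = bg$r, prob = bg$p, lower.tail = FALSE)
}

#' Bayes factor for an observed contact count
#'
#' BF = [Pr(X < x) / Pr(X >= x)] * prior_ratio under the fitted null, where
#' the prior odds Pr(H1)/Pr(H0) default to 0.001 for FDR control. A
#' degenerate null (point mass at zero) gives BF = Inf for any x >= 1,
#' flagged rather than suppressed.
#'
#' @param x observed PET count(s), non-negative integer, vectorized.
#' @param bg `negbin_background` from [fit_negbin()]/[sample_background()].
#' @param prior_ratio prior odds Pr(H1)/Pr(H0) (default 0.001).
#' @param bf_threshold significance cutoff (default 20).
#' @return data.frame: x, p_lt, p_ge, bf, significant, degenerate.
#' @export
bayes_factor <- function(x, bg, prior_ratio = 0.001, bf_threshold = 20) {
  if (prior_ratio <= 0) stop("prior_ratio must be positive")
  stopifnot(all(x >= 0))
  p_lt <- ifelse(x == 0, 0, .bg_ple(bg, x - 1))
  p_ge <- ifelse(x == 0, 1, .bg_pgt(bg, x - 1))
  bf <- ifelse(p_ge <= 0, Inf, p_lt / p_ge * prior_ratio)
  data.frame(x = x, p_lt = p_lt, p_ge = p_ge, bf = bf,
             significant = bf >= bf_threshold,
             degenerate = bg$family == "pointmass" & x >= 1)
}

#' Call significant interactions for one bait
#'
#' Bins every chromosome at the bait's peak size, counts PET partner ends per
#' bin, and tests every bin with at least `min_count` PETs (plus every other
#' bait region, treated with its own size) against a size- and
#' distance-matched sampled background. Bins overlapping any bait region are
#' excluded from bin-level testing (bait partners are tested as bait-bait
#' pairs instead).
#'
#' @param bait_id id of the bait to test.
#' @param pets PET data.frame from [extract_pets()].
#' @param baits merged bait GRanges.
#' @param genome a [Genome()].
#' @param index [contact_index()] over the full contact set.
#' @param config a [call_config()].
#' @return data.frame of tested calls: bait_id, chrom, start, end,
#'   partner_type, partner_id, distance, inter, x, p_lt, p_ge, bf,
#'   significant, high_confidence, degenerate.
#' @export
call_interactions <- function(bait_id, pets, baits, genome, index,
                              config = call_config()) {
  bi <- match(bait_id, mcols(baits)$bait_id)
  if (is.na(bi)) stop(sprintf("unknown bait id '%s'", bait_id))
  bait <- baits[bi]
  L <- width(bait)
  bmid <- .gr_mid(bait)
  bchrom <- as.character(seqnames(bait))
  bpets <- pets[pets$bait_id == bait_id, , drop = FALSE]

  grid <- bin_genome(genome, L)
  counts <- count_pets(bpets, grid)
  in_bait <- overlapsAny(grid, baits, ignore.strand = TRUE)
  cand <- which(counts >= config$min_count & !in_bait)

  ## bait-bait partners
  others <- setdiff(seq_along(baits), bi)
  x_bb <- integer(length(others))
  if (length(others) && nrow(bpets)) {
    pgr <- GRanges(bpets$partner_chrom, IRanges(bpets$partner_pos,
                                                bpets$partner_pos))
    x_bb <- countOverlaps(baits[others], pgr, ignore.strand = TRUE)
  }
  keep_bb <- which(x_bb >= config$min_count)

  tests <- data.frame(
    chrom = c(as.character(seqnames(grid))[cand],
              as.character(seqnames(baits))[others][keep_bb]),
    start = c(start(grid)[cand], start(baits)[others][keep_bb]),
    end = c(end(grid)[cand], end(baits)[others][keep_bb]),
    partner_type = rep(c("bin", "bait"), c(length(cand), length(keep_bb))),
    partner_id = c(sprintf("%s:bin%d", as.character(seqnames(grid))[cand],
                           mcols(grid)$bin[cand]),
                   mcols(baits)$bait_id[others][keep_bb]),
    x = c(counts[cand], x_bb[keep_bb]),
    stringsAsFactors = FALSE)
  if (nrow(tests) == 0L) {
    return(data.frame(bait_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      partner_type = character(), partner_id = character(),
                      distance = numeric(), inter = logical(), x = integer(),
                      p_lt = numeric(), p_ge = numeric(), bf = numeric(),
                      significant = logical(), high_confidence = logical(),
                      degenerate = logical(), stringsAsFactors = FALSE))
  }
  ord <- order(tests$chrom, tests$start, tests$partner_type)
  tests <- tests[ord, , drop = FALSE]
  pmid <- floor((tests$start + tests$end) / 2)
  tests$inter <- tests$chrom != bchrom
  tests$distance <- ifelse(tests$inter, NA_real_, abs(pmid - bmid))

  res <- vector("list", nrow(tests))
  bg_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tests))) {
    Lj <- tests$end[i] - tests$start[i] + 1
    ## identical (L_i, L_j, d) pairs define the same background; share the
    ## sampled null (e.g. bins equidistant left and right of the bait)
    key <- paste(L, Lj, tests$inter[i],
                 if (tests$inter[i]) "" else tests$distance[i])
    if (!is.null(bg_cache[[key]])) {
      res[[i]] <- bayes_factor(tests$x[i], bg_cache[[key]],
                               config$prior_ratio, config$bf_threshold)
      next
    }
    seed_i <- (config$seed + 131L * bi + i) %% .Machine$integer.max
    bg <- tryCatch(
      sample_background(L, Lj,
                        if (tests$inter[i]) NULL else tests$distance[i],
                        index, n = config$n_samples, seed = seed_i,
                        n_min = config$n_min,
                        max_attempts = config$max_attempt_factor *
                          config$n_samples),
      error = function(e) e)
    if (inherits(bg, "error")) {
      ## distance/size combination not placeable in this genome: report the
      ## pair untested rather than aborting the whole bait
      warning(sprintf("bait %s vs %s: %s", bait_id, tests$partner_id[i],
                      conditionMessage(bg)))
      res[[i]] <- data.frame(x = tests$x[i], p_lt = NA_real_,
                             p_ge = NA_real_, bf = NA_real_,
                             significant = FALSE, degenerate = FALSE)
    } else {
      bg_cache[[key]] <- bg
      res[[i]] <- bayes_factor(tests$x[i], bg, config$prior_ratio,
                               config$bf_threshold)
    }
  }
  bfdf <- do.call(rbind, res)
  out <- data.frame(bait_id = bait_id, tests[c("chrom", "start", "end",
                                               "partner_type", "partner_id",
                                               "distance", "inter")],
                    bfdf[c("x", "p_lt", "p_ge", "bf", "significant",
                           "degenerate")],
                    stringsAsFactors = FALSE)
  out$high_confidence <- out$bf >= 20
  rownames(out) <- NULL
  out
}

#' Call interactions for every bait
#'
#' @inheritParams call_interactions
#' @param contacts full deduplicated contact data.frame (chrom1, pos1,
#'   chrom2, pos2) used for background sampling; when `NULL`, PET coordinates
#'   are used.
#' @return combined calls data.frame (one row per tested pair).
#' @export
call_all_interactions <- function(pets, baits, genome, contacts = NULL,
                                  config = call_config()) {
  if (is.null(contacts)) {
    contacts <- data.frame(chrom1 = pets$bait_chrom, pos1 = pets$bait_mid,
                           chrom2 = pets$partner_chrom,
                           pos2 = pets$partner_pos, stringsAsFactors = FALSE)
  }
  index <- contact_index(contacts, baits, genome)
  res <- lapply(mcols(baits)$bait_id, call_interactions, pets = pets,
                baits = baits, genome = genome, index = index,
                config = config)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Merge constituent-enhancer PETs to super-enhancer level
#'
#' If a super-enhancer has several constituent enhancer baits, their PETs are
#' pooled as the PETs of the SE (union, deduplicated by read id within each
#' SE) and re-anchored at the SE span, for SE-level interaction testing.
#'
#' @param pets PET data.frame.
#' @param baits merged bait GRanges with an `se_id` mcols column.
#' @return list: `pets` (SE-level PETs with `bait_id` = SE id), `se_baits`
#'   (one GRanges interval per SE spanning its member baits).
#' @export
merge_se_pets <- function(pets, baits) {
  se <- mcols(baits)$se_id
  if (is.null(se)) stop("baits need an mcols column 'se_id'")
  keep <- !is.na(se)
  sp <- split(baits[keep], se[keep])
  se_baits <- unlist(range(sp, ignore.strand = TRUE))
  mcols(se_baits)$bait_id <- names(se_baits)
  names(se_baits) <- NULL
  map <- setNames(se, mcols(baits)$bait_id)
  pp <- pets[!is.na(map[pets$bait_id]), , drop = FALSE]
  pp$bait_id <- unname(map[pp$bait_id])
  pp <- pp[!duplicated(paste(pp$bait_id, pp$read_id)), , drop = FALSE]
  idx <- match(pp$bait_id, mcols(se_baits)$bait_id)
  pp$bait_chrom <- as.character(seqnames(se_baits))[idx]
  pp$bait_mid <- .gr_mid(se_baits)[idx]
  pp$inter <- pp$bait_chrom != pp$partner_chrom
  pp$distance <- ifelse(pp$inter, NA_real_, abs(pp$bait_mid - pp$partner_pos))
  rownames(pp) <- NULL
  list(pets = pp, se_baits = sort(se_baits, ignore.strand = TRUE))
}

#' Capture rate: percentage of targeted regions with significant interactions
#'
#' @param n_with_significant number of targeted regions with at least one
#'   significant interaction.
#' @param n_targeted number of targeted regions (> 0).
#' @return percentage rounded to one decimal.
#' @examples
#' capture_rate(156, 157)  # 99.4
#' @export
capture_rate <- function(n_with_significant, n_targeted) {
  if (any(n_targeted <= 0)) stop("n_targeted must be positive")
  if (any(n_with_significant < 0 | n_with_significant > n_targeted))
    stop("n_with_significant must be in [0, n_targeted]")
  round(100 * n_with_significant / n_targeted, 1)
}
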