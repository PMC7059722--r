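## Seeded generators for every input the pipeline needs: genomes, baits,
## genome-wide proximity-ligation contact libraries with distance decay and
## planted loops, raw read pairs with library artifacts, and time-course
## signal tables. All generators are deterministic functions of the
## configuration (seed included).

#' Simulation configuration
#'
#' Defaults describe the reference simulation used throughout the test suite:
#' a compact 1.5-Mb three-chromosome genome, 50 bait peaks of ~2 kb, and a
#' genome-wide ligation library sized so that roughly 100,000 bait-anchored
#' PETs are recovered (about 2,000 per bait, a realistic captured depth at
#' which bait-size bins carry counts of order one or more across testable
#' distances, as in real capture libraries). Intra-chromosomal partner
#' offsets follow a shifted power-law decay P(d) proportional to
#' (1 + d/d0)^(-gamma). Bait capture enrichment is off by default, so the
#' bait-anchored PET counts are exchangeable with the sampled background (a
#' calibrated null); planted loops and `capture_enrichment` add signal on
#' top.
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_baits number of bait peaks.
#' @param bait_size_range min/max bait peak size (bp).
#' @param n_contacts size of the genome-wide contact library.
#' @param decay_gamma distance-decay exponent (> 0).
#' @param decay_d0 decay scale in bp (avoids the singularity at d = 0).
#' @param f_trans fraction of inter-chromosomal contacts.
#' @param capture_enrichment multiplier on bait-anchored contact intensity
#'   (1 = no capture bias).
#' @param loops data.frame of planted loops (`bait`, `chrom`, `start`, `end`,
#'   `fold` with fold >= 1), or NULL.
#' @param dispersion negative-binomial size for planted/enriched counts.
#' @param count_model `"negbin"` or `"poisson"` for planted/enriched counts.
#' @param duplicate_rate,self_ligation_rate,low_mapq_rate artifact rates in
#'   [0, 1] for the read-pair wrapper.
#' @param junction_fraction fraction of raw reads carrying a GATC ligation
#'   junction.
#' @param read_length raw read length (bp).
#' @param timepoints time-course sampling times (hours).
#' @param coupling_slope linear coupling of E-P interaction signal to
#'   expression; `other_coupling` is the weaker coupling of non-enhancer
#'   interactions.
#' @param noise_sd Gaussian noise SD on time-course signals.
#' @param other_coupling coupling of "other" interactions to expression.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1234L,
                       chrom_lengths = c(chr1 = 6e5, chr2 = 5e5, chr3 = 4e5),
                       n_baits = 50L,
                       bait_size_range = c(1500L, 2500L),
                       n_contacts = 1000000L,
                       decay_gamma = 1.0,
                       decay_d0 = 5000,
                       f_trans = 0.05,
                       capture_enrichment = 1,
                       loops = NULL,
                       dispersion = 10,
                       count_model = c("negbin", "poisson"),
                       duplicate_rate = 0.10,
                       self_ligation_rate = 0.05,
                       low_mapq_rate = 0.05,
                       junction_fraction = 0.20,
                       read_length = 75L,
                       timepoints = c(0, 2, 6, 12, 24),
                       coupling_slope = 1,
                       other_coupling = 0.3,
                       noise_sd = 0.1) {
  count_model <- match.arg(count_model)
  rates <- c(f_trans, duplicate_rate, self_ligation_rate, low_mapq_rate,
             junction_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (decay_gamma <= 0) stop("decay_gamma must be positive")
  if (!is.null(loops) && any(loops$fold < 1)) stop("loop fold must be >= 1")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: seed %d, %d chroms (%s bp), %d baits, ",
                     "%d contacts, decay (1 + d/%g)^-%g, %d planted loops\n"),
              x$seed, length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ","), x$n_baits,
              x$n_contacts, x$decay_d0, x$decay_gamma,
              if (is.null(x$loops)) 0L else nrow(x$loops)))
  invisible(x)
}

#' Simulated genome from a configuration
#' @param cfg a [sim_config()].
#' @return a [Genome()].
#' @export
simulate_genome <- function(cfg) Genome(cfg$chrom_lengths)

#' Simulated non-overlapping bait peaks
#'
#' @param cfg a [sim_config()].
#' @return merged bait GRanges (mcols `bait_id`), placed uniformly without
#'   overlap; deterministic under the config seed.
#' @export
simulate_baits <- function(cfg) {
  genome <- simulate_genome(cfg)
  set.seed(cfg$seed + 1L)
  sizes <- round(runif(cfg$n_baits, cfg$bait_size_range[1],
                       cfg$bait_size_range[2]))
  chroms <- names(genome)
  w <- unclass(genome)
  placed <- GRanges(seqinfo = GenomeInfoDb::Seqinfo(chroms, w))
  for (i in seq_len(cfg$n_baits)) {
    for (try in 1:500) {
      c <- chroms[sample.int(length(chroms), 1, prob = w)]
      st <- floor(runif(1) * (unclass(genome)[[c]] - sizes[i] - 2000)) + 1000
      cand <- GRanges(c, IRanges(st, st + sizes[i] - 1))
      ## keep a 2-bait-size gap so merged baits never abut
      if (length(placed) == 0L ||
          !any(overlapsAny(cand + 2 * max(sizes), placed))) {
        placed <- c(placed, cand)
        break
      }
    }
  }
  mcols(placed)$bait_id <- sprintf("bait%03d", seq_along(placed))
  GenomeInfoDb::seqlevels(placed) <- chroms
  GenomeInfoDb::seqlengths(placed) <- w
  sort(placed, ignore.strand = TRUE)
}

## decay step weights over 1-kb distance steps up to `max_bp`
.decay_weights <- function(cfg, max_bp) {
  k <- seq_len(max(floor(max_bp / 1000), 1L))
  d <- (k - 0.5) * 1000
  (1 + d / cfg$decay_d0)^(-cfg$decay_gamma)
}

## density per bp at distance d (positive-distance normalization)
.decay_density_bp <- function(cfg, d, max_bp) {
  w <- .decay_weights(cfg, max_bp)
  k <- pmin(pmax(ceiling(d / 1000), 1L), length(w))
  (w[k] / sum(w)) / 1000
}

## draw signed decay offsets; out-of-bounds partners are discarded (NA) so
## the local contact intensity at distance d is identical for every anchor,
## matching the intensity seen by random background placements
.draw_partners <- function(cfg, chrom_len, anchor) {
  n <- length(anchor)
  w <- .decay_weights(cfg, max(chrom_len))
  k <- sample.int(length(w), n, replace = TRUE, prob = w)
  d <- (k - 1) * 1000 + floor(runif(n) * 1000) + 1
  sgn <- ifelse(runif(n) < 0.5, -1, 1)
  p <- anchor + sgn * d
  ifelse(p >= 1 & p <= chrom_len, p, NA_real_)
}

.rcount <- function(cfg, n, mu) {
  if (cfg$count_model == "poisson") stats::rpois(n, mu)
  else stats::rnbinom(n, size = cfg$dispersion, mu = mu)
}

#' Simulate a genome-wide contact library with planted loops
#'
#' Generates `n_contacts` proximity-ligation contacts: anchors uniform over
#' the genome, intra-chromosomal partners at shifted power-law decay
#' distances, a fraction `f_trans` inter-chromosomal. When
#' `capture_enrichment` > 1, additional bait-anchored contacts are drawn
#' bin-wise (negative binomial or Poisson per `count_model`) so bait PET
#' depth exceeds the library background by that factor. Each planted loop
#' adds (fold - 1) times the expected local decay baseline between its bait
#' peak and target interval.
#'
#' @param cfg a [sim_config()].
#' @param baits optional bait GRanges (default [simulate_baits()]).
#' @return list: `contacts` (chrom1, pos1, chrom2, pos2, origin), `truth`
#'   (planted-loop table with expected baseline and planted counts),
#'   `baits`, `genome`.
#' @export
simulate_pets <- function(cfg, baits = NULL) {
  genome <- simulate_genome(cfg)
  if (is.null(baits)) baits <- simulate_baits(cfg)
  set.seed(cfg$seed + 2L)
  G <- sum(unclass(genome))
  chroms <- names(genome)
  M <- unclass(genome)

  n <- cfg$n_contacts
  c1 <- sample(chroms, n, replace = TRUE, prob = M)
  p1 <- floor(runif(n) * M[c1]) + 1
  trans <- if (length(chroms) < 2L) rep(FALSE, n) else
    runif(n) < cfg$f_trans
  c2 <- c1
  p2 <- rep(NA_real_, n)
  if (any(trans)) {
    for (c in chroms) {
      s <- which(trans & c1 == c)
      if (!length(s)) next
      oc <- setdiff(chroms, c)
      cc <- oc[sample.int(length(oc), length(s), replace = TRUE,
                          prob = M[oc])]
      c2[s] <- cc
      p2[s] <- floor(runif(length(s)) * M[cc]) + 1
    }
  }
  for (c in chroms) {
    s <- which(!trans & c1 == c)
    if (!length(s)) next
    p2[s] <- .draw_partners(cfg, rep(M[[c]], length(s)), p1[s])
  }
  keep <- !is.na(p2)
  contacts <- data.frame(chrom1 = c1[keep], pos1 = p1[keep],
                         chrom2 = c2[keep], pos2 = p2[keep],
                         origin = "background", stringsAsFactors = FALSE)

  ## capture enrichment: extra bait-anchored contacts, bin-wise counts
  if (cfg$capture_enrichment > 1) {
    extra <- list()
    for (i in seq_along(baits)) {
      bc <- as.character(seqnames(baits))[i]
      bmid <- .gr_mid(baits)[i]
      Lb <- width(baits)[i]
      w <- .decay_weights(cfg, M[[bc]])
      ## expected library contacts anchored in this bait, split over steps
      e_anchor <- cfg$n_contacts * (1 - cfg$f_trans) * 2 * Lb / G
      mu_step <- (cfg$capture_enrichment - 1) * e_anchor * w / sum(w)
      cnt <- .rcount(cfg, length(mu_step), mu_step)
      ks <- which(cnt > 0)
      if (!length(ks)) next
      reps <- cnt[ks]
      k <- rep(ks, reps)
      d <- (k - 1) * 1000 + floor(runif(length(k)) * 1000) + 1
      sgn <- ifelse(runif(length(k)) < 0.5, -1, 1)
      pp <- bmid + sgn * d
      pa <- start(baits)[i] + floor(runif(length(k)) * Lb)
      inb <- pp >= 1 & pp <= M[[bc]]
      pp <- pp[inb]; pa <- pa[inb]
      if (!length(pp)) next
      extra[[length(extra) + 1L]] <-
        data.frame(chrom1 = bc, pos1 = pa, chrom2 = bc, pos2 = pp,
                   origin = "capture", stringsAsFactors = FALSE)
    }
    if (length(extra)) contacts <- rbind(contacts, do.call(rbind, extra))
  }

  truth <- data.frame(bait = character(), chrom = character(),
                      start = numeric(), end = numeric(), fold = numeric(),
                      expected_base = numeric(), n_planted = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(cfg$loops) && nrow(cfg$loops) > 0L) {
    for (r in seq_len(nrow(cfg$loops))) {
      lp <- cfg$loops[r, ]
      bi <- match(lp$bait, mcols(baits)$bait_id)
      if (is.na(bi)) stop(sprintf("loop %d: unknown bait '%s'", r, lp$bait))
      bc <- as.character(seqnames(baits))[bi]
      if (lp$chrom != bc) stop("planted loops must be intra-chromosomal")
      Lb <- width(baits)[bi]
      Lt <- lp$end - lp$start + 1
      d <- abs(floor((lp$start + lp$end) / 2) - .gr_mid(baits)[bi])
      fbp <- .decay_density_bp(cfg, d, M[[bc]])
      e_base <- cfg$n_contacts * (1 - cfg$f_trans) * fbp * Lb * Lt / G *
        max(cfg$capture_enrichment, 1)
      n_extra <- .rcount(cfg, 1L, (lp$fold - 1) * e_base)
      if (n_extra > 0) {
        pa <- start(baits)[bi] + floor(runif(n_extra) * Lb)
        pt <- lp$start + floor(runif(n_extra) * Lt)
        contacts <- rbind(contacts,
                          data.frame(chrom1 = bc, pos1 = pa, chrom2 = bc,
                                     pos2 = pt, origin = "loop",
                                     stringsAsFactors = FALSE))
      }
      truth <- rbind(truth,
                     data.frame(bait = lp$bait, chrom = lp$chrom,
                                start = lp$start, end = lp$end,
                                fold = lp$fold, expected_base = e_base,
                                n_planted = n_extra,
                                stringsAsFactors = FALSE))
    }
  }
  rownames(contacts) <- NULL
  list(contacts = contacts, truth = truth, baits = baits, genome = genome)
}

#' Build a planted-loop table for a set of baits
#'
#' Picks `n_loops` baits (round-robin, deterministically under `seed`) and
#' places one intra-chromosomal target interval per pick at the requested
#' distance from the bait midpoint, on whichever side fits inside the
#' chromosome without touching any bait peak.
#'
#' @param baits merged bait GRanges.
#' @param genome a [Genome()].
#' @param n_loops number of loops to plant.
#' @param distance bait-midpoint to target-midpoint distance (bp); recycled.
#' @param width target interval width (bp).
#' @param fold enrichment over the local decay baseline (>= 1); recycled.
#' @param seed seed for the bait picks.
#' @return data.frame usable as the `loops` argument of [sim_config()].
#' @export
plant_loops <- function(baits, genome, n_loops = 10L, distance = 1e5,
                        width = 4000L, fold = 30, seed = 1L) {
  set.seed(seed)
  distance <- rep_len(distance, n_loops)
  fold <- rep_len(fold, n_loops)
  picks <- sample(seq_along(baits), min(n_loops, length(baits)))
  picks <- rep_len(picks, n_loops)
  out <- list()
  for (i in seq_len(n_loops)) {
    bi <- picks[i]
    bc <- as.character(seqnames(baits))[bi]
    bmid <- .gr_mid(baits)[bi]
    M <- unclass(genome)[[bc]]
    for (side in sample(c(1, -1), 2)) {
      tmid <- bmid + side * distance[i]
      st <- round(tmid - width / 2); en <- st + width - 1
      if (st < 1 || en > M) next
      tgt <- GRanges(bc, IRanges(st, en))
      if (any(overlapsAny(tgt, baits, ignore.strand = TRUE))) next
      out[[length(out) + 1L]] <-
        data.frame(bait = mcols(baits)$bait_id[bi], chrom = bc, start = st,
                   end = en, fold = fold[i], stringsAsFactors = FALSE)
      break
    }
  }
  do.call(rbind, out)
}

#' Score interaction calls against a planted-loop truth table
#'
#' Recall is the fraction of planted loops recovered by at least one
#' significant call from the loop's bait overlapping the target interval;
#' precision is the fraction of significant calls explained by a planted
#' loop of the same bait.
#'
#' @param calls calls data.frame from [call_all_interactions()].
#' @param truth truth table from [simulate_pets()].
#' @return list: recall, precision, n_true, n_called, plus per-loop hits.
#' @export
score_calls <- function(calls, truth) {
  sig <- calls[!is.na(calls$significant) & calls$significant, , drop = FALSE]
  hit_loop <- logical(nrow(truth))
  call_true <- logical(nrow(sig))
  for (i in seq_len(nrow(truth))) {
    m <- sig$bait_id == truth$bait[i] & sig$chrom == truth$chrom[i] &
      sig$start <= truth$end[i] & sig$end >= truth$start[i]
    hit_loop[i] <- any(m)
    call_true <- call_true | m
  }
  list(recall = if (nrow(truth)) mean(hit_loop) else NA_real_,
       precision = if (nrow(sig)) mean(call_true) else NA_real_,
       n_true = nrow(truth), n_called = nrow(sig), loop_hit = hit_loop)
}

.random_dna <- function(n, len, avoid = NULL) {
  out <- character(n)
  todo <- seq_len(n)
  while (length(todo)) {
    s <- vapply(todo, function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")
    ok <- if (is.null(avoid)) rep(TRUE, length(s)) else !grepl(avoid, s,
                                                               fixed = TRUE)
    out[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  out
}

#' Wrap contacts into raw read pairs with library artifacts
#'
#' Each contact becomes one read pair (MAPQ 60 on both ends); artifacts are
#' injected at the configured rates: PCR duplicates (exact coordinate
#' copies), self-ligation pairs (both ends inside one bait peak), and
#' low-MAPQ ends. Optionally generates raw sequences of which a configured
#' fraction carry a GATC ligation junction.
#'
#' @param cfg a [sim_config()].
#' @param contacts contact data.frame from [simulate_pets()].
#' @param baits bait GRanges.
#' @param sequences generate raw read sequences (default FALSE; quadratic in
#'   nothing but slower, meant for small n).
#' @return list: `pairs` (read-pair data.frame), `truth` (artifact counts),
#'   and `reads` (character vector or NULL).
#' @export
simulate_read_pairs <- function(cfg, contacts, baits, sequences = FALSE) {
  set.seed(cfg$seed + 3L)
  n <- nrow(contacts)
  pairs <- data.frame(read_id = sprintf("read%07d", seq_len(n)),
                      chrom1 = contacts$chrom1, pos1 = contacts$pos1,
                      mapq1 = 60L, chrom2 = contacts$chrom2,
                      pos2 = contacts$pos2, mapq2 = 60L,
                      stringsAsFactors = FALSE)
  ## self-ligations: both ends inside one random bait
  n_self <- stats::rbinom(1, n, cfg$self_ligation_rate)
  if (n_self > 0) {
    bi <- sample.int(length(baits), n_self, replace = TRUE)
    w <- width(baits)[bi]
    self <- data.frame(read_id = sprintf("self%07d", seq_len(n_self)),
                       chrom1 = as.character(seqnames(baits))[bi],
                       pos1 = start(baits)[bi] + floor(runif(n_self) * w),
                       mapq1 = 60L,
                       chrom2 = as.character(seqnames(baits))[bi],
                       pos2 = start(baits)[bi] + floor(runif(n_self) * w),
                       mapq2 = 60L, stringsAsFactors = FALSE)
    pairs <- rbind(pairs, self)
  }
  ## low-MAPQ ends
  n_low <- stats::rbinom(1, nrow(pairs), cfg$low_mapq_rate)
  low_idx <- sample.int(nrow(pairs), n_low)
  if (n_low > 0) {
    which_end <- runif(n_low) < 0.5
    pairs$mapq1[low_idx[which_end]] <- sample(0:29, sum(which_end),
                                              replace = TRUE)
    pairs$mapq2[low_idx[!which_end]] <- sample(0:29, sum(!which_end),
                                               replace = TRUE)
  }
  ## PCR duplicates: exact copies appended
  n_dup <- stats::rbinom(1, nrow(pairs), cfg$duplicate_rate)
  dup_idx <- sample.int(nrow(pairs), n_dup, replace = TRUE)
  if (n_dup > 0) {
    dups <- pairs[dup_idx, , drop = FALSE]
    dups$read_id <- sprintf("dup%07d", seq_len(n_dup))
    pairs <- rbind(pairs, dups)
  }
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  rownames(pairs) <- NULL
  reads <- NULL
  n_junction <- 0L
  if (sequences) {
    nr <- nrow(pairs)
    has_j <- runif(nr) < cfg$junction_fraction
    n_junction <- sum(has_j)
    reads <- character(nr)
    reads[!has_j] <- .random_dna(sum(!has_j), cfg$read_length, avoid = "GATC")
    if (n_junction > 0) {
      pre_len <- 20L + floor(runif(n_junction) * (cfg$read_length - 30L))
      reads[has_j] <- vapply(seq_len(n_junction), function(i) {
        pre <- .random_dna(1, pre_len[i], avoid = "GATC")
        post <- .random_dna(1, cfg$read_length - pre_len[i] - 4L)
        paste0(pre, "GATC", post)
      }, "")
    }
  }
  truth <- c(n_contacts = n, n_self_ligation = n_self,
             n_low_mapq = n_low, n_duplicates = n_dup,
             n_junction_reads = n_junction)
  list(pairs = pairs, truth = truth, reads = reads)
}

#' Simulate coupled expression and interaction time courses
#'
#' Activated promoters follow a monotone-increasing expression trajectory
#' over the timepoints, repressed promoters a monotone-decreasing one. E-P
#' interaction signal is linearly coupled to expression with slope
#' `coupling_slope` plus Gaussian noise; "other" interactions use the weaker
#' `other_coupling`. With zero noise and slope 1 the E-P trajectory equals
#' the expression trajectory.
#'
#' @param cfg a [sim_config()].
#' @param promoters data.frame with `promoter_id` and `class`
#'   ("activated"/"repressed").
#' @return list: `signals` (named list of matrices promoter x timepoint for
#'   RNA, `3C-all`, `3C-EP`, `3C-other`), `truth` (coupling parameters).
#' @export
simulate_timecourse <- function(cfg, promoters) {
  set.seed(cfg$seed + 4L)
  stopifnot(all(promoters$class %in% c("activated", "repressed")))
  tp <- cfg$timepoints
  ramp <- seq(0, 1, length.out = length(tp))
  n <- nrow(promoters)
  expr <- t(vapply(seq_len(n), function(i) {
    traj <- if (promoters$class[i] == "activated") 1 + 2 * ramp else
      3 - 2 * ramp
    pmax(traj + rnorm(length(tp), 0, cfg$noise_sd), 0)
  }, numeric(length(tp))))
  couple <- function(slope) t(vapply(seq_len(n), function(i)
    pmax(slope * expr[i, ] + (1 - slope) * mean(expr[i, ]) +
           rnorm(length(tp), 0, cfg$noise_sd), 0),
    numeric(length(tp))))
  ep <- couple(cfg$coupling_slope)
  other <- couple(cfg$other_coupling)
  all3c <- ep + other
  dimnames(expr) <- dimnames(ep) <- dimnames(other) <- dimnames(all3c) <-
    list(promoters$promoter_id, as.character(tp))
  list(signals = list(RNA = expr, `3C-all` = all3c, `3C-EP` = ep,
                      `3C-other` = other),
       truth = list(coupling_slope = cfg$coupling_slope,
                    other_coupling = cfg$other_coupling,
                    noise_sd = cfg$noise_sd))
}
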