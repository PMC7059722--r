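## Read-pair preprocessing: junction trimming, MAPQ filtering, duplicate
## removal, bait assignment and PET extraction.

#' Trim reads at the first ligation-junction site
#'
#' Proximity ligation of DpnII sticky ends reconstitutes the GATC recognition
#' sequence at the ligation junction, so a read running through the junction
#' carries sequence from two genomic locations. Trimming keeps the 5' fragment
#' up to (and excluding) the first occurrence of the site so the remainder can
#' be remapped.
#'
#' @param seqs character vector of read sequences over A, C, G, T, N.
#' @param site junction sequence (default `"GATC"`, DpnII).
#' @param min_len minimum retained length; shorter 5' fragments become `NA`.
#' @return character vector; reads without the site are returned unchanged,
#'   trimmed reads shorter than `min_len` are `NA`.
#' @examples
#' trim_at_junction(c("ACGTTTGATCAAAA", "ACGTACGTACGT"), min_len = 4)
#' @export
trim_at_junction <- function(seqs, site = "GATC", min_len = 20L) {
  if (!nzchar(site)) stop("site must be non-empty")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(sprintf("non-DNA characters in read %d", which(bad)[1L]))
  pos <- regexpr(site, seqs, fixed = TRUE)
  out <- seqs
  hit <- pos > 0L
  out[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
  out[nchar(out) < min_len] <- NA_character_
  out
}

#' Read aligned read pairs
#'
#' The native interchange format is a tab-separated table with a header row
#' and columns `read_id, chrom1, pos1, mapq1, chrom2, pos2, mapq2` (positions
#' 1-based). SAM/BAM input is supported through Rsamtools: primary alignments
#' are paired by query name.
#'
#' @param path input path.
#' @param format `"tsv"` (default, also used for `.txt`), `"sam"` or `"bam"`;
#'   guessed from the file extension when missing.
#' @return data.frame of read pairs.
#' @export
read_pairs <- function(path, format = c("auto", "tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) ext else "tsv"
  }
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    need <- c("read_id", "chrom1", "pos1", "mapq1", "chrom2", "pos2", "mapq2")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
    return(df[need])
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM/BAM input requires the Rsamtools package")
  bam <- if (format == "sam") Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                               indexDestination = FALSE) else path
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(bam, param = prm)[[1]]
  first <- bitwAnd(b$flag, 64L) > 0L
  d1 <- data.frame(read_id = b$qname, chrom = as.character(b$rname),
                   pos = b$pos, mapq = b$mapq,
                   stringsAsFactors = FALSE)[first, ]
  d2 <- data.frame(read_id = b$qname, chrom = as.character(b$rname),
                   pos = b$pos, mapq = b$mapq,
                   stringsAsFactors = FALSE)[!first, ]
  m <- merge(d1, d2, by = "read_id", suffixes = c("1", "2"))
  m[c("read_id", "chrom1", "pos1", "mapq1", "chrom2", "pos2", "mapq2")]
}

#' Write read pairs as TSV
#' @param pairs data.frame from [read_pairs()].
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep read pairs with both ends at or above a MAPQ cutoff
#'
#' @param pairs read-pair data.frame.
#' @param min_mapq minimum mapping quality, applied to both ends (default 30).
#' @return filtered data.frame.
#' @export
filter_mapq <- function(pairs, min_mapq = 30L) {
  stopifnot(min_mapq >= 0)
  pairs[pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq, , drop = FALSE]
}

#' Remove PCR duplicates
#'
#' A duplicate is a pair whose unordered coordinate tuple
#' \{(chrom1, pos1), (chrom2, pos2)\} has been seen before; the first
#' occurrence is kept. The key is exact (no fuzzy window).
#'
#' @param pairs read-pair data.frame.
#' @return deduplicated data.frame.
#' @export
dedup_pairs <- function(pairs) {
  a <- paste(pairs$chrom1, pairs$pos1, sep = ":")
  b <- paste(pairs$chrom2, pairs$pos2, sep = ":")
  key <- ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  pairs[!duplicated(key), , drop = FALSE]
}

#' Merge sgRNA peaks into bait regions
#'
#' Multiple sgRNA peaks targeting the same cis-regulatory element are merged
#' into a single bait peak (the enclosing range), whose width is the bait
#' size L used for binning and background matching.
#'
#' @param peaks GRanges of sgRNA peaks with an mcols column `bait_id`
#'   (optionally `bait_class`, `se_id`).
#' @return GRanges with one merged interval per bait id.
#' @export
merge_baits <- function(peaks) {
  if (is.null(mcols(peaks)$bait_id)) stop("peaks need an mcols column 'bait_id'")
  sp <- split(peaks, mcols(peaks)$bait_id)
  merged <- unlist(range(sp, ignore.strand = TRUE))
  mcols(merged)$bait_id <- names(merged)
  for (col in c("bait_class", "se_id")) {
    if (!is.null(mcols(peaks)[[col]])) {
      first <- !duplicated(mcols(peaks)$bait_id)
      v <- setNames(mcols(peaks)[[col]][first], mcols(peaks)$bait_id[first])
      mcols(merged)[[col]] <- unname(v[names(merged)])
    }
  }
  names(merged) <- NULL
  sort(merged, ignore.strand = TRUE)
}

## map 1-bp positions to bait index (NA if outside all baits)
.assign_bait <- function(chrom, pos, baits) {
  gr <- GRanges(chrom, IRanges(pos, pos))
  hits <- findOverlaps(gr, baits, ignore.strand = TRUE)
  out <- rep(NA_integer_, length(gr))
  out[queryHits(hits)] <- subjectHits(hits)
  out
}

#' Extract pair-end tags (PETs) from preprocessed read pairs
#'
#' Classifies each deduplicated, MAPQ-filtered read pair against the merged
#' bait peaks: both ends inside the same bait peak are self-ligations
#' (circularized fragments, discarded); exactly one end inside a bait emits a
#' PET anchored at that bait; ends in two different baits emit one PET per
#' bait (flagged `bait_bait` so global totals are not double counted); pairs
#' touching no bait are counted as off-target and dropped.
#'
#' @param pairs read-pair data.frame (deduplicated, MAPQ filtered).
#' @param baits merged bait GRanges from [merge_baits()]; must be mutually
#'   non-overlapping.
#' @return list with `pets` (data.frame: bait_id, bait_chrom, bait_mid,
#'   partner_chrom, partner_pos, distance, inter, bait_bait, read_id) and
#'   `summary` (named counts: total, pet_pairs, self_ligation, off_target,
#'   bait_bait_pairs, pets_emitted).
#' @export
extract_pets <- function(pairs, baits) {
  if (length(baits) > 1L) {
    self <- findOverlaps(baits, ignore.strand = TRUE, drop.self = TRUE)
    if (length(self) > 0L)
      stop("bait peaks overlap; merge them (merge_baits) before PET extraction")
  }
  b1 <- .assign_bait(pairs$chrom1, pairs$pos1, baits)
  b2 <- .assign_bait(pairs$chrom2, pairs$pos2, baits)
  self_lig <- !is.na(b1) & !is.na(b2) & b1 == b2
  off <- is.na(b1) & is.na(b2)
  both <- !is.na(b1) & !is.na(b2) & b1 != b2
  one <- xor(is.na(b1), is.na(b2))

  emit <- function(bait_idx, partner_chrom, partner_pos, read_id, flag_bb) {
    if (length(bait_idx) == 0L)
      return(data.frame(bait_id = character(), bait_chrom = character(),
                        bait_mid = numeric(), partner_chrom = character(),
                        partner_pos = numeric(), distance = numeric(),
                        inter = logical(), bait_bait = logical(),
                        read_id = character(), stringsAsFactors = FALSE))
    bchrom <- as.character(seqnames(baits))[bait_idx]
    bmid <- .gr_mid(baits)[bait_idx]
    inter <- bchrom != partner_chrom
    data.frame(bait_id = mcols(baits)$bait_id[bait_idx],
               bait_chrom = bchrom, bait_mid = bmid,
               partner_chrom = partner_chrom, partner_pos = partner_pos,
               distance = ifelse(inter, NA_real_, abs(bmid - partner_pos)),
               inter = inter, bait_bait = flag_bb, read_id = read_id,
               stringsAsFactors = FALSE)
  }

  i1 <- which(one & !is.na(b1))   # anchored at end1's bait, partner = end2
  i2 <- which(one & !is.na(b2))
  ib <- which(both)
  pets <- rbind(
    emit(b1[i1], pairs$chrom2[i1], pairs$pos2[i1], pairs$read_id[i1], FALSE),
    emit(b2[i2], pairs$chrom1[i2], pairs$pos1[i2], pairs$read_id[i2], FALSE),
    emit(b1[ib], pairs$chrom2[ib], pairs$pos2[ib], pairs$read_id[ib], TRUE),
    emit(b2[ib], pairs$chrom1[ib], pairs$pos1[ib], pairs$read_id[ib], TRUE))
  ord <- order(pets$bait_id, pets$partner_chrom, pets$partner_pos, pets$read_id)
  pets <- pets[ord, , drop = FALSE]
  rownames(pets) <- NULL
  summary <- c(total = nrow(pairs), pet_pairs = sum(one),
               self_ligation = sum(self_lig), off_target = sum(off),
               bait_bait_pairs = sum(both), pets_emitted = nrow(pets))
  list(pets = pets, summary = summary)
}

#' Write PETs as a per-bait BEDPE
#'
#' End 1 is the full bait peak, end 2 the 1-bp partner position; the BEDPE
#' name column carries the bait id.
#'
#' @param pets PET data.frame from [extract_pets()].
#' @param baits merged bait GRanges.
#' @param path output path.
#' @export
write_pets_bedpe <- function(pets, baits, path) {
  idx <- match(pets$bait_id, mcols(baits)$bait_id)
  df <- data.frame(chrom1 = pets$bait_chrom,
                   start1 = start(baits)[idx], end1 = end(baits)[idx],
                   chrom2 = pets$partner_chrom,
                   start2 = pets$partner_pos, end2 = pets$partner_pos,
                   name = pets$bait_id, stringsAsFactors = FALSE)
  write_bedpe(df, path)
}

#' Read PETs from a per-bait BEDPE written by [write_pets_bedpe()]
#' @param path BEDPE path.
#' @return PET data.frame in the [extract_pets()] layout.
#' @export
read_pets_bedpe <- function(path) {
  df <- read_bedpe(path)
  bait_mid <- floor((df$start1 + df$end1) / 2)
  inter <- df$chrom1 != df$chrom2
  out <- data.frame(bait_id = if (!is.null(df$name)) df$name else ".",
                    bait_chrom = df$chrom1, bait_mid = bait_mid,
                    partner_chrom = df$chrom2, partner_pos = df$start2,
                    distance = ifelse(inter, NA_real_, abs(bait_mid - df$start2)),
                    inter = inter, bait_bait = FALSE,
                    read_id = sprintf("pet%06d", seq_len(nrow(df))),
                    stringsAsFactors = FALSE)
  out
}
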