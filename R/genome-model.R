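#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels
#' @importFrom stats rnbinom rpois rnorm runif setNames
#' @importFrom utils read.table write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib capture3c, .registration = TRUE
NULL

## Internal convention: all in-memory intervals are GRanges (1-based, closed).
## BED/BEDPE on disk are 0-based half-open; conversion happens only in the
## readers/writers below. GTF on disk is 1-based closed, imported as-is.

#' Construct a genome (chromosome-size map)
#'
#' @param seqlengths named numeric vector of chromosome lengths in bp.
#' @return A named integer-like vector of class `Genome`.
#' @examples
#' g <- Genome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
Genome <- function(seqlengths) {
  if (is.null(names(seqlengths)) || any(names(seqlengths) == "") ||
      anyDuplicated(names(seqlengths)))
    stop("chromosome names must be present and unique")
  if (any(!is.finite(seqlengths)) || any(seqlengths <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(round(as.numeric(seqlengths)), names = names(seqlengths),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x), "chromosomes,",
      format(sum(x), big.mark = ","), "bp total\n")
  invisible(x)
}

## split file into tokenized lines, skipping blanks and track/browser/# lines
.read_lines_tokens <- function(path, min_fields, what) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  toks <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(toks)
  if (any(nf < min_fields)) {
    bad <- idx[which(nf < min_fields)[1L]]
    stop(sprintf("%s: malformed %s line %d (expected >= %d tab-separated fields)",
                 path, what, bad, min_fields))
  }
  list(tokens = toks, lineno = idx)
}

.as_num_or_stop <- function(x, path, lineno, what, field) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    bad <- lineno[which(is.na(v))[1L]]
    stop(sprintf("%s: malformed %s line %d (non-numeric %s)", path, what, bad, field))
  }
  v
}

#' Read a chrom.sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path file path.
#' @return A [Genome()].
#' @export
read_chrom_sizes <- function(path) {
  p <- .read_lines_tokens(path, 2L, "chrom.sizes")
  nm <- vapply(p$tokens, `[[`, "", 1L)
  len <- .as_num_or_stop(vapply(p$tokens, `[[`, "", 2L), path, p$lineno,
                         "chrom.sizes", "length")
  Genome(setNames(len, nm))
}

#' Write a chrom.sizes file
#' @param genome a [Genome()].
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(paste(names(genome), format(unclass(genome), scientific = FALSE,
                                         trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' BED is 0-based half-open on disk; the returned GRanges is 1-based closed.
#' Columns beyond the first three are taken as name, score, strand when present.
#'
#' @param path file path.
#' @param genome optional [Genome()]; when given, intervals are validated
#'   against chromosome bounds and seqlengths are attached.
#' @param extra_cols optional character vector naming additional columns after
#'   the standard six; stored in `mcols`.
#' @return GRanges.
#' @export
read_bed <- function(path, genome = NULL, extra_cols = NULL) {
  p <- .read_lines_tokens(path, 3L, "BED")
  chrom <- vapply(p$tokens, `[[`, "", 1L)
  start0 <- .as_num_or_stop(vapply(p$tokens, `[[`, "", 2L), path, p$lineno, "BED", "start")
  end0 <- .as_num_or_stop(vapply(p$tokens, `[[`, "", 3L), path, p$lineno, "BED", "end")
  if (any(start0 < 0 | end0 <= start0)) {
    bad <- p$lineno[which(start0 < 0 | end0 <= start0)[1L]]
    stop(sprintf("%s: malformed BED line %d (need 0 <= start < end)", path, bad))
  }
  nf <- lengths(p$tokens)
  getcol <- function(k) ifelse(nf >= k, vapply(p$tokens, function(t)
    if (length(t) >= k) t[[k]] else NA_character_, ""), NA_character_)
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  if (any(nf >= 4L)) mcols(gr)$name <- getcol(4L)
  if (any(nf >= 5L)) {
    sc <- suppressWarnings(as.numeric(getcol(5L)))
    mcols(gr)$score <- sc
  }
  if (any(nf >= 6L)) {
    st <- getcol(6L)
    st[is.na(st) | !st %in% c("+", "-")] <- "*"
    strand(gr) <- st
  }
  if (!is.null(extra_cols)) {
    for (i in seq_along(extra_cols))
      mcols(gr)[[extra_cols[i]]] <- getcol(6L + i)
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
      stop(sprintf("%s: chromosome(s) not in genome: %s", path,
                   paste(unknown, collapse = ", ")))
    if (any(end0 > unclass(genome)[chrom]))
      stop(sprintf("%s: interval beyond chromosome end", path))
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unclass(genome)
  }
  gr
}

#' Write a GRanges to a BED file (0-based half-open on disk)
#'
#' @param gr GRanges; `mcols` columns `name` and `score` are written when
#'   present, plus any columns named in `extra_cols`.
#' @param path output path.
#' @param extra_cols optional extra mcols columns to append after strand.
#' @export
write_bed <- function(gr, path, extra_cols = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr),
                   stringsAsFactors = FALSE)
  mc <- mcols(gr)
  n_std <- 3L
  if (!is.null(mc$name) || !is.null(extra_cols) || !is.null(mc$score)) {
    df$name <- if (!is.null(mc$name)) mc$name else "."
    n_std <- 4L
  }
  if (!is.null(mc$score) || !is.null(extra_cols)) {
    df$score <- if (!is.null(mc$score)) mc$score else 0
    df$strand <- sub("\\*", ".", as.character(strand(gr)))
    n_std <- 6L
  }
  for (col in extra_cols) df[[col]] <- mc[[col]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file
#'
#' @param path file path.
#' @return data.frame with 1-based closed coordinates: chrom1, start1, end1,
#'   chrom2, start2, end2, and name/score when present.
#' @export
read_bedpe <- function(path) {
  p <- .read_lines_tokens(path, 6L, "BEDPE")
  col <- function(k) vapply(p$tokens, `[[`, "", k)
  num <- function(k, f) .as_num_or_stop(col(k), path, p$lineno, "BEDPE", f)
  df <- data.frame(chrom1 = col(1L), start1 = num(2L, "start1") + 1,
                   end1 = num(3L, "end1"),
                   chrom2 = col(4L), start2 = num(5L, "start2") + 1,
                   end2 = num(6L, "end2"), stringsAsFactors = FALSE)
  nf <- lengths(p$tokens)
  if (any(nf >= 7L)) df$name <- vapply(p$tokens, function(t)
    if (length(t) >= 7L) t[[7L]] else ".", "")
  if (any(nf >= 8L)) df$score <- suppressWarnings(as.numeric(
    vapply(p$tokens, function(t) if (length(t) >= 8L) t[[8L]] else "0", "")))
  if (any(df$end1 < df$start1 - 1 | df$end2 < df$start2 - 1)) {
    stop(sprintf("%s: malformed BEDPE interval", path))
  }
  df
}

#' Write a BEDPE file (0-based half-open on disk)
#'
#' @param df data.frame as returned by [read_bedpe()] (1-based closed).
#' @param path output path.
#' @export
write_bedpe <- function(df, path) {
  out <- data.frame(df$chrom1, df$start1 - 1, df$end1,
                    df$chrom2, df$start2 - 1, df$end2,
                    stringsAsFactors = FALSE)
  if (!is.null(df$name)) out[[7]] <- df$name
  if (!is.null(df$score)) {
    if (is.null(df$name)) out[[7]] <- "."
    out[[8]] <- df$score
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports GENCODE-style GTF (via rtracklayer) and reduces it to one record
#' per gene with a strand-aware transcription start site: TSS is the gene-body
#' start on `+` and the gene-body end on `-`.
#'
#' @param path GTF path.
#' @return data.frame: gene_id, gene_name, chrom, start, end (1-based closed),
#'   strand, tss.
#' @export
read_gene_models <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  feat <- if ("type" %in% names(mcols(gtf))) as.character(mcols(gtf)$type) else
    rep("gene", length(gtf))
  genes <- gtf[feat == "gene"]
  if (length(genes) == 0L) {           # derive gene bodies from transcripts
    tx <- gtf[feat %in% c("transcript", "mRNA")]
    if (length(tx) == 0L) stop(sprintf("%s: no gene or transcript features", path))
    sp <- split(tx, mcols(tx)$gene_id)
    genes <- unlist(range(sp))
    mcols(genes)$gene_id <- names(genes)
    mcols(genes)$gene_name <- names(genes)
  }
  gid <- mcols(genes)$gene_id
  gname <- mcols(genes)$gene_name
  if (is.null(gname)) gname <- gid
  st <- as.character(strand(genes))
  data.frame(gene_id = gid,
             gene_name = ifelse(is.na(gname), gid, gname),
             chrom = as.character(seqnames(genes)),
             start = start(genes), end = end(genes),
             strand = st,
             tss = ifelse(st == "-", end(genes), start(genes)),
             stringsAsFactors = FALSE)
}

#' Read/write a TSV matrix with a header row and row-name column
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_tsv_matrix
#' @param m matrix with dimnames.
#' @export
write_tsv_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise interval overlap (half-open semantics)
#'
#' Element-wise test whether intervals in `a` overlap intervals in `b`
#' (recycled). Strand is ignored: 3C contacts are strandless.
#'
#' @param a,b GRanges of equal length (or length 1).
#' @return logical vector.
#' @export
overlaps <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    start(a) <= end(b) & start(b) <= end(a)
}

#' Remove peaks overlapping a blacklist
#'
#' Whole-peak removal (not clipping): any peak overlapping any blacklist
#' interval is dropped.
#'
#' @param peaks,blacklist GRanges.
#' @return GRanges subset of `peaks`.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  if (length(blacklist) == 0L || length(peaks) == 0L) return(peaks)
  peaks[!overlapsAny(peaks, blacklist, ignore.strand = TRUE)]
}

## midpoint of a 1-based closed interval, vectorized
.gr_mid <- function(gr) floor((start(gr) + end(gr)) / 2)
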