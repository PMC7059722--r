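## Depth- and length-normalized signal metrics and cross-timepoint
## normalization.

#' PETs per kilobase of bait region per million read pairs (PPKM)
#'
#' PPKM = PETs * 1e9 / (region size in bp * total read pairs). The single
#' 1e9 factor implements "per kilobase ... per million" exactly, with no
#' intermediate rounding.
#'
#' @param pets PET count(s).
#' @param size_bp captured region size in bp (> 0).
#' @param total_pairs library size: total deduplicated, MAPQ-filtered read
#'   pairs (> 0). Use a consistent denominator across samples.
#' @return numeric PPKM value(s).
#' @examples
#' ppkm(100, 1000, 1e6)  # 100
#' @export
ppkm <- function(pets, size_bp, total_pairs) {
  if (any(size_bp <= 0)) stop("size_bp must be positive")
  if (any(total_pairs <= 0)) stop("total_pairs must be positive")
  pets * 1e9 / (size_bp * total_pairs)
}

#' Fragments per kilobase per million mapped reads (FPKM)
#'
#' Same formula and contracts as [ppkm()], for read/fragment counts over a
#' transcript or captured region.
#'
#' @param fragments fragment count(s).
#' @param size_bp region/transcript size in bp (> 0).
#' @param total_mapped total mapped reads (> 0).
#' @return numeric FPKM value(s).
#' @export
fpkm <- function(fragments, size_bp, total_mapped) {
  if (any(size_bp <= 0)) stop("size_bp must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  fragments * 1e9 / (size_bp * total_mapped)
}

#' Normalize a time-course signal by its mean over all timepoints
#'
#' Each value is divided by the mean of the series, so the normalized series
#' has mean 1 (NPPKM/NFPKM); this puts different data types on a common
#' relative scale across timepoints.
#'
#' @param values ordered non-negative numeric vector (one per timepoint).
#' @return normalized vector with mean 1; an all-zero input is returned
#'   unchanged with a warning.
#' @examples
#' normalize_timecourse(c(2, 4, 6, 8, 10))
#' @export
normalize_timecourse <- function(values) {
  if (any(values < 0)) stop("values must be non-negative")
  m <- mean(values)
  if (m == 0) {
    warning("all-zero time course; returning zeros")
    return(values)
  }
  values / m
}
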