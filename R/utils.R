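#' @useDynLib tecurate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# All in-memory coordinates in this package are 0-based half-open.
# Conversions to/from the 1-based inclusive conventions of the external
# dialects happen only inside the parsers/serializers in io-*.R.

#' Union of 0-based half-open intervals
#'
#' @param starts,ends integer vectors of equal length (0-based half-open).
#' @return data.frame with columns `start`, `end`: disjoint, sorted intervals.
#' @keywords internal
interval_union <- function(starts, ends) {
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  stopifnot(length(starts) == length(ends), all(ends > starts))
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Total length covered by a set of intervals
#' @keywords internal
interval_union_length <- function(starts, ends) {
  u <- interval_union(starts, ends)
  sum(u$end - u$start)
}

# per-row overlap (in bases) between intervals [s1,e1) and a fixed interval set
interval_overlap_length <- function(s1, e1, mask) {
  if (nrow(mask) == 0L) return(rep(0L, length(s1)))
  a <- IRanges::IRanges(start = s1 + 1L, end = e1)
  b <- IRanges::reduce(IRanges::IRanges(start = mask$start + 1L, end = mask$end))
  ov <- IRanges::pintersect(IRanges::findOverlapPairs(a, b))
  out <- rep(0L, length(s1))
  hits <- IRanges::findOverlaps(a, b)
  if (length(hits) > 0L) {
    w <- IRanges::width(ov)
    out_tab <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(out_tab))] <- as.integer(out_tab)
  }
  out
}

#' Reverse complement of a DNA string
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  gc / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
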