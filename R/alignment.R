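#' Local pairwise alignment of two DNA sequences
#'
#' Smith-Waterman alignment with a linear gap penalty. The pipeline uses it
#' to verify identity/coverage claims of hit tables; it is deliberately a
#' simple scoring scheme (match/mismatch/gap), not a biologically tuned
#' aligner. Ties between maximal-scoring alignments are broken
#' deterministically by earliest query start, then earliest subject start,
#' then fewest gaps.
#'
#' @param a,b DNA strings over `{A,C,G,T}`; both nonempty.
#' @param match,mismatch,gap scoring parameters (linear gap penalty).
#' @return a list of class `local_alignment` with elements `score`,
#'   `identity` (matches / aligned columns; 0 for an empty alignment),
#'   `matches`, `aligned_columns`, `gaps`, and `q_interval`, `s_interval`
#'   (0-based half-open; empty `[0,0)` when no cell scores above zero).
#' @examples
#' local_align("ACGTACGT", "ACGTACGT")$score  # 16
#' @export
local_align <- function(a, b, match = 2L, mismatch = -1L, gap = -2L) {
  if (!nzchar(a) || !nzchar(b)) stop("local_align: sequences must be nonempty")
  a <- toupper(a); b <- toupper(b)
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) {
    stop("local_align: sequences must be over {A,C,G,T}")
  }
  r <- .local_align_cpp(a, b, as.integer(match), as.integer(mismatch),
                        as.integer(gap))
  identity <- if (r$aligned_columns > 0) r$matches / r$aligned_columns else 0
  structure(list(
    score = r$score,
    identity = identity,
    matches = r$matches,
    aligned_columns = r$aligned_columns,
    gaps = r$gaps,
    q_interval = c(r$q_start, r$q_end),
    s_interval = c(r$s_start, r$s_end)
  ), class = "local_alignment")
}

#' DUST-style low-complexity masking
#'
#' Slides a window along the sequence and scores its triplet composition:
#' `score = sum(c_t * (c_t - 1) / 2) / (w - 3)` over the counts `c_t` of the
#' 64 possible triplets in the window. Windows whose score exceeds
#' `score_thresh` are masked entirely; overlapping masked windows are
#' merged. A homopolymer scores ~(w-2)/2 (~31 for w = 64); uniform random
#' DNA scores ~0.5, so the default threshold of 2 leaves random sequence
#' almost untouched.
#'
#' @param seq DNA string (characters outside `{A,C,G,T}` never match any
#'   triplet and dilute the score).
#' @param window window width in nt.
#' @param score_thresh masking threshold; windows scoring strictly above it
#'   are masked.
#' @return a `mask_track`: list with `seq_len` and `intervals` (data.frame
#'   of disjoint sorted 0-based half-open intervals).
#' @export
dust_mask <- function(seq, window = 64L, score_thresh = 2.0) {
  n <- nchar(seq)
  empty <- structure(list(seq_len = n,
                          intervals = data.frame(start = integer(0),
                                                 end = integer(0))),
                     class = "mask_track")
  if (n < 3L) return(empty)
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(s, c("A", "C", "G", "T")) - 1L  # NA for ambiguity codes
  ntrip <- n - 2L
  trip <- code[seq_len(ntrip)] * 16L + code[seq_len(ntrip) + 1L] * 4L +
    code[seq_len(ntrip) + 2L]                    # NA propagates
  w <- min(as.integer(window), n)
  wt <- w - 2L                                   # triplets per window
  denom <- max(1L, w - 3L)
  counts <- integer(64)
  score2 <- 0                                    # sum c*(c-1)/2 (doubled bookkeeping avoided)
  add <- function(t) {
    if (!is.na(t)) {
      counts[t + 1L] <<- counts[t + 1L] + 1L
      score2 <<- score2 + (counts[t + 1L] - 1L)
    }
  }
  drop1 <- function(t) {
    if (!is.na(t)) {
      score2 <<- score2 - (counts[t + 1L] - 1L)
      counts[t + 1L] <<- counts[t + 1L] - 1L
    }
  }
  for (k in seq_len(wt)) add(trip[k])
  starts <- integer(0); ends <- integer(0)
  nwin <- ntrip - wt + 1L
  for (i in seq_len(nwin)) {
    if (score2 / denom > score_thresh) {
      starts <- c(starts, i - 1L)
      ends <- c(ends, i - 1L + w)
    }
    if (i < nwin) {
      drop1(trip[i])
      add(trip[i + wt])
    }
  }
  if (length(starts) == 0L) return(empty)
  u <- interval_union(starts, pmin(ends, n))
  structure(list(seq_len = n, intervals = u), class = "mask_track")
}

#' Tandem-repeat content of a sequence
#'
#' Internal stand-in for a full tandem-repeat finder: for each candidate
#' period `p`, positions where `seq[i] == seq[i + p]` are scanned for
#' maximal runs whose cumulative match rate stays at or above
#' `min_identity`. A qualifying run of match positions spanning `[i, j]`
#' yields a repeat region `[i, j + p)` which must be at least
#' `max(min_copies * p, min_array_nt)` long. Periods are scanned in
#' ascending order and runs almost entirely (>= 90%) covered by
#' smaller-period records are dropped, which suppresses harmonics. When a
#' genuine TRF `.dat` file is available, prefer its records (see
#' [read_trf_dat()] and [tandem_filter()]); this detector is the fallback.
#'
#' @param seq DNA string, length >= 2.
#' @param max_period largest period scanned.
#' @param min_copies minimum number of motif copies in a reported region.
#' @param min_identity minimum match rate within a reported region.
#' @param min_array_nt minimum total length of a reported region; filters
#'   the chance micro-runs that random sequence produces at small periods.
#' @return list with `fraction` (covered bases / sequence length) and
#'   `records` (data.frame: `start`, `end`, `period`, `copies`).
#' @export
tandem_fraction <- function(seq, max_period = 100L, min_copies = 2.0,
                            min_identity = 0.85, min_array_nt = 12L) {
  n <- nchar(seq)
  if (n < 2L) stop("tandem_fraction: sequence must have length >= 2")
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  recs <- data.frame(start = integer(0), end = integer(0),
                     period = integer(0), copies = numeric(0))
  accepted <- data.frame(start = integer(0), end = integer(0))
  for (p in seq_len(min(max_period, n %/% 2L))) {
    L <- n - p
    m <- s[seq_len(L)] == s[seq_len(L) + p]
    i <- 1L
    while (i <= L) {
      if (!m[i]) { i <- i + 1L; next }
      matches <- 0L; tot <- 0L; best_end <- i - 1L
      j <- i
      while (j <= L) {
        tot <- tot + 1L
        if (m[j]) {
          matches <- matches + 1L
          if (matches / tot >= min_identity) best_end <- j
        }
        if (matches / tot < min_identity) break
        j <- j + 1L
      }
      if (best_end >= i) {
        start0 <- i - 1L
        end0 <- best_end + p              # half-open; includes trailing motif
        len <- end0 - start0
        if (len >= max(min_copies * p, min_array_nt)) {
          ov <- interval_overlap_length(start0, end0, accepted)
          if (ov / len <= 0.9) {
            recs <- rbind(recs, data.frame(start = start0, end = end0,
                                           period = p, copies = len / p))
            accepted <- interval_union(c(accepted$start, start0),
                                       c(accepted$end, end0))
          }
        }
      }
      i <- j + 1L
    }
  }
  frac <- if (nrow(recs) == 0L) 0 else
    interval_union_length(recs$start, recs$end) / n
  list(fraction = frac, records = recs)
}

#' Six-frame translation and ORF finding
#'
#' ORFs are maximal stop-free stretches of at least `min_aa` residues in
#' any of the six reading frames; a start codon is *not* required, because
#' the downstream use is protein-domain evidence on (possibly truncated)
#' consensus models, not gene calling. Coordinates are reported on the
#' forward strand of the input, 0-based half-open.
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @param min_aa minimum ORF length in amino acids.
#' @return data.frame with columns `frame` (+1..+3, -1..-3), `m_start`,
#'   `m_end` (nt, forward strand), `peptide`.
#' @export
six_frame_orfs <- function(seq, min_aa = 50L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- data.frame(frame = integer(0), m_start = integer(0),
                    m_end = integer(0), peptide = character(0))
  orfs_one_strand <- function(s, sign) {
    res <- list()
    for (f in 1:3) {
      sub <- substring(s, f)
      ncod <- nchar(sub) %/% 3L
      if (ncod < 1L) next
      sub <- substring(sub, 1L, ncod * 3L)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
      stops <- c(0L, which(strsplit(aa, "", fixed = TRUE)[[1]] == "*"),
                 nchar(aa) + 1L)
      for (k in seq_len(length(stops) - 1L)) {
        a0 <- stops[k]          # aa index before the stretch (1-based math)
        a1 <- stops[k + 1L] - 1L
        if (a1 - a0 < min_aa) next
        pep <- substring(aa, a0 + 1L, a1)
        nt0 <- (f - 1L) + 3L * a0          # 0-based on this strand
        nt1 <- (f - 1L) + 3L * a1
        if (sign > 0) {
          res[[length(res) + 1L]] <- data.frame(
            frame = f, m_start = nt0, m_end = nt1, peptide = pep)
        } else {
          res[[length(res) + 1L]] <- data.frame(
            frame = -f, m_start = n - nt1, m_end = n - nt0, peptide = pep)
        }
      }
    }
    res
  }
  res <- c(orfs_one_strand(seq, 1L), orfs_one_strand(revcomp(seq), -1L))
  if (length(res) > 0L) out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$frame, out$m_start), , drop = FALSE]
}
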