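# Per-genome mobilome statistics: merged repeat coverage, coverage
# percentages, presence/absence matrices, GC-median splits.

#' Merge genomic hit intervals per contig
#'
#' Union of the subject (genomic) intervals per contig; each genomic base
#' is counted once no matter how many models hit it.
#'
#' @param hits model-vs-genome hit data.frame (`subject_id` = contig,
#'   `s_start`/`s_end` 0-based half-open).
#' @param contig_lengths optional named integer vector; when given, a hit
#'   extending past its contig is an error.
#' @return list with `intervals` (data.frame `contig_id`, `start`, `end`)
#'   and `covered` (total bases).
#' @export
merge_intervals <- function(hits, contig_lengths = NULL) {
  if (nrow(hits) == 0L) {
    return(list(intervals = data.frame(contig_id = character(0),
                                       start = integer(0), end = integer(0)),
                covered = 0L))
  }
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[hits$subject_id]
    if (any(is.na(lim))) {
      stop("hit on contig without a known length: ",
           paste(unique(hits$subject_id[is.na(lim)]), collapse = ", "))
    }
    if (any(hits$s_end > lim)) {
      stop("hit interval exceeds contig length on ",
           paste(unique(hits$subject_id[hits$s_end > lim]), collapse = ", "))
    }
  }
  per <- lapply(split(hits, hits$subject_id), function(h) {
    u <- interval_union(h$s_start, h$s_end)
    data.frame(contig_id = h$subject_id[1], start = u$start, end = u$end,
               stringsAsFactors = FALSE)
  })
  intervals <- do.call(rbind, per)
  rownames(intervals) <- NULL
  list(intervals = intervals,
       covered = sum(intervals$end - intervals$start))
}

#' Per-genome TE coverage summary
#'
#' `te_percent` is `100 * covered / assembly_length` rounded to two
#' decimals with round-half-even (R's `round`).
#'
#' @param genome_id genome name.
#' @param covered merged TE-covered bases.
#' @param assembly_length assembly size in nt (> 0).
#' @param copy_count optional TE copy count.
#' @param main_family optional main family label.
#' @return one-row data.frame (`genome_id`, `assembly_length`,
#'   `te_covered`, `te_percent`, `copy_count`, `main_family`).
#' @export
genome_te_coverage <- function(genome_id, covered, assembly_length,
                               copy_count = NA_integer_,
                               main_family = NA_character_) {
  if (assembly_length <= 0) stop("assembly_length must be > 0")
  if (covered > assembly_length) {
    stop("covered (", covered, ") exceeds assembly length (",
         assembly_length, ") for ", genome_id)
  }
  data.frame(genome_id = genome_id,
             assembly_length = assembly_length,
             te_covered = covered,
             te_percent = round(100 * covered / assembly_length, 2),
             copy_count = copy_count,
             main_family = main_family,
             stringsAsFactors = FALSE)
}

#' Presence/absence matrix of TE families across genomes
#'
#' @param counts data.frame with `genome_id`, `family`, `copy_count`; one
#'   row per (genome, family). Presence is `copy_count > 0`.
#' @param genomes optional character vector of all genomes (rows); genomes
#'   without any counts appear as all-`FALSE` rows.
#' @param families optional character vector of all families (columns).
#' @return logical matrix, genomes x families.
#' @export
build_presence_matrix <- function(counts, genomes = NULL, families = NULL) {
  if (anyDuplicated(counts[c("genome_id", "family")])) {
    stop("duplicate (genome, family) row in counts")
  }
  genomes <- genomes %||% sort(unique(counts$genome_id))
  if (anyDuplicated(genomes)) stop("duplicate genome id")
  families <- families %||% sort(unique(counts$family))
  m <- matrix(FALSE, nrow = length(genomes), ncol = length(families),
              dimnames = list(genomes, families))
  if (nrow(counts) > 0L) {
    present <- counts[counts$copy_count > 0, , drop = FALSE]
    unknown <- setdiff(present$genome_id, genomes)
    if (length(unknown) > 0L) {
      stop("counts reference unknown genome: ", paste(unknown, collapse = ", "))
    }
    m[cbind(present$genome_id, present$family)] <- TRUE
  }
  m
}

#' GC-median split of TE presence
#'
#' Splits genomes at the median GC content (lower median for even counts,
#' documented convention) and counts TE-bearing genomes strictly below vs
#' at-or-above the median.
#'
#' @param metadata data.frame with `gc_percent` (in (0,100)) and logical
#'   `has_te`.
#' @return list with `median_gc`, `n_below`, `n_at_or_above`,
#'   `te_below`, `te_at_or_above`.
#' @export
gc_split_summary <- function(metadata) {
  stopifnot(nrow(metadata) >= 2L,
            all(metadata$gc_percent > 0 & metadata$gc_percent < 100))
  gc <- metadata$gc_percent
  med <- sort(gc)[ceiling(length(gc) / 2)]  # lower median for even n
  below <- gc < med
  list(median_gc = med,
       n_below = sum(below),
       n_at_or_above = sum(!below),
       te_below = sum(metadata$has_te & below),
       te_at_or_above = sum(metadata$has_te & !below))
}

#' Summarize the mobilome of several genomes
#'
#' Runs [merge_intervals()] and [genome_te_coverage()] per genome and
#' derives the main family per genome by covered bases.
#'
#' @param genome_hits model-vs-genome hits with `genome_id` column.
#' @param assembly_lengths named numeric vector (genome id -> nt).
#' @param classifications data.frame (`model_id`, `family`) from
#'   [curate_models()]; optional, used for `main_family` and the
#'   per-family copy counts.
#' @param contig_lengths optional named vector for bounds checking.
#' @return list with `summaries` (one row per genome, incl. zero-hit
#'   genomes) and `family_counts` (`genome_id`, `family`, `copy_count`).
#' @export
summarize_mobilome <- function(genome_hits, assembly_lengths,
                               classifications = NULL,
                               contig_lengths = NULL) {
  fam_of <- function(ids) {
    if (is.null(classifications)) return(rep(NA_character_, length(ids)))
    classifications$family[match(ids, classifications$model_id)]
  }
  summaries <- list(); fam_counts <- list()
  for (g in names(assembly_lengths)) {
    h <- genome_hits[genome_hits$genome_id == g, , drop = FALSE]
    cov <- merge_intervals(h, contig_lengths)$covered
    fams <- fam_of(h$query_id)
    main <- NA_character_
    if (nrow(h) > 0L && any(!is.na(fams))) {
      by_fam <- tapply(h$s_end - h$s_start, fams, sum)
      main <- names(by_fam)[which.max(by_fam)]
      fam_counts[[g]] <- data.frame(genome_id = g,
                                    family = names(table(fams)),
                                    copy_count = as.integer(table(fams)),
                                    stringsAsFactors = FALSE)
    }
    summaries[[g]] <- genome_te_coverage(g, cov, assembly_lengths[[g]],
                                         copy_count = nrow(h),
                                         main_family = main)
  }
  list(summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       family_counts = if (length(fam_counts))
         do.call(rbind, c(fam_counts, list(make.row.names = FALSE))) else
           data.frame(genome_id = character(0), family = character(0),
                      copy_count = integer(0)))
}
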