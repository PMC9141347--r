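# Tabular dialects. Files carry the conventions of the tools that emit
# them (1-based inclusive coordinates, percent identities); everything is
# normalized to 0-based half-open fractions at the parser boundary.

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_len = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), evalue = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read BLAST tabular hits (outfmt 6)
#'
#' Expects the 12-column tab-separated dialect (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`);
#' extra columns are ignored. File coordinates are 1-based inclusive;
#' subject intervals with `sstart > send` are stored ascending with strand
#' `"-"`. Percent identity is converted to a fraction.
#'
#' @param path tab-separated hits file.
#' @return data.frame of alignment hits with columns `query_id`,
#'   `subject_id`, `pct_identity` (fraction), `aln_len`, `q_start`,
#'   `q_end`, `s_start`, `s_end` (0-based half-open), `strand`, `evalue`,
#'   `score`; file order preserved.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 12L) {
      stop("line ", i, ": expected >= 12 tab-separated columns, got ",
           length(p))
    }
    num <- suppressWarnings(as.numeric(p[3:12]))
    if (anyNA(num)) {
      stop("line ", i, ": non-numeric value in column ",
           which(is.na(num))[1] + 2L)
    }
    qs <- num[5]; qe <- num[6]; ss <- num[7]; se <- num[8]
    strand <- if (ss <= se) "+" else "-"
    rows[[i]] <- data.frame(
      query_id = p[1], subject_id = p[2],
      pct_identity = num[1] / 100, aln_len = as.integer(num[2]),
      q_start = as.integer(qs - 1L), q_end = as.integer(qe),
      s_start = as.integer(min(ss, se) - 1L), s_end = as.integer(max(ss, se)),
      strand = strand, evalue = num[9], score = num[10],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Write alignment hits as BLAST tabular (outfmt 6)
#'
#' Inverse of [read_tabular_hits()]: coordinates go back to 1-based
#' inclusive and minus-strand subject intervals are swapped to descending.
#' Mismatch and gap-open counts are not tracked internally and are written
#' as 0.
#'
#' @param hits alignment-hit data.frame.
#' @param path output file.
#' @export
write_tabular_hits <- function(hits, path) {
  mism <- round((1 - hits$pct_identity) * hits$aln_len)
  ss <- ifelse(hits$strand == "+", hits$s_start + 1L, hits$s_end)
  se <- ifelse(hits$strand == "+", hits$s_end, hits$s_start + 1L)
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.4g",
                   hits$query_id, hits$subject_id, hits$pct_identity * 100,
                   hits$aln_len, mism, 0L,
                   hits$q_start + 1L, hits$q_end, ss, se,
                   hits$evalue, hits$score)
  writeLines(lines, path)
  invisible(path)
}

#' Read RepeatMasker .out annotation
#'
#' Standard layout: two header lines plus a blank line, then whitespace-
#' separated rows where the query is a genome contig and the matching
#' repeat is a library model. `C` in the strand column means minus strand.
#' The three repeat-position columns contain one parenthesized
#' "(bases left)" entry whose position depends on strand; it is dropped
#' and the remaining two positions ordered ascending.
#'
#' @param path RepeatMasker `.out` file.
#' @return alignment-hit data.frame (query = model, subject = contig;
#'   `pct_identity` = 1 - divergence/100); 0-based half-open coordinates.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # skip the two header lines and any blank lines
  body <- which(!grepl("^\\s*$", lines) &
                  !grepl("^\\s*(SW|score)\\s", lines) &
                  !grepl("perc perc|div\\. del\\.", lines))
  body <- setdiff(body, 1:2)
  if (length(body) == 0L) return(empty_hits())
  rows <- vector("list", length(body))
  for (k in seq_along(body)) {
    i <- body[k]
    p <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(p) < 14L) {
      stop("line ", i, ": truncated RepeatMasker row (", length(p),
           " fields)")
    }
    num <- suppressWarnings(as.numeric(p[c(1:4, 6:7)]))
    if (anyNA(num)) stop("line ", i, ": non-numeric field in RepeatMasker row")
    reppos <- p[12:14]
    open_par <- grepl("^\\(", reppos)
    if (sum(open_par) != 1L) {
      stop("line ", i, ": expected one parenthesized repeat-left field")
    }
    rp <- as.numeric(reppos[!open_par])
    rows[[k]] <- data.frame(
      query_id = p[10], subject_id = p[5],
      pct_identity = 1 - num[2] / 100, aln_len = as.integer(num[6] - num[5] + 1),
      q_start = as.integer(min(rp) - 1L), q_end = as.integer(max(rp)),
      s_start = as.integer(num[5] - 1L), s_end = as.integer(num[6]),
      strand = if (p[9] == "C") "-" else "+",
      evalue = 0, score = num[1],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Read Tandem Repeats Finder .dat output
#'
#' Parses the "Sequence:" block dialect: each `Sequence: <id>` line starts
#' a block whose data rows begin with `start end period copies ...`
#' (1-based inclusive).
#'
#' @param path TRF `.dat` file.
#' @return data.frame with `model_id`, `start`, `end` (0-based half-open),
#'   `period`, `copies`.
#' @export
read_trf_dat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  cur <- NA_character_
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "Sequence:")) {
      cur <- trimws(sub("^Sequence:", "", ln))
      next
    }
    p <- strsplit(ln, "\\s+")[[1]]
    if (is.na(suppressWarnings(as.numeric(p[1])))) next  # parameter lines etc.
    if (is.na(cur)) stop("line ", i, ": data row before any 'Sequence:' header")
    if (length(p) < 4L) stop("line ", i, ": truncated TRF row")
    num <- suppressWarnings(as.numeric(p[1:4]))
    if (anyNA(num)) stop("line ", i, ": non-numeric TRF field")
    start0 <- as.integer(num[1] - 1L); end0 <- as.integer(num[2])
    period <- as.integer(num[3])
    if (end0 - start0 < 2L * period) {
      stop("line ", i, ": tandem record shorter than two periods")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model_id = cur, start = start0, end = end0,
      period = period, copies = num[4], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(model_id = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      copies = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Write tandem records as TRF-style .dat
#' @param records data.frame as returned by [read_trf_dat()].
#' @param path output file.
#' @export
write_trf_dat <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in unique(records$model_id)) {
    writeLines(paste("Sequence:", id), con)
    r <- records[records$model_id == id, , drop = FALSE]
    writeLines(sprintf("%d %d %d %.1f", r$start + 1L, r$end, r$period,
                       r$copies), con)
  }
  invisible(path)
}

#' Read exon records from GFF3
#'
#' Keeps `exon` features only; start/end are converted from the GFF
#' 1-based inclusive convention. Features whose coordinates are missing
#' (`.`) are skipped with a warning. The free-text product is taken from
#' the `product=` (or `description=`) attribute when present.
#'
#' @param path GFF3 file.
#' @param genome_id genome the annotation belongs to (GFF carries only
#'   contig ids).
#' @return data.frame with `genome_id`, `contig_id`, `start`, `end`
#'   (0-based half-open), `strand`, `product`.
#' @export
read_gff_exons <- function(path, genome_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- list()
  for (i in seq_along(lines)) {
    p <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(p) < 9L) next
    if (p[3] != "exon") next
    if (p[4] == "." || p[5] == ".") {
      warning("GFF exon without coordinates skipped (", p[1], ")")
      next
    }
    start <- as.integer(p[4]); end <- as.integer(p[5])
    if (is.na(start) || is.na(end) || end < start) {
      warning("GFF exon with unparseable coordinates skipped (", p[1], ")")
      next
    }
    attrs <- p[9]
    prod <- ""
    m <- regmatches(attrs, regexec("(?:^|;)\\s*(?:product|description)=([^;]*)",
                                   attrs))[[1]]
    if (length(m) == 2L) prod <- utils::URLdecode(m[2])
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = genome_id, contig_id = p[1],
      start = start - 1L, end = end, strand = p[7], product = prod,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(genome_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0)))
  }
  do.call(rbind, rows)
}

#' Write exon records as GFF3
#' @param exons data.frame as returned by [read_gff_exons()].
#' @param path output file.
#' @export
write_gff_exons <- function(exons, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttecurate\texon\t%d\t%d\t.\t%s\t.\tproduct=%s",
                     exons$contig_id, exons$start + 1L, exons$end,
                     exons$strand, exons$product))
  writeLines(lines, path)
  invisible(path)
}

EVIDENCE_SOURCES <- c("dfam", "interpro", "sprot", "known_te", "trna")

empty_evidence <- function() {
  data.frame(model_id = character(0), source = character(0),
             accession = character(0), description = character(0),
             te_related = logical(0), family_label = character(0),
             m_start = integer(0), m_end = integer(0), frame = integer(0),
             evalue = numeric(0), pseudo = logical(0),
             stringsAsFactors = FALSE)
}

#' Read a protein/profile evidence table
#'
#' Tab-separated with header columns `model_id source accession
#' description family_label m_start m_end frame evalue pseudo`. This is
#' the package's own dialect: coordinates are already 0-based half-open on
#' the model. `te_related` is (re)derived from the description with
#' [tag_te_relatedness()], never trusted from the file.
#'
#' @param path TSV file.
#' @return evidence data.frame.
#' @export
read_evidence_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (nrow(df) == 0L) return(empty_evidence())
  req <- c("model_id", "source", "accession", "description", "family_label",
           "m_start", "m_end", "frame", "evalue", "pseudo")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("evidence table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !df$source %in% EVIDENCE_SOURCES
  if (any(bad)) {
    stop("unknown evidence source: ", paste(unique(df$source[bad]),
                                            collapse = ", "))
  }
  if (any(df$m_end <= df$m_start)) stop("evidence interval with m_end <= m_start")
  df$pseudo <- as.logical(df$pseudo)
  df$frame <- as.integer(df$frame)
  df$description[is.na(df$description)] <- ""
  out <- tag_te_relatedness(df[req])
  out[c("model_id", "source", "accession", "description", "te_related",
        "family_label", "m_start", "m_end", "frame", "evalue", "pseudo")]
}

#' Write an evidence table
#' @param evidence evidence data.frame.
#' @param path output file.
#' @export
write_evidence_tsv <- function(evidence, path) {
  cols <- c("model_id", "source", "accession", "description", "family_label",
            "m_start", "m_end", "frame", "evalue", "pseudo")
  utils::write.table(evidence[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
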