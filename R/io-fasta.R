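#' Consensus-model container
#'
#' Consensus repeat models are kept in an ordinary data.frame with one row
#' per model and columns `model_id`, `sequence`, `length`, `source_genome`,
#' `status` (`candidate` / `discarded` / `accepted`), `discard_stage`,
#' `discard_reason`, `sine_flag`. Status only ever moves forward from
#' `candidate`.
#'
#' @param model_id unique character ids.
#' @param sequence DNA strings.
#' @param source_genome genome of origin or `"merged"`.
#' @return data.frame of class `consensus_models`.
#' @export
consensus_models <- function(model_id, sequence, source_genome = "merged") {
  if (anyDuplicated(model_id)) {
    stop("duplicate model id: ",
         paste(unique(model_id[duplicated(model_id)]), collapse = ", "))
  }
  sequence <- toupper(sequence)
  if (any(nchar(sequence) == 0L)) stop("empty sequence in model set")
  n <- length(model_id)
  df <- data.frame(
    model_id = as.character(model_id),
    sequence = sequence,
    length = nchar(sequence),
    source_genome = rep_len(as.character(source_genome), n),
    status = rep_len("candidate", n),
    discard_stage = rep_len(NA_character_, n),
    discard_reason = rep_len(NA_character_, n),
    sine_flag = rep_len(FALSE, n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("consensus_models", "data.frame")
  df
}

#' Read consensus models (or genomes) from FASTA
#'
#' Sequences are upper-cased and validated against `{A,C,G,T,N}`. Consensus
#' models must additionally be free of `N`: ambiguity handling stops at the
#' genome level, so a model containing `N` is rejected with a clear error
#' unless `allow_n = TRUE` (used when reading genome contigs).
#'
#' @param path FASTA file.
#' @param source_genome provenance label stored on each record.
#' @param allow_n permit `N` characters (genomes yes, models no).
#' @return `consensus_models` data.frame, in file order.
#' @export
read_fasta <- function(path, source_genome = "merged", allow_n = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(dss))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id: ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    offending <- ids[bad][1]
    if (!allow_n && any(grepl("N", seqs[bad]))) {
      stop("sequence '", offending, "' contains N; consensus models must be ",
           "unambiguous (read genomes with allow_n = TRUE)")
    }
    stop("sequence '", offending, "' contains characters outside {A,C,G,T,N}")
  }
  consensus_models(ids, seqs, source_genome)
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param x `consensus_models` data.frame or a named character vector.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    ids <- x$model_id
    seqs <- x$sequence
  } else {
    ids <- names(x)
    seqs <- unname(x)
  }
  con <- file(path, open = "wb")  # binary: byte-stable newlines
  on.exit(close(con))
  for (k in seq_along(ids)) {
    wrapped <- gsub("(.{60})", "\\1\n", seqs[[k]])
    wrapped <- sub("\n$", "", wrapped)
    writeLines(c(paste0(">", ids[[k]]), wrapped), con, sep = "\n")
  }
  invisible(path)
}
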