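# Evidence integration: vet protein/profile evidence against masked
# regions, apply the accept/discard rules, classify accepted models.

.te_vocab_env <- new.env(parent = emptyenv())

#' TE-keyword vocabulary
#'
#' The list of word-boundary keywords that mark a protein/profile
#' description as TE-related (reverse transcriptase, integrase, Gypsy,
#' ...). Shipped as an editable plain-text data file
#' (`extdata/te_keywords.txt`, one keyword per line, `#` comments) so the
#' vocabulary can grow without touching code.
#'
#' @param path optional alternative vocabulary file.
#' @return character vector of keywords (lower case).
#' @export
te_keywords <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.te_vocab_env$keywords)) return(.te_vocab_env$keywords)
    path <- system.file("extdata", "te_keywords.txt", package = "tecurate")
    lines <- readLines(path)
    kw <- tolower(trimws(lines[nzchar(trimws(lines)) &
                                  !startsWith(trimws(lines), "#")]))
    .te_vocab_env$keywords <- kw
    return(kw)
  }
  lines <- readLines(path)
  tolower(trimws(lines[nzchar(trimws(lines)) &
                         !startsWith(trimws(lines), "#")]))
}

description_is_te <- function(description, keywords = te_keywords()) {
  pat <- paste0("\\b(", paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                   keywords), collapse = "|"), ")\\b")
  grepl(pat, description, ignore.case = TRUE, perl = TRUE)
}

#' Tag evidence rows as TE-related
#'
#' Sets `te_related` from a case-insensitive word-boundary match of the
#' description against the keyword vocabulary ([te_keywords()]). The flag
#' is always derived, never read from input files.
#'
#' @param evidence evidence data.frame.
#' @param keywords keyword vector; defaults to the shipped vocabulary.
#' @return the evidence data.frame with `te_related` set.
#' @export
tag_te_relatedness <- function(evidence, keywords = te_keywords()) {
  evidence$te_related <- description_is_te(evidence$description, keywords)
  evidence
}

#' Vet evidence against masked regions
#'
#' Drops evidence rows whose model interval overlaps the low-complexity /
#' tandem mask by strictly more than `lowcomp_overlap_thresh` of the
#' interval, and rows shorter than `min_evidence_nt` (too short to be a
#' credible domain alignment).
#'
#' @param model one-row model slice.
#' @param evidence evidence data.frame.
#' @param mask a `mask_track` ([dust_mask()]), optionally widened with
#'   tandem intervals (see [model_mask()]).
#' @param config [pipeline_config()].
#' @return vetted evidence data.frame.
#' @export
screen_evidence <- function(model, evidence, mask,
                            config = pipeline_config()) {
  ev <- evidence[evidence$model_id == model$model_id, , drop = FALSE]
  if (nrow(ev) == 0L) return(ev)
  len <- ev$m_end - ev$m_start
  ov <- interval_overlap_length(ev$m_start, ev$m_end, mask$intervals)
  keep <- !(ov / len > config$lowcomp_overlap_thresh) &
    len >= config$min_evidence_nt
  ev[keep, , drop = FALSE]
}

#' Combined low-complexity and tandem mask for a model
#'
#' @param model one-row model slice.
#' @param config [pipeline_config()].
#' @param tandem_records optional external tandem records for the model.
#' @return a `mask_track`.
#' @export
model_mask <- function(model, config = pipeline_config(),
                       tandem_records = NULL) {
  dm <- dust_mask(model$sequence, window = config$dust_window,
                  score_thresh = config$dust_thresh)
  recs <- if (is.null(tandem_records)) {
    tandem_fraction(model$sequence)$records
  } else {
    tandem_records[tandem_records$model_id == model$model_id, , drop = FALSE]
  }
  u <- interval_union(c(dm$intervals$start, recs$start),
                      c(dm$intervals$end, recs$end))
  structure(list(seq_len = model$length, intervals = u),
            class = "mask_track")
}

#' Accept or discard a model from vetted evidence
#'
#' A model is accepted iff at least one TE-related evidence row survives
#' vetting, *unless* the Dfam/InterPro conflict rule fires: a Dfam hit in
#' the presence of InterPro rows that are all non-TE indicates a repeat
#' that looks like a TE by sequence but encodes an unrelated protein, and
#' the model is discarded. Absence of InterPro rows does not invalidate
#' Dfam support (support from any one source suffices).
#'
#' @param model one-row model slice.
#' @param vetted vetted, `te_related`-tagged evidence for this model.
#' @return one-row data.frame (`model_id`, `verdict`, `stage`, `reason`,
#'   `supporting_evidence` comma-joined accessions).
#' @export
curate_model <- function(model, vetted) {
  v <- vetted[vetted$model_id == model$model_id &
                vetted$source != "trna", , drop = FALSE]
  te_rows <- v[v$te_related, , drop = FALSE]
  interpro <- v[v$source == "interpro", , drop = FALSE]
  has_dfam <- any(v$source == "dfam")
  conflict <- has_dfam && nrow(interpro) > 0L && !any(interpro$te_related)
  if (nrow(te_rows) == 0L) {
    verdict <- "discarded"; reason <- "no_te_evidence"; support <- ""
  } else if (conflict) {
    verdict <- "discarded"; reason <- "dfam_interpro_conflict"; support <- ""
  } else {
    verdict <- "accepted"; reason <- ""
    support <- paste(te_rows$accession, collapse = ",")
  }
  data.frame(model_id = model$model_id, verdict = verdict,
             stage = "evidence_curation", reason = reason,
             supporting_evidence = support, stringsAsFactors = FALSE)
}

LTR_LABELS <- c("gypsy", "ty3")
LINE_LABELS <- c("r2", "line", "l1", "cr1", "ape+rt")

#' Classify an accepted model into a TE family
#'
#' Majority vote over the family labels of the TE-related evidence:
#' Gypsy/Ty3 labels vote for `LTR_Gypsy_like`, R2/LINE-type labels for
#' `LINE_like`. With TE evidence but no label majority the structural
#' flag decides between `LTR_unclassified` and `nonLTR_unclassified`.
#' Label ties are broken by the lowest-e-value labeled row. A SINE flag
#' (from tRNA pseudogene screening) overrides everything.
#'
#' @param model one-row model slice; must be accepted.
#' @param vetted vetted evidence for the model.
#' @param ltr_structure_flag does the model have LTR structure (terminal
#'   repeats), as reported upstream? Detecting it de novo is out of scope.
#' @param sine_flag is the model a tRNA-derived SINE candidate?
#' @return one-row data.frame (`model_id`, `family`, `basis`).
#' @export
classify_model <- function(model, vetted, ltr_structure_flag = FALSE,
                           sine_flag = FALSE) {
  if (!identical(model$status, "accepted")) {
    stop("classify_model: model '", model$model_id, "' is not accepted")
  }
  v <- vetted[vetted$model_id == model$model_id, , drop = FALSE]
  if (sine_flag) {
    basis <- v$accession[v$source == "trna" & v$pseudo %in% TRUE]
    if (length(basis) == 0L) basis <- v$accession[v$te_related]
    return(data.frame(model_id = model$model_id, family = "SINE_candidate",
                      basis = paste(basis, collapse = ","),
                      stringsAsFactors = FALSE))
  }
  te <- v[v$te_related & v$source != "trna", , drop = FALSE]
  grp <- rep(NA_character_, nrow(te))
  lab <- tolower(ifelse(is.na(te$family_label), "", te$family_label))
  grp[lab %in% LTR_LABELS] <- "ltr"
  grp[lab %in% LINE_LABELS] <- "line"
  n_ltr <- sum(grp %in% "ltr"); n_line <- sum(grp %in% "line")
  family <- NULL
  if (n_ltr + n_line > 0L) {
    if (n_ltr > n_line) {
      family <- "LTR_Gypsy_like"; basis <- te$accession[grp %in% "ltr"]
    } else if (n_line > n_ltr) {
      family <- "LINE_like"; basis <- te$accession[grp %in% "line"]
    } else {
      labeled <- te[!is.na(grp), , drop = FALSE]
      best <- labeled[order(labeled$evalue), , drop = FALSE][1, ]
      family <- if (tolower(best$family_label) %in% LTR_LABELS)
        "LTR_Gypsy_like" else "LINE_like"
      basis <- best$accession
    }
  } else {
    family <- if (ltr_structure_flag) "LTR_unclassified" else
      "nonLTR_unclassified"
    basis <- te$accession
  }
  data.frame(model_id = model$model_id, family = family,
             basis = paste(basis, collapse = ","), stringsAsFactors = FALSE)
}

#' Curate and classify a set of surviving models
#'
#' Convenience wrapper running [model_mask()], [screen_evidence()],
#' [curate_model()] and [classify_model()] per model.
#'
#' @param models `consensus_models` data.frame (cascade survivors).
#' @param evidence evidence data.frame (all sources, incl. tRNA rows).
#' @param config [pipeline_config()].
#' @param ltr_flags named logical vector (by model id) of LTR structure
#'   flags; missing ids default to `FALSE`.
#' @param tandem_records optional external tandem records for masking.
#' @return list with `models` (statuses updated), `decisions`,
#'   `classifications`.
#' @export
curate_models <- function(models, evidence, config = pipeline_config(),
                          ltr_flags = NULL, tandem_records = NULL) {
  decisions <- list(); classifications <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, , drop = FALSE]
    if (!m$status %in% c("candidate", "accepted")) next
    mask <- model_mask(m, config, tandem_records)
    vetted <- screen_evidence(m, evidence, mask, config)
    dec <- curate_model(m, vetted)
    decisions[[length(decisions) + 1L]] <- dec
    if (dec$verdict == "accepted") {
      models$status[i] <- "accepted"
      flag <- isTRUE(ltr_flags[m$model_id])
      classifications[[length(classifications) + 1L]] <-
        classify_model(models[i, , drop = FALSE], vetted,
                       ltr_structure_flag = flag,
                       sine_flag = isTRUE(m$sine_flag))
    } else {
      models$status[i] <- "discarded"
      models$discard_stage[i] <- "evidence_curation"
      models$discard_reason[i] <- dec$reason
    }
  }
  list(models = models,
       decisions = if (length(decisions)) do.call(rbind, decisions) else
         data.frame(),
       classifications = if (length(classifications))
         do.call(rbind, classifications) else
           data.frame(model_id = character(0), family = character(0),
                      basis = character(0)))
}
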