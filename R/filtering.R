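# The curation cascade. Stage order is canonical: redundancy clustering,
# copy-number/full-length screening, exon overlap, tandem content, tRNA
# screening. Each filter is a pure function of (model, evidence, config).

CASCADE_STAGES <- c("clustering", "copy_number", "exon", "tandem", "trna")

#' Cluster redundant consensus models
#'
#' Two models are linked when some all-vs-all hit between them (with
#' e-value at or below `config$evalue_cluster`) has identity strictly
#' above `cluster_id_thresh` *and* alignment length covering strictly more
#' than `cluster_cov_thresh` of the shorter model. Clusters are connected
#' components of this link graph (single linkage); in each cluster the
#' longest model is kept (ties: lexicographically smallest id) and the
#' rest are redundant.
#'
#' @param models `consensus_models` data.frame.
#' @param hits all-vs-all alignment-hit data.frame (model vs model).
#' @param config [pipeline_config()].
#' @return list with `clusters` (list of `representative_id`,
#'   `member_ids`), and `discarded` (character ids).
#' @export
cluster_models <- function(models, hits, config = pipeline_config()) {
  ids <- models$model_id
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), ids)
  if (length(unknown) > 0L) {
    stop("hit references unknown model id: ", paste(unknown, collapse = ", "))
  }
  len <- stats::setNames(models$length, ids)
  h <- hits[hits$evalue <= config$evalue_cluster &
              hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(h) > 0L) {
    cov <- h$aln_len / pmin(len[h$query_id], len[h$subject_id])
    link <- h$pct_identity > config$cluster_id_thresh &
      cov > config$cluster_cov_thresh
    h <- h[link, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = h$query_id, to = h$subject_id),
    directed = FALSE,
    vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership[ids]
  clusters <- lapply(split(ids, memb), function(members) {
    maxlen <- max(len[members])
    cands <- sort(members[len[members] == maxlen])
    list(representative_id = cands[1], member_ids = sort(members))
  })
  names(clusters) <- NULL
  reps <- vapply(clusters, `[[`, character(1), "representative_id")
  clusters <- clusters[order(reps)]
  discarded <- setdiff(ids, sort(reps))
  list(clusters = clusters, discarded = discarded)
}

#' Copy-number / full-length filter
#'
#' A genomic hit is full-length when it spans at least
#' `full_length_frac` of the model. The model is kept iff at least one
#' genome contains `min_copies` or more full-length hits; interspersed
#' repeats recur within a genome, while conserved genes picked up by
#' de-novo repeat discovery typically appear once or twice per genome.
#'
#' @param model one-row slice of a `consensus_models` data.frame.
#' @param genome_hits model-vs-genome hit data.frame with an extra
#'   `genome_id` column.
#' @param config [pipeline_config()].
#' @return list with `keep`, `reason` (`NA` or `"low_copy_or_partial"`),
#'   and `max_full_copies` (best per-genome full-length count).
#' @export
copy_number_filter <- function(model, genome_hits, config = pipeline_config()) {
  h <- genome_hits[genome_hits$query_id == model$model_id, , drop = FALSE]
  full <- (h$q_end - h$q_start) / model$length >= config$full_length_frac
  per_genome <- if (any(full)) table(h$genome_id[full]) else integer(0)
  max_full <- if (length(per_genome) > 0L) max(per_genome) else 0L
  keep <- max_full >= config$min_copies
  list(keep = keep,
       reason = if (keep) NA_character_ else "low_copy_or_partial",
       max_full_copies = as.integer(max_full))
}

#' Exon-overlap filter
#'
#' Hits whose exon product mentions "hypothetical" or any TE keyword are
#' ignored (a model matching a TE-annotated or unannotated gene must not
#' be penalized). The model is discarded when the union of the remaining
#' hit intervals covers strictly more than `exon_frac_thresh` of its
#' length.
#'
#' @param model one-row model slice.
#' @param exon_hits model-vs-exon hit data.frame; an optional `product`
#'   column carries the exon annotation text.
#' @param config [pipeline_config()].
#' @return list with `keep` and `fraction`.
#' @export
exon_overlap_filter <- function(model, exon_hits, config = pipeline_config()) {
  h <- exon_hits[exon_hits$query_id == model$model_id, , drop = FALSE]
  if (nrow(h) > 0L) {
    prod <- if ("product" %in% names(h)) h$product else rep("", nrow(h))
    prod[is.na(prod)] <- ""
    qualifying <- !grepl("hypothetical", prod, ignore.case = TRUE) &
      !description_is_te(prod)
    h <- h[qualifying, , drop = FALSE]
  }
  frac <- if (nrow(h) == 0L) 0 else
    interval_union_length(h$q_start, h$q_end) / model$length
  list(keep = !(frac > config$exon_frac_thresh), fraction = frac)
}

#' Tandem-repeat filter
#'
#' Uses externally supplied tandem records (TRF `.dat`) when given;
#' otherwise falls back to the internal [tandem_fraction()] detector.
#' Discards when the union of tandem intervals covers strictly more than
#' `tandem_frac_thresh` of the model.
#'
#' @param model one-row model slice.
#' @param tandem_records data.frame (`model_id`, `start`, `end`, `period`,
#'   `copies`) or `NULL` to use the internal detector.
#' @param config [pipeline_config()].
#' @return list with `keep` and `fraction`.
#' @export
tandem_filter <- function(model, tandem_records = NULL,
                          config = pipeline_config()) {
  if (is.null(tandem_records)) {
    recs <- tandem_fraction(model$sequence)$records
  } else {
    recs <- tandem_records[tandem_records$model_id == model$model_id, ,
                           drop = FALSE]
  }
  frac <- if (nrow(recs) == 0L) 0 else
    interval_union_length(recs$start, recs$end) / model$length
  list(keep = !(frac > config$tandem_frac_thresh), fraction = frac)
}

#' tRNA screening
#'
#' Models containing an intact tRNA prediction are conserved tRNA genes
#' (or long conserved regions around them), not TEs, and are discarded.
#' Models whose only tRNA predictions are pseudogenes are kept and flagged
#' as candidate tRNA-derived SINEs.
#'
#' @param model one-row model slice.
#' @param trna_rows evidence data.frame rows with `source == "trna"` and a
#'   logical `pseudo` column.
#' @return list with `keep`, `reason`, `sine_flag`.
#' @export
trna_filter <- function(model, trna_rows) {
  r <- trna_rows[trna_rows$model_id == model$model_id &
                   trna_rows$source == "trna", , drop = FALSE]
  if (nrow(r) == 0L) {
    return(list(keep = TRUE, reason = NA_character_, sine_flag = FALSE))
  }
  if (any(!r$pseudo %in% TRUE)) {
    return(list(keep = FALSE, reason = "trna_gene", sine_flag = FALSE))
  }
  list(keep = TRUE, reason = NA_character_, sine_flag = TRUE)
}

#' Run the full filtering cascade
#'
#' Applies the five stages in canonical order and keeps complete
#' accounting: every discarded model carries exactly one (stage, reason)
#' pair, and the stage report satisfies flow conservation
#' (`n_out == n_in - n_discarded`, chained across stages).
#'
#' @param models `consensus_models` data.frame (status `candidate`).
#' @param evidence list with elements `av_hits` (all-vs-all hits),
#'   `genome_hits` (model-vs-genome hits with `genome_id`), `exon_hits`,
#'   `tandem_records` (or `NULL` for the internal detector), `trna_rows`.
#' @param config [pipeline_config()].
#' @return list with `models` (all models, statuses updated), `survivors`
#'   (surviving subset), `report` (stage report data.frame), `decisions`
#'   (per-discarded-model data.frame).
#' @export
run_cascade <- function(models, evidence, config = pipeline_config()) {
  stopifnot(is.data.frame(models))
  ev <- list(
    av_hits = evidence$av_hits %||% empty_hits(),
    genome_hits = evidence$genome_hits %||% cbind(empty_hits(),
                                                  genome_id = character(0)),
    exon_hits = evidence$exon_hits %||% empty_hits(),
    tandem_records = evidence$tandem_records,
    trna_rows = evidence$trna_rows %||% empty_evidence()
  )
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_discarded = integer(0), n_out = integer(0))
  decisions <- data.frame(model_id = character(0), stage = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  active <- models$status == "candidate"

  mark <- function(id, stage, reason) {
    i <- match(id, models$model_id)
    models$status[i] <<- "discarded"
    models$discard_stage[i] <<- stage
    models$discard_reason[i] <<- reason
    active[i] <<- FALSE
    decisions[nrow(decisions) + 1L, ] <<- list(id, stage, reason)
  }
  log_stage <- function(stage, n_in, n_disc) {
    report[nrow(report) + 1L, ] <<- list(stage, n_in, n_disc, n_in - n_disc)
  }

  # 1. redundancy clustering. Unlike the low-level cluster_models() (which
  # errors on unknown ids), the cascade tolerates hits naming models that
  # are not in the current candidate set, so re-running on survivors with
  # the original hit tables is idempotent.
  n_in <- sum(active)
  if (n_in > 0L) {
    av <- ev$av_hits
    act_ids <- models$model_id[active]
    av <- av[av$query_id %in% act_ids & av$subject_id %in% act_ids, ,
             drop = FALSE]
    cl <- cluster_models(models[active, , drop = FALSE], av, config)
    for (id in cl$discarded) mark(id, "clustering", "redundant")
  }
  log_stage("clustering", n_in, n_in - sum(active))

  # 2. copy number / full length
  n_in <- sum(active)
  for (id in models$model_id[active]) {
    r <- copy_number_filter(models[models$model_id == id, ], ev$genome_hits,
                            config)
    if (!r$keep) mark(id, "copy_number", r$reason)
  }
  log_stage("copy_number", n_in, n_in - sum(active))

  # 3. exon overlap
  n_in <- sum(active)
  for (id in models$model_id[active]) {
    r <- exon_overlap_filter(models[models$model_id == id, ], ev$exon_hits,
                             config)
    if (!r$keep) mark(id, "exon", "exon_overlap")
  }
  log_stage("exon", n_in, n_in - sum(active))

  # 4. tandem content
  n_in <- sum(active)
  for (id in models$model_id[active]) {
    r <- tandem_filter(models[models$model_id == id, ], ev$tandem_records,
                       config)
    if (!r$keep) mark(id, "tandem", "tandem_repeat")
  }
  log_stage("tandem", n_in, n_in - sum(active))

  # 5. tRNA screening
  n_in <- sum(active)
  for (id in models$model_id[active]) {
    r <- trna_filter(models[models$model_id == id, ], ev$trna_rows)
    if (!r$keep) {
      mark(id, "trna", r$reason)
    } else if (r$sine_flag) {
      models$sine_flag[models$model_id == id] <- TRUE
    }
  }
  log_stage("trna", n_in, n_in - sum(active))

  list(models = models,
       survivors = models[active, , drop = FALSE],
       report = report,
       decisions = decisions)
}
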