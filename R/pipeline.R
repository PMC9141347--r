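#' Run the full curation pipeline on a dataset
#'
#' simulate/load -> filtering cascade -> evidence curation ->
#' mobilome summary -> gain/loss parsimony. The dataset can come from
#' [simulate_dataset()] / [read_dataset()] or be assembled by hand with
#' the same element names.
#'
#' @param ds dataset list (`models`, `av_hits`, `genome_hits`,
#'   `exon_hits`, `tandem_records`, `trna_rows`, `evidence`, `ltr_flags`,
#'   `tree_text`, `assembly_lengths`).
#' @param config [pipeline_config()].
#' @return list with `cascade` ([run_cascade()] output), `curation`
#'   ([curate_models()] output), `library` (accepted models), `summary`
#'   ([summarize_mobilome()] output), `presence` (presence matrix), and
#'   `parsimony` (per-family [enumerate_scenarios()] results, when a tree
#'   is available).
#' @export
run_pipeline <- function(ds, config = pipeline_config()) {
  casc <- run_cascade(ds$models, list(
    av_hits = ds$av_hits, genome_hits = ds$genome_hits,
    exon_hits = ds$exon_hits, tandem_records = ds$tandem_records,
    trna_rows = ds$trna_rows), config)
  evidence <- rbind(ds$evidence, ds$trna_rows)
  cur <- curate_models(casc$survivors, evidence, config,
                       ltr_flags = ds$ltr_flags,
                       tandem_records = ds$tandem_records)
  accepted <- cur$models[cur$models$status == "accepted", , drop = FALSE]
  gh <- ds$genome_hits[ds$genome_hits$query_id %in% accepted$model_id, ,
                       drop = FALSE]
  summ <- summarize_mobilome(gh, as.list(ds$assembly_lengths),
                             classifications = cur$classifications)
  pres <- build_presence_matrix(summ$family_counts,
                                genomes = names(ds$assembly_lengths))
  pars <- NULL
  if (!is.null(ds$tree_text) && ncol(pres) > 0L) {
    tree <- parse_newick(ds$tree_text)
    pars <- lapply(stats::setNames(colnames(pres), colnames(pres)),
                   function(fam) {
                     states <- stats::setNames(pres[, fam],
                                               rownames(pres))
                     enumerate_scenarios(tree, states)
                   })
  }
  list(cascade = casc, curation = cur, library = accepted,
       summary = summ, presence = pres, parsimony = pars)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic dataset directory),
#' `filter` (cascade a dataset, write surviving FASTA + decisions +
#' stage report), `curate` (evidence curation on cascade survivors),
#' `summarize` (per-genome coverage + presence/absence TSVs),
#' `parsimony` (Newick + presence TSV -> scenario report). Installed as
#' `scripts/tecurate` under the package root for `Rscript` use.
#'
#' @param args character vector, e.g. `c("simulate", "--seed", "1",
#'   "--out", "dir")`.
#' @return invisibly, the subcommand's main result.
#' @export
te_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tecurate <simulate|filter|curate|summarize|parsimony> [options]",
    "  simulate  --seed INT --out DIR",
    "  filter    --data DIR --out DIR",
    "  curate    --data DIR --out DIR",
    "  summarize --data DIR --out DIR",
    "  parsimony --tree FILE --presence FILE --out FILE", sep = "\n")
  if (length(args) < 1L) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  out <- opt("out")
  if (is.null(out)) stop(usage, call. = FALSE)
  if (cmd == "simulate") {
    recipe <- simulation_recipe(rng_seed = as.integer(opt("seed", "1")))
    ds <- simulate_dataset(recipe, dir = out)
    message("wrote dataset with ", nrow(ds$models), " candidate models to ",
            out)
    return(invisible(ds))
  }
  if (cmd == "parsimony") {
    tree <- read_newick(opt("tree"))
    pres <- utils::read.table(opt("presence"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    states <- stats::setNames(as.logical(pres[[2]]), pres[[1]])
    res <- enumerate_scenarios(tree, states)
    lines <- c(sprintf("minimum cost\t%g", res$cost),
               vapply(res$scenarios, function(s) {
                 sprintf("scenario\tgains=%s\tlosses=%s\tcost=%g",
                         paste(s$gains, collapse = ","),
                         paste(s$losses, collapse = ","), s$cost)
               }, character(1)))
    writeLines(lines, out)
    message(length(res$scenarios), " optimal scenario(s), cost ", res$cost)
    return(invisible(res))
  }
  ds <- read_dataset(opt("data"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- pipeline_config()
  if (cmd == "filter") {
    casc <- run_cascade(ds$models, ds, cfg)
    write_fasta(casc$survivors, file.path(out, "survivors.fasta"))
    utils::write.table(casc$report, file.path(out, "stage_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(casc$decisions, file.path(out, "decisions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(casc))
  }
  res <- run_pipeline(ds, cfg)
  if (cmd == "curate") {
    lib <- res$library
    cls <- res$curation$classifications
    lib$model_id <- paste0(lib$model_id, "#",
                           cls$family[match(lib$model_id, cls$model_id)])
    write_fasta(lib, file.path(out, "library.fasta"))
    utils::write.table(res$curation$decisions,
                       file.path(out, "curation_decisions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res$curation))
  }
  if (cmd == "summarize") {
    utils::write.table(res$summary$summaries,
                       file.path(out, "mobilome_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pm <- data.frame(genome_id = rownames(res$presence), res$presence,
                     check.names = FALSE)
    utils::write.table(pm, file.path(out, "presence_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res$summary))
  }
  stop(usage, call. = FALSE)
}
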