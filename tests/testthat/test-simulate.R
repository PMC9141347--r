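test_that("simulation is a pure function of the seed", {
  r <- simulation_recipe(rng_seed = 33)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(r, dir = d1)
  simulate_dataset(r, dir = d2)
  for (f in c("genomes.fasta", "models.fasta", "av_hits.tsv",
              "genome_hits.tsv", "evidence.tsv", "truth_candidates.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the genomes
  d3 <- withr::local_tempdir()
  simulate_dataset(simulation_recipe(rng_seed = 34), dir = d3)
  expect_false(identical(readLines(file.path(d1, "genomes.fasta")),
                         readLines(file.path(d3, "genomes.fasta"))))
})

test_that("realized GC tracks the target", {
  r <- simulation_recipe(rng_seed = 5, gc_target = 0.20,
                         contig_lengths = c(50000L, 50000L), n_genomes = 1L)
  sim <- simulate_genomes(r)
  gc <- sum(vapply(sim$genomes$sequence, function(s)
    nchar(gsub("[^GC]", "", s)), numeric(1))) /
    sum(nchar(sim$genomes$sequence))
  expect_lt(abs(gc - 0.20), 0.02)
})

test_that("the ground truth ledger is complete and consistent", {
  r <- simulation_recipe(rng_seed = 12)
  sim <- simulate_genomes(r)
  ds <- emit_candidates(sim, r)
  # fates partition the candidate set
  expect_setequal(ds$truth$model_id, ds$models$model_id)
  expect_false(anyDuplicated(ds$truth$model_id) > 0)
  expect_setequal(unique(ds$truth$fate),
                  c("true_te", "redundant", "low_copy", "gene_decoy",
                    "tandem_decoy", "trna_decoy"))
  # 5 planted copies promised -> 5 intervals recorded, within contigs
  r5 <- simulation_recipe(rng_seed = 13, copies_per_te = 5L,
                          te_templates = list(list(family = "LTR_Gypsy_like",
                                                   length = 1000L,
                                                   ltr_flag = TRUE)),
                          n_gene_decoys = 0L, n_tandem_decoys = 0L,
                          n_trna_decoys = 0L, n_low_copy = 0L)
  sim5 <- simulate_genomes(r5)
  expect_equal(nrow(sim5$planted), 5L)
  clen <- stats::setNames(nchar(sim5$genomes$sequence),
                          sim5$genomes$contig_id)
  expect_true(all(sim5$planted$start >= 0))
  expect_true(all(sim5$planted$end <= clen[sim5$planted$contig_id]))
  # planted copies really sit in the genomes: exact substring identity
  # matches the ledger within rounding of the mutation count
  for (k in seq_len(nrow(sim5$planted))) {
    p <- sim5$planted[k, ]
    ctg <- sim5$genomes$sequence[sim5$genomes$contig_id == p$contig_id]
    frag <- substr(ctg, p$start + 1L, p$end)
    tpl <- sim5$templates[[p$template_id]]
    mism <- sum(strsplit(frag, "")[[1]] != strsplit(tpl, "")[[1]])
    expect_equal(1 - mism / nchar(tpl), p$identity)
  }
})

test_that("emitted hit tables are consistent with local re-alignment", {
  r <- simulation_recipe(rng_seed = 77)
  ds <- simulate_dataset(r)
  # the redundant pair is the only one passing the 90/90 rule
  cfg <- pipeline_config()
  cl <- cluster_models(ds$models, ds$av_hits, cfg)
  expect_setequal(cl$discarded,
                  ds$truth$model_id[ds$truth$fate == "redundant"])
  # re-align an emitted redundant pair: identity within 0.02 of the table
  h <- ds$av_hits[1, ]
  a <- ds$models$sequence[ds$models$model_id == h$query_id]
  b <- ds$models$sequence[ds$models$model_id == h$subject_id]
  al <- local_align(substr(a, 1, 400), substr(b, 1, 400))
  expect_lt(abs(al$identity - h$pct_identity), 0.02)
  # gene decoy exon hits cover > 40% of the decoy model
  gd <- ds$truth$model_id[ds$truth$fate == "gene_decoy"][1]
  eh <- ds$exon_hits[ds$exon_hits$query_id == gd, ]
  len <- ds$models$length[ds$models$model_id == gd]
  expect_gt(sum(eh$aln_len[1]) / len, 0.40)
})

test_that("recipe validation rejects impossible worlds", {
  expect_error(simulation_recipe(gc_target = 0.05))
  expect_error(simulation_recipe(divergence = 0.6))
  expect_error(simulation_recipe(contig_lengths = c(100L)),
               "exceeds longest contig")
  # un-placeable recipe: too many copies for the contigs
  r <- simulation_recipe(rng_seed = 1, copies_per_te = 40L,
                         contig_lengths = c(2000L), n_genomes = 1L,
                         te_templates = list(list(family = "LINE_like",
                                                  length = 1500L,
                                                  ltr_flag = FALSE)))
  expect_error(simulate_genomes(r), "could not place")
})

test_that("datasets round-trip through the plain-text directory format", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(simulation_recipe(rng_seed = 3), dir = d)
  back <- read_dataset(d)
  expect_equal(back$models$sequence, ds$models$sequence)
  expect_equal(back$truth, ds$truth, ignore_attr = TRUE)
  expect_equal(back$genome_hits$s_start, ds$genome_hits$s_start)
  expect_equal(back$evidence$te_related, ds$evidence$te_related)
  expect_equal(back$assembly_lengths, ds$assembly_lengths,
               ignore_attr = TRUE)
  # the cascade gives identical decisions on the reloaded dataset
  r1 <- run_cascade(ds$models, ds, pipeline_config())
  r2 <- run_cascade(back$models, back, pipeline_config())
  expect_equal(r1$decisions, r2$decisions)
})
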