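make_models <- function(lens, prefix = "m") {
  set.seed(404)
  consensus_models(paste0(prefix, seq_along(lens)),
                   vapply(lens, random_dna, character(1)))
}

hit_row <- function(q, s, id, len, evalue = 1e-50) {
  data.frame(query_id = q, subject_id = s, pct_identity = id,
             aln_len = len, q_start = 0L, q_end = len, s_start = 0L,
             s_end = len, strand = "+", evalue = evalue, score = 2 * len,
             stringsAsFactors = FALSE)
}

genome_hit <- function(model, genome, frac, len) {
  span <- round(frac * len)
  data.frame(query_id = model, subject_id = paste0(genome, "_c1"),
             pct_identity = 0.95, aln_len = span, q_start = 0L,
             q_end = span, s_start = 0L, s_end = span, strand = "+",
             evalue = 0, score = 2 * span, genome_id = genome,
             stringsAsFactors = FALSE)
}

test_that("clustering keeps the longest model per 90/90 component", {
  cfg <- pipeline_config()
  m <- make_models(c(1000, 950, 800, 700, 600))
  # no qualifying hits: all singletons
  cl <- cluster_models(m, hit_row("m1", "m2", 0.95, 100), cfg)
  expect_length(cl$clusters, 5L)  # 100/950 coverage fails
  expect_length(cl$discarded, 0L)

  # the worked 90/90 case: 900/950 = 0.947 > 0.90 and identity 0.95 > 0.90
  cl <- cluster_models(m, hit_row("m1", "m2", 0.95, 900), cfg)
  expect_length(cl$discarded, 1L)
  expect_equal(cl$discarded, "m2")
  reps <- vapply(cl$clusters, `[[`, character(1), "representative_id")
  expect_true("m1" %in% reps && !"m2" %in% reps)

  # boundary: identity exactly at threshold does not link (strict >)
  cl <- cluster_models(m, hit_row("m1", "m2", 0.90, 900), cfg)
  expect_length(cl$discarded, 0L)

  # transitive chain A~B, B~C clusters all three
  hits <- rbind(hit_row("m1", "m2", 0.95, 900),
                hit_row("m2", "m3", 0.95, 790))
  cl <- cluster_models(m, hits, cfg)
  sizes <- sort(vapply(cl$clusters, function(x) length(x$member_ids),
                       integer(1)))
  expect_equal(sizes, c(1L, 1L, 3L))
  expect_equal(cl$discarded, c("m2", "m3"))

  expect_error(cluster_models(m, hit_row("m1", "nope", 0.99, 900), cfg),
               "unknown model id")
})

test_that("clustering matches a brute-force closure oracle on random graphs", {
  cfg <- pipeline_config()
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    m <- make_models(rep(500L, n))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    linked <- pairs[stats::runif(nrow(pairs)) < 0.25, , drop = FALSE]
    hits <- do.call(rbind, c(list(empty_h <- hit_row("m1", "m1", 0, 1)[0, ]),
                             lapply(seq_len(nrow(linked)), function(k) {
                               hit_row(paste0("m", linked[k, 1]),
                                       paste0("m", linked[k, 2]), 0.95, 480)
                             })))
    cl <- cluster_models(m, hits, cfg)
    # oracle: reachability by adjacency-matrix closure
    adj <- diag(n) > 0
    for (k in seq_len(nrow(linked))) {
      adj[linked[k, 1], linked[k, 2]] <- TRUE
      adj[linked[k, 2], linked[k, 1]] <- TRUE
    }
    for (rep2 in seq_len(n)) adj <- (adj %*% adj) > 0
    comp_oracle <- apply(adj, 1, function(r) paste(which(r), collapse = ","))
    got <- vapply(cl$clusters, function(cc)
      paste(sort(as.integer(sub("m", "", cc$member_ids))), collapse = ","),
      character(1))
    expect_setequal(got, unique(comp_oracle))
    # permutation invariance of the partition
    perm <- sample(n)
    cl2 <- cluster_models(m[perm, ], hits, cfg)
    got2 <- vapply(cl2$clusters, function(cc)
      paste(sort(as.integer(sub("m", "", cc$member_ids))), collapse = ","),
      character(1))
    expect_setequal(got2, got)
  }
})

test_that("copy-number filter keeps >= 3 full-length copies in one genome", {
  cfg <- pipeline_config()
  m <- make_models(1000L)[1, ]
  # 2 full-length hits in every genome -> discard
  gh <- rbind(genome_hit("m1", "g1", 1, 1000), genome_hit("m1", "g1", 1, 1000),
              genome_hit("m1", "g2", 1, 1000), genome_hit("m1", "g2", 1, 1000))
  r <- copy_number_filter(m, gh, cfg)
  expect_false(r$keep)
  expect_equal(r$reason, "low_copy_or_partial")

  # exactly 3 in one genome -> keep (inclusive boundary)
  gh <- rbind(gh, genome_hit("m1", "g1", 1, 1000))
  expect_true(copy_number_filter(m, gh, cfg)$keep)

  # full-length boundary: 80% of the model counts, 79.9% does not
  gh80 <- do.call(rbind, replicate(3, genome_hit("m1", "g1", 0.80, 1000),
                                   simplify = FALSE))
  expect_true(copy_number_filter(m, gh80, cfg)$keep)

  # 10 hits at 30% coverage -> no full-length hit -> discard
  gh30 <- do.call(rbind, replicate(10, genome_hit("m1", "g1", 0.30, 1000),
                                   simplify = FALSE))
  r <- copy_number_filter(m, gh30, cfg)
  expect_false(r$keep)
  expect_equal(r$max_full_copies, 0L)
})

test_that("exon filter unions intervals and respects the strict 40% rule", {
  cfg <- pipeline_config()
  m <- make_models(1000L)[1, ]
  ex_hit <- function(a, b, product = "actin") {
    data.frame(query_id = "m1", subject_id = "e", pct_identity = 0.9,
               aln_len = b - a, q_start = a, q_end = b, s_start = 0L,
               s_end = b - a, strand = "+", evalue = 1e-30, score = 100,
               product = product, stringsAsFactors = FALSE)
  }
  # union 401 -> 0.401 > 0.40 -> discard
  r <- exon_overlap_filter(m, ex_hit(0L, 401L), cfg)
  expect_false(r$keep)
  expect_equal(r$fraction, 0.401)
  # union exactly 400 -> keep (not strictly greater)
  r <- exon_overlap_filter(m, ex_hit(0L, 400L), cfg)
  expect_true(r$keep)
  expect_equal(r$fraction, 0.400)
  # overlapping hits union to 400: [100,300) + [200,500)
  r <- exon_overlap_filter(m, rbind(ex_hit(100L, 300L), ex_hit(200L, 500L)),
                           cfg)
  expect_equal(r$fraction * m$length,
               union_len_oracle(c(100L, 200L), c(300L, 500L)))
  expect_true(r$keep)
  # hypothetical and TE-like products are excluded before the union
  r <- exon_overlap_filter(m, rbind(
    ex_hit(0L, 500L, "hypothetical protein"),
    ex_hit(0L, 500L, "retrotransposon gag protein")), cfg)
  expect_equal(r$fraction, 0)
  expect_true(r$keep)
})

test_that("tandem filter uses records when given, detector otherwise", {
  cfg <- pipeline_config()
  m <- consensus_models("m1", strrep("AT", 300))
  expect_false(tandem_filter(m, NULL, cfg)$keep)  # internal detector: ~1.0

  set.seed(5)
  m2 <- consensus_models("m1", random_dna(1000))
  expect_true(tandem_filter(m2, NULL, cfg)$keep)

  # external records: [0,250) + [200,450) union 450 -> 0.45 -> discard
  recs <- data.frame(model_id = "m1", start = c(0L, 200L),
                     end = c(250L, 450L), period = 5L, copies = 50)
  r <- tandem_filter(m2, recs, cfg)
  expect_false(r$keep)
  expect_equal(r$fraction, 0.45)
  # a model absent from supplied records is untouched
  recs$model_id <- "other"
  expect_error(tandem_filter(m2, recs, cfg), NA)
  expect_equal(tandem_filter(m2, recs, cfg)$fraction, 0)
})

test_that("tRNA screening discards genes, flags pseudogene-only models", {
  m <- make_models(300L)[1, ]
  row <- function(pseudo) {
    data.frame(model_id = "m1", source = "trna", accession = "tRNA-Lys",
               description = "tRNA", family_label = NA, m_start = 0L,
               m_end = 72L, frame = NA, evalue = 1e-10, pseudo = pseudo,
               te_related = FALSE, stringsAsFactors = FALSE)
  }
  r <- trna_filter(m, row(FALSE))
  expect_false(r$keep)
  expect_equal(r$reason, "trna_gene")

  r <- trna_filter(m, row(TRUE))
  expect_true(r$keep)
  expect_true(r$sine_flag)

  r <- trna_filter(m, row(TRUE)[0, ])
  expect_true(r$keep)
  expect_false(r$sine_flag)

  # mixed intact + pseudo still counts as a gene
  expect_false(trna_filter(m, rbind(row(TRUE), row(FALSE)))$keep)
})

test_that("the cascade keeps full accounting and is idempotent", {
  cfg <- pipeline_config()
  # empty input: all-zero report
  r0 <- run_cascade(consensus_models(character(0), character(0)), list(), cfg)
  expect_true(all(r0$report$n_in == 0 & r0$report$n_out == 0))

  ds <- simulate_dataset(simulation_recipe(rng_seed = 9))
  r <- run_cascade(ds$models, ds, cfg)
  # flow conservation within and across stages
  expect_equal(r$report$n_out, r$report$n_in - r$report$n_discarded)
  expect_equal(r$report$n_in[-1], r$report$n_out[-nrow(r$report)])
  expect_equal(r$report$n_in[1], nrow(ds$models))
  expect_equal(r$report$n_out[nrow(r$report)], nrow(r$survivors))
  expect_equal(sum(r$report$n_discarded) + nrow(r$survivors), nrow(ds$models))
  # every discarded model carries exactly one (stage, reason)
  disc <- r$models[r$models$status == "discarded", ]
  expect_equal(sort(disc$model_id), sort(r$decisions$model_id))
  expect_false(any(is.na(disc$discard_stage)) || any(is.na(disc$discard_reason)))
  # ground-truth stage flow for the default composition (10 candidates)
  expect_equal(r$report$n_in, c(10L, 8L, 7L, 5L, 3L))
  expect_equal(r$report$n_out, c(8L, 7L, 5L, 3L, 2L))
  # second pass on survivors discards nothing
  ds2 <- ds
  ds2$models <- r$survivors
  r2 <- run_cascade(r$survivors, ds2, cfg)
  expect_equal(nrow(r2$survivors), nrow(r$survivors))
  expect_equal(sum(r2$report$n_discarded), 0L)
})

test_that("no planted true TE is ever dropped (seeded property)", {
  cfg <- pipeline_config()
  for (seed in c(201, 202, 203)) {
    ds <- simulate_dataset(simulation_recipe(rng_seed = seed))
    r <- run_cascade(ds$models, ds, cfg)
    true_te <- ds$truth$model_id[ds$truth$fate == "true_te"]
    expect_true(all(true_te %in% r$survivors$model_id))
    # verdicts are reproducible: pure function of inputs
    r2 <- run_cascade(ds$models, ds, cfg)
    expect_identical(r$decisions, r2$decisions)
  }
})
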