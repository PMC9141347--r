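# Synthetic genomes with planted TEs, decoys, and matching evidence
# tables. The generator states a small but complete world: every candidate
# model it emits has a known intended fate, so the cascade and the
# curation rules can be checked against ground truth without downloads.

STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# stop-free (frame +1) coding-like sequence of length n (n trimmed to a
# multiple of 3), base composition close to the GC target
coding_dna <- function(n, gc = 0.5) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  pbase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(strsplit(codons, ""), function(b) prod(pbase[b]), numeric(1))
  k <- max(1L, n %/% 3L)
  paste(sample(codons, k, replace = TRUE, prob = w / sum(w)), collapse = "")
}

# substitution-only mutation; returns realized identity so hit tables stay
# exactly consistent with the planted copies
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k > 0L) {
    s <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample.int(n, k)
    for (p in pos) {
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    }
    seq <- paste(s, collapse = "")
  }
  list(sequence = seq, n_sub = k, identity = 1 - k / n)
}

#' Simulation recipe
#'
#' States the synthetic world: contig sizes on the 5-50 kb scale, a GC
#' target inside the 0.15-0.60 range that real apicomplexan-style genomes
#' span, two planted autonomous TE families (an LTR element with 200-nt
#' terminal repeats around a coding interior, and a LINE-like element with
#' an RT+endonuclease ORF region), and the standard decoy set: one
#' redundant variant per TE, a low-copy repeat, multigene-family decoys
#' (annotated exons, >= 3 copies), tandem-repeat decoys (70% tandem), and
#' a tRNA-gene decoy. Copy number defaults to 4 full-length copies of each
#' TE in its home genome, above the keep threshold of 3; divergence
#' defaults to 3% substitutions per copy.
#'
#' @param rng_seed integer seed; the whole dataset is a pure function of
#'   it.
#' @param n_genomes number of genomes.
#' @param contig_lengths integer vector of contig lengths used for every
#'   genome.
#' @param gc_target background GC fraction, in `[0.15, 0.60]`.
#' @param te_templates list of `list(family, length, ltr_flag)` entries.
#' @param copies_per_te planted full-length copies of each TE in its home
#'   genome.
#' @param divergence per-site substitution probability for each planted
#'   copy (must stay well below the 10% redundancy margin; `< 0.3`).
#' @param n_low_copy,n_gene_decoys,n_tandem_decoys,n_trna_decoys decoy
#'   counts.
#' @param redundant_per_te redundant ~95%-identical variants emitted per
#'   TE template.
#' @return validated list of class `simulation_recipe`.
#' @export
simulation_recipe <- function(rng_seed = 1L,
                              n_genomes = 3L,
                              contig_lengths = c(20000L, 15000L, 10000L),
                              gc_target = 0.35,
                              te_templates = list(
                                list(family = "LTR_Gypsy_like", length = 1500L,
                                     ltr_flag = TRUE),
                                list(family = "LINE_like", length = 1200L,
                                     ltr_flag = FALSE)),
                              copies_per_te = 4L,
                              divergence = 0.03,
                              n_low_copy = 1L,
                              n_gene_decoys = 2L,
                              n_tandem_decoys = 2L,
                              n_trna_decoys = 1L,
                              redundant_per_te = 1L) {
  r <- list(rng_seed = as.integer(rng_seed), n_genomes = as.integer(n_genomes),
            contig_lengths = as.integer(contig_lengths),
            gc_target = gc_target, te_templates = te_templates,
            copies_per_te = as.integer(copies_per_te),
            divergence = divergence,
            n_low_copy = as.integer(n_low_copy),
            n_gene_decoys = as.integer(n_gene_decoys),
            n_tandem_decoys = as.integer(n_tandem_decoys),
            n_trna_decoys = as.integer(n_trna_decoys),
            redundant_per_te = as.integer(redundant_per_te))
  stopifnot(r$n_genomes >= 1L, all(r$contig_lengths > 0L),
            r$gc_target >= 0.15, r$gc_target <= 0.60,
            r$divergence >= 0, r$divergence < 0.5,
            r$copies_per_te >= 0L, r$n_low_copy >= 0L,
            r$n_gene_decoys >= 0L, r$n_tandem_decoys >= 0L,
            r$n_trna_decoys >= 0L, r$redundant_per_te >= 0L)
  maxlen <- max(vapply(te_templates, `[[`, numeric(1), "length"), 0)
  if (maxlen > max(r$contig_lengths)) {
    stop("largest template (", maxlen, " nt) exceeds longest contig")
  }
  structure(r, class = "simulation_recipe")
}

# build the template sequences and the candidate ledger for a recipe
build_templates <- function(recipe) {
  gc <- recipe$gc_target
  ids <- character(0); seqs <- character(0)
  fate <- character(0); family <- character(0); ltr <- logical(0)
  add <- function(id, seq, f, fam = NA_character_, lf = FALSE) {
    ids <<- c(ids, id); seqs <<- c(seqs, seq)
    fate <<- c(fate, f); family <<- c(family, fam); ltr <<- c(ltr, lf)
  }
  for (k in seq_along(recipe$te_templates)) {
    t <- recipe$te_templates[[k]]
    if (isTRUE(t$ltr_flag)) {
      tr <- rand_dna(200L, gc)
      inner <- coding_dna(t$length - 400L, gc)
      seq <- paste0(tr, inner, tr)
    } else {
      seq <- paste0(rand_dna(100L, gc), coding_dna(t$length - 200L, gc),
                    rand_dna(100L, gc))
    }
    add(paste0("te", k), seq, "true_te", t$family, isTRUE(t$ltr_flag))
  }
  for (k in seq_len(recipe$n_low_copy)) {
    add(paste0("lowcopy", k), rand_dna(800L, gc), "low_copy")
  }
  for (k in seq_len(recipe$n_gene_decoys)) {
    add(paste0("gene", k), coding_dna(900L, gc), "gene_decoy")
  }
  for (k in seq_len(recipe$n_tandem_decoys)) {
    motif <- rand_dna(7L, gc)
    tail_len <- 490L
    seq <- paste0(rand_dna(210L, gc),
                  substring(strrep(motif, ceiling(tail_len / 7)), 1L, tail_len))
    add(paste0("tandem", k), seq, "tandem_decoy")
  }
  for (k in seq_len(recipe$n_trna_decoys)) {
    add(paste0("trna", k), rand_dna(300L, gc), "trna_decoy")
  }
  list(sequences = stats::setNames(seqs, ids),
       candidates = data.frame(model_id = ids, fate = fate, family = family,
                               ltr_flag = ltr, stringsAsFactors = FALSE))
}

#' Simulate genomes with planted elements
#'
#' Background sequence is i.i.d. at the GC target; each template is
#' planted at non-overlapping uniform positions in its home genome (the
#' templates rotate over genomes), every copy independently mutated at the
#' divergence rate. True TEs get `copies_per_te` copies; decoys get 3
#' (enough to clear the copy-number stage, so each decoy reaches the stage
#' meant to catch it); low-copy templates get 2.
#'
#' @param recipe a [simulation_recipe()].
#' @return list with `genomes` (data.frame `genome_id`, `contig_id`,
#'   `sequence`), `templates`, `candidates` (the ground-truth ledger),
#'   `planted` (per-copy data.frame with realized identity), and
#'   `assembly_lengths`.
#' @export
simulate_genomes <- function(recipe = simulation_recipe()) {
  set.seed(recipe$rng_seed)
  tpl <- build_templates(recipe)
  genome_ids <- paste0("g", seq_len(recipe$n_genomes))
  contigs <- list()
  for (g in genome_ids) {
    for (j in seq_along(recipe$contig_lengths)) {
      contigs[[paste0(g, "_c", j)]] <-
        list(genome = g, seq = rand_dna(recipe$contig_lengths[j],
                                        recipe$gc_target),
             occupied = data.frame(start = integer(0), end = integer(0)))
    }
  }
  cand <- tpl$candidates
  cand$home_genome <- genome_ids[(seq_len(nrow(cand)) - 1L) %%
                                   recipe$n_genomes + 1L]
  n_copies <- ifelse(cand$fate == "true_te", recipe$copies_per_te,
                     ifelse(cand$fate == "low_copy", 2L, 3L))
  planted <- list()
  for (i in seq_len(nrow(cand))) {
    tseq <- tpl$sequences[[cand$model_id[i]]]
    tlen <- nchar(tseq)
    g <- cand$home_genome[i]
    gcontigs <- names(contigs)[vapply(contigs, function(x) x$genome == g,
                                      logical(1))]
    for (cp in seq_len(n_copies[i])) {
      mut <- mutate_seq(tseq, recipe$divergence)
      placed <- FALSE
      for (cn in sample(gcontigs)) {
        clen <- nchar(contigs[[cn]]$seq)
        if (clen < tlen) next
        for (try in 1:200) {
          start <- sample.int(clen - tlen + 1L, 1L) - 1L
          occ <- contigs[[cn]]$occupied
          if (interval_overlap_length(start, start + tlen, occ) == 0L) {
            substr(contigs[[cn]]$seq, start + 1L, start + tlen) <- mut$sequence
            contigs[[cn]]$occupied <- rbind(occ,
                                            data.frame(start = start,
                                                       end = start + tlen))
            planted[[length(planted) + 1L]] <- data.frame(
              genome_id = g, contig_id = cn, start = start,
              end = start + tlen, template_id = cand$model_id[i],
              fate = cand$fate[i], family = cand$family[i],
              identity = mut$identity, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (!placed) {
        stop("could not place copy ", cp, " of ", cand$model_id[i],
             " without overlap; enlarge contigs or reduce copies")
      }
    }
  }
  genomes <- data.frame(
    genome_id = vapply(contigs, `[[`, character(1), "genome"),
    contig_id = names(contigs),
    sequence = vapply(contigs, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE, row.names = NULL)
  asm <- tapply(nchar(genomes$sequence), genomes$genome_id, sum)
  list(genomes = genomes, templates = tpl$sequences, candidates = cand,
       planted = do.call(rbind, planted),
       assembly_lengths = asm[genome_ids])
}

#' Emit candidate models and all evidence tables for a simulation
#'
#' Candidate models are the templates themselves (consensus building is
#' the job of upstream de-novo tools and out of scope) plus one truncated,
#' ~95%-identical redundant variant per true TE. Hit tables are derived
#' from the ground truth, so identities match the planted copies exactly;
#' evidence rows for true TEs carry the planted family labels; decoys get
#' the evidence that the stage meant to catch them expects (exon hits over
#' 60% of gene decoys, tandem records over 70% of tandem decoys, an intact
#' tRNA prediction on tRNA decoys) and no TE evidence.
#'
#' @param sim result of [simulate_genomes()].
#' @param recipe the recipe used.
#' @return list with `models`, `av_hits`, `genome_hits`, `exon_hits`,
#'   `exons`, `tandem_records`, `trna_rows`, `evidence`, `ltr_flags`,
#'   `truth` (candidate ledger incl. redundant variants), `tree_text`,
#'   `assembly_lengths`.
#' @export
emit_candidates <- function(sim, recipe = simulation_recipe()) {
  set.seed(recipe$rng_seed + 7919L)  # independent stream, still seed-derived
  cand <- sim$candidates
  seqs <- sim$templates
  truth <- cand[c("model_id", "fate", "family", "ltr_flag")]
  av <- list()
  # redundant variants: truncated to 95% length, ~3% diverged
  for (id in cand$model_id[cand$fate == "true_te"]) {
    for (k in seq_len(recipe$redundant_per_te)) {
      vid <- paste0(id, "_v", k)
      vlen <- floor(nchar(seqs[[id]]) * 0.95)
      mut <- mutate_seq(substring(seqs[[id]], 1L, vlen), 0.03)
      seqs[[vid]] <- mut$sequence
      truth <- rbind(truth, data.frame(model_id = vid, fate = "redundant",
                                       family = NA_character_,
                                       ltr_flag = FALSE))
      av[[length(av) + 1L]] <- data.frame(
        query_id = vid, subject_id = id, pct_identity = mut$identity,
        aln_len = vlen, q_start = 0L, q_end = vlen, s_start = 0L,
        s_end = vlen, strand = "+", evalue = 1e-80,
        score = round(2 * vlen * mut$identity), stringsAsFactors = FALSE)
    }
  }
  models <- consensus_models(names(seqs), unname(seqs),
                             source_genome = "merged")
  av_hits <- if (length(av)) do.call(rbind, av) else empty_hits()
  # genome hits straight from the planted ledger (full-length, identity
  # as realized by the mutation step)
  gh <- sim$planted
  genome_hits <- data.frame(
    query_id = gh$template_id, subject_id = gh$contig_id,
    pct_identity = gh$identity,
    aln_len = gh$end - gh$start,
    q_start = 0L, q_end = gh$end - gh$start,
    s_start = gh$start, s_end = gh$end, strand = "+",
    evalue = 0, score = round(2 * (gh$end - gh$start) * gh$identity),
    genome_id = gh$genome_id, stringsAsFactors = FALSE)
  # gene decoys: exon annotations on the planted copies + model-vs-exon hits
  products <- c("60S ribosomal protein L7", "elongation factor 1-alpha",
                "heat shock protein 70", "actin")
  exon_rows <- list(); exon_hits <- list()
  gene_ids <- cand$model_id[cand$fate == "gene_decoy"]
  exk <- 0L
  for (id in gene_ids) {
    L <- nchar(seqs[[id]])
    q0 <- round(0.1 * L); q1 <- round(0.7 * L)  # 60% of the model
    p <- sim$planted[sim$planted$template_id == id, , drop = FALSE]
    for (j in seq_len(nrow(p))) {
      exk <- exk + 1L
      prod <- products[(exk - 1L) %% length(products) + 1L]
      exon_rows[[exk]] <- data.frame(
        genome_id = p$genome_id[j], contig_id = p$contig_id[j],
        start = p$start[j] + q0, end = p$start[j] + q1, strand = "+",
        product = prod, stringsAsFactors = FALSE)
      exon_hits[[exk]] <- data.frame(
        query_id = id, subject_id = paste0("exon_", exk),
        pct_identity = p$identity[j], aln_len = q1 - q0,
        q_start = q0, q_end = q1, s_start = 0L, s_end = q1 - q0,
        strand = "+", evalue = 1e-60, score = 2 * (q1 - q0),
        product = prod, stringsAsFactors = FALSE)
    }
  }
  # tandem decoys: TRF-style records over the tandem 70%
  tnd <- list()
  for (id in cand$model_id[cand$fate == "tandem_decoy"]) {
    L <- nchar(seqs[[id]])
    tnd[[length(tnd) + 1L]] <- data.frame(
      model_id = id, start = 210L, end = L, period = 7L,
      copies = (L - 210L) / 7, stringsAsFactors = FALSE)
  }
  tandem_records <- if (length(tnd)) do.call(rbind, tnd) else
    data.frame(model_id = character(0), start = integer(0),
               end = integer(0), period = integer(0), copies = numeric(0))
  # tRNA decoys: intact tRNA prediction
  trna <- list()
  for (id in cand$model_id[cand$fate == "trna_decoy"]) {
    trna[[length(trna) + 1L]] <- data.frame(
      model_id = id, source = "trna", accession = "tRNA-Lys-TTT",
      description = "tRNA-Lys (anticodon TTT)", family_label = NA_character_,
      m_start = 100L, m_end = 172L, frame = NA_integer_, evalue = 1e-10,
      pseudo = FALSE, stringsAsFactors = FALSE)
  }
  trna_rows <- tag_te_relatedness(
    if (length(trna)) do.call(rbind, trna) else empty_evidence())
  # protein/profile evidence for the true TEs, inside the coding interior
  ev <- list()
  add_ev <- function(id, source, acc, desc, label, a, b, evalue) {
    ev[[length(ev) + 1L]] <<- data.frame(
      model_id = id, source = source, accession = acc, description = desc,
      family_label = label, m_start = a, m_end = b, frame = 1L,
      evalue = evalue, pseudo = NA, stringsAsFactors = FALSE)
  }
  for (i in which(cand$fate == "true_te")) {
    id <- cand$model_id[i]
    L <- nchar(seqs[[id]])
    if (cand$family[i] == "LTR_Gypsy_like") {
      add_ev(id, "dfam", "DF0001234", "Gypsy LTR retrotransposon", "Gypsy",
             260L, 760L, 1e-35)
      add_ev(id, "interpro", "IPR000477",
             "reverse transcriptase (RNA-dependent DNA polymerase)",
             NA_character_, 400L, 900L, 1e-28)
      add_ev(id, "sprot", "P10401", "gag-pol polyprotein", "Gypsy",
             300L, 1000L, 1e-22)
    } else {
      add_ev(id, "dfam", "DF0005678", "R2 non-LTR retrotransposon (LINE)",
             "R2", 150L, 650L, 1e-32)
      add_ev(id, "interpro", "IPR000477",
             "reverse transcriptase (RNA-dependent DNA polymerase)",
             "LINE", 300L, 800L, 1e-26)
      add_ev(id, "interpro", "IPR004808", "apurinic endonuclease",
             NA_character_, 820L, min(1000L, L - 10L), 1e-15)
    }
  }
  evidence <- tag_te_relatedness(
    if (length(ev)) do.call(rbind, ev) else empty_evidence())
  ltr_flags <- stats::setNames(cand$ltr_flag, cand$model_id)
  genome_ids <- paste0("g", seq_len(recipe$n_genomes))
  tree_text <- if (recipe$n_genomes >= 3L) {
    paste0("(", genome_ids[1], ",(", genome_ids[2], ",",
           paste(genome_ids[-(1:2)], collapse = ","), "));")
  } else {
    paste0("(", paste(genome_ids, collapse = ","), ");")
  }
  list(models = models, av_hits = av_hits, genome_hits = genome_hits,
       exon_hits = if (length(exon_hits)) do.call(rbind, exon_hits) else
         cbind(empty_hits(), product = character(0)),
       exons = if (length(exon_rows)) do.call(rbind, exon_rows) else NULL,
       tandem_records = tandem_records, trna_rows = trna_rows,
       evidence = evidence, ltr_flags = ltr_flags, truth = truth,
       tree_text = tree_text, assembly_lengths = sim$assembly_lengths)
}

#' Simulate a complete dataset (genomes + candidates + evidence)
#'
#' @param recipe a [simulation_recipe()].
#' @param dir optional directory; when given, all tables are written as
#'   plain-text files (FASTA / BLAST-tabular / GFF3 / TRF .dat / TSV /
#'   Newick) via [write_dataset()].
#' @return list combining [simulate_genomes()] and [emit_candidates()]
#'   output (`sim` element plus the dataset tables).
#' @export
simulate_dataset <- function(recipe = simulation_recipe(), dir = NULL) {
  sim <- simulate_genomes(recipe)
  ds <- emit_candidates(sim, recipe)
  ds$sim <- sim
  ds$recipe <- recipe
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a simulated dataset as plain-text files
#' @param ds dataset from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(stats::setNames(ds$sim$genomes$sequence,
                              ds$sim$genomes$contig_id), p("genomes.fasta"))
  write_fasta(ds$models, p("models.fasta"))
  write_tabular_hits(ds$av_hits, p("av_hits.tsv"))
  utils::write.table(ds$genome_hits, p("genome_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$exon_hits, p("exon_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ds$exons)) write_gff_exons(ds$exons, p("exons.gff3"))
  write_trf_dat(ds$tandem_records, p("tandem.dat"))
  write_evidence_tsv(ds$evidence, p("evidence.tsv"))
  write_evidence_tsv(ds$trna_rows, p("trna.tsv"))
  utils::write.table(ds$truth, p("truth_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$sim$planted, p("truth_planted.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(model_id = names(ds$ltr_flags), ltr_flag = ds$ltr_flags),
    p("model_attrs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ds$tree_text, p("tree.nwk"))
  utils::write.table(
    data.frame(genome_id = names(ds$assembly_lengths),
               assembly_length = as.integer(ds$assembly_lengths)),
    p("assembly_lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  r <- ds$recipe
  writeLines(c(
    paste0("rng_seed=", r$rng_seed), paste0("n_genomes=", r$n_genomes),
    paste0("contig_lengths=", paste(r$contig_lengths, collapse = ",")),
    paste0("gc_target=", r$gc_target),
    paste0("copies_per_te=", r$copies_per_te),
    paste0("divergence=", r$divergence)), p("recipe.txt"))
  invisible(dir)
}

#' Read back a simulated dataset directory
#' @param dir dataset directory written by [write_dataset()].
#' @return list shaped like [emit_candidates()] output.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  gh <- utils::read.table(p("genome_hits.tsv"), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  eh <- utils::read.table(p("exon_hits.tsv"), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  attrs <- utils::read.table(p("model_attrs.tsv"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  asm <- utils::read.table(p("assembly_lengths.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  list(models = read_fasta(p("models.fasta")),
       av_hits = read_tabular_hits(p("av_hits.tsv")),
       genome_hits = gh, exon_hits = eh,
       exons = if (file.exists(p("exons.gff3")))
         read_gff_exons(p("exons.gff3")) else NULL,
       tandem_records = read_trf_dat(p("tandem.dat")),
       evidence = read_evidence_tsv(p("evidence.tsv")),
       trna_rows = read_evidence_tsv(p("trna.tsv")),
       ltr_flags = stats::setNames(attrs$ltr_flag, attrs$model_id),
       truth = utils::read.table(p("truth_candidates.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE),
       tree_text = paste(readLines(p("tree.nwk")), collapse = ""),
       assembly_lengths = stats::setNames(asm$assembly_length, asm$genome_id))
}
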