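# tecurate

Curation of transposable-element (TE) consensus libraries, mobilome
summaries, and gain/loss parsimony on species trees.

## The problem

De-novo repeat finders (RepeatModeler and friends) emit thousands of
consensus models of interspersed repeats per genome. In compact parasite
genomes most of those models are not TEs at all: they are multigene
families, conserved genes shared across genomes, tandem/low-complexity
repeats, or tRNA genes. `tecurate` implements the curation cascade that
turns raw candidate models plus their supporting hit tables into a small,
evidence-backed TE library, and then the downstream bookkeeping: how much
of each genome the library masks, which genomes carry which families, and
the most parsimonious invasion/extinction history of each family on a
rooted phylogeny.

The package is aimed at people curating repeat libraries for small
eukaryotic (especially parasite) genomes, and at anyone who wants the
cascade's rules to be testable instead of folklore.

## What it computes

**Filtering cascade** (stage order is canonical, every threshold lives in
one `pipeline_config()` object):

1. *Redundancy clustering* — models are single-linkage clustered when a
   BLAST-style hit shows identity > 90% over > 90% of the shorter model;
   the longest member represents each cluster.
2. *Copy number / full length* — a model is kept iff some genome contains
   ≥ 3 hits spanning ≥ 80% of the model (conserved genes typically occur
   once or twice per genome).
3. *Exon overlap* — discarded when annotated exons (excluding
   "hypothetical" and TE-like products) cover > 40% of the model.
4. *Tandem content* — discarded when tandem repeats (TRF records, or the
   built-in periodicity scanner) cover > 40% of the model.
5. *tRNA screening* — intact tRNA predictions mark conserved tRNA genes
   (discard); pseudogene-only predictions flag tRNA-derived SINE
   candidates (keep + flag).

**Evidence curation** — protein/profile evidence rows (Dfam / InterPro /
Swiss-Prot / known-TE style) are vetted against a DUST low-complexity
mask (window score `sum c_t(c_t−1)/2 / (w−3)` over triplet counts) plus
tandem intervals; a model is accepted iff TE-related evidence survives
and the Dfam-vs-InterPro conflict rule does not fire. Accepted models are
classified (LTR Gypsy-like, LINE-like, LTR/nonLTR unclassified, SINE
candidate) by majority vote over evidence family labels.

**Mobilome summary** — merged (union) coverage per genome,
`te_percent = 100 · covered / assembly_length` (half-even, 2 decimals),
presence/absence matrices, and a GC-median split of TE-bearing genomes.

**Gain/loss parsimony** — with the ancestral state fixed to *absent*, the
Sankoff recursion
`C_v(s) = Σ_{c ∈ children(v)} min_t [ w(s→t) + C_c(t) ]`
gives the minimum event cost (gain = 0→1, loss = 1→0, unit weights by
default), and an exhaustive backtrack enumerates **all** optimal
scenarios as (gain-edge set, loss-edge set), each verified by replaying
the events down the tree. A Dollo (single-origin) variant is included for
comparison.

**Synthetic data** — `simulation_recipe()` / `simulate_dataset()` build
toy genomes (5–50 kb contigs, GC 0.15–0.60) with planted LTR and
LINE-like elements, redundant variants, low-copy repeats, multigene-family
decoys, tandem decoys, and tRNA decoys, plus every evidence table and a
ground-truth ledger, so the whole pipeline is testable offline.

## Worked example

```r
library(tecurate)
ds  <- simulate_dataset(simulation_recipe(rng_seed = 42))
res <- run_pipeline(ds)
res$cascade$report
#>         stage n_in n_discarded n_out
#> 1  clustering   10           2     8
#> 2 copy_number    8           1     7
#> 3        exon    7           2     5
#> 4      tandem    5           2     3
#> 5        trna    3           1     2
res$curation$classifications
#>   model_id         family               basis
#> 1      te1 LTR_Gypsy_like    DF0001234,P10401
#> 2      te2      LINE_like DF0005678,IPR000477
```

Ten candidates enter; two redundant variants fall to clustering, one
low-copy repeat to the copy-number stage, two multigene-family decoys to
the exon filter, two tandem decoys to the tandem filter, one tRNA gene to
tRNA screening — and the two planted TEs survive and are classified into
their planted families. Coverage per genome:

```r
res$summary$summaries[, c("genome_id", "te_covered", "te_percent")]
#>   genome_id te_covered te_percent
#> 1        g1       5992      13.32
#> 2        g2       4796      10.66
#> 3        g3          0       0.00
```

Parsimony on a shipped 9-taxon piroplasmid fixture (LINE-like presence in
*B. ovata*, *B. bigemina*, *B. divergens*, *T. equi*):

```r
tr <- read_newick(system.file("extdata", "piroplasmid_tree.nwk", package = "tecurate"))
st <- read.table(system.file("extdata", "piroplasmid_presence.tsv", package = "tecurate"),
                 header = TRUE, sep = "\t")
es <- enumerate_scenarios(tr, setNames(st$has_te, st$species))
es$cost        # 3
es$scenarios
#> <scenario> cost 3: 1 gain(s) [stem], 2 loss(es) [B_bovis, node6]
#> <scenario> cost 3: 2 gain(s) [node3, T_equi], 1 loss(es) [B_bovis]
#> <scenario> cost 3: 3 gain(s) [B_divergens, node1, T_equi], 0 loss(es) []
```

The first two are the classic "single invasion, two extinctions" vs "two
invasions, one extinction" stories; the third (three independent gains)
is equally parsimonious under unit costs, which is exactly why the
enumeration is exhaustive.

## Command line

```sh
Rscript inst/scripts/tecurate simulate  --seed 1 --out data/
Rscript inst/scripts/tecurate filter    --data data/ --out run/
Rscript inst/scripts/tecurate curate    --data data/ --out run/
Rscript inst/scripts/tecurate summarize --data data/ --out run/
Rscript inst/scripts/tecurate parsimony --tree tree.nwk --presence presence.tsv --out scenarios.tsv
```

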