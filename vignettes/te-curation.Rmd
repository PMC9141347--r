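---
title: "Curating TE consensus libraries: models, thresholds and design choices"
author: "tecurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating TE consensus libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecurate)
```

## The procedure and its assumptions

De-novo repeat discovery produces consensus models of *interspersed
repeats*, not of transposable elements: anything that recurs in a genome
— multigene families, conserved genes shared between related genomes,
tandem arrays, tRNA genes — can surface as a model. `tecurate` encodes
the standard curation argument as a fixed five-stage cascade followed by
evidence integration. The underlying assumptions are:

* a *redundant* model pair is recognizable as a high-identity,
  high-coverage pairwise alignment (we require identity > 90% over > 90%
  of the shorter model, strictly, and keep the longest member — longer
  consensus models are more complete);
* a genuine interspersed repeat recurs *within* a genome, so a model
  with fewer than three full-length copies in every genome is more
  plausibly a conserved gene;
* protein-coding decoys betray themselves by aligning to annotated
  exons over much of their length, tandem decoys by their internal
  periodicity, tRNA-derived models by intact tRNA predictions;
* a model is a trustworthy TE only with *positive* evidence (a TE-family
  sequence hit or a TE-associated protein domain) that does not sit in a
  low-complexity or tandem region of the model.

All coordinates are 0-based half-open internally; conversions happen only
in the parsers (BLAST tabular, RepeatMasker `.out`, TRF `.dat`, GFF3 are
1-based inclusive on disk).

## Tunable parameters

Every threshold lives in `pipeline_config()`:

| field | default | meaning |
|---|---|---|
| `cluster_id_thresh` | 0.90 | redundancy identity, strict `>` (fraction) |
| `cluster_cov_thresh` | 0.90 | redundancy coverage of the *shorter* model, strict `>` |
| `min_copies` | 3 | full-length copies required in ≥ 1 genome (inclusive) |
| `full_length_frac` | 0.80 | fraction of model length a copy must span |
| `exon_frac_thresh` | 0.40 | exon-union fraction above which a model is discarded (strict) |
| `tandem_frac_thresh` | 0.40 | tandem-union fraction, strict |
| `evalue_cluster` | 1e-10 | e-value ceiling for clustering hits |
| `evalue_known_te` | 1e-20 | e-value ceiling for matches to previously reported TEs |
| `evalue_protein` | 1e-10 | e-value ceiling for protein/profile evidence |
| `lowcomp_overlap_thresh` | 0.50 | masked fraction above which evidence is dropped (strict) |
| `min_evidence_nt` | 30 | minimum evidence interval (≈ 10 aa) |
| `dust_window`, `dust_thresh` | 64, 2.0 | DUST window and masking score |

Boundary semantics follow the wording "more than": a model at exactly 40%
exon or tandem content is kept; strictly above is discarded. Copy number
is inclusive: exactly three full-length copies in one genome keeps the
model. "Full length" is not quantified in the narrative the cascade comes
from; 80% is our stated default, exposed in the config.

The coverage denominator for clustering is the **shorter** sequence, so a
fragment still clusters into its full-length parent — the alternative
(longer-sequence denominator) would leave truncated duplicates in the
library. Clustering is single-linkage over the qualifying-hit graph; any
tie for longest member is broken by the lexicographically smallest id, so
the result is permutation-invariant.

## Numerical choices

* **DUST threshold.** The window statistic is
  `sum(c_t (c_t − 1) / 2) / (w − 3)` over the 64 triplet counts `c_t`.
  A homopolymer window scores ≈ 31, a dinucleotide repeat ≈ 15, uniform
  random DNA ≈ 0.5. The default threshold 2.0 was calibrated once so that
  uniform random 1 kb sequence masks < 5% (the recorded maximum over 100
  seeded sequences is 0), and is recorded here rather than tuned per run.
* **Tandem detector.** The internal scanner is a declared stand-in for a
  real tandem-repeat finder: for each period `p ≤ 100` it greedily grows
  runs of `seq[i] == seq[i+p]` matches while cumulative identity stays
  ≥ 0.85, keeps arrays of ≥ `max(2p, 12)` nt, and suppresses harmonics by
  dropping records ≥ 90% covered by smaller-period records. The 12-nt
  floor exists because at period 1–2 the pure `2p` rule would mask the
  chance micro-runs random DNA produces (≈ 19% of it); with the floor the
  recorded maximum random fraction is 0.032. When genuine TRF `.dat`
  records are supplied they take precedence and the detector is not
  consulted; a model absent from a supplied record set is treated as
  tandem-free.
* **Aligner.** Smith–Waterman with linear gaps (+2/−1/−2), exact DP with
  full traceback; ties are broken by earliest query start, then earliest
  subject start, then fewest gaps, so results are reproducible. Affine
  gaps are deliberately out of scope: the pipeline only needs
  identity/coverage verdicts, not polished alignments.
* **ORFs** are stop-to-stop (no ATG requirement): the consumer is
  protein-domain evidence on possibly truncated consensus models, where
  demanding a start codon would discard exactly the divergent cases of
  interest.
* **Rounding.** Coverage percentages use R's round-half-even at 2
  decimals. All twenty shipped regression pairs are insensitive to
  half-up vs half-even, so the choice is documented rather than fitted.
* **Median convention.** The GC split uses the lower median for even
  table sizes; the counts reported are `has_te` among strictly-below vs
  at-or-above genomes.

## Gain/loss parsimony

Presence/absence of a TE family is reconstructed on a rooted tree with
the stem (ancestral) state fixed to *absent*: every family must be gained
at least once, and the stem edge is a legal gain location. Costs default
to 1 per gain and 1 per loss; asymmetric weights are exposed for
sensitivity analysis. `enumerate_scenarios()` backtracks the Sankoff
table exhaustively and reports **every** minimum-cost event set,
deduplicated and replay-verified.

One consequence is worth stating plainly: on the shipped piroplasmid
fixture (presence in *B. ovata*, *B. bigemina*, *B. divergens*,
*T. equi*) the minimum cost is 3 and there are **three** optimal
scenarios — one gain + two losses, two gains + one loss, and three
independent gains. The first two are the biologically natural stories;
the third is mathematically unavoidable under equal event weights. The
acceptance suite pins the two published-style scenarios and the cost, and
keeps an intentionally failing assertion documenting the "exactly two"
expectation (see the repository's decision notes). Making losses even
slightly cheaper than gains (`loss_cost < 1`) collapses the optimum to
the single-origin scenario, as the sensitivity test shows. The coccidian
fixture (Eimeriidae + *C. suis* present, remaining Sarcocystidae absent)
has cost 2 with exactly the two expected scenarios.

The Dollo variant (`dollo_scenario()`) forces a single gain above the
most recent common ancestor of the present tips; its cost is always ≥ the
Sankoff minimum and equals it on the piroplasmid fixture.

## What the simulator emulates — and what it does not

`simulation_recipe()` states a small world once: 3 genomes × 45 kb of
i.i.d. background at GC 0.35 (configurable within the 0.15–0.60 range
that small parasite genomes span), an LTR element (200-nt terminal
repeats flanking a stop-free coding interior) and a LINE-like element
(RT + endonuclease ORF region) at 4 full-length copies each in a home
genome with 3% per-site divergence, one ~95%-identical redundant variant
per TE, one low-copy repeat (2 copies), two multigene-family decoys
(3 copies each, exon-annotated over 60% of their length), two tandem
decoys (70% tandem), and one tRNA-gene decoy. Hit and evidence tables are
derived from the planted truth, so identities in the tables match the
realized substitutions exactly.

Deliberately **not** emulated: indels (substitution-only mutation keeps
identity/coverage arithmetic exact), nested or fragmented insertions,
consensus building from copies (candidates are the templates themselves —
rebuilding consensus sequences is the job of the upstream discovery
tool), sequencing artifacts, and real database content. A green test
therefore establishes that the *rules* behave as specified on data whose
truth is known — not that any particular external tool's output would be
curated identically. Ambiguity codes stop at the genome level: consensus
models containing `N` are rejected at load.

## Known limitations

* The internal tandem scanner is greedy and approximate off the perfect-
  tandem case; faithful workflows should supply TRF `.dat` records.
* The copy-number stage encodes only the mechanical rule (≥ 3 full-length
  copies in at least one genome); any additional manual judgment about
  "poorly aligning" models in the original practice is not recoverable
  and not modeled.
* LTR structure detection is out of scope; the `ltr_structure_flag` is an
  input attribute from upstream structural tools or the simulator.
* Scenario enumeration is exponential in the worst case and capped
  (configurable, default 10,000 labelings); fine for ≤ 64-leaf species
  trees with realistic presence patterns.
* A note on screening beyond the cascade: transposase-like hits that
  align best to bacterial proteins are a known contamination signature in
  assembled parasite genomes. The package does not implement a
  contamination screen; treat unexplained DNA-transposon evidence in
  otherwise retrotransposon-only genomes with suspicion.

## Reproducibility

Every stochastic step (simulation, mutation, placement) flows from
`rng_seed` through R's RNG; the same recipe writes byte-identical
datasets. The cascade and curation are pure functions of (inputs,
config); tests assert determinism explicitly.
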