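# venomalt

**venomalt** is an R toolkit for integrative transcriptome–proteome analysis
of venom glands: it quantifies how *alternative transcription* — alternative
5′/3′ splice sites, exon skipping, mutually exclusive exons, alternative
first/last exons, intron retention — expands the repertoire of proteins
secreted in venom. It was built around the analysis style used for theridiid
spider venom (latrotoxins, latrodectins, ICKs, CRISPs, enzymes, LRR
proteins), but every step is generic.

It is aimed at researchers who have, from upstream tools:

* a merged transcript annotation (GTF) and transcript sequences (FASTA),
* a homology-hit table (best blastx-style hit per transcript, with frame),
* a filtered peptide-evidence table from venom mass spectrometry,
* per-library read counts with replicate structure across tissues,
* a splice-junction support table,

and who want a tested, scriptable path from those inputs to the venom
inventory and its summary statistics.

## What it computes

| Stage | Functions |
|---|---|
| Transcript/locus bookkeeping | `read_annotation()`, `multi_transcript_census()`, `classify_novel_intergenic()`, `attach_junction_support()` |
| Splice-event classification (7 classes) | `classify_pair()`, `locus_event_summary()`, `event_frequency_table()` |
| ORF-based protein prediction | `find_orfs()`, `select_protein()`, `trim_to_met()`, `deduplicate_proteins()` |
| Peptide-parsimony protein inference | `filter_evidence()`, `infer_identifications()`, `enumerate_counts()`, `purge_contaminants()`, `gene_contribution_summary()` |
| Venom-gland upregulation | `compute_tpm()`, `call_vgtup()`, `expression_rank_flags()`, `pattern_classify()` |
| Integrated reports | `categorize()`, `build_table1()`, `build_table2()`, `two_proportion_chisq()`, `report_percent()` |
| Synthetic data with ground truth | `fixture_spec()`, `make_annotation_fixture()`, `make_evidence_fixture()`, `make_counts_fixture()` |

Two statistics sit at the core:

* **Protein inventory bounds.** After filtering (peptide probability ≥ 0.95,
  protein probability ≥ 0.99, ≥ 2 distinct peptides), proteins whose peptide
  set is a strict subset of another's are removed (no independent evidence),
  and proteins with identical peptide sets merge into identification groups.
  With `I` identifications, the venom holds at least `min = I` proteins
  (one per identification) and at most
  `max = Σ_g (distinct member sequences of g)`.

* **Pooled two-proportion chi-square.** For proportions `k1/n1` vs `k2/n2`
  with pooled `p̂ = (k1+k2)/(n1+n2)`:

  `χ² = (k1/n1 − k2/n2)² / (p̂(1−p̂)(1/n1 + 1/n2))`, df = 1.

Upregulation calling follows the three-pairwise-comparison design: the focal
tissue is tested against each other tissue at FDR 5% (Benjamini–Hochberg,
over a pluggable negative-binomial engine, after adding +5 to every count),
and the final upregulated set is the exact three-way intersection.

## Worked example

All fixtures are generated, seeded and carry their ground truth:

```r
library(venomalt)
spec <- fixture_spec(seed = 1)

# annotation with planted splice events
fx <- make_annotation_fixture(spec)
multi_transcript_census(fx$loci)
#> n_single  n_multi
#>        2        8
event_frequency_table(fx$loci)
#>               label count percent
#> 1:             A5SS     2    14.3
#> ...                                 (each of the 7 classes planted twice)

# proteins and venom inference
ev  <- make_evidence_fixture(spec)
ids <- purge_contaminants(
  infer_identifications(
    filter_evidence(ev$observations, ev$protein_probabilities),
    ev$protein_seqs),
  ev$protein_labels)
enumerate_counts(ids)
#> $min_count [1] 6      # one protein per identification
#> $max_count [1] 7      # all distinct members of every group
#> $kinds: unique 4, group_distinct 1, group_identical 1

# venom-gland upregulation on a planted 8-fold count matrix
cf <- make_counts_fixture(spec)
length(call_vgtup(cf$em)$vgtup)
#> [1] 20               # all 20 planted transcripts recovered

# in-paper style arithmetic from printed integers
two_proportion_chisq(58, 86, 11922, 58158)$statistic
#> [1] 115.8223
report_percent(58, 86)
#> [1] 67.4
```

The `min_count`/`max_count` pair reads: the evidence guarantees at least 6
distinct proteins (4 uniquely identified, 2 groups each contributing at
least one), and at most 7 (the distinct group contributes both members; the
identical group only one sequence). The chi-square value tests whether
multi-transcript genes are over-represented among venom-protein genes
relative to the genome.

A command-line wrapper covers the same pipeline
(`inst/cli/venomalt <subcommand>`; see `?venomalt_cli`).

## Scope

Upstream steps (read alignment, transcript assembly, spectrum matching,
homology search, domain/toxicity prediction) are external by design; this
package starts from their tabular outputs. The built-in differential
expression engine is a deliberately simple moderated NB Wald test — not a
re-implementation of empirical-Bayes engines — and is pluggable via the
`engine` argument. See `vignettes/venom-proteotranscriptomics.Rmd` for the
full methods account.
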