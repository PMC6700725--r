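---
title: "Methods: alternative transcription and the venom proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alternative transcription and the venom proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomalt)
```

# The problem

Venom glands secrete a protein cocktail whose diversity can exceed the
number of genes encoding it, because a single locus may produce several
transcripts — through alternative splice sites, skipped or mutually
exclusive exons, alternative first/last exons, or retained introns — each
potentially encoding a distinct protein. Tying mass-spectrometry evidence
from milked venom back to transcript models asks three linked questions:
which transcripts exist and how do they differ (events), which proteins can
the peptide evidence actually discriminate (inference), and which
transcripts are preferentially expressed in the venom gland (upregulation).
`venomalt` implements that chain as small, testable operations.

# Transcript models and coordinates

GTF input is read as 1-based inclusive and stored 0-based half-open; all
emitted files restore the GTF convention. Half-open intervals make interval
arithmetic (overlaps, adjacency, intron gaps) unambiguous. Transcripts must
have non-overlapping, same-strand, same-chromosome exons; single-exon
transcripts are valid and simply have no introns. A locus is novel
intergenic when none of its exons overlaps any reference exon *on either
strand* — the merged-annotation "class code u" notion; antisense-overlap
subclasses are deliberately not distinguished because only the intergenic
class is used downstream. Junction-support lookup keys on
(chromosome, start, end) and checks strand only when the table provides one,
since junction tables vary in whether they are stranded.

# Splice-event classification

The seven-class vocabulary is standard in event-level splicing tools; the
definitions here are exact on coordinates (no fuzz window), on the grounds
that assembled models share coordinates exactly when they share junctions.
"First" and "last" are in transcription order, so strand-aware. For a
transcript pair on the same strand:

* **EXON_SKIP** — an internal exon of one transcript lies inside an intron
  of the other whose boundaries match the flanking junctions.
* **MXE** — two non-overlapping internal exons, one per transcript, inside
  the same pair of shared flanking junctions.
* **A5SS / A3SS** — two introns share their acceptor (donor) but differ at
  the donor (acceptor), **and the exons carrying the differing boundary
  overlap**.
* **INTRON_RETENTION** — an intron of one transcript is contained in an
  exon of the other, with both outer flanking boundaries coinciding.
* **AFE / ALE** — non-overlapping first (last) exons, each splicing into a
  shared downstream acceptor (from a shared upstream donor).

The overlap condition on A5SS/A3SS is an addition to the naive "share one
boundary, differ at the other" phrasing and is load-bearing: without it,
every exon-skipping pair also witnesses one A5SS and one A3SS (its skipping
intron shares a boundary with each flanking intron), and every AFE/ALE pair
witnesses a spurious splice-site event, so no planted single-event fixture
could ever be recovered cleanly. Requiring the differing boundary to fall on
overlapping exons restricts A5SS/A3SS to genuine splice-site choice within a
common exon, and it subsumes the rule that terminal-exon rewirings are
reported only as AFE/ALE. A pair may still witness several labels at once
(e.g. an AFE and an independent downstream skip).

**Counting unit.** Per locus, events are deduplicated by
`(label, witnessing coordinates)` over all unordered transcript pairs: a
skipped exon shared by three transcript pairs is one event. This convention
was chosen because transcript-rich loci would otherwise count the same
physical event quadratically many times, which is inconsistent with
event-per-gene magnitudes around two. The true counting unit used in any
given published tally is rarely stated; ours is explicit and tested.

# ORF-based protein prediction

One protein per transcript, in three steps:

1. **`find_orfs()`** scans the three sense frames for maximal stop-free
   codon stretches ending at a stop or at the transcript end, keeping those
   `> 90` nt (default `min_nt = 91`, configurable; the boundary is read as
   strictly greater). ORFs are *not* ATG-anchored — predictions are trimmed
   to the first methionine afterwards, which implies upstream context may be
   included, exactly as a trim-later pipeline requires. Codons containing
   `N` translate to `X` and do not terminate an ORF. ORFs running into the
   transcript end without a stop are kept: truncated assembled models are
   common. Only sense frames are scanned because transcript models are
   stranded; whether any given upstream pipeline also scanned antisense
   frames is generally unknowable, so this choice is documented rather than
   guessed.
2. **`select_protein()`** takes the longest ORF in the frame of the best
   homology hit (smallest e-value, ties by input order); without a hit, or
   with no ORF in the hit frame, the longest over all frames. Ties break by
   smallest frame then smallest start, making selection deterministic.
3. **`trim_to_met()`** keeps the suffix from the first M; Met-less
   predictions are flagged and treated as singletons by
   `deduplicate_proteins()`, which partitions transcripts by exact equality
   of the trimmed sequence (CD-hit-at-100%-identity behavior).

# Peptide-parsimony protein inference

Thresholds are **inclusive** (a peptide at exactly 0.95 survives): defaults
are peptide probability ≥ 0.95, protein probability ≥ 0.99, and ≥ 2
*distinct peptide sequences* (not spectra) per protein; all three are
arguments. Spectral probabilities are inputs, not computed — the probability
model lives in external search software.

"No independent evidence" is operationalized as strict-subset subsumption:
a protein whose (filtered) peptide set is a strict subset of another
surviving protein's set is removed. Proteins with *identical* peptide sets
are indistinguishable and merge into one identification, whose kind is
assigned after Met trimming: `unique`, `group_identical` (members share one
sequence, arising from distinct transcripts), or `group_distinct`. Proteins
sharing only some peptides, with neither set nested, remain separate
identifications — the alternative (transitive closure into super-groups) is
defensible but less conservative, and the choice is flagged in the
documentation. Peptide-to-protein matching treats I and L as distinct by
default because the upstream search database defines the space; an
`il_equivalent` flag is provided.

The inventory bounds follow: minimum = number of identifications, maximum =
total distinct member sequences. Contaminant purging removes an
identification only when *every* member matches a contaminant keyword
(keratin, trypsin, hemocyanin by default, case-insensitive); mixed groups
are flagged, not silently dropped.

**Per-gene contributions.** A gene's *unambiguous* venom count is the number
of identifications whose members all belong to the gene — each such
identification guarantees at least one of the gene's proteins is present —
and its *possible* count is the number of distinct member sequences of the
gene across all identifications. On the canonical worked locus (four
transcripts, four proteins, one discriminated, two grouped, one excluded)
this yields (4, 4, 2, 3). A phrasing that counted only uniquely identified
sequences as unambiguous would give 1 and contradict that example, so the
identification-level count is used.

# Expression analysis

TPM is the within-library length-normalized measure
(`rate = count/length`, scaled to sum to 10⁶ per library; asserted to a
relative tolerance of 1e-6 in tests). A pseudocount of +5 per cell is
applied *before* testing, preventing degenerate zero/zero comparisons, in
the stated order of the emulated pipeline.

**The test engine is a design decision, not a reproduction.** The
pairwise/intersection/threshold logic — focal tissue vs each of the three
other tissues at per-comparison FDR 5%, final set = exact three-way
intersection — is implemented exactly. The per-transcript test inside it is
deliberately simple and self-contained: median-of-ratios size factors,
method-of-moments dispersion (variance = μ + αμ²) pooled within groups and
shrunk toward the transcriptome median (`α* = (10·median + df·α̂)/(10 + df)`;
with two replicates per group df = 2, so shrinkage is strong — individual
4-sample dispersion estimates are far too noisy to use raw), and a Wald
statistic on the log ratio of group means referred to the standard normal.
Empirical-Bayes posterior-probability engines used in published analyses are
*not* re-implemented and no numerical equivalence is claimed; the `engine`
argument accepts any function with the same contract. The FDR here is
Benjamini–Hochberg; published counts obtained under a posterior-probability
control will differ.

Rank flags use ties-share-the-better-rank and a `ceiling(k% · n)` cutoff,
so with 100 transcripts exactly one is "top 1%". The order-of-magnitude
pattern label is fixed at ≥ 10×, with the convention that a zero focal mean
satisfies it against any positive tissue; "broad expression" means > 5 TPM
in every tissue. Percentages print half-up to one decimal, matching how
ratios are conventionally typeset (58/86 → 67.4).

The pooled two-proportion chi-square (no continuity correction) is used for
the multi-transcript enrichment test; on the printed integers it reproduces
the published statistic to two decimals, whereas a one-sample
goodness-of-fit reading of the same integers gives ≈ 116.3 — the pooled
form is therefore what the published value actually is, despite the
"goodness-of-fit" name attached to it.

# What the synthetic world does and does not establish

The generator (`fixture_spec()` defaults) states a small world:

* **Annotation**: ten loci; the seven event classes planted one per locus,
  one locus with all seven in disjoint coordinate blocks, two
  single-transcript loci; strands alternate, with minus-strand templates
  reflected so the planted label is preserved in transcription order.
  Transcript sequences have exactly one designed ORF (stop-dense `TAGC`
  padding plus frame-blocker codons that plant stops in the shifted frames),
  so the predicted protein is known by construction.
* **Evidence**: the planned numbers of unique proteins, distinct groups,
  identical groups and subsumed proteins are realized literally (private
  peptides; identical peptide sets over shared cores; strict-subset sets),
  plus a below-threshold peptide, a single-peptide protein and labelled
  contaminants to exercise the filters.
* **Counts**: 4 tissues × 2 replicate libraries; 200 transcripts, 20
  planted at 8-fold in the venom gland; negative binomial with dispersion
  α = 0.1 (typical bulk RNA-seq overdispersion); baseline means log-normal
  (meanlog = log 100, sdlog = 1), library size factors uniform on
  0.8–1.2, lengths uniform on 500–3000 nt. The magnitudes not fixed by the
  emulated design were chosen once as ordinary bulk RNA-seq values for
  quantifiable transcripts, before any test outcome was observed.

A green suite on this world establishes that the *rules* are implemented
exactly (oracle equivalence, planted-structure recovery, determinism), and
that the test engine has usable operating characteristics under clean NB
data with strong effects. It does **not** establish that real venom-gland
libraries would yield any particular upregulated count: real data add
unmodeled features — varying gene-wise dispersions, correlated counts,
mapping ambiguity between isoforms, polymorphism, batch structure — and the
engine differs from empirical-Bayes engines by design. Likewise, peptide
evidence here is noise-free given its probabilities; real evidence graphs
are denser and messier.

# Numerical and degenerate-input choices

* Event comparison is exact on integer coordinates; no fuzz parameter
  exists on purpose.
* `find_orfs` on an empty sequence returns an empty table; a transcript
  with no qualifying ORF is dropped from `predict_proteins()` with a
  warning naming it, and errors from `select_protein()` name the
  transcript.
* Zero total rate in a library makes TPM undefined and errors; a zero-event
  frequency table reports 0.0 percents with a `no_events` attribute rather
  than NaN.
* Degenerate pooled proportions (0 or 1) define the chi-square statistic as
  0.
* Fixture generation restores the caller's RNG state; all randomness flows
  from the spec seed.

# Known limitations

* The event-counting unit, while principled, cannot be validated against
  any published total without the original data; only the convention is
  tested.
* Identification groups that span genes count toward per-gene *possible*
  but never *unambiguous* contributions; a probabilistic allocation is out
  of scope.
* The DE engine's normal reference is anti-conservative in principle at
  n = 2 per group; the strong dispersion shrinkage compensates in the
  tested regime (empirical per-comparison false discovery stays below the
  asserted 0.10 bound), but heavy-tailed real data may behave differently.
* Category assignment from free-text homology labels is heuristic by
  nature; the keyword rule table is user-editable and first-match-wins.
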