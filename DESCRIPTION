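Package: venomalt
Title: Alternative Transcription and Venom Proteome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative transcriptome-proteome toolkit for studying how
    alternative transcription expands venom protein diversity. Parses
    transcript annotations (GTF) into gene loci, classifies alternative
    splicing events between transcript pairs into the seven standard classes
    (alternative 5'/3' splice sites, exon skipping, mutually exclusive exons,
    alternative first/last exons, intron retention), predicts one protein per
    transcript by a homology-guided longest-ORF rule, performs
    peptide-parsimony protein inference with grouping of indistinguishable
    proteins and minimum/maximum inventory enumeration, calls venom-gland
    upregulated transcripts from replicated count matrices with a pluggable
    negative-binomial engine, and joins the results into per-category and
    per-gene summary tables. A seeded synthetic-data module generates
    annotation, peptide-evidence and count fixtures with known ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
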