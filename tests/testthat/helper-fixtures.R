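# shared shorthand builders for tests

mk_tx <- function(id, exons, strand = "+", gene = "G", chrom = "chr1",
                  source = "novel") {
  transcript_model(id, gene, chrom, strand,
                   matrix(as.integer(exons), ncol = 2L, byrow = TRUE),
                   source = source)
}

# canonical, order-independent signature of a locus list for set comparison
locus_signature <- function(loci) {
  sig <- lapply(loci, function(locus) {
    txs <- lapply(locus$transcripts, function(tx)
      paste(tx$chrom, tx$strand,
            paste(tx$exons[, "start"], tx$exons[, "end"], sep = "-",
                  collapse = ","),
            sep = "|"))
    paste0(locus$gene_id, "{", paste(sort(unlist(txs)), collapse = ";"), "}")
  })
  sort(unlist(sig))
}

# random toy transcript pair on a coarse grid (shared boundaries are likely)
random_tx_pair <- function(max_exons = 4L, grid = seq(0L, 200L, 10L)) {
  strand <- sample(c("+", "-"), 1L)
  mk <- function(id) {
    k <- sample(seq_len(max_exons), 1L)
    bnd <- sort(sample(grid, 2L * k))
    mk_tx(id, bnd, strand = strand)
  }
  list(a = mk("tA"), b = mk("tB"))
}

# random small evidence graph: proteins x peptides bipartite structure
random_evidence_graph <- function(n_prot = NULL, n_pep = NULL) {
  if (is.null(n_prot)) n_prot <- sample(2:10, 1L)
  if (is.null(n_pep)) n_pep <- sample(2:12, 1L)
  prots <- sprintf("P%02d", seq_len(n_prot))
  peps <- sprintf("PEP%02d", seq_len(n_pep))
  protein_ids <- lapply(seq_len(n_pep), function(i)
    sample(prots, sample(seq_len(min(3L, n_prot)), 1L)))
  obs <- data.table::data.table(peptide_sequence = peps,
                                peptide_probability = 1,
                                protein_ids = protein_ids)
  ## a few duplicated sequences to exercise group_identical
  base <- replicate(n_prot, paste(sample(LETTERS, 12L, TRUE), collapse = ""))
  dup <- sample(n_prot, size = floor(n_prot / 3))
  if (length(dup) >= 2L) base[dup] <- base[dup[1L]]
  list(observations = obs, protein_seqs = stats::setNames(base, prots))
}
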