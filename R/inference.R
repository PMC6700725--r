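## Peptide-parsimony protein inference.
##
## From filtered peptide evidence: proteins whose peptide set is a strict
## subset of another surviving protein's set lack independent evidence and are
## removed (Occam parsimony); proteins with identical peptide sets are
## indistinguishable and merge into one identification (a group); the
## remaining identifications give a conservative minimum protein count (one
## per identification) and a maximum (all distinct member sequences).

#' Read a peptide evidence table
#'
#' Tab-separated with header columns `peptide_sequence`,
#' `peptide_probability`, `protein_ids` (semicolon-joined) and
#' `protein_probability`.  The probability of a protein is taken as the
#' maximum `protein_probability` over the rows that mention it.
#'
#' @param path file path.
#' @return List with `observations` (a `data.table` with a `protein_ids`
#'   list-column) and `protein_probabilities` (named numeric vector).
#' @export
read_evidence_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("peptide_sequence",
                                              "protein_ids")))
  need <- c("peptide_sequence", "peptide_probability", "protein_ids",
            "protein_probability")
  if (!all(need %in% names(dt)))
    stop("evidence table must have columns: ", paste(need, collapse = ", "))
  obs <- data.table(peptide_sequence = dt$peptide_sequence,
                    peptide_probability = dt$peptide_probability,
                    protein_ids = strsplit(dt$protein_ids, ";", fixed = TRUE))
  long <- data.table(protein = unlist(obs$protein_ids),
                     prob = rep(dt$protein_probability,
                                lengths(obs$protein_ids)))
  pp <- long[, .(prob = max(prob)), by = protein]
  list(observations = obs,
       protein_probabilities = setNames(pp$prob, pp$protein))
}

#' Filter peptide evidence by probability and peptide-count thresholds
#'
#' Removes peptide observations below `peptide_p_min`; removes proteins below
#' `protein_p_min` or with fewer than `min_peptides` distinct surviving
#' peptide sequences from all matched sets; finally drops observations whose
#' matched set becomes empty.  All thresholds are inclusive.
#'
#' @param observations `data.table` with columns `peptide_sequence`,
#'   `peptide_probability` and list-column `protein_ids`.
#' @param protein_probabilities named numeric vector (protein id ->
#'   probability), or `NULL` to skip the protein-probability filter.
#' @param peptide_p_min,protein_p_min,min_peptides thresholds; defaults 0.95,
#'   0.99 and 2.
#' @return The filtered observations table (same structure).
#' @export
filter_evidence <- function(observations, protein_probabilities = NULL,
                            peptide_p_min = 0.95, protein_p_min = 0.99,
                            min_peptides = 2L) {
  obs <- observations[observations$peptide_probability >= peptide_p_min, ]
  if (nrow(obs) == 0L) return(obs)
  long <- data.table(peptide = rep(obs$peptide_sequence,
                                   lengths(obs$protein_ids)),
                     protein = unlist(obs$protein_ids))
  npep <- long[, .(n = length(unique(peptide))), by = protein]
  keep <- npep$protein[npep$n >= min_peptides]
  if (!is.null(protein_probabilities)) {
    known <- names(protein_probabilities)
    miss <- setdiff(keep, known)
    if (length(miss))
      stop("no protein probability for: ", paste(miss, collapse = ", "))
    keep <- keep[protein_probabilities[keep] >= protein_p_min]
  }
  obs <- copy(obs)
  obs[, protein_ids := lapply(protein_ids, intersect, y = keep)]
  obs[lengths(protein_ids) > 0L]
}

#' Infer protein identifications by peptide parsimony
#'
#' Builds the protein-to-peptide-set map from filtered observations, removes
#' proteins whose peptide set is a strict subset of another protein's set
#' (no independent evidence), and merges proteins with identical peptide sets
#' into one identification.  Identification kind is assigned by comparing the
#' members' (Met-trimmed) sequences: `unique` (one member),
#' `group_identical` (several members, one distinct sequence) or
#' `group_distinct` (several members, two or more distinct sequences).
#' Proteins sharing only some peptides, neither set subsuming the other,
#' remain separate identifications.
#'
#' @param observations filtered table from [filter_evidence()].
#' @param protein_seqs named character vector of (Met-trimmed) protein
#'   sequences covering every matched protein id.
#' @param validate check that every peptide is a substring of each matched
#'   protein's sequence (default `TRUE`).
#' @param il_equivalent treat isoleucine and leucine as equivalent during
#'   validation (default `FALSE`).
#' @return List of identifications; each is a list with
#'   `member_protein_ids`, `kind`, `peptide_set`, `n_distinct_sequences`.
#' @export
infer_identifications <- function(observations, protein_seqs,
                                  validate = TRUE, il_equivalent = FALSE) {
  if (nrow(observations) == 0L) return(list())
  long <- data.table(peptide = rep(observations$peptide_sequence,
                                   lengths(observations$protein_ids)),
                     protein = unlist(observations$protein_ids))
  long <- unique(long)
  miss <- setdiff(unique(long$protein), names(protein_seqs))
  if (length(miss))
    stop("no sequence for matched protein(s): ", paste(miss, collapse = ", "))
  if (validate) {
    canon <- function(x) if (il_equivalent) gsub("I", "L", x, fixed = TRUE)
                         else x
    ok <- mapply(function(p, pr)
      grepl(canon(p), canon(protein_seqs[[pr]]), fixed = TRUE),
      long$peptide, long$protein)
    if (!all(ok))
      stop("peptide not a substring of its matched protein: ",
           paste(unique(long$peptide[!ok]), collapse = ", "))
  }
  pepsets <- split(long$peptide, long$protein)
  pepsets <- lapply(pepsets, function(x) sort(unique(x)))
  prots <- names(pepsets)
  n <- length(prots)
  subsumed <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- pepsets[[i]]; b <- pepsets[[j]]
      if (length(a) < length(b) && all(a %in% b)) { subsumed[i] <- TRUE; break }
    }
  }
  prots <- prots[!subsumed]
  pepsets <- pepsets[!subsumed]
  key <- vapply(pepsets, paste, "", collapse = "\x01")
  groups <- split(prots, key)
  ## keep first-appearance order for reproducibility
  groups <- groups[unique(key)]
  lapply(groups, function(members) {
    seqs <- unique(unname(protein_seqs[members]))
    kind <- if (length(members) == 1L) "unique"
            else if (length(seqs) == 1L) "group_identical"
            else "group_distinct"
    list(member_protein_ids = members, kind = kind,
         peptide_set = pepsets[[match(members[1L], prots)]],
         n_distinct_sequences = length(seqs))
  })
}

#' Minimum/maximum venom protein counts
#'
#' The conservative minimum assumes a single protein per identification; the
#' maximum counts every distinct member sequence of every identification.
#'
#' @param identifications list from [infer_identifications()].
#' @return List with `min_count`, `max_count` and `kinds`, a named integer
#'   tally over `unique` / `group_distinct` / `group_identical`.
#' @export
enumerate_counts <- function(identifications) {
  kinds <- vapply(identifications, `[[`, "", "kind")
  tally <- setNames(integer(3),
                    c("unique", "group_distinct", "group_identical"))
  tt <- table(kinds)
  tally[names(tt)] <- as.integer(tt)
  list(min_count = length(identifications),
       max_count = sum(vapply(identifications, `[[`, 0L,
                              "n_distinct_sequences")),
       kinds = tally)
}

#' Purge contaminant identifications
#'
#' Matches contaminant keywords against per-protein homology descriptions,
#' case-insensitively.  An identification is removed when every member
#' carries a contaminant label; mixed groups are retained with a
#' `contaminant_flag`.
#'
#' @param identifications list from [infer_identifications()].
#' @param protein_labels named character vector of homology descriptions
#'   (protein id -> label); missing or `NA` labels never match.
#' @param contaminant_labels keywords; default
#'   `c("keratin", "trypsin", "hemocyanin")`.
#' @return The purged identification list; surviving mixed groups carry
#'   `contaminant_flag = TRUE`.
#' @export
purge_contaminants <- function(identifications, protein_labels,
                               contaminant_labels = c("keratin", "trypsin",
                                                      "hemocyanin")) {
  if (length(contaminant_labels) == 0L) return(identifications)
  pat <- paste(tolower(contaminant_labels), collapse = "|")
  is_contam <- function(id) {
    lab <- protein_labels[id]
    !is.na(lab) & grepl(pat, tolower(lab))
  }
  out <- list()
  for (ident in identifications) {
    hit <- is_contam(ident$member_protein_ids)
    if (all(hit)) next
    if (any(hit)) ident$contaminant_flag <- TRUE
    out[[length(out) + 1L]] <- ident
  }
  out
}

#' Per-gene venom contribution summary
#'
#' For each gene locus: the number of transcripts, the number of distinct
#' predicted proteins, the number unambiguously identified in venom (one per
#' identification whose members all belong to the gene: each such
#' identification guarantees at least one of the gene's proteins is present),
#' and the number possibly in venom (distinct member sequences of the gene
#' across all identifications).
#'
#' @param loci list of `GeneLocus` objects.
#' @param proteins named list of Met-trimmed `PredictedProtein` objects keyed
#'   by transcript id (protein ids are transcript ids).
#' @param identifications list from [infer_identifications()].
#' @return A `data.table` with columns `gene_id`, `n_transcripts`,
#'   `n_distinct_proteins`, `n_unambiguously_in_venom`,
#'   `n_possibly_in_venom`.
#' @export
gene_contribution_summary <- function(loci, proteins, identifications) {
  tx2gene <- unlist(lapply(loci, function(locus)
    setNames(rep(locus$gene_id, length(locus$transcripts)),
             names(locus$transcripts))))
  all_members <- unique(unlist(lapply(identifications, `[[`,
                                      "member_protein_ids")))
  dangling <- setdiff(all_members, names(proteins))
  if (length(dangling))
    stop("identification member(s) with no predicted protein: ",
         paste(dangling, collapse = ", "))
  dangling <- setdiff(names(proteins), names(tx2gene))
  if (length(dangling))
    stop("protein(s) on transcripts absent from the annotation: ",
         paste(dangling, collapse = ", "))
  seq_of <- vapply(proteins, `[[`, "", "met_trimmed")
  rows <- lapply(loci, function(locus) {
    g <- locus$gene_id
    txs <- names(locus$transcripts)
    gseqs <- seq_of[intersect(txs, names(seq_of))]
    ## Met-less predictions (NA) each count as their own distinct protein
    n_distinct <- length(unique(gseqs[!is.na(gseqs)])) + sum(is.na(gseqs))
    unamb <- 0L
    poss_seqs <- character(0)
    for (ident in identifications) {
      members <- ident$member_protein_ids
      in_gene <- tx2gene[members] == g
      if (!any(in_gene)) next
      if (all(in_gene)) unamb <- unamb + 1L
      poss_seqs <- union(poss_seqs, unname(seq_of[members[in_gene]]))
    }
    data.table(gene_id = g, n_transcripts = length(txs),
               n_distinct_proteins = n_distinct,
               n_unambiguously_in_venom = unamb,
               n_possibly_in_venom = length(poss_seqs))
  })
  rbindlist(rows)
}
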