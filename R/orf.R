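## ORF-based protein prediction: one protein per transcript.
##
## ORFs are maximal stop-free stretches in the three sense frames (stop-to-stop
## or running to the transcript end), not ATG-anchored; predictions are trimmed
## to the first methionine afterwards, so a prediction may begin upstream of
## Met.  Codons containing N translate to X and do not terminate an ORF.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Find open reading frames in a transcript sequence
#'
#' Scans the three sense frames for maximal stop-free codon stretches ending
#' at a stop codon or at the transcript end, and returns those whose
#' nucleotide length (excluding the stop) is at least `min_nt`.  The default
#' `min_nt = 91` implements a strictly-greater-than-90-nt rule.
#'
#' @param tx_seq nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param min_nt minimum ORF length in nucleotides (inclusive).
#' @return A `data.table` with columns `frame` (0, 1, 2), `start`, `end`
#'   (0-based half-open transcript coordinates of the stop-free stretch,
#'   stop codon excluded), `aa_sequence`.  Empty for an empty sequence.
#' @export
find_orfs <- function(tx_seq, min_nt = 91L) {
  empty <- data.table(frame = integer(0), start = integer(0),
                      end = integer(0), aa_sequence = character(0))
  tx_seq <- toupper(tx_seq)
  n <- nchar(tx_seq)
  if (n == 0L) return(empty)
  if (grepl("[^ACGTN]", tx_seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  out <- list()
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    if (f + 3L > n) next
    codons <- substring(tx_seq, starts, starts + 2L)
    is_stop <- codons %in% .STOP_CODONS
    aa <- .translate_codons(codons)
    ## runs of non-stop codons, each terminated by a stop or the sequence end
    run_id <- cumsum(is_stop)
    for (r in unique(run_id[!is_stop])) {
      idx <- which(run_id == r & !is_stop)
      if (3L * length(idx) < min_nt) next
      out[[length(out) + 1L]] <- data.table(
        frame = f,
        start = f + 3L * (idx[1L] - 1L),
        end = f + 3L * idx[length(idx)],
        aa_sequence = paste(aa[idx], collapse = ""))
    }
  }
  if (length(out) == 0L) return(empty)
  res <- rbindlist(out)
  setorder(res, frame, start)
  res[]
}

#' Select one protein prediction per transcript
#'
#' Applies the homology-guided rule: with a homology hit, the longest ORF in
#' the hit's reading frame (ties broken by smallest start); without a hit (or
#' with no ORF in the hit frame), the longest ORF over all frames (ties by
#' smallest frame, then smallest start).
#'
#' @param orfs ORF table from [find_orfs()]; must be non-empty.
#' @param hit optional list/row with a `frame` element in `{0,1,2}` (e.g. one
#'   row of a homology-hit table), or `NULL`.
#' @param transcript_id recorded on the result.
#' @return A `PredictedProtein`: list with `transcript_id`, `full_sequence`,
#'   `met_trimmed` (`NA` until [trim_to_met()]), `selection_basis`
#'   (`"hit_frame"` or `"longest_overall"`), `frame`, `start`, `end`.
#' @export
select_protein <- function(orfs, hit = NULL, transcript_id = NA_character_) {
  if (is.null(orfs) || nrow(orfs) == 0L)
    stop("no ORF predicted for transcript ", transcript_id)
  basis <- "longest_overall"
  cand <- orfs
  if (!is.null(hit)) {
    in_frame <- orfs[orfs$frame == hit$frame, ]
    if (nrow(in_frame) > 0L) {
      cand <- in_frame
      basis <- "hit_frame"
    }
  }
  len <- nchar(cand$aa_sequence)
  best <- cand[order(-len, cand$frame, cand$start), ][1L, ]
  structure(list(transcript_id = transcript_id,
                 full_sequence = best$aa_sequence,
                 met_trimmed = NA_character_,
                 selection_basis = basis,
                 frame = best$frame, start = best$start, end = best$end),
            class = "PredictedProtein")
}

#' Trim a predicted protein to its first methionine
#'
#' Sets `met_trimmed` to the suffix of the full sequence starting at the first
#' `M`.  Proteins without a methionine keep `met_trimmed = NA` and are flagged
#' (`no_met = TRUE`); they are treated as singletons downstream.
#'
#' @param p a `PredictedProtein` from [select_protein()].
#' @return The protein with `met_trimmed` (and `no_met`) set; idempotent.
#' @export
trim_to_met <- function(p) {
  stopifnot(nzchar(p$full_sequence))
  pos <- regexpr("M", p$full_sequence, fixed = TRUE)
  if (pos == -1L) {
    p$met_trimmed <- NA_character_
    p$no_met <- TRUE
  } else {
    p$met_trimmed <- substring(p$full_sequence, pos)
    p$no_met <- FALSE
  }
  p
}

#' Predict the protein of a single transcript
#'
#' Convenience wrapper: [find_orfs()] then [select_protein()] then
#' [trim_to_met()].
#'
#' @inheritParams find_orfs
#' @inheritParams select_protein
#' @return A Met-trimmed `PredictedProtein`.
#' @export
predict_protein <- function(tx_seq, hit = NULL,
                            transcript_id = NA_character_, min_nt = 91L) {
  trim_to_met(select_protein(find_orfs(tx_seq, min_nt), hit, transcript_id))
}

#' Collapse transcripts with 100%-identical predicted proteins
#'
#' Partitions predictions by exact string equality of the Met-trimmed
#' sequence.  Flagged Met-less proteins form singleton clusters.
#'
#' @param proteins list of Met-trimmed `PredictedProtein` objects.
#' @return A `data.table` with columns `cluster` (integer id), `sequence`
#'   (`NA` for Met-less singletons), `transcript_id`; the number of distinct
#'   proteins equals `length(unique(cluster))`.
#' @export
deduplicate_proteins <- function(proteins) {
  if (length(proteins) == 0L)
    return(data.table(cluster = integer(0), sequence = character(0),
                      transcript_id = character(0)))
  dt <- data.table(
    transcript_id = vapply(proteins, `[[`, "", "transcript_id"),
    sequence = vapply(proteins, `[[`, "", "met_trimmed"))
  key <- ifelse(is.na(dt$sequence),
                paste0("\x01no_met\x01", dt$transcript_id), dt$sequence)
  dt[, cluster := as.integer(factor(key, levels = unique(key)))]
  setorder(dt, cluster)
  dt[, .(cluster, sequence, transcript_id)]
}

## ---- homology hits and FASTA plumbing --------------------------------------

#' Read a homology-hit table
#'
#' Tab-separated with header columns `transcript_id`, `subject`, `e_value`,
#' `frame` (0/1/2).
#'
#' @param path file path.
#' @return A `data.table` of hits.
#' @export
read_homology_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("transcript_id", "subject", "e_value", "frame")
  if (!all(need %in% names(dt)))
    stop("homology table must have columns: ", paste(need, collapse = ", "))
  if (any(dt$e_value <= 0)) stop("e_value must be positive")
  if (!all(dt$frame %in% 0:2)) stop("frame must be 0, 1 or 2")
  dt[]
}

#' Best hit per transcript
#'
#' Smallest e-value wins; ties are broken by input order.
#'
#' @param hits table from [read_homology_table()].
#' @return A `data.table` with one row per transcript id present.
#' @export
best_hits <- function(hits) {
  hits <- copy(hits)[, .row := .I]
  setorder(hits, transcript_id, e_value, .row)
  out <- hits[!duplicated(transcript_id)]
  out[, .row := NULL]
  out[]
}

#' Predict proteins for a set of transcripts
#'
#' Runs the full per-transcript rule over a named vector of transcript
#' sequences, using the best homology hit (when present) to pick the reading
#' frame.
#'
#' @param tx_seqs named character vector of nucleotide sequences, keyed by
#'   transcript id.
#' @param hits optional homology-hit table (see [read_homology_table()]).
#' @param min_nt minimum ORF length in nucleotides.
#' @return Named list of `PredictedProtein` objects; transcripts with no ORF
#'   of sufficient length are dropped with a warning naming them.
#' @export
predict_proteins <- function(tx_seqs, hits = NULL, min_nt = 91L) {
  best <- if (!is.null(hits) && nrow(hits) > 0L) best_hits(hits) else NULL
  out <- list()
  none <- character(0)
  for (tid in names(tx_seqs)) {
    orfs <- find_orfs(tx_seqs[[tid]], min_nt)
    if (nrow(orfs) == 0L) { none <- c(none, tid); next }
    hit <- if (!is.null(best) && tid %in% best$transcript_id)
      as.list(best[best$transcript_id == tid, ][1L, ]) else NULL
    out[[tid]] <- trim_to_met(select_protein(orfs, hit, tid))
  }
  if (length(none))
    warning("no ORF >= ", min_nt, " nt for transcript(s): ",
            paste(none, collapse = ", "))
  out
}

#' Read transcript sequences from FASTA
#' @param path FASTA file path.
#' @return Named character vector keyed by the first word of each header.
#' @export
read_transcript_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write predicted proteins to FASTA
#'
#' Met-trimmed sequences are written; Met-less predictions are skipped.
#'
#' @param proteins list of `PredictedProtein` objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  seqs <- vapply(proteins, `[[`, "", "met_trimmed")
  ids <- vapply(proteins, `[[`, "", "transcript_id")
  keep <- !is.na(seqs)
  ss <- Biostrings::AAStringSet(setNames(seqs[keep], ids[keep]))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
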