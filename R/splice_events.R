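## Pairwise alternative-transcription event classification.
##
## Seven-class vocabulary: A5SS, A3SS, EXON_SKIP, MXE, AFE, ALE,
## INTRON_RETENTION.  All comparisons are exact on coordinates (no fuzz
## window): assembled transcript models share coordinates when they share
## junctions.  "First"/"last" are in transcription order, so strand-aware.

#' Event label vocabulary
#' @export
EVENT_LABELS <- c("A5SS", "A3SS", "EXON_SKIP", "MXE", "AFE", "ALE",
                  "INTRON_RETENTION")

.empty_events <- function() {
  data.table(label = character(0), gene_id = character(0),
             transcript_a = character(0), transcript_b = character(0),
             witness = character(0), chrom = character(0),
             strand = character(0))
}

## transcription-order helpers (exons are sorted genomically)
.first_exon <- function(tx) {
  i <- if (tx$strand == "+") 1L else nrow(tx$exons)
  tx$exons[i, ]
}
.last_exon <- function(tx) {
  i <- if (tx$strand == "+") nrow(tx$exons) else 1L
  tx$exons[i, ]
}
.first_intron <- function(tx) {
  ii <- introns(tx)
  if (nrow(ii) == 0L) return(NULL)
  ii[if (tx$strand == "+") 1L else nrow(ii), ]
}
.last_intron <- function(tx) {
  ii <- introns(tx)
  if (nrow(ii) == 0L) return(NULL)
  ii[if (tx$strand == "+") nrow(ii) else 1L, ]
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

#' Classify alternative-transcription events between two transcripts
#'
#' Compares the exon chains of two transcript models from the same locus
#' (same chrom and strand) and returns every witnessed event:
#' \describe{
#'   \item{EXON_SKIP}{an internal exon of one transcript lies inside an intron
#'     of the other whose boundaries match the flanking junctions.}
#'   \item{MXE}{two non-overlapping internal exons, one per transcript, inside
#'     the same pair of shared flanking junctions.}
#'   \item{A5SS / A3SS}{two introns share their acceptor (resp. donor)
#'     boundary but differ at the donor (resp. acceptor).}
#'   \item{INTRON_RETENTION}{an intron of one transcript is contained within
#'     an exon of the other and both flanking exon boundaries coincide.}
#'   \item{AFE / ALE}{the transcripts' first (resp. last) exons in
#'     transcription order do not overlap and each splices into a shared
#'     downstream acceptor (resp. from a shared upstream donor).}
#' }
#' Terminal-exon differences witnessing AFE/ALE are not additionally reported
#' as A5SS/A3SS at the same coordinates; otherwise a pair may witness several
#' labels at once.  The result is symmetric in its arguments.
#'
#' @param a,b `TranscriptModel` objects sharing chrom and strand, with
#'   different transcript ids.
#' @return A `data.table` with columns `label`, `gene_id`, `transcript_a`,
#'   `transcript_b`, `witness`, `chrom`, `strand`; zero rows when the chains
#'   witness no event (e.g. identical transcripts).
#' @export
classify_pair <- function(a, b) {
  if (!identical(a$chrom, b$chrom) || !identical(a$strand, b$strand))
    stop("transcripts ", a$transcript_id, " and ", b$transcript_id,
         " are not on the same chrom/strand")
  if (identical(a$transcript_id, b$transcript_id))
    stop("classify_pair needs two distinct transcripts")
  chrom <- a$chrom; strand <- a$strand
  ids <- sort(c(a$transcript_id, b$transcript_id))
  plus <- strand == "+"
  out <- list()
  emit <- function(label, witness)
    out[[length(out) + 1L]] <<- data.table(
      label = label, gene_id = a$gene_id, transcript_a = ids[1L],
      transcript_b = ids[2L], witness = witness, chrom = chrom,
      strand = strand)

  ia <- introns(a); ib <- introns(b)
  exa <- a$exons; exb <- b$exons

  ## ---- EXON_SKIP & MXE (genomically strand-invariant) ----
  both <- list(list(t1 = a, t2 = b), list(t1 = b, t2 = a))
  for (d in both) {
    ex1 <- d$t1$exons; in2 <- introns(d$t2)
    n1 <- nrow(ex1)
    if (n1 >= 3L && nrow(in2) > 0L) {
      for (i in 2:(n1 - 1L)) {
        L <- ex1[i - 1L, "end"]; R <- ex1[i + 1L, "start"]
        if (any(in2[, "start"] == L & in2[, "end"] == R))
          emit("EXON_SKIP",
               sprintf("%s:%d-%d", chrom, ex1[i, "start"], ex1[i, "end"]))
      }
    }
  }
  na <- nrow(exa); nb <- nrow(exb)
  if (na >= 3L && nb >= 3L) {
    for (i in 2:(na - 1L)) {
      for (j in 2:(nb - 1L)) {
        x <- exa[i, ]; y <- exb[j, ]
        if (.overlaps(x["start"], x["end"], y["start"], y["end"])) next
        if (exa[i - 1L, "end"] == exb[j - 1L, "end"] &&
            exa[i + 1L, "start"] == exb[j + 1L, "start"]) {
          pair <- rbind(x, y)
          pair <- pair[order(pair[, "start"]), ]
          emit("MXE", sprintf("%s:%d-%d|%d-%d", chrom,
                              pair[1L, "start"], pair[1L, "end"],
                              pair[2L, "start"], pair[2L, "end"]))
        }
      }
    }
  }

  ## ---- AFE / ALE ----
  afe <- ale <- FALSE
  fia <- .first_intron(a); fib <- .first_intron(b)
  if (!is.null(fia) && !is.null(fib)) {
    fa <- .first_exon(a); fb <- .first_exon(b)
    shared_acc <- if (plus) fia["end"] == fib["end"]
                  else fia["start"] == fib["start"]
    if (shared_acc && !.overlaps(fa["start"], fa["end"],
                                 fb["start"], fb["end"])) {
      afe <- TRUE
      pair <- rbind(fa, fb); pair <- pair[order(pair[, "start"]), ]
      emit("AFE", sprintf("%s:%d-%d|%d-%d", chrom,
                          pair[1L, "start"], pair[1L, "end"],
                          pair[2L, "start"], pair[2L, "end"]))
    }
  }
  lia <- .last_intron(a); lib <- .last_intron(b)
  if (!is.null(lia) && !is.null(lib)) {
    la <- .last_exon(a); lb <- .last_exon(b)
    shared_don <- if (plus) lia["start"] == lib["start"]
                  else lia["end"] == lib["end"]
    if (shared_don && !.overlaps(la["start"], la["end"],
                                 lb["start"], lb["end"])) {
      ale <- TRUE
      pair <- rbind(la, lb); pair <- pair[order(pair[, "start"]), ]
      emit("ALE", sprintf("%s:%d-%d|%d-%d", chrom,
                          pair[1L, "start"], pair[1L, "end"],
                          pair[2L, "start"], pair[2L, "end"]))
    }
  }

  ## ---- A5SS / A3SS ----
  ## donor = 5' intron boundary in transcription order, acceptor = 3'.  The
  ## exons flanking the differing boundary must overlap: this keeps the event
  ## a splice-site choice within a common exon, and stops exon-skipping and
  ## alternative-first/last-exon pairs (whose introns also share one
  ## boundary) from being double-reported at the same coordinates.
  if (nrow(ia) > 0L && nrow(ib) > 0L) {
    for (i in seq_len(nrow(ia))) {
      for (j in seq_len(nrow(ib))) {
        ja <- ia[i, ]; jb <- ib[j, ]
        same_start <- ja["start"] == jb["start"]
        same_end <- ja["end"] == jb["end"]
        if (same_start == same_end) next
        ## shared acceptor + differing donor -> A5SS; mirror -> A3SS
        label <- if (plus) {
          if (same_end) "A5SS" else "A3SS"
        } else {
          if (same_start) "A5SS" else "A3SS"
        }
        ## exons carrying the differing boundary: left of the introns when
        ## they differ at start, right when they differ at end
        fx_a <- if (same_end) exa[i, ] else exa[i + 1L, ]
        fx_b <- if (same_end) exb[j, ] else exb[j + 1L, ]
        if (!.overlaps(fx_a["start"], fx_a["end"],
                       fx_b["start"], fx_b["end"])) next
        shared <- if (same_end) ja["end"] else ja["start"]
        diffs <- sort(if (same_end) c(ja["start"], jb["start"])
                      else c(ja["end"], jb["end"]))
        emit(label, sprintf("%s:%d|%d/%d", chrom, shared,
                            diffs[1L], diffs[2L]))
      }
    }
  }

  ## ---- INTRON_RETENTION ----
  for (d in both) {
    ex1 <- d$t1$exons; in1 <- introns(d$t1); ex2 <- d$t2$exons
    if (nrow(in1) == 0L) next
    for (i in seq_len(nrow(in1))) {
      ls <- ex1[i, "start"]; re <- ex1[i + 1L, "end"]
      if (any(ex2[, "start"] == ls & ex2[, "end"] == re))
        emit("INTRON_RETENTION",
             sprintf("%s:%d-%d", chrom, in1[i, "start"], in1[i, "end"]))
    }
  }

  if (length(out) == 0L) return(.empty_events())
  unique(rbindlist(out))
}

#' Summarize events across all transcript pairs of a locus
#'
#' Runs [classify_pair()] over every unordered pair of transcripts at the
#' locus and deduplicates by `(label, witness)`, so an event witnessed by
#' several transcript pairs is counted once per locus.
#'
#' @param locus a `GeneLocus`.
#' @return Event `data.table` as from [classify_pair()], one row per distinct
#'   `(label, witness)`; the `transcript_a`/`transcript_b` columns keep the
#'   first witnessing pair.  Zero rows for a single-transcript locus.
#' @export
locus_event_summary <- function(locus) {
  txs <- locus$transcripts
  if (length(txs) < 2L) return(.empty_events())
  out <- list()
  for (i in seq_len(length(txs) - 1L))
    for (j in (i + 1L):length(txs))
      out[[length(out) + 1L]] <- classify_pair(txs[[i]], txs[[j]])
  ev <- rbindlist(out)
  if (nrow(ev) == 0L) return(.empty_events())
  ev[!duplicated(ev[, .(label, witness)])]
}

#' Event-class frequency table
#'
#' Aggregates per-locus deduplicated events over a list of loci and reports,
#' for each of the seven labels, the count and its percentage of all events
#' (rounded half-up to one decimal).
#'
#' @param loci list of `GeneLocus` objects.
#' @return A `data.table` with columns `label`, `count`, `percent`.  With zero
#'   events all percents are reported as 0.0 and the attribute `no_events` is
#'   set to `TRUE`.
#' @export
event_frequency_table <- function(loci) {
  ev <- rbindlist(lapply(loci, locus_event_summary))
  counts <- if (nrow(ev) == 0L) integer(0) else table(ev$label)
  n <- setNames(integer(length(EVENT_LABELS)), EVENT_LABELS)
  n[names(counts)] <- as.integer(counts)
  total <- sum(n)
  tab <- data.table(label = EVENT_LABELS, count = as.integer(n))
  if (total == 0L) {
    tab[, percent := 0.0]
    setattr(tab, "no_events", TRUE)
  } else {
    tab[, percent := .round1(100 * count / total)]
    setattr(tab, "no_events", FALSE)
  }
  tab[]
}

## round half-up to 1 decimal (matches printed-percentage convention)
.round1 <- function(x) floor(x * 10 + 0.5) / 10
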