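## Transcript-model containers and locus-level bookkeeping.
##
## Coordinates are stored 0-based half-open internally; GTF files are read as
## 1-based inclusive and written back in that convention.

#' Construct a transcript model
#'
#' A `TranscriptModel` is a stranded chain of non-overlapping exons on a single
#' sequence region, belonging to one gene.  Exon coordinates use the internal
#' 0-based half-open convention; exons are sorted by position on construction.
#'
#' @param transcript_id,gene_id character scalars.
#' @param chrom sequence region name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column numeric matrix (or data.frame) of `start`, `end`
#'   half-open intervals; rows may be unsorted.
#' @param source `"reference"` or `"novel"`.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             source = "novel") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  if (!source %in% c("reference", "novel"))
    stop("source must be 'reference' or 'novel'")
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("empty or inverted exon interval in transcript ", transcript_id)
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
    stop("overlapping exons in transcript ", transcript_id)
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, source = source),
    class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s%s, %d exon(s), span %d-%d\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$exons[1L, "start"], x$exons[nrow(x$exons), "end"]))
  invisible(x)
}

#' Introns of a transcript model
#'
#' Gaps between consecutive exons, half-open on the same strand/chrom as the
#' transcript.  Single-exon transcripts have no introns.
#'
#' @param tx a `TranscriptModel`.
#' @return Integer matrix with columns `start`, `end` (0 rows if none).
#' @export
introns <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-n, "end"], end = ex[-1L, "start"])
}

#' Construct a gene locus
#'
#' A `GeneLocus` groups the transcript models sharing one `gene_id`; it is the
#' unit of splice-event classification and per-gene protein summaries.
#'
#' @param gene_id character scalar.
#' @param transcripts list of `TranscriptModel` objects carrying this gene id.
#' @param homology_label optional best-hit description (e.g. "latrotoxin").
#' @return An object of class `GeneLocus`.
#' @export
gene_locus <- function(gene_id, transcripts, homology_label = NA_character_) {
  if (length(transcripts) < 1L) stop("a locus needs at least one transcript")
  ok <- vapply(transcripts, function(t) identical(t$gene_id, gene_id),
               logical(1))
  if (!all(ok))
    stop("transcript(s) ",
         paste(vapply(transcripts[!ok], `[[`, "", "transcript_id"),
               collapse = ", "),
         " do not carry gene_id ", gene_id)
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gene_id, transcripts = transcripts,
                 homology_label = homology_label),
            class = "GeneLocus")
}

#' @export
print.GeneLocus <- function(x, ...) {
  cat(sprintf("GeneLocus %s: %d transcript(s)%s\n", x$gene_id,
              length(x$transcripts),
              if (is.na(x$homology_label)) "" else
                paste0(" [", x$homology_label, "]")))
  invisible(x)
}

## ---- GTF I/O ---------------------------------------------------------------

.parse_gtf_attr <- function(attr, key) {
  pat <- paste0(key, '\\s+"([^"]*)"')
  m <- regexpr(pat, attr)
  out <- rep(NA_character_, length(attr))
  out[m != -1L] <- sub(pat, "\\1", regmatches(attr, m))
  out
}

#' Read a GTF annotation into gene loci
#'
#' Reads exon records from a GTF file (1-based inclusive coordinates),
#' converts them to the internal 0-based half-open convention, and assembles
#' one `TranscriptModel` per `transcript_id` grouped into `GeneLocus` objects
#' by `gene_id`.  Feature types other than `exon` are ignored.
#'
#' @param path GTF file path.
#' @param source value recorded on every transcript (`"reference"` or
#'   `"novel"`); the GTF source column is not interpreted.
#' @return Named list of `GeneLocus` objects (names are gene ids), ordered by
#'   first appearance in the file.
#' @export
read_annotation <- function(path, source = "novel") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop("malformed GTF record at line ", lineno[bad[1L]],
         ": expected 9 tab-separated fields, found ",
         length(fields[[bad[1L]]]))
  dt <- data.table(
    chrom   = vapply(fields, `[[`, "", 1L),
    feature = vapply(fields, `[[`, "", 3L),
    start   = suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L))),
    end     = suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L))),
    strand  = vapply(fields, `[[`, "", 7L),
    attr    = vapply(fields, `[[`, "", 9L),
    line    = lineno)
  dt <- dt[feature == "exon"]
  if (nrow(dt) == 0L) return(structure(list(), names = character(0)))
  if (anyNA(dt$start) || anyNA(dt$end))
    stop("malformed GTF record at line ",
         dt$line[which(is.na(dt$start) | is.na(dt$end))[1L]],
         ": non-integer coordinates")
  dt[, gene_id := .parse_gtf_attr(attr, "gene_id")]
  dt[, transcript_id := .parse_gtf_attr(attr, "transcript_id")]
  if (anyNA(dt$gene_id) || anyNA(dt$transcript_id))
    stop("malformed GTF record at line ",
         dt$line[which(is.na(dt$gene_id) | is.na(dt$transcript_id))[1L]],
         ": missing gene_id or transcript_id attribute")
  ## GTF 1-based inclusive -> 0-based half-open
  dt[, start := start - 1L]
  bad <- which(dt$end <= dt$start)
  if (length(bad))
    stop("empty exon interval at line ", dt$line[bad[1L]])

  loci <- list()
  for (g in unique(dt$gene_id)) {
    gdt <- dt[gene_id == g]
    txs <- lapply(unique(gdt$transcript_id), function(tid) {
      tdt <- gdt[transcript_id == tid]
      if (length(unique(tdt$chrom)) > 1L || length(unique(tdt$strand)) > 1L)
        stop("transcript ", tid, " has exons on mixed chrom/strand ",
             "(line ", tdt$line[1L], ")")
      transcript_model(tid, g, tdt$chrom[1L], tdt$strand[1L],
                       cbind(tdt$start, tdt$end), source = source)
    })
    loci[[g]] <- gene_locus(g, txs)
  }
  loci
}

#' Write gene loci to a GTF file
#'
#' Emits one `transcript` record and per-exon `exon` records per transcript,
#' restoring the 1-based inclusive GTF convention.  [read_annotation()] on the
#' output reproduces the locus/transcript/exon sets exactly.
#'
#' @param loci list of `GeneLocus` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(loci, path) {
  rows <- character(0)
  for (locus in loci) {
    for (tx in locus$transcripts) {
      attr9 <- sprintf('gene_id "%s"; transcript_id "%s";',
                       locus$gene_id, tx$transcript_id)
      ex <- tx$exons
      rows <- c(rows,
        sprintf("%s\tvenomalt\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                tx$chrom, ex[1L, "start"] + 1L, ex[nrow(ex), "end"],
                tx$strand, attr9),
        sprintf("%s\tvenomalt\texon\t%d\t%d\t.\t%s\t.\t%s",
                tx$chrom, ex[, "start"] + 1L, ex[, "end"], tx$strand, attr9))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

## ---- locus-level operations ------------------------------------------------

.loci_exon_granges <- function(loci) {
  dt <- rbindlist(lapply(loci, function(locus)
    rbindlist(lapply(locus$transcripts, function(tx)
      data.table(gene = locus$gene_id, chrom = tx$chrom,
                 start = tx$exons[, "start"], end = tx$exons[, "end"])))))
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(dt$start + 1L, dt$end),
                         gene = dt$gene)
}

#' Classify query loci as novel intergenic
#'
#' A query locus is `novel_intergenic` when none of its exons overlaps any
#' exon of the reference annotation on either strand (the merged-annotation
#' "class code u"); every other locus is `other`.
#'
#' @param query,reference lists of `GeneLocus` objects on the same coordinate
#'   system.
#' @return Named character vector over `query` gene ids with values
#'   `"novel_intergenic"` or `"other"`.  An empty reference makes every query
#'   locus novel intergenic.
#' @export
classify_novel_intergenic <- function(query, reference) {
  qids <- vapply(query, `[[`, "", "gene_id")
  if (length(reference) == 0L)
    return(setNames(rep("novel_intergenic", length(query)), qids))
  qgr <- .loci_exon_granges(query)
  rgr <- .loci_exon_granges(reference)
  ## disjoint seqlevel sets are a legitimate no-overlap case, not a warning
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(qgr, rgr, ignore.strand = TRUE) > 0)
  hit_genes <- unique(qgr$gene[hits])
  setNames(ifelse(qids %in% hit_genes, "other", "novel_intergenic"), qids)
}

#' Census of single- versus multiple-transcript genes
#'
#' @param loci list of `GeneLocus` objects.
#' @return Named integer vector `c(n_single =, n_multi =)`; a locus is multi
#'   when it carries two or more transcripts.
#' @export
multi_transcript_census <- function(loci) {
  n_tx <- vapply(loci, function(locus) length(locus$transcripts), integer(1))
  c(n_single = sum(n_tx == 1L), n_multi = sum(n_tx >= 2L))
}

#' Read a splice-junction support table
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `strand`,
#' `unique_read_count`; coordinates must already use the internal half-open
#' convention of the annotation after conversion.
#'
#' @param path file path.
#' @return A `data.table` of junction support records.
#' @export
read_junction_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "start", "end", "strand", "unique_read_count")
  if (!all(need %in% names(dt)))
    stop("junction table must have columns: ", paste(need, collapse = ", "))
  dt[, `:=`(chrom = as.character(chrom), strand = as.character(strand),
            start = as.integer(start), end = as.integer(end),
            unique_read_count = as.integer(unique_read_count))]
  if (any(dt$unique_read_count < 0)) stop("negative junction read count")
  dt[]
}

#' Attach junction read support to a locus
#'
#' Maps every intron of every transcript at the locus to its supporting
#' spliced-read count; introns absent from the table map to 0.  Junctions are
#' keyed on (chrom, start, end); strand is checked only when the table carries
#' one (a `"."` strand matches either).
#'
#' @param locus a `GeneLocus`.
#' @param table junction support table as from [read_junction_table()].
#' @return A `data.table` with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `read_count`, one row per intron occurrence.
#' @export
attach_junction_support <- function(locus, table) {
  intr <- rbindlist(lapply(locus$transcripts, function(tx) {
    ii <- introns(tx)
    if (nrow(ii) == 0L) return(NULL)
    data.table(transcript_id = tx$transcript_id, chrom = tx$chrom,
               start = ii[, "start"], end = ii[, "end"], strand = tx$strand)
  }))
  if (is.null(intr) || nrow(intr) == 0L)
    return(data.table(transcript_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), read_count = integer(0)))
  intr[, read_count := 0L]
  if (!is.null(table) && nrow(table) > 0L) {
    for (i in seq_len(nrow(intr))) {
      hit <- table$chrom == intr$chrom[i] &
        table$start == intr$start[i] & table$end == intr$end[i] &
        (table$strand == "." | table$strand == intr$strand[i])
      if (any(hit)) intr[i, read_count := table$unique_read_count[which(hit)[1L]]]
    }
  }
  intr[]
}
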