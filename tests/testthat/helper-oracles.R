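# independent brute-force oracles, written directly from the definitions and
# deliberately structured differently from the implementation (transcription
# coordinate space; explicit scans)

# multiset of event labels for a transcript pair
oracle_event_labels <- function(a, b) {
  stopifnot(a$strand == b$strand, a$chrom == b$chrom)
  to_t <- function(tx) {                 # map to transcription coordinates
    ex <- tx$exons
    if (tx$strand == "-")
      ex <- cbind(-ex[, 2L], -ex[, 1L])[rev(seq_len(nrow(ex))), ,
                                        drop = FALSE]
    unname(ex)
  }
  A <- to_t(a); B <- to_t(b)
  intr <- function(E) {
    if (nrow(E) < 2L) return(matrix(numeric(0), ncol = 2L))
    cbind(E[-nrow(E), 2L], E[-1L, 1L])
  }
  IA <- intr(A); IB <- intr(B)
  ov <- function(x, y) x[1L] < y[2L] && y[1L] < x[2L]
  labs <- character(0)

  skip_count <- function(E1, I2) {
    cnt <- 0L
    if (nrow(E1) >= 3L && nrow(I2) > 0L)
      for (i in 2:(nrow(E1) - 1L))
        if (any(I2[, 1L] == E1[i - 1L, 2L] & I2[, 2L] == E1[i + 1L, 1L]))
          cnt <- cnt + 1L
    cnt
  }
  labs <- c(labs, rep("EXON_SKIP", skip_count(A, IB) + skip_count(B, IA)))

  if (nrow(A) >= 3L && nrow(B) >= 3L)
    for (i in 2:(nrow(A) - 1L))
      for (j in 2:(nrow(B) - 1L))
        if (!ov(A[i, ], B[j, ]) &&
            A[i - 1L, 2L] == B[j - 1L, 2L] &&
            A[i + 1L, 1L] == B[j + 1L, 1L])
          labs <- c(labs, "MXE")

  if (nrow(IA) > 0L && nrow(IB) > 0L) {
    for (i in seq_len(nrow(IA)))
      for (j in seq_len(nrow(IB))) {
        ja <- IA[i, ]; jb <- IB[j, ]
        if (ja[2L] == jb[2L] && ja[1L] != jb[1L] && ov(A[i, ], B[j, ]))
          labs <- c(labs, "A5SS")
        if (ja[1L] == jb[1L] && ja[2L] != jb[2L] &&
            ov(A[i + 1L, ], B[j + 1L, ]))
          labs <- c(labs, "A3SS")
      }
    if (IA[1L, 2L] == IB[1L, 2L] && !ov(A[1L, ], B[1L, ]))
      labs <- c(labs, "AFE")
    if (IA[nrow(IA), 1L] == IB[nrow(IB), 1L] &&
        !ov(A[nrow(A), ], B[nrow(B), ]))
      labs <- c(labs, "ALE")
  }

  ir_count <- function(E1, I1, E2) {
    cnt <- 0L
    if (nrow(I1) > 0L)
      for (i in seq_len(nrow(I1)))
        if (any(E2[, 1L] == E1[i, 1L] & E2[, 2L] == E1[i + 1L, 2L]))
          cnt <- cnt + 1L
    cnt
  }
  labs <- c(labs, rep("INTRON_RETENTION",
                      ir_count(A, IA, B) + ir_count(B, IB, A)))
  sort(labs)
}

# exhaustive per-frame codon walk
oracle_orfs <- function(seq, min_nt = 91L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (f in 0:2) {
    i <- f + 1L
    aa <- character(0)
    run_start <- i
    flush <- function(end_pos) {
      if (3L * length(aa) >= min_nt)
        rows[[length(rows) + 1L]] <<- data.table::data.table(
          frame = f, start = run_start - 1L, end = end_pos - 1L,
          aa_sequence = paste(aa, collapse = ""))
    }
    while (i + 2L <= n) {
      cod <- substr(seq, i, i + 2L)
      if (cod %in% stops) {
        flush(i)
        aa <- character(0)
        run_start <- i + 3L
      } else {
        r <- Biostrings::GENETIC_CODE[cod]
        aa <- c(aa, if (is.na(r)) "X" else unname(r))
      }
      i <- i + 3L
    }
    flush(i)
  }
  if (length(rows) == 0L)
    return(data.table::data.table(frame = integer(0), start = integer(0),
                                  end = integer(0),
                                  aa_sequence = character(0)))
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, frame, start)
  out[]
}

# parsimony inference by direct pairwise set comparison; returns the
# canonical partition: sorted list of sorted member vectors
oracle_infer_partition <- function(observations) {
  long <- unique(data.table::data.table(
    peptide = rep(observations$peptide_sequence,
                  lengths(observations$protein_ids)),
    protein = unlist(observations$protein_ids)))
  sets <- lapply(split(long$peptide, long$protein), function(x)
    sort(unique(x)))
  keep <- names(sets)
  for (p in names(sets))
    for (q in names(sets))
      if (p != q && length(sets[[p]]) < length(sets[[q]]) &&
          all(sets[[p]] %in% sets[[q]]))
        keep <- setdiff(keep, p)
  sets <- sets[keep]
  key <- vapply(sets, paste, "", collapse = "+")
  part <- lapply(split(names(sets), key), sort)
  unname(part[order(vapply(part, `[[`, "", 1L))])
}

canonical_partition <- function(identifications) {
  part <- lapply(identifications, function(x) sort(x$member_protein_ids))
  unname(part[order(vapply(part, `[[`, "", 1L))])
}
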