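## Seeded synthetic fixtures with known ground truth for every stage.
##
## The generator states a small world shaped like the study's data: loci
## carrying each splice-event class, transcript sequences with one designed
## ORF each, peptide evidence realizing a planned unique/grouped/subsumed
## partition, and negative-binomial count matrices (4 tissues x 2 replicates)
## with a planted venom-gland-upregulated set.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a fixture specification
#'
#' Defaults state the emulated world: ten loci covering each of the seven
#' event classes (plus one locus planted with all seven and two
#' single-transcript loci); an evidence plan of 3 unique proteins, 1
#' distinct group, 1 identical group and 1 subsumed protein; an expression
#' plan of 200 transcripts with 20 planted 8-fold venom-gland-upregulated at
#' negative-binomial dispersion 0.1, 4 tissues x 2 replicate libraries.
#'
#' @param seed integer seed governing all randomness.
#' @param n_loci number of annotation loci.
#' @param event_plan list of length `n_loci`; each element a character vector
#'   of event labels to plant at that locus (empty = single transcript).
#' @param max_exons optional cap on exons per transcript; a plan whose
#'   template needs more raises an error.
#' @param protein_plan list with counts `u` (unique), `g_distinct`,
#'   `g_identical`, `subsumed`, and `group_size`.
#' @param expression_plan list with `n_transcripts`, `n_planted`, `fold`,
#'   `dispersion`, `base_meanlog`, `base_sdlog`, `tissues`, `n_reps`.
#' @param contaminants number of planted contaminant proteins in the
#'   evidence fixture.
#' @return A list of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_loci = 10L,
                         event_plan = NULL,
                         max_exons = Inf,
                         protein_plan = list(u = 3L, g_distinct = 1L,
                                             g_identical = 1L, subsumed = 1L,
                                             group_size = 2L),
                         expression_plan = list(
                           n_transcripts = 200L, n_planted = 20L, fold = 8,
                           dispersion = 0.1, base_meanlog = log(100),
                           base_sdlog = 1,
                           tissues = c("venom_gland", "silk_gland", "ovary",
                                       "cephalothorax"),
                           n_reps = 2L),
                         contaminants = 1L) {
  if (is.null(event_plan)) {
    event_plan <- c(as.list(EVENT_LABELS), list(EVENT_LABELS),
                    list(character(0)), list(character(0)))
    event_plan <- event_plan[seq_len(min(n_loci, length(event_plan)))]
    while (length(event_plan) < n_loci)
      event_plan <- c(event_plan, list(character(0)))
  }
  if (length(event_plan) != n_loci)
    stop("event_plan must have one element per locus")
  structure(list(seed = seed, n_loci = n_loci, event_plan = event_plan,
                 max_exons = max_exons, protein_plan = protein_plan,
                 expression_plan = expression_plan,
                 contaminants = contaminants),
            class = "FixtureSpec")
}

## Event templates in plus-strand transcription coordinates within a block.
## Each yields a transcript pair witnessing exactly the labelled event.
.event_templates <- list(
  EXON_SKIP = list(a = rbind(c(0, 100), c(200, 300), c(400, 500)),
                   b = rbind(c(0, 100), c(400, 500)), need = 3L),
  MXE = list(a = rbind(c(0, 100), c(200, 300), c(600, 700)),
             b = rbind(c(0, 100), c(400, 500), c(600, 700)), need = 3L),
  A5SS = list(a = rbind(c(0, 100), c(400, 500)),
              b = rbind(c(0, 150), c(400, 500)), need = 2L),
  A3SS = list(a = rbind(c(0, 100), c(400, 500)),
              b = rbind(c(0, 100), c(350, 500)), need = 2L),
  INTRON_RETENTION = list(a = rbind(c(0, 100), c(200, 300)),
                          b = rbind(c(0, 300)), need = 2L),
  AFE = list(a = rbind(c(0, 100), c(400, 500)),
             b = rbind(c(200, 300), c(400, 500)), need = 2L),
  ALE = list(a = rbind(c(0, 100), c(400, 500)),
             b = rbind(c(0, 100), c(600, 700)), need = 2L))
.BLOCK_SPAN <- 1000L

.NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

## stop-dense padding: "TAGC" repeats carry a stop every <= 4 codons in any
## frame and contain no ATG
.pad_seq <- function(n) substr(strrep("TAGC", ceiling(n / 4) + 1L), 1L, n)

## frame-blocker codon pairs: stop-free and ATG-free in frame 0, but planting
## a TAA at shift +1 ("CTAAGG") and a TGA at shift +2 ("ACTGAC")
.BLOCKERS <- c("CTAAGG", "ACTGAC")

## A transcript sequence of length len with exactly one designed ORF:
## pad + ATG + random codons interleaved with frame blockers + TAA + pad.
## Returns list(seq, protein) where protein is the Met-trimmed truth.
.design_tx_seq <- function(len) {
  pad_min <- 12L
  n_cod <- min(45L, (len - 2L * pad_min - 6L) %/% 3L)
  if (n_cod < 32L)  # Met-led ORF of n_cod - 1 aa must exceed 90 nt
    stop("transcript of length ", len, " too short for a designed ORF")
  m <- n_cod - 2L  # body codons between the ATG and the stop
  body <- character(0)
  k <- 0L
  while (length(body) < m) {
    body <- c(body, sample(.NONSTOP_CODONS, 4L, replace = TRUE))
    blk <- .BLOCKERS[k %% 2L + 1L]
    body <- c(body, substr(blk, 1L, 3L), substr(blk, 4L, 6L))
    k <- k + 1L
  }
  body <- body[seq_len(m)]  # blocker halves are non-stop, safe to truncate
  cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
  pad_left_n <- pad_min + (3L - pad_min %% 3L) %% 3L
  pad_right_n <- len - pad_left_n - nchar(cds)
  stopifnot(pad_right_n >= 0L)
  seq <- paste0(.pad_seq(pad_left_n), cds, .pad_seq(pad_right_n))
  codons <- substring(cds, seq.int(1L, nchar(cds) - 3L, 3L),
                      seq.int(3L, nchar(cds) - 1L, 3L))
  list(seq = seq, protein = paste(.translate_codons(codons), collapse = ""))
}

#' Generate an annotation fixture with planted splice events
#'
#' For every planted event label the locus contains a transcript pair whose
#' exon chains witness exactly that event; several labels at one locus are
#' realized in disjoint coordinate blocks so no cross-pair event arises.
#' Loci alternate between the two strands (minus-strand blocks are reflected
#' so the planted label is preserved in transcription order).  Each
#' transcript gets a sequence of its spliced length containing one designed
#' ORF, so the predicted protein is known.
#'
#' @param spec a `FixtureSpec`.
#' @param dir optional directory; when given, writes `annotation.gtf`,
#'   `transcripts.fa` and `ground_truth.json` there.
#' @return List with `loci` (list of `GeneLocus`), `tx_seqs` (named
#'   character), `truth` (list with `events` table of planted
#'   `(gene_id, label)` and `proteins`, the named Met-trimmed truth), and
#'   file paths when `dir` was given.
#' @export
make_annotation_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  .with_seed(spec$seed, {
    loci <- list()
    tx_seqs <- character(0)
    truth_events <- list()
    truth_prot <- character(0)
    for (li in seq_len(spec$n_loci)) {
      labels <- spec$event_plan[[li]]
      bad <- setdiff(labels, EVENT_LABELS)
      if (length(bad))
        stop("unknown event label(s): ", paste(bad, collapse = ", "))
      gid <- sprintf("GENE%03d", li)
      chrom <- "scaffold_1"
      strand <- if (li %% 2L == 1L) "+" else "-"
      offset <- (li - 1L) * 100000L
      txs <- list()
      mk_tx <- function(exons_rel, block_offset) {
        if (strand == "-")  # reflect within the block to keep the label
          exons_rel <- cbind(.BLOCK_SPAN - exons_rel[, 2L],
                             .BLOCK_SPAN - exons_rel[, 1L])
        tid <- sprintf("%s.%d", gid, length(txs) + 1L)
        txs[[length(txs) + 1L]] <<- transcript_model(
          tid, gid, chrom, strand,
          exons_rel + offset + block_offset,
          source = if (length(txs) %% 2L == 0L) "novel" else "reference")
        tid
      }
      if (length(labels) == 0L) {
        mk_tx(rbind(c(0L, 200L)), 0L)
      } else {
        for (k in seq_along(labels)) {
          tpl <- .event_templates[[labels[k]]]
          if (tpl$need > spec$max_exons)
            stop("contradictory plan: ", labels[k], " needs ", tpl$need,
                 " exons but max_exons is ", spec$max_exons)
          block <- (k - 1L) * 10000L
          mk_tx(tpl$a, block)
          mk_tx(tpl$b, block)
          truth_events[[length(truth_events) + 1L]] <-
            data.table(gene_id = gid, label = labels[k])
        }
      }
      loci[[gid]] <- gene_locus(gid, txs)
      for (tx in txs) {
        len <- sum(tx$exons[, "end"] - tx$exons[, "start"])
        d <- .design_tx_seq(len)
        tx_seqs[[tx$transcript_id]] <- d$seq
        truth_prot[[tx$transcript_id]] <- d$protein
      }
    }
    truth <- list(
      events = if (length(truth_events)) rbindlist(truth_events)
               else data.table(gene_id = character(0), label = character(0)),
      proteins = truth_prot)
    out <- list(loci = loci, tx_seqs = tx_seqs, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$gtf <- file.path(dir, "annotation.gtf")
      write_annotation(loci, out$gtf)
      out$fasta <- file.path(dir, "transcripts.fa")
      writeLines(paste0(">", names(tx_seqs), "\n", tx_seqs), out$fasta)
      out$truth_json <- file.path(dir, "ground_truth.json")
      jsonlite::write_json(
        list(events = truth$events,
             proteins = as.list(truth$proteins)),
        out$truth_json, auto_unbox = TRUE, digits = NA)
    }
    out
  })
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.rand_aa <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

#' Generate a peptide-evidence fixture with a planned ambiguity structure
#'
#' Realizes exactly the planned identification partition: unique proteins get
#' two or more private peptides; members of a group share an identical
#' peptide set (identical groups share the whole sequence, distinct groups
#' share a common core from which the peptides are drawn); subsumed proteins
#' are substrings of a unique protein and share a strict subset of its
#' peptides.  Below-threshold noise peptides and planted contaminant
#' proteins exercise the filtering and purge steps.
#'
#' @param spec a `FixtureSpec` (fields `protein_plan`, `contaminants`,
#'   `seed`).
#' @param proteins optional named character vector of Met-trimmed protein
#'   sequences to draw members from; when `NULL` sequences are synthesized.
#'   An infeasible plan (e.g. an identical group without duplicated supplied
#'   sequences) raises an error.
#' @param dir optional directory; writes `evidence.tsv` and
#'   `evidence_truth.json` there.
#' @return List with `observations`, `protein_probabilities`,
#'   `protein_seqs`, `protein_labels` and `truth` (planned partition:
#'   `members` list and `kinds` tally).
#' @export
make_evidence_fixture <- function(spec, proteins = NULL, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  plan <- spec$protein_plan
  gs <- if (is.null(plan$group_size)) 2L else plan$group_size
  .with_seed(spec$seed + 1L, {
    seqs <- character(0)
    labels <- character(0)
    rows <- list()
    truth_members <- list()
    truth_kinds <- character(0)
    pid <- 0L
    new_id <- function() { pid <<- pid + 1L; sprintf("P%03d", pid) }
    add_row <- function(pep, prob, ids, pprob)
      rows[[length(rows) + 1L]] <<- data.table(
        peptide_sequence = pep, peptide_probability = prob,
        protein_ids = paste(ids, collapse = ";"),
        protein_probability = pprob)
    ## peptide unique to the given member set and distinct from `avoid`;
    ## re-drawn on collision
    fresh_pep <- function(from, not_in, avoid = character(0)) {
      for (try in 1:100) {
        start <- sample(nchar(from) - 8L, 1L)
        s <- substr(from, start, start + 8L)
        if (!s %in% avoid &&
            !any(vapply(not_in, function(q) grepl(s, q, fixed = TRUE),
                        logical(1))))
          return(s)
      }
      stop("could not draw a discriminating peptide")
    }

    supplied <- !is.null(proteins)
    pool <- if (supplied) proteins else character(0)
    take_seq <- function() {
      ## returns one synthesized sequence, or draws from the supplied pool
      if (!supplied) return(.rand_aa(40L))
      if (length(pool) == 0L) stop("plan infeasible: supplied proteins exhausted")
      s <- pool[[1L]]; pool <<- pool[-1L]; s
    }

    ## uniques
    for (k in seq_len(plan$u)) {
      id <- new_id()
      seqs[[id]] <- take_seq()
      labels[[id]] <- "toxin-like protein"
      others <- seqs[names(seqs) != id]
      drawn <- character(0)
      for (p in 1:2) {
        pep <- fresh_pep(seqs[[id]], others, avoid = drawn)
        drawn <- c(drawn, pep)
        add_row(pep, stats::runif(1, 0.96, 1), id, 0.995)
      }
      truth_members[[length(truth_members) + 1L]] <- id
      truth_kinds <- c(truth_kinds, "unique")
    }
    ## distinct groups: shared core, distinct flanks
    for (k in seq_len(plan$g_distinct)) {
      core <- if (supplied) NA_character_ else .rand_aa(22L)
      ids <- character(gs)
      for (m in seq_len(gs)) {
        ids[m] <- new_id()
        seqs[[ids[m]]] <- if (supplied) take_seq()
                          else paste0(.rand_aa(9L), core, .rand_aa(9L))
        labels[[ids[m]]] <- "toxin-like protein"
      }
      if (supplied) {
        ## feasibility: members must share >= 2 common 9-mers
        common <- .common_ninemers(seqs[ids])
        if (length(common) < 2L)
          stop("plan infeasible: supplied proteins share too few peptides ",
               "for a distinct group")
        core_peps <- common[1:2]
      } else {
        core_peps <- c(substr(core, 1L, 9L), substr(core, 12L, 20L))
      }
      others <- seqs[!names(seqs) %in% ids]
      for (p in core_peps) {
        if (any(vapply(others, function(q) grepl(p, q, fixed = TRUE),
                       logical(1))))
          stop("plan infeasible: group peptide not discriminating")
        add_row(p, stats::runif(1, 0.96, 1), ids, 0.995)
      }
      truth_members[[length(truth_members) + 1L]] <- ids
      truth_kinds <- c(truth_kinds,
                       if (length(unique(unname(seqs[ids]))) == 1L)
                         "group_identical" else "group_distinct")
    }
    ## identical groups: same sequence, distinct protein (transcript) ids
    for (k in seq_len(plan$g_identical)) {
      base <- if (supplied) {
        dup <- unname(pool[duplicated(pool) | duplicated(pool, fromLast = TRUE)])
        if (length(dup) == 0L)
          stop("plan infeasible: no duplicated supplied sequences ",
               "for an identical group")
        dup[1L]
      } else .rand_aa(40L)
      ids <- character(gs)
      for (m in seq_len(gs)) {
        ids[m] <- new_id()
        seqs[[ids[m]]] <- base
        labels[[ids[m]]] <- "toxin-like protein"
        if (supplied) {
          i <- match(base, pool)
          if (!is.na(i)) pool <- pool[-i]
        }
      }
      others <- seqs[!names(seqs) %in% ids]
      drawn <- character(0)
      for (p in 1:2) {
        pep <- fresh_pep(base, others, avoid = drawn)
        drawn <- c(drawn, pep)
        add_row(pep, stats::runif(1, 0.96, 1), ids, 0.995)
      }
      truth_members[[length(truth_members) + 1L]] <- ids
      truth_kinds <- c(truth_kinds, "group_identical")
    }
    ## subsumed proteins: substring of a fresh unique protein, sharing a
    ## strict subset of its peptides
    for (k in seq_len(plan$subsumed)) {
      host <- new_id()
      seqs[[host]] <- take_seq()
      labels[[host]] <- "toxin-like protein"
      sub <- new_id()
      seqs[[sub]] <- substr(seqs[[host]], 1L, 25L)
      labels[[sub]] <- "toxin-like protein"
      others <- seqs[!names(seqs) %in% c(host, sub)]
      p1 <- fresh_pep(seqs[[sub]], others)
      p2 <- fresh_pep(substr(seqs[[sub]], 10L, 25L), others, avoid = p1)
      ## a host-only peptide from the region the subsumed protein lacks
      p3 <- fresh_pep(substr(seqs[[host]], 26L, nchar(seqs[[host]])),
                      c(others, seqs[[sub]]))
      add_row(p1, stats::runif(1, 0.96, 1), c(host, sub), 0.995)
      add_row(p2, stats::runif(1, 0.96, 1), c(host, sub), 0.995)
      add_row(p3, stats::runif(1, 0.96, 1), host, 0.995)
      truth_members[[length(truth_members) + 1L]] <- host
      truth_kinds <- c(truth_kinds, "unique")
    }
    ## contaminants: pass all thresholds, purged by label
    for (k in seq_len(spec$contaminants)) {
      id <- new_id()
      seqs[[id]] <- .rand_aa(40L)
      labels[[id]] <- c("keratin, type II", "trypsin precursor",
                        "hemocyanin subunit")[(k - 1L) %% 3L + 1L]
      others <- seqs[names(seqs) != id]
      for (p in 1:2) add_row(fresh_pep(seqs[[id]], others),
                             stats::runif(1, 0.96, 1), id, 0.995)
    }
    ## noise: a below-threshold peptide and a single-peptide protein
    if (length(seqs)) {
      first <- names(seqs)[1L]
      add_row(fresh_pep(seqs[[first]], seqs[-1L]), 0.50, first, 0.995)
      weak <- new_id()
      seqs[[weak]] <- .rand_aa(40L)
      labels[[weak]] <- "toxin-like protein"
      add_row(fresh_pep(seqs[[weak]], seqs[names(seqs) != weak]),
              stats::runif(1, 0.96, 1), weak, 0.995)
    }

    obs_raw <- rbindlist(rows)
    observations <- data.table(
      peptide_sequence = obs_raw$peptide_sequence,
      peptide_probability = obs_raw$peptide_probability,
      protein_ids = strsplit(obs_raw$protein_ids, ";", fixed = TRUE))
    kt <- setNames(integer(3),
                   c("unique", "group_distinct", "group_identical"))
    tt <- table(truth_kinds)
    kt[names(tt)] <- as.integer(tt)
    out <- list(
      observations = observations,
      protein_probabilities = setNames(rep(0.995, length(seqs)),
                                       names(seqs)),
      protein_seqs = unlist(seqs),
      protein_labels = unlist(labels),
      truth = list(members = truth_members, kinds = kt))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$evidence <- file.path(dir, "evidence.tsv")
      fwrite(obs_raw, out$evidence, sep = "\t")
      out$truth_json <- file.path(dir, "evidence_truth.json")
      jsonlite::write_json(list(members = truth_members,
                                kinds = as.list(kt)),
                           out$truth_json, auto_unbox = TRUE, digits = NA)
    }
    out
  })
}

.common_ninemers <- function(seqs) {
  mers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 9L) return(character(0))
    unique(substring(s, 1:(n - 8L), 9:n))
  })
  Reduce(intersect, mers)
}

#' Generate a negative-binomial count fixture with planted upregulation
#'
#' Counts are drawn per transcript and library from a negative binomial with
#' variance `mu + dispersion * mu^2`; baseline means are log-normal across
#' transcripts and shared across tissues, library size factors are mildly
#' variable, and the planted transcripts have their venom-gland mean
#' multiplied by the planned fold change.
#'
#' @param spec a `FixtureSpec` (fields `expression_plan`, `seed`).
#' @param dir optional directory; writes `counts.tsv`, `lengths.tsv`,
#'   `tissues.tsv` and `counts_truth.json` there.
#' @return List with `em` (an `ExpressionMatrix`), `truth` (character vector
#'   of planted transcript ids) and file paths when `dir` was given.
#' @export
make_counts_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  ep <- spec$expression_plan
  .with_seed(spec$seed + 2L, {
    n <- ep$n_transcripts
    ids <- sprintf("TX%04d", seq_len(n))
    libs <- as.vector(t(outer(ep$tissues, seq_len(ep$n_reps),
                              function(t, r) paste0(t, "_r", r))))
    tissues <- setNames(rep(ep$tissues, each = ep$n_reps), libs)
    base <- rlnorm(n, meanlog = ep$base_meanlog, sdlog = ep$base_sdlog)
    planted <- if (ep$n_planted > 0L)
      sort(sample(ids, ep$n_planted)) else character(0)
    sf <- runif(length(libs), 0.8, 1.2)
    names(sf) <- libs
    size <- 1 / ep$dispersion
    counts <- matrix(0L, n, length(libs), dimnames = list(ids, libs))
    for (j in seq_along(libs)) {
      mu <- base
      if (tissues[j] == "venom_gland" && length(planted))
        mu[match(planted, ids)] <- mu[match(planted, ids)] * ep$fold
      counts[, j] <- rnbinom(n, mu = mu * sf[j], size = size)
    }
    lengths <- setNames(sample(500:3000, n, replace = TRUE), ids)
    em <- expression_matrix(counts, lengths, tissues)
    out <- list(em = em, truth = planted)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$counts <- file.path(dir, "counts.tsv")
      cdt <- data.table(transcript_id = ids)
      for (j in libs) cdt[[j]] <- counts[, j]
      fwrite(cdt, out$counts, sep = "\t")
      out$lengths <- file.path(dir, "lengths.tsv")
      fwrite(data.table(transcript_id = ids, length = unname(lengths)),
             out$lengths, sep = "\t")
      out$tissues <- file.path(dir, "tissues.tsv")
      fwrite(data.table(library = libs, tissue = unname(tissues)),
             out$tissues, sep = "\t")
      out$truth_json <- file.path(dir, "counts_truth.json")
      jsonlite::write_json(list(planted = planted), out$truth_json,
                           auto_unbox = FALSE, digits = NA)
    }
    out
  })
}
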