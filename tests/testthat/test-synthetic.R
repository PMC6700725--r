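test_that("fixture generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- fixture_spec(seed = 123)
  make_annotation_fixture(spec, dir = d1)
  make_evidence_fixture(spec, dir = d1)
  make_counts_fixture(spec, dir = d1)
  make_annotation_fixture(spec, dir = d2)
  make_evidence_fixture(spec, dir = d2)
  make_counts_fixture(spec, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  ## a different seed changes the world
  d3 <- withr::local_tempdir()
  make_counts_fixture(fixture_spec(seed = 124), dir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "counts.tsv"))),
    unname(tools::md5sum(file.path(d3, "counts.tsv")))))
})

test_that("generator leaves the global RNG state untouched", {
  set.seed(55)
  before <- .Random.seed
  invisible(make_annotation_fixture(fixture_spec(seed = 99)))
  expect_identical(.Random.seed, before)
})

test_that("every emitted file parses by its reader without warnings", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 31)
  ann <- make_annotation_fixture(spec, dir = dir)
  ev <- make_evidence_fixture(spec, dir = dir)
  cf <- make_counts_fixture(spec, dir = dir)
  expect_no_warning(read_annotation(ann$gtf))
  expect_no_warning(read_transcript_fasta(ann$fasta))
  expect_no_warning(read_evidence_table(ev$evidence))
  expect_no_warning(read_expression_tables(cf$counts, cf$lengths,
                                           cf$tissues))
  seqs <- read_transcript_fasta(ann$fasta)
  expect_setequal(names(seqs), names(ann$tx_seqs))
  expect_identical(seqs[names(ann$tx_seqs)], ann$tx_seqs)
})

test_that("planted events are the generator's ground truth, per strand", {
  for (seed in c(1, 2)) {
    fx <- make_annotation_fixture(fixture_spec(seed = seed))
    got <- data.table::rbindlist(lapply(fx$loci, locus_event_summary))
    got <- got[, .(gene_id, label)][order(gene_id, label)]
    want <- fx$truth$events[order(gene_id, label)]
    expect_equal(got, want)
  }
  ## single-label plans on each strand (odd loci are plus, even minus)
  fx <- make_annotation_fixture(
    fixture_spec(seed = 3, n_loci = 2L,
                 event_plan = list("MXE", "MXE")))
  strands <- vapply(fx$loci, function(l) l$transcripts[[1L]]$strand, "")
  expect_setequal(strands, c("+", "-"))
  for (l in fx$loci)
    expect_equal(locus_event_summary(l)$label, "MXE")
})

test_that("contradictory event plans are rejected", {
  expect_error(
    make_annotation_fixture(fixture_spec(seed = 1, n_loci = 1L,
                                         event_plan = list("MXE"),
                                         max_exons = 2L)),
    "contradictory")
  expect_error(
    make_annotation_fixture(fixture_spec(seed = 1, n_loci = 1L,
                                         event_plan = list("BOGUS"))),
    "unknown event label")
})

test_that("empty plans give single-transcript loci with zero events", {
  fx <- make_annotation_fixture(
    fixture_spec(seed = 4, n_loci = 2L,
                 event_plan = list(character(0), character(0))))
  expect_true(all(vapply(fx$loci, function(l) length(l$transcripts), 0L)
                  == 1L))
  expect_equal(nrow(fx$truth$events), 0L)
})

test_that("evidence fixtures realize the planned partition exactly", {
  set.seed(1)  # plans below are deterministic via the spec seed anyway
  plans <- list(
    list(u = 2L, g_distinct = 0L, g_identical = 0L, subsumed = 0L,
         group_size = 2L),
    list(u = 5L, g_distinct = 3L, g_identical = 2L, subsumed = 2L,
         group_size = 3L),
    list(u = 0L, g_distinct = 2L, g_identical = 1L, subsumed = 0L,
         group_size = 2L))
  for (i in seq_along(plans)) {
    spec <- fixture_spec(seed = 100 + i, protein_plan = plans[[i]])
    ev <- make_evidence_fixture(spec)
    filt <- filter_evidence(ev$observations, ev$protein_probabilities)
    ids <- infer_identifications(filt, ev$protein_seqs)
    ids <- purge_contaminants(ids, ev$protein_labels)
    expect_equal(canonical_partition(ids),
                 canonical_partition(lapply(ev$truth$members, function(m)
                   list(member_protein_ids = m))),
                 info = paste("plan", i))
    expect_equal(enumerate_counts(ids)$kinds, ev$truth$kinds,
                 info = paste("plan", i))
  }
})

test_that("infeasible plans with supplied proteins are rejected", {
  spec <- fixture_spec(seed = 9, protein_plan = list(
    u = 1L, g_distinct = 0L, g_identical = 1L, subsumed = 0L,
    group_size = 2L))
  distinct <- c(a = strrep("MA", 20), b = strrep("MC", 20),
                c = strrep("MD", 20))
  expect_error(make_evidence_fixture(spec, proteins = distinct),
               "infeasible")
})

test_that("count draws match the stated negative-binomial moments", {
  spec <- fixture_spec(seed = 77, expression_plan = list(
    n_transcripts = 10000L, n_planted = 0L, fold = 1, dispersion = 0.1,
    base_meanlog = log(100), base_sdlog = 0,
    tissues = c("venom_gland", "silk_gland", "ovary", "cephalothorax"),
    n_reps = 2L))
  cf <- make_counts_fixture(spec)
  ## all transcripts share mu = 100 * sf_j within a library
  for (j in seq_len(ncol(cf$em$counts))) {
    x <- cf$em$counts[, j]
    mu <- mean(x)
    expect_equal(mu, 100, tolerance = 0.15)
    ## variance = mu + 0.1 mu^2; MC tolerance at n = 1e4
    expect_equal(stats::var(x), mu + 0.1 * mu^2, tolerance = 0.1)
  }
})

test_that("planted fold changes are bookkept in the ground truth", {
  cf0 <- make_counts_fixture(fixture_spec(seed = 5, expression_plan = list(
    n_transcripts = 50L, n_planted = 0L, fold = 1, dispersion = 0.1,
    base_meanlog = log(100), base_sdlog = 1,
    tissues = c("venom_gland", "silk_gland", "ovary", "cephalothorax"),
    n_reps = 2L)))
  expect_length(cf0$truth, 0L)
  cf <- make_counts_fixture(fixture_spec(seed = 5))
  expect_length(cf$truth, 20L)
  expect_true(all(cf$truth %in% rownames(cf$em$counts)))
  ## planted transcripts really are venom-gland enriched on average
  vg <- names(cf$em$tissues)[cf$em$tissues == "venom_gland"]
  other <- setdiff(colnames(cf$em$counts), vg)
  ratio <- rowMeans(cf$em$counts[cf$truth, vg]) /
    pmax(1, rowMeans(cf$em$counts[cf$truth, other]))
  expect_gt(median(ratio), 4)
})
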