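mk_em <- function(counts, lengths = NULL, n_reps = 2L,
                  tissues = c("venom_gland", "silk_gland", "ovary",
                              "cephalothorax")) {
  libs <- paste0(rep(tissues, each = n_reps), "_r", seq_len(n_reps))
  colnames(counts) <- libs[seq_len(ncol(counts))]
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("tx%d", seq_len(nrow(counts)))
  if (is.null(lengths))
    lengths <- setNames(rep(1000, nrow(counts)), rownames(counts))
  tmap <- setNames(rep(tissues, each = n_reps), libs)
  expression_matrix(counts, lengths, tmap[colnames(counts)])
}

test_that("pseudocount shifts every cell and nothing else", {
  em <- mk_em(matrix(0:7, nrow = 2, ncol = 4), n_reps = 2L,
              tissues = c("venom_gland", "silk_gland"))
  shifted <- add_pseudocount(em, 5L)
  expect_equal(shifted$counts[1L, 1L], 5)
  expect_equal(shifted$counts, em$counts + 5)
  expect_equal(shifted$lengths, em$lengths)
  expect_equal(add_pseudocount(em, 0L)$counts, em$counts)
  expect_equal(colSums(shifted$counts), colSums(em$counts) + 5 * 2)
})

test_that("TPM normalizes each library to one million", {
  one <- mk_em(matrix(50, 1, 2), tissues = "venom_gland")
  expect_equal(unname(compute_tpm(one)[1L, ]), c(1e6, 1e6))

  two <- expression_matrix(
    matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "venom_gland_r1")),
    c(a = 100, b = 200), c(venom_gland_r1 = "venom_gland"))
  expect_equal(unname(compute_tpm(two)[, 1L]), c(2 / 3, 1 / 3) * 1e6)

  set.seed(9)
  em <- mk_em(matrix(rpois(800, 40), 100, 8),
              lengths = setNames(runif(100, 200, 3000),
                                 sprintf("tx%d", 1:100)))
  expect_equal(unname(colSums(compute_tpm(em))), rep(1e6, 8),
               tolerance = 1e-9)

  zero <- mk_em(matrix(0, 2, 2), tissues = "venom_gland")
  expect_error(compute_tpm(zero), "zero total rate")
})

test_that("constructor validates counts, lengths and tissue map", {
  m <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("l1", "l2")))
  expect_error(expression_matrix(m - 5, c(a = 1, b = 1),
                                 c(l1 = "x", l2 = "y")), "non-negative")
  expect_error(expression_matrix(m, c(a = 1), c(l1 = "x", l2 = "y")),
               "length")
  expect_error(expression_matrix(m, c(a = 1, b = 1), c(l1 = "x")), "tissue")
})

test_that("upregulation calls recover an 8-fold planted set", {
  cf <- make_counts_fixture(fixture_spec(seed = 61))
  calls <- call_vgtup(cf$em)
  expect_gte(length(intersect(calls$vgtup, cf$truth)) / length(cf$truth),
             0.9)
  fdp <- length(setdiff(calls$vgtup, cf$truth)) / max(1, length(calls$vgtup))
  expect_lte(fdp, 0.1)
})

test_that("a flat transcript is never called and errors are informative", {
  set.seed(71)
  counts <- matrix(rnbinom(200 * 8, mu = 100, size = 10), 200, 8)
  counts[1L, ] <- 100  # identical in all libraries
  em <- mk_em(counts)
  emp <- add_pseudocount(em, 5L)
  up <- pairwise_upregulated(emp, "venom_gland", "silk_gland")
  expect_false("tx1" %in% up)
  expect_error(pairwise_upregulated(emp, "venom_gland", "no_such"),
               "no libraries")
  one_rep <- mk_em(counts[, c(1, 3, 4)], n_reps = 1L,
                   tissues = c("venom_gland", "silk_gland", "ovary"))
  expect_error(pairwise_upregulated(add_pseudocount(one_rep), "venom_gland",
                                    "silk_gland"), "2 replicates")
})

test_that("the upregulated set is monotone in the FDR threshold", {
  cf <- make_counts_fixture(fixture_spec(seed = 81))
  strict <- call_vgtup(cf$em, fdr = 0.01)
  loose <- call_vgtup(cf$em, fdr = 0.05)
  expect_true(all(strict$vgtup %in% loose$vgtup))
})

test_that("three-way intersection is exact", {
  expect_equal(vgtup_set(list(c("a", "b"), c("b", "c"), c("b", "d"))), "b")
  expect_equal(vgtup_set(list(c("a", "b"), c("a", "b"), "c")), character(0))
  expect_error(vgtup_set(list(c("a"), c("a"))), "three")
  set.seed(91)
  sets <- replicate(3, sample(letters, 10), simplify = FALSE)
  expect_setequal(vgtup_set(sets),
                  intersect(intersect(sets[[1]], sets[[2]]), sets[[3]]))
})

test_that("rank flags use ceiling cutoffs and share tied ranks", {
  tpm <- matrix(c(100:1), 100, 2)
  rownames(tpm) <- sprintf("tx%d", 1:100)
  colnames(tpm) <- c("venom_gland_r1", "venom_gland_r2")
  tis <- setNames(c("venom_gland", "venom_gland"), colnames(tpm))
  fl <- expression_rank_flags(tpm, tis)
  expect_true(fl[transcript_id == "tx1", top1])
  expect_false(fl[transcript_id == "tx2", top1])
  expect_true(fl[transcript_id == "tx2", top5])
  expect_false(fl[transcript_id == "tx6", top5])
  ## permutation invariance
  fl2 <- expression_rank_flags(tpm[sample(100), , drop = FALSE], tis)
  expect_equal(fl2[order(transcript_id)], fl[order(transcript_id)])
  ## ties share the better rank
  tpm[2L, ] <- tpm[1L, ]
  fl3 <- expression_rank_flags(tpm, tis)
  expect_true(all(fl3[transcript_id %in% c("tx1", "tx2"), rank] == 1L))
})

test_that("pattern labels follow the TPM rules", {
  means <- rbind(
    a = c(venom_gland = 0, silk_gland = 3, ovary = 0, cephalothorax = 0),
    b = c(100, 1, 1, 1),
    c = c(6, 6, 6, 6),
    d = c(2, 25, 1, 1))
  colnames(means) <- c("venom_gland", "silk_gland", "ovary", "cephalothorax")
  pat <- pattern_classify(means)
  expect_equal(unlist(pat[transcript_id == "a",
                          .(zero_in_vg, higher_elsewhere,
                            order_of_magnitude_elsewhere,
                            highest_avg_in_vg, broad_expression)]),
               c(zero_in_vg = TRUE, higher_elsewhere = TRUE,
                 order_of_magnitude_elsewhere = TRUE,
                 highest_avg_in_vg = FALSE, broad_expression = FALSE))
  expect_true(pat[transcript_id == "b", highest_avg_in_vg])
  expect_false(pat[transcript_id == "b", higher_elsewhere])
  expect_true(pat[transcript_id == "c", broad_expression])
  expect_false(pat[transcript_id == "c", highest_avg_in_vg])
  expect_true(pat[transcript_id == "d", order_of_magnitude_elsewhere])
})

test_that("expression tables round-trip through the readers", {
  dir <- withr::local_tempdir()
  cf <- make_counts_fixture(fixture_spec(seed = 93), dir = dir)
  em <- read_expression_tables(cf$counts, cf$lengths, cf$tissues)
  expect_equal(em$counts, cf$em$counts)
  expect_equal(em$lengths, cf$em$lengths)
  expect_equal(em$tissues, cf$em$tissues)
})
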