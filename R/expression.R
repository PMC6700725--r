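## Expression containers, TPM, and expression-pattern classification.

#' Construct an expression matrix
#'
#' Transcripts-by-libraries raw counts with per-transcript effective lengths
#' and a library-to-tissue map (the replicated design: several libraries per
#' tissue).
#'
#' @param counts numeric matrix of non-negative counts with transcript row
#'   names and library column names.
#' @param lengths named numeric vector of effective transcript lengths (nt)
#'   covering every row.
#' @param tissues named character vector mapping every library (column) to
#'   one tissue.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, lengths, tissues) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript row names and library column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(rownames(counts) %in% names(lengths)))
    stop("every transcript needs an effective length")
  if (!all(colnames(counts) %in% names(tissues)))
    stop("every library must be mapped to a tissue")
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop("effective lengths must be positive")
  structure(list(counts = counts, lengths = lengths,
                 tissues = tissues[colnames(counts)]),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d transcripts x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$tissues)),
                            table(x$tissues)), collapse = ", ")))
  invisible(x)
}

#' Add a pseudocount to every cell
#'
#' The default of 5 counts per cell prevents underflow in downstream testing
#' when counts are zero in both replicates of a tissue; lengths are untouched.
#'
#' @param m an `ExpressionMatrix`.
#' @param c non-negative integer pseudocount (default 5).
#' @return The shifted `ExpressionMatrix`.
#' @export
add_pseudocount <- function(m, c = 5L) {
  stopifnot(c >= 0)
  m$counts <- m$counts + c
  m
}

#' Transcripts-per-million matrix
#'
#' Per library: `rate = count / length`, `TPM = rate / sum(rates) * 1e6`, so
#' each library column sums to one million.
#'
#' @param m an `ExpressionMatrix`.
#' @return Numeric matrix of TPM with the same dimnames as the counts.
#' @export
compute_tpm <- function(m) {
  rate <- m$counts / m$lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("zero total rate in library(ies): ",
                          paste(colnames(m$counts)[tot == 0], collapse = ", "))
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Transcripts significantly upregulated in one tissue versus another
#'
#' Runs a two-condition test engine per transcript, applies
#' Benjamini-Hochberg control at `fdr`, and returns the transcripts that are
#' significant with a higher normalized mean in `tissue_a`.  The engine is
#' pluggable; the default is [nb_wald_engine()] (a moderated-dispersion
#' negative-binomial Wald test, declared non-equivalent to empirical-Bayes
#' engines used elsewhere).
#'
#' @param m an `ExpressionMatrix` (counts as to be tested, i.e. pseudocounted
#'   if desired).
#' @param tissue_a,tissue_b tissue labels; both need at least 2 replicate
#'   libraries.
#' @param fdr Benjamini-Hochberg rate (default 0.05).
#' @param engine function `(counts, group)` returning a `data.table` with
#'   columns `transcript_id`, `p_value`, `mean_a`, `mean_b`.
#' @return Character vector of upregulated transcript ids, with the full
#'   per-transcript result table (including `padj`) in attribute `"table"`.
#' @export
pairwise_upregulated <- function(m, tissue_a = "venom_gland", tissue_b,
                                 fdr = 0.05, engine = nb_wald_engine) {
  for (t in c(tissue_a, tissue_b)) {
    nlib <- sum(m$tissues == t)
    if (nlib == 0L) stop("no libraries for tissue ", t)
    if (nlib < 2L) stop("tissue ", t, " needs at least 2 replicates")
  }
  libs <- names(m$tissues)[m$tissues %in% c(tissue_a, tissue_b)]
  grp <- factor(m$tissues[libs], levels = c(tissue_a, tissue_b))
  res <- engine(m$counts[, libs, drop = FALSE], grp)
  res$padj <- p.adjust(res$p_value, method = "BH")
  up <- res$transcript_id[res$padj <= fdr & res$mean_a > res$mean_b]
  structure(up, table = res)
}

#' Intersect per-comparison upregulation calls
#'
#' The final upregulated set is the exact intersection of the three pairwise
#' comparisons against the other tissues.
#'
#' @param sets list of exactly three character vectors of transcript ids.
#' @return Character vector (the intersection).
#' @export
vgtup_set <- function(sets) {
  if (!is.list(sets) || length(sets) != 3L)
    stop("vgtup_set needs exactly three comparison sets")
  Reduce(intersect, sets)
}

#' Call venom-gland upregulated transcripts
#'
#' Full calling pipeline: add the pseudocount, test venom gland against each
#' other tissue at the given FDR, and intersect the per-comparison sets.
#'
#' @param m an `ExpressionMatrix` of raw counts.
#' @param tissue_a the focal tissue (default `"venom_gland"`).
#' @param fdr per-comparison Benjamini-Hochberg rate.
#' @param pseudocount added to every cell before testing (default 5).
#' @param engine test engine, see [pairwise_upregulated()].
#' @return List with `vgtup` (intersection) and `per_comparison` (named list
#'   of per-tissue upregulated sets).
#' @export
call_vgtup <- function(m, tissue_a = "venom_gland", fdr = 0.05,
                       pseudocount = 5L, engine = nb_wald_engine) {
  others <- setdiff(unique(m$tissues), tissue_a)
  if (length(others) != 3L)
    stop("expected exactly 3 comparison tissues, found ", length(others))
  mp <- add_pseudocount(m, pseudocount)
  per <- lapply(others, function(t)
    as.character(pairwise_upregulated(mp, tissue_a, t, fdr, engine)))
  names(per) <- others
  list(vgtup = vgtup_set(per), per_comparison = per)
}

#' Expression rank percentiles and top-1%/top-5% flags
#'
#' Ranks transcripts by mean TPM over the replicates of one tissue; tied
#' transcripts share the better (lower) rank.  A transcript is in the top k%
#' when its rank is at most `ceiling(k/100 * n)`.
#'
#' @param tpm TPM matrix from [compute_tpm()].
#' @param tissues library-to-tissue map.
#' @param tissue focal tissue (default `"venom_gland"`).
#' @return A `data.table` with columns `transcript_id`, `mean_tpm`, `rank`,
#'   `percentile`, `top1`, `top5`.
#' @export
expression_rank_flags <- function(tpm, tissues, tissue = "venom_gland") {
  libs <- names(tissues)[tissues == tissue]
  if (length(libs) == 0L) stop("no libraries for tissue ", tissue)
  mu <- rowMeans(tpm[, libs, drop = FALSE])
  rk <- rank(-mu, ties.method = "min")
  n <- length(mu)
  data.table(transcript_id = rownames(tpm), mean_tpm = mu,
             rank = as.integer(rk), percentile = 100 * rk / n,
             top1 = rk <= ceiling(0.01 * n), top5 = rk <= ceiling(0.05 * n))
}

#' Per-tissue mean TPM
#'
#' @param tpm TPM matrix.
#' @param tissues library-to-tissue map.
#' @return Matrix transcripts x tissues of means over replicate libraries.
#' @export
tissue_means <- function(tpm, tissues) {
  tset <- unique(tissues)
  out <- vapply(tset, function(t)
    rowMeans(tpm[, names(tissues)[tissues == t], drop = FALSE]),
    numeric(nrow(tpm)))
  dimnames(out) <- list(rownames(tpm), tset)
  out
}

#' Classify per-transcript cross-tissue expression patterns
#'
#' Labels, evaluated on per-tissue mean TPM with `vg` as the focal tissue:
#' \describe{
#'   \item{zero_in_vg}{focal-tissue mean is exactly 0.}
#'   \item{highest_avg_in_vg}{focal mean strictly greatest across tissues.}
#'   \item{higher_elsewhere}{some other tissue mean strictly exceeds the
#'     focal mean.}
#'   \item{broad_expression}{mean above 5 TPM in every tissue.}
#'   \item{order_of_magnitude_elsewhere}{some other tissue mean at least 10x
#'     the focal mean (any positive mean qualifies when the focal mean is 0).}
#' }
#'
#' @param means transcripts x tissues matrix from [tissue_means()].
#' @param vg focal tissue column (default `"venom_gland"`).
#' @return A `data.table` of logical flags, one row per transcript.
#' @export
pattern_classify <- function(means, vg = "venom_gland") {
  if (!vg %in% colnames(means)) stop("no tissue column ", vg)
  v <- means[, vg]
  others <- means[, setdiff(colnames(means), vg), drop = FALSE]
  omax <- apply(others, 1L, max)
  data.table(
    transcript_id = rownames(means),
    zero_in_vg = v == 0,
    highest_avg_in_vg = v > omax,
    higher_elsewhere = omax > v,
    broad_expression = apply(means > 5, 1L, all),
    order_of_magnitude_elsewhere = ifelse(v == 0, omax > 0, omax >= 10 * v))
}

## ---- tabular I/O -----------------------------------------------------------

#' Read counts, lengths and tissue-map files into an `ExpressionMatrix`
#'
#' `counts_path`: tab-separated, first column `transcript_id`, remaining
#' columns one per library.  `lengths_path`: columns `transcript_id`,
#' `length`.  `tissues_path`: columns `library`, `tissue`.
#'
#' @param counts_path,lengths_path,tissues_path file paths.
#' @return An `ExpressionMatrix`.
#' @export
read_expression_tables <- function(counts_path, lengths_path, tissues_path) {
  cdt <- fread(counts_path, sep = "\t", header = TRUE)
  counts <- as.matrix(cdt[, -1L])
  rownames(counts) <- cdt[[1L]]
  ldt <- fread(lengths_path, sep = "\t", header = TRUE)
  tdt <- fread(tissues_path, sep = "\t", header = TRUE)
  expression_matrix(counts, setNames(ldt$length, ldt$transcript_id),
                    setNames(tdt$tissue, tdt$library))
}
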