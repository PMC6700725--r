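## Built-in two-condition negative-binomial test engine.
##
## Deliberately simple and self-contained: median-of-ratios library-size
## normalization, method-of-moments per-transcript dispersion shrunk toward
## the transcriptome median, and a Wald test on the log ratio of group means.
## This engine is NOT an empirical-Bayes reimplementation; the surrounding
## pairwise/intersection/threshold logic is exact, the engine is pluggable.

#' Median-of-ratios library size factors
#'
#' DESeq-style: per library, the median across transcripts of the ratio of
#' the count to the transcript's geometric mean; factors are rescaled to a
#' geometric mean of one.  Transcripts with a zero count in any library are
#' excluded from the reference set.
#'
#' @param counts transcripts x libraries count matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors_mor <- function(counts) {
  lg <- log(counts)
  ref <- rowMeans(lg)
  use <- is.finite(ref)
  if (!any(use)) stop("no transcript with positive counts in all libraries")
  sf <- apply(counts[use, , drop = FALSE], 2L, function(col)
    exp(median(log(col) - ref[use])))
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test for two conditions
#'
#' For each transcript, size-factor-normalized counts give group means
#' `mean_a`, `mean_b`; a method-of-moments dispersion (variance =
#' mu + alpha mu^2) is estimated from the pooled within-group variance and
#' shrunk toward the transcriptome-wide median (`alpha* = (w0 * median +
#' df * alpha_hat) / (w0 + df)`, `w0 = 10`, `df` the within-group degrees of
#' freedom), then the Wald statistic
#' `z = log(mean_a / mean_b) / sqrt((1/mean_a + alpha)/n_a +
#' (1/mean_b + alpha)/n_b)` is referred to the standard normal, two-sided.
#' Counts are expected to be strictly positive (apply a pseudocount first).
#'
#' @param counts transcripts x libraries matrix of (pseudocounted) counts.
#' @param group factor of length `ncol(counts)` with exactly two levels; the
#'   first level is condition "a".
#' @return A `data.table` with columns `transcript_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `dispersion`, `p_value`.
#' @export
nb_wald_engine <- function(counts, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  a <- which(group == levels(group)[1L])
  b <- which(group == levels(group)[2L])
  n_a <- length(a); n_b <- length(b)
  if (n_a < 2L || n_b < 2L) stop("need >= 2 replicates per condition")
  sf <- size_factors_mor(counts)
  y <- sweep(counts, 2L, sf, "/")
  m_a <- rowMeans(y[, a, drop = FALSE])
  m_b <- rowMeans(y[, b, drop = FALSE])
  v_a <- apply(y[, a, drop = FALSE], 1L, stats::var)
  v_b <- apply(y[, b, drop = FALSE], 1L, stats::var)
  df <- n_a + n_b - 2L
  s2 <- ((n_a - 1L) * v_a + (n_b - 1L) * v_b) / df
  mu <- (n_a * m_a + n_b * m_b) / (n_a + n_b)
  alpha_hat <- pmax(0, (s2 - mu) / mu^2)
  w0 <- 10
  alpha <- (w0 * median(alpha_hat) + df * alpha_hat) / (w0 + df)
  se <- sqrt((1 / m_a + alpha) / n_a + (1 / m_b + alpha) / n_b)
  z <- (log(m_a) - log(m_b)) / se
  data.table(transcript_id = rownames(counts), mean_a = m_a, mean_b = m_b,
             log2fc = log2(m_a / m_b), dispersion = alpha,
             p_value = 2 * pnorm(-abs(z)))
}
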