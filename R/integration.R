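## Integrated summary tables and in-paper arithmetic.

#' Protein category vocabulary
#' @export
PROTEIN_CATEGORIES <- c("Latrotoxin", "Latrodectin", "CRISP", "ICK",
                        "Protease", "OtherEnzyme", "LRR", "Uncharacterized",
                        "NovelFamily", "NoHit")

#' Default keyword rules for toxin/other categories
#'
#' Ordered first-match-wins rules mapping homology-description keywords
#' (case-insensitive regular expressions) to categories.  User-editable:
#' pass your own table to [categorize()].
#'
#' @return A `data.table` with columns `pattern`, `category`.
#' @export
default_keyword_rules <- function() {
  data.table(
    pattern = c("latrotoxin", "latrodectin",
                "crisp|cysteine-rich secretory",
                "\\bick\\b|cystine knot|knottin",
                "protease|proteinase|peptidase|metalloprot",
                "lipase|amylase|hyaluronidase|chitinase|esterase|enzyme",
                "leucine-rich repeat|\\blrr\\b",
                "novel family",
                "uncharacterized|hypothetical|unknown"),
    category = c("Latrotoxin", "Latrodectin", "CRISP", "ICK", "Protease",
                 "OtherEnzyme", "LRR", "NovelFamily", "Uncharacterized"))
}

#' Assign a protein category from a homology label
#'
#' First matching keyword rule wins; an absent (`NA`) label gives `NoHit`;
#' a label matching no rule gives `Uncharacterized`.  Category assignment
#' from free-text homology descriptions is inherently heuristic.
#'
#' @param homology_label character vector of best-hit descriptions (`NA` for
#'   none).
#' @param keyword_rules ordered rule table (`pattern`, `category`); default
#'   [default_keyword_rules()].
#' @return Character vector of categories from [PROTEIN_CATEGORIES].
#' @export
categorize <- function(homology_label,
                       keyword_rules = default_keyword_rules()) {
  out <- rep("Uncharacterized", length(homology_label))
  matched <- logical(length(homology_label))
  for (i in seq_len(nrow(keyword_rules))) {
    hit <- !matched & !is.na(homology_label) &
      grepl(keyword_rules$pattern[i], homology_label, ignore.case = TRUE)
    out[hit] <- keyword_rules$category[i]
    matched <- matched | hit
  }
  out[is.na(homology_label)] <- "NoHit"
  out
}

#' Pooled two-proportion chi-square test
#'
#' Without continuity correction: with pooled proportion
#' `p = (k1 + k2) / (n1 + n2)`, the statistic is
#' `(k1/n1 - k2/n2)^2 / (p (1 - p) (1/n1 + 1/n2))`, referred to chi-square
#' with 1 df.  Degenerate pooled proportions (0 or 1) give statistic 0.
#'
#' @param k1,n1 successes and trials in sample 1.
#' @param k2,n2 successes and trials in sample 2.
#' @return List with `statistic`, `df` (always 1) and `p_value`.
#' @export
two_proportion_chisq <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p <- (k1 + k2) / (n1 + n2)
  stat <- if (p <= 0 || p >= 1) 0
          else (k1 / n1 - k2 / n2)^2 / (p * (1 - p) * (1 / n1 + 1 / n2))
  list(statistic = stat, df = 1L, p_value = pchisq(stat, 1L,
                                                   lower.tail = FALSE))
}

#' Percentage rounded half-up to one decimal
#'
#' @param k numerator (integer count).
#' @param n positive denominator.
#' @return `100 * k / n` rounded half-up to one decimal.
#' @export
report_percent <- function(k, n) {
  if (any(n == 0)) stop("denominator must be non-zero")
  .round1(100 * k / n)
}

#' Per-category venom inventory table
#'
#' For each protein category: the minimum and maximum number of proteins in
#' venom (from the identification structure), the number of upregulated
#' transcripts of that category, and the number of proteins both in venom and
#' from an upregulated transcript.  `n_both` uses the maximum-estimate member
#' set: every distinct member sequence whose transcript is in the upregulated
#' set counts.
#'
#' An identification's category is the category of its first member's
#' transcript; fixtures and real inventories group homologous proteins, so
#' members are expected to share a category (a mixed group raises an error).
#'
#' @param identifications list from [infer_identifications()].
#' @param vgtup character vector of upregulated transcript ids.
#' @param categories named character vector: transcript id -> category, for
#'   every transcript of interest (identification members and upregulated
#'   transcripts).
#' @param protein_tx named character vector: protein id -> transcript id
#'   (identity when protein ids are transcript ids).
#' @param protein_seqs named character vector of member sequences, used to
#'   count distinct members in the maximum estimate.
#' @return A `data.table` with one row per category: `category`, `min_in_venom`,
#'   `max_in_venom`, `n_vgtup`, `n_both`.
#' @export
build_table1 <- function(identifications, vgtup, categories, protein_tx,
                         protein_seqs) {
  tab <- data.table(category = PROTEIN_CATEGORIES, min_in_venom = 0L,
                    max_in_venom = 0L, n_vgtup = 0L, n_both = 0L)
  setkey(tab, category)
  for (ident in identifications) {
    members <- ident$member_protein_ids
    txs <- protein_tx[members]
    if (anyNA(txs))
      stop("identification member(s) with no transcript link: ",
           paste(members[is.na(txs)], collapse = ", "))
    cats <- categories[txs]
    if (anyNA(cats))
      stop("transcript(s) with no category: ",
           paste(txs[is.na(cats)], collapse = ", "))
    if (length(unique(cats)) > 1L)
      stop("identification mixes categories: ",
           paste(unique(cats), collapse = ", "))
    cat1 <- cats[1L]
    ## one representative member per distinct sequence (maximum estimate)
    rep_members <- members[!duplicated(unname(protein_seqs[members]))]
    tab[cat1, min_in_venom := min_in_venom + 1L]
    tab[cat1, max_in_venom := max_in_venom + length(rep_members)]
    tab[cat1, n_both := n_both +
          sum(protein_tx[rep_members] %in% vgtup)]
  }
  vg_cats <- categories[intersect(vgtup, names(categories))]
  vt <- table(vg_cats)
  for (cc in names(vt)) tab[cc, n_vgtup := n_vgtup + as.integer(vt[[cc]])]
  setkey(tab, NULL)
  tab[match(PROTEIN_CATEGORIES, category)]
}

#' Per-gene summary rows
#'
#' Joins the per-gene contribution summary with locus homology labels and
#' categories into rows shaped like a per-locus report (gene, homology label,
#' transcripts / distinct proteins / proteins in venom).
#'
#' @param loci list of `GeneLocus` objects.
#' @param contribution table from [gene_contribution_summary()].
#' @return A `data.table` with columns `gene_id`, `homology_label`,
#'   `category`, `n_transcripts`, `n_distinct_proteins`,
#'   `n_unambiguously_in_venom`, `n_possibly_in_venom`.
#' @export
build_table2 <- function(loci, contribution) {
  lab <- data.table(
    gene_id = vapply(loci, `[[`, "", "gene_id"),
    homology_label = vapply(loci, `[[`, "", "homology_label"))
  lab[, category := categorize(homology_label)]
  out <- merge(lab, contribution, by = "gene_id", sort = FALSE)
  out[]
}
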