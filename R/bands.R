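# Association of KOG classes and categories with the four human
# chromosomal band types L1+, L1-, H3-, H3+ (ordered by increasing GC).

BAND_LEVELS <- c("L1+", "L1-", "H3-", "H3+")

#' Load a gene-to-band-type mapping
#'
#' @param path TSV with columns `gene_id`, `band` (one of `L1+`, `L1-`,
#'   `H3-`, `H3+`), or a data.frame with those columns.
#' @return A data.frame with `gene_id` and `band` (factor in GC order).
#' @export
load_band_map <- function(path) {
  map <- if (is.data.frame(path)) path else read_tsv(path)
  if (!all(c("gene_id", "band") %in% names(map)))
    stop_kog("band map must have columns gene_id, band", "kogGC3_parse_error")
  bad <- setdiff(unique(as.character(map$band)), BAND_LEVELS)
  if (length(bad))
    stop_kog(sprintf("invalid band label(s): %s", paste(bad, collapse = ", ")),
             "kogGC3_invalid_band")
  data.frame(gene_id = as.character(map$gene_id),
             band = factor(map$band, levels = BAND_LEVELS))
}

#' Band coverage of a gene set
#'
#' @param records Gene records (needs `id`).
#' @param band_map A [load_band_map()] table.
#' @return Fraction of the records' genes with a band assignment.
#' @export
band_coverage <- function(records, band_map) {
  mean(records$id %in% band_map$gene_id)
}

#' Class-by-band count table and frequency profiles
#'
#' @param records Labeled gene records (`id`, `kog_class`).
#' @param band_map A [load_band_map()] table.
#' @return A list with `counts` (classes x 4 bands), `class_profiles`
#'   (rows sum to 1: each class's distribution over bands), and
#'   `band_composition` (columns sum to 1: each band's composition by
#'   class, the denominator used by the proportion Z-tests).
#' @export
band_frequencies <- function(records, band_map) {
  idx <- match(records$id, band_map$gene_id)
  keep <- !is.na(idx) & !is.na(records$kog_class)
  if (!any(keep))
    stop_kog("no gene with both class and band assignment", "kogGC3_empty_input")
  counts <- table(kog_class = records$kog_class[keep],
                  band = band_map$band[idx[keep]])
  counts <- unclass(counts)[, BAND_LEVELS, drop = FALSE]
  class_profiles <- counts / rowSums(counts)
  band_composition <- sweep(counts, 2, colSums(counts), "/")
  list(counts = counts, class_profiles = class_profiles,
       band_composition = band_composition)
}

#' Category-by-band chi-square test
#'
#' Pearson chi-square (no continuity correction) of a categories x bands
#' count table, canonically the 3 categories against the two GC-richest
#' band types H3- and H3+ (df = 2).
#'
#' @param counts Numeric count matrix (categories x bands).
#' @return A list with `chi2`, `df`, `p`, `expected`.
#' @export
category_band_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_kog("zero marginal in the contingency table", "kogGC3_degenerate_table")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  if (any(ct$expected < 5))
    warn_kog("expected count < 5 in some cell: chi-square approximation weak",
             "kogGC3_small_expected")
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Two-proportion Z-test for a class's band frequency
#'
#' Pooled one-sided Z-test comparing a class's share of one band's genes
#' against its share of another band's genes, with pooled proportion
#' (k1+k2)/(n1+n2) and no continuity correction.
#'
#' @param k1,n1 Class genes and total genes in the first band.
#' @param k2,n2 Class genes and total genes in the second band.
#' @param alternative `"greater"` (default): first proportion greater;
#'   or `"less"`.
#' @return A list with `z`, `p` (one-sided), `p1`, `p2`.
#' @examples
#' class_proportion_ztest(30, 100, 10, 100)$z  # ~3.54
#' @export
class_proportion_ztest <- function(k1, n1, k2, n2,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (n1 <= 0 || n2 <= 0)
    stop_kog("band totals must be positive", "kogGC3_bad_argument")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
  list(z = z, p = p, p1 = p1, p2 = p2)
}

#' Positive- vs negative-group band distribution
#'
#' Partitions the classes by the sign of their butterfly delta, tabulates
#' each group's share of every band's genes, and runs a one-tailed Z-test
#' of whether the positive group's share is higher in H3+ than in L1+.
#'
#' @param butterfly A [butterfly_analysis()] table.
#' @param records Labeled gene records (`id`, `kog_class`).
#' @param band_map A [load_band_map()] table.
#' @return A list with `group_shares` (2 x 4 matrix, columns sum to 1),
#'   `counts`, and `test` (z, p for positive group H3+ vs L1+).
#' @export
group_band_comparison <- function(butterfly, records, band_map) {
  sign_of <- setNames(ifelse(butterfly$delta > 0, "positive", "negative"),
                      butterfly$kog_class)
  if (!all(c("positive", "negative") %in% sign_of))
    stop_kog("one of the butterfly sign groups is empty",
             "kogGC3_empty_group")
  idx <- match(records$id, band_map$gene_id)
  keep <- !is.na(idx) & records$kog_class %in% names(sign_of)
  grp <- factor(sign_of[records$kog_class[keep]],
                levels = c("negative", "positive"))
  band <- band_map$band[idx[keep]]
  counts <- unclass(table(group = grp, band = band))[, BAND_LEVELS, drop = FALSE]
  shares <- sweep(counts, 2, colSums(counts), "/")
  test <- class_proportion_ztest(counts["positive", "H3+"], sum(counts[, "H3+"]),
                                 counts["positive", "L1+"], sum(counts[, "L1+"]),
                                 alternative = "greater")
  list(group_shares = shares, counts = counts, test = test)
}
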