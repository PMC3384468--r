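# Within-genome Blue/Black/Red GC3 comparisons, between-genome GC3
# increments over ortholog pairs, and coding/non-coding GC correlations.

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The exact null distribution is used
#' when `min(n, m) <= 8` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (`x` versus `y`).
#' @return A list with `U` (the U statistic of `x`), `p`, `method`
#'   (`"exact"` or `"normal"`), and `alternative`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop_kog("mann_whitney requires two non-empty samples", "kogGC3_empty_input")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal",
       alternative = alternative)
}

#' Test the Blue < Black < Red GC3 hierarchy within one genome
#'
#' Two-sided Mann-Whitney comparisons of gene-level GC3 between each pair
#' of categories, with the direction read from the sample means. The
#' verdict is `"PATTERN"` when all three comparisons are significant at
#' `alpha` and the means are ordered Blue < Black < Red; `"PARTIAL"` when
#' Red significantly exceeds both Blue and Black but Black and Blue do not
#' differ significantly (the marsupial/monotreme situation); `"NONE"`
#' otherwise. No multiple-testing correction is applied across the three
#' tests; interpret the three p-values jointly.
#'
#' @param records Labeled gene records with `gc3` and `category`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `kog_hierarchy`: list with `comparisons`
#'   (data.frame: pair, U, p, direction), `means`, `verdict`, `alpha`.
#' @export
category_hierarchy_test <- function(records, alpha = 0.05) {
  rec <- records[!is.na(records$category) &
                   records$category %in% c("BLUE", "BLACK", "RED"), ]
  smp <- split(rec$gc3, factor(rec$category, levels = c("BLUE", "BLACK", "RED")))
  if (any(lengths(smp) == 0L))
    stop_kog(sprintf("missing category: %s",
                     paste(names(smp)[lengths(smp) == 0], collapse = ", ")),
             "kogGC3_missing_category")
  means <- vapply(smp, mean, numeric(1))
  pairs <- list(c("RED", "BLACK"), c("RED", "BLUE"), c("BLACK", "BLUE"))
  cmp <- do.call(rbind, lapply(pairs, function(pr) {
    mw <- mann_whitney(smp[[pr[1]]], smp[[pr[2]]], "two.sided")
    data.frame(pair = paste(pr, collapse = "-"),
               U = mw$U, p = mw$p,
               direction = if (means[pr[1]] >= means[pr[2]]) pr[1] else pr[2])
  }))
  sig <- cmp$p < alpha
  ordered_means <- means["BLUE"] < means["BLACK"] && means["BLACK"] < means["RED"]
  red_top <- means["RED"] > means["BLACK"] && means["RED"] > means["BLUE"]
  verdict <- if (all(sig) && ordered_means) "PATTERN"
  else if (sig[1] && sig[2] && !sig[3] && red_top) "PARTIAL"
  else "NONE"
  structure(list(comparisons = cmp, means = means, verdict = verdict,
                 alpha = alpha, n = lengths(smp)),
            class = "kog_hierarchy")
}

#' @exportS3Method print kog_hierarchy
print.kog_hierarchy <- function(x, ...) {
  cat("GC3 category hierarchy test (two-sided Mann-Whitney)\n")
  cat(sprintf("  means: Blue %.4f (n=%d)  Black %.4f (n=%d)  Red %.4f (n=%d)\n",
              x$means["BLUE"], x$n["BLUE"], x$means["BLACK"], x$n["BLACK"],
              x$means["RED"], x$n["RED"]))
  for (i in seq_len(nrow(x$comparisons)))
    cat(sprintf("  %-10s U = %.1f  p = %.3g  higher: %s\n",
                x$comparisons$pair[i], x$comparisons$U[i],
                x$comparisons$p[i], x$comparisons$direction[i]))
  cat(sprintf("  verdict: %s (alpha = %g, uncorrected)\n", x$verdict, x$alpha))
  invisible(x)
}

#' GC3 increment between orthologous genomes
#'
#' For each ortholog pair, delta = GC3(reference gene) - GC3(target gene),
#' grouped by the reference gene's category; per-category mean and
#' standard error, plus two-sided Mann-Whitney tests of the Red deltas
#' against Black and against Blue.
#'
#' @param pairs Ortholog pairs ([best_reciprocal_hits()]); only `ref_id`,
#'   `target_id` are used.
#' @param ref_records,target_records Labeled ([label_records()]) and plain
#'   gene-record tables; category labels are taken from `ref_records`.
#' @return A list with `deltas` (data.frame: ref_id, target_id, category,
#'   delta), `summary` (per category: n, mean_delta, se_delta), `tests`
#'   (Red-Black, Red-Blue), and `degenerate` (TRUE when every delta is 0,
#'   in which case no tests are run).
#' @export
delta_gc3 <- function(pairs, ref_records, target_records) {
  ri <- match(pairs$ref_id, ref_records$id)
  ti <- match(pairs$target_id, target_records$id)
  if (any(is.na(ri)) || any(is.na(ti)))
    stop_kog("pair references a gene absent from the records",
             "kogGC3_unknown_gene")
  deltas <- data.frame(ref_id = pairs$ref_id,
                       target_id = pairs$target_id,
                       category = ref_records$category[ri],
                       delta = ref_records$gc3[ri] - target_records$gc3[ti])
  deltas <- deltas[!is.na(deltas$category), , drop = FALSE]
  grp <- split(deltas$delta, deltas$category)
  summary <- data.frame(
    category = names(grp),
    n = lengths(grp),
    mean_delta = vapply(grp, mean, numeric(1)),
    se_delta = vapply(grp, function(d)
      if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_, numeric(1)),
    row.names = NULL)
  degenerate <- all(deltas$delta == 0)
  tests <- NULL
  if (!degenerate && all(c("RED", "BLACK", "BLUE") %in% names(grp))) {
    tests <- list(red_vs_black = mann_whitney(grp$RED, grp$BLACK, "two.sided"),
                  red_vs_blue = mann_whitney(grp$RED, grp$BLUE, "two.sided"))
  }
  list(deltas = deltas, summary = summary, tests = tests,
       degenerate = degenerate)
}

#' Correlations between coding and non-coding GC
#'
#' Pairwise Pearson and Spearman correlations (with p-values) over genes
#' with complete values, typically GC3 versus intron GC and flanking-region
#' GC.
#'
#' @param tab A data.frame of numeric columns (e.g. `gc3`, `gc_intron`,
#'   `gc_flank`); rows with any `NA` are dropped.
#' @return A list with `n` and, for each of `pearson` and `spearman`,
#'   matrices `r` and `p`.
#' @export
gc_correlations <- function(tab) {
  tab <- tab[complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 3L)
    stop_kog("gc_correlations requires at least 3 complete rows",
             "kogGC3_empty_input")
  vars <- names(tab)
  k <- length(vars)
  out <- lapply(c(pearson = "pearson", spearman = "spearman"), function(meth) {
    r <- diag(1, k); p <- matrix(NA_real_, k, k)
    dimnames(r) <- dimnames(p) <- list(vars, vars)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ct <- suppressWarnings(cor.test(tab[[i]], tab[[j]], method = meth))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
    list(r = r, p = p)
  })
  c(out, list(n = nrow(tab)))
}
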