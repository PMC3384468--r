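# Per-class deviation of mean GC3 from the genome mean ("butterfly plot"
# tables) and cross-genome recurrence of positive classes.

#' Genome-wide mean GC3
#'
#' The genome mean is taken over all available coding sequences when the
#' full set is supplied; otherwise it falls back to the KOG-classified
#' subset with a warning.
#'
#' @param kog_records Gene records of the KOG-classified subset.
#' @param all_records Optional gene records of the full CDS set.
#' @return The mean GC3.
#' @export
genome_mean_gc3 <- function(kog_records, all_records = NULL) {
  if (!is.null(all_records) && nrow(all_records) > 0L)
    return(mean(all_records$gc3))
  if (is.null(kog_records) || nrow(kog_records) == 0L)
    stop_kog("no records to average", "kogGC3_empty_input")
  warn_kog("full CDS set not supplied: genome mean computed on the KOG subset",
           "kogGC3_kog_subset_mean")
  mean(kog_records$gc3)
}

#' Butterfly analysis: class deviations from the genome mean
#'
#' For each KOG class, delta = class mean GC3 - genome mean GC3, with a
#' two-sided one-sample t-test of the class's gene-level GC3 against the
#' genome mean (treated as a constant) and Bonferroni correction over the
#' retained classes. Entries are sorted ascending by delta, so negative
#' classes cluster on the left wing and positive on the right. A class
#' with zero variance reports its delta sign but no p-value.
#'
#' @param records Labeled gene records (`gc3`, `kog_class`, `category`).
#' @param genome_mean Genome-wide mean GC3 ([genome_mean_gc3()]).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A data.frame of class `kog_butterfly`: `kog_class`, `category`,
#'   `n`, `delta`, `t`, `p_raw`, `p_bonferroni`, `significant_higher`.
#'   Classes with fewer than 2 genes are excluded with a warning.
#' @export
butterfly_analysis <- function(records, genome_mean, alpha = 0.05) {
  rec <- records[!is.na(records$kog_class), , drop = FALSE]
  grp <- split(rec$gc3, rec$kog_class)
  small <- names(grp)[lengths(grp) < 2L]
  if (length(small)) {
    warn_kog(sprintf("excluding class(es) with n < 2: %s",
                     paste(small, collapse = ", ")), "kogGC3_small_class")
    grp <- grp[lengths(grp) >= 2L]
  }
  if (!length(grp))
    stop_kog("no class with n >= 2", "kogGC3_empty_input")
  m <- length(grp)
  catalog <- kog_classes()
  rows <- lapply(names(grp), function(cl) {
    x <- grp[[cl]]
    delta <- mean(x) - genome_mean
    if (sd(x) == 0) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      tt <- t.test(x, mu = genome_mean, alternative = "two.sided")
    }
    p_bonf <- min(1, tt$p.value * m)
    data.frame(kog_class = cl,
               category = catalog$category[match(cl, catalog$letter)],
               n = length(x), delta = delta,
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_bonferroni = p_bonf,
               significant_higher = isTRUE(delta > 0 && !is.na(p_bonf) &&
                                             p_bonf < alpha))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delta), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "genome_mean") <- genome_mean
  class(out) <- c("kog_butterfly", "data.frame")
  out
}

#' Cross-genome recurrence of butterfly signs
#'
#' Percentage of genomes in which each class lies on the positive side of
#' the butterfly plot, and in which it is significantly higher.
#'
#' @param entries A named list of [butterfly_analysis()] tables, one per
#'   genome (>= 2 genomes).
#' @return A data.frame: `kog_class`, `category`, `n_genomes`,
#'   `pct_positive`, `pct_significant_higher`.
#' @export
butterfly_recurrence <- function(entries) {
  if (length(entries) < 2L)
    stop_kog("recurrence needs at least two genomes", "kogGC3_empty_input")
  all <- do.call(rbind, lapply(names(entries), function(g) {
    e <- as.data.frame(entries[[g]])
    e$genome <- g
    e
  }))
  grp <- split(all, all$kog_class)
  out <- do.call(rbind, lapply(grp, function(e)
    data.frame(kog_class = e$kog_class[1], category = e$category[1],
               n_genomes = nrow(e),
               pct_positive = 100 * mean(e$delta > 0),
               pct_significant_higher = 100 * mean(e$significant_higher))))
  rownames(out) <- NULL
  out[order(out$kog_class), ]
}
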