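# Ternary (de Finetti) occupancy of the three categories per genome and
# the class-label permutation test of the Red category's confinement to
# the high-GC3 corner.

#' Split the GC3 range of class means into Low / Medium / High intervals
#'
#' The range spanned by the per-class mean GC3 values of one genome is
#' split into three intervals of equal width. Intervals are half-open
#' `[a, b)` except the last, which is closed; a mean exactly on an
#' interior boundary belongs to the upper interval.
#'
#' @param class_means Numeric vector of per-class mean GC3 (>= 2 classes).
#' @return Numeric vector of 4 breakpoints.
#' @export
gc3_intervals <- function(class_means) {
  if (length(class_means) < 2L)
    stop_kog("need at least two class means", "kogGC3_empty_input")
  lo <- min(class_means); hi <- max(class_means)
  if (lo == hi)
    stop_kog("all class means equal: GC3 range degenerate",
             "kogGC3_degenerate_range")
  seq(lo, hi, length.out = 4L)
}

#' Assign values to the Low / Medium / High intervals
#'
#' @param x Numeric values within the interval range.
#' @param breaks Breakpoints from [gc3_intervals()].
#' @return Factor with levels `Low`, `Medium`, `High`.
#' @export
assign_interval <- function(x, breaks) {
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx < 1L] <- 1L; idx[idx > 3L] <- 3L
  factor(c("Low", "Medium", "High")[idx], levels = c("Low", "Medium", "High"))
}

#' Ternary occupancy points of the categories
#'
#' For each category, the fraction of its functional classes falling in
#' the Low, Medium and High GC3 intervals — the coordinates of the
#' category's point on a de Finetti diagram.
#'
#' @param class_summary Per-class summary (data.frame with `kog_class`,
#'   `category`, `mean_gc3`), e.g. `summarize_by_class(...)$classes`.
#' @param genome Genome label attached to the output.
#' @param breaks Optional breakpoints; computed from the class means when
#'   omitted.
#' @return A data.frame: `genome`, `category`, `p_low`, `p_med`, `p_high`,
#'   `n_classes`; the three proportions sum to 1.
#' @export
ternary_points <- function(class_summary, genome = "genome", breaks = NULL) {
  if (is.null(breaks)) breaks <- gc3_intervals(class_summary$mean_gc3)
  iv <- assign_interval(class_summary$mean_gc3, breaks)
  cats <- unique(class_summary$category)
  out <- do.call(rbind, lapply(cats, function(cc) {
    sel <- class_summary$category == cc
    if (!any(sel))
      stop_kog(sprintf("category %s has no classes", cc), "kogGC3_empty_input")
    tab <- table(iv[sel])
    n <- sum(sel)
    data.frame(genome = genome, category = cc,
               p_low = unname(tab["Low"]) / n,
               p_med = unname(tab["Medium"]) / n,
               p_high = unname(tab["High"]) / n,
               n_classes = n)
  }))
  rownames(out) <- NULL
  out
}

#' Confinement statistic of the Red category
#'
#' Scalar summary of how strongly the Red (metabolism) points sit toward
#' the High-GC3 vertex across genomes. The default statistic is the mean
#' over genomes of `p_high - p_low` (1 = fully confined to High, 0 =
#' symmetric, negative = toward Low). The alternative `"dist_low"` is the
#' mean Euclidean distance of the Red point from the Low vertex (1, 0, 0).
#'
#' @param points Ternary points of the Red category across genomes
#'   (data.frame with `p_low`, `p_med`, `p_high`).
#' @param statistic `"high_minus_low"` (default) or `"dist_low"`.
#' @return The scalar statistic.
#' @export
confinement_statistic <- function(points,
                                  statistic = c("high_minus_low", "dist_low")) {
  statistic <- match.arg(statistic)
  if (statistic == "high_minus_low")
    mean(points$p_high - points$p_low)
  else
    mean(sqrt((points$p_low - 1)^2 + points$p_med^2 + points$p_high^2))
}

#' Permutation test of the Red category's ternary confinement
#'
#' Holds each genome's class-to-interval assignments fixed and permutes
#' the category labels over classes within each genome (preserving
#' category sizes), recomputing the Red points and the confinement
#' statistic each time. The p-value uses the add-one estimator
#' `p = (1 + #{S_perm >= S_obs}) / (n_perm + 1)`, which never returns 0.
#'
#' @param class_table A data.frame with one row per (genome, class):
#'   columns `genome`, `kog_class`, `category`, and either `interval`
#'   (factor Low/Medium/High) or `mean_gc3` (intervals computed per
#'   genome).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (required; the null is Monte-Carlo).
#' @param statistic Passed to [confinement_statistic()].
#' @return An object of class `kog_permutation`: list with
#'   `observed_stat`, `null_stats`, `p_value`, `n_perm`, `seed`,
#'   `statistic`.
#' @export
definetti_permutation_test <- function(class_table, n_perm = 1000L, seed,
                                       statistic = c("high_minus_low", "dist_low")) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop_kog("n_perm must be >= 1", "kogGC3_bad_argument")
  if (missing(seed)) stop_kog("seed is required", "kogGC3_bad_argument")
  if (is.null(class_table$interval)) {
    # rows sorted by genome so the per-genome interval vectors concatenate
    # back in row order
    class_table <- class_table[order(class_table$genome), ]
    class_table$interval <- unlist(lapply(
      split(seq_len(nrow(class_table)), class_table$genome), function(i)
        as.character(assign_interval(class_table$mean_gc3[i],
                                     gc3_intervals(class_table$mean_gc3[i])))),
      use.names = FALSE)
  }
  genomes <- split(class_table, class_table$genome)
  # compact per-genome representation: integer interval codes + red mask
  pre <- lapply(genomes, function(g) {
    list(iv = match(as.character(g$interval), c("Low", "Medium", "High")),
         n_red = sum(g$category == "RED"),
         red = which(g$category == "RED"))
  })
  if (any(vapply(pre, function(g) g$n_red, integer(1)) == 0L))
    stop_kog("every genome needs at least one RED class", "kogGC3_empty_input")
  stat_one <- function(iv_red, n_red) {
    p_low <- sum(iv_red == 1L) / n_red
    p_med <- sum(iv_red == 2L) / n_red
    p_high <- sum(iv_red == 3L) / n_red
    if (statistic == "high_minus_low") p_high - p_low
    else sqrt((p_low - 1)^2 + p_med^2 + p_high^2)
  }
  red_stat <- function(perm) {
    mean(vapply(pre, function(g) {
      idx <- if (perm) sample.int(length(g$iv), g$n_red) else g$red
      stat_one(g$iv[idx], g$n_red)
    }, numeric(1)))
  }
  observed <- red_stat(perm = FALSE)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) red_stat(perm = TRUE), numeric(1))
  })
  p <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p, n_perm = n_perm, seed = seed,
                 statistic = statistic),
            class = "kog_permutation")
}

#' @exportS3Method print kog_permutation
print.kog_permutation <- function(x, ...) {
  cat("Ternary confinement permutation test\n")
  cat(sprintf("  statistic (%s): observed S = %.4f\n", x$statistic, x$observed_stat))
  cat(sprintf("  p = %.4g  (%d permutations, add-one estimator, seed %d)\n",
              x$p_value, x$n_perm, x$seed))
  invisible(x)
}
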