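# Gene -> KOG class mapping, the published filtering rules, and per-class /
# per-category summaries.

#' Load a gene-to-KOG-class mapping table
#'
#' Reads a TSV with columns `gene_id` and `class_letters` (comma-separated
#' when a gene sits in several classes). Rows are retained verbatim,
#' including multi-class genes; filtering is a separate, explicit step
#' ([apply_kog_filters()]).
#'
#' @param path Path to the mapping TSV, or a data.frame with those columns.
#' @return A data.frame with columns `gene_id`, `class_letters`.
#' @export
load_kog_map <- function(path) {
  map <- if (is.data.frame(path)) path else read_tsv(path)
  if (!all(c("gene_id", "class_letters") %in% names(map)))
    stop_kog("mapping must have columns gene_id, class_letters",
             "kogGC3_parse_error")
  map$class_letters <- gsub(" ", "", map$class_letters)
  letters_used <- unique(unlist(strsplit(map$class_letters, ",", fixed = TRUE)))
  known <- kog_classes()$letter
  bad <- setdiff(letters_used, known)
  if (length(bad)) {
    rows <- map$gene_id[vapply(strsplit(map$class_letters, ",", fixed = TRUE),
                               function(x) any(x %in% bad), logical(1))]
    stop_kog(sprintf("unknown KOG class letter(s) %s in rows: %s",
                     paste(bad, collapse = ", "),
                     paste(utils::head(rows, 10), collapse = ", ")),
             "kogGC3_unknown_class")
  }
  map[, c("gene_id", "class_letters")]
}

#' Apply the KOG dataset filtering rules
#'
#' Three rules, applied in order: (i) genes classified in more than one
#' class are removed; (ii) the poorly characterized classes R (function
#' prediction only) and S (function unknown) are removed; (iii) classes
#' whose remaining gene count is below `min_class_size` are removed
#' (strictly less than: a class of exactly `min_class_size` genes
#' survives). Rule (iii) counts genes after rules (i)-(ii).
#'
#' @param map A data.frame from [load_kog_map()].
#' @param min_class_size Minimum retained class size (default 100).
#' @return An object of class `kog_filter_report`: a list with `map` (the
#'   filtered single-class mapping, columns `gene_id`, `kog_class`,
#'   `category`) and `report` (per-rule removal counts and the fractions
#'   removed on both the full and the post-multi-class denominator).
#' @export
apply_kog_filters <- function(map, min_class_size = 100L) {
  catalog <- kog_classes()
  n_input <- nrow(map)
  classes <- strsplit(map$class_letters, ",", fixed = TRUE)

  multi <- lengths(classes) > 1L
  n_multi <- sum(multi)
  map1 <- data.frame(gene_id = map$gene_id[!multi],
                     kog_class = unlist(classes[!multi], use.names = FALSE) %||% character(0))
  if (n_input == 0L) map1 <- data.frame(gene_id = character(0), kog_class = character(0))

  rs <- map1$kog_class %in% c("R", "S")
  n_rs <- sum(rs)
  map2 <- map1[!rs, , drop = FALSE]

  counts <- table(factor(map2$kog_class, levels = catalog$letter))
  small_classes <- names(counts)[counts > 0 & counts < min_class_size]
  small <- map2$kog_class %in% small_classes
  n_small <- sum(small)
  map3 <- map2[!small, , drop = FALSE]
  map3$category <- catalog$category[match(map3$kog_class, catalog$letter)]
  rownames(map3) <- NULL

  report <- list(
    n_input = n_input,
    removed_multi_class = n_multi,
    removed_rs = n_rs,
    removed_small_classes = n_small,
    small_classes = small_classes,
    n_retained = nrow(map3),
    frac_rs_of_input = if (n_input) n_rs / n_input else NA_real_,
    frac_rs_of_single = if (nrow(map1)) n_rs / nrow(map1) else NA_real_,
    min_class_size = min_class_size,
    empty_result = nrow(map3) == 0L
  )
  structure(list(map = map3, report = report), class = "kog_filter_report")
}

#' @exportS3Method print kog_filter_report
print.kog_filter_report <- function(x, ...) {
  r <- x$report
  cat("KOG filter report\n")
  cat(sprintf("  input genes:            %d\n", r$n_input))
  cat(sprintf("  removed multi-class:    %d\n", r$removed_multi_class))
  cat(sprintf("  removed R/S:            %d (%.1f%% of input)\n",
              r$removed_rs, 100 * r$frac_rs_of_input))
  cat(sprintf("  removed small classes:  %d (%s)\n", r$removed_small_classes,
              paste(r$small_classes, collapse = ", ")))
  cat(sprintf("  retained:               %d\n", r$n_retained))
  invisible(x)
}

#' Attach KOG class and category labels to gene records
#'
#' @param records A [gene_records()] table.
#' @param map A filtered mapping (`$map` of [apply_kog_filters()], or any
#'   data.frame with `gene_id`, `kog_class`).
#' @return `records` with `kog_class` and `category` columns; genes absent
#'   from the map get `NA`.
#' @export
label_records <- function(records, map) {
  idx <- match(records$id, map$gene_id)
  records$kog_class <- map$kog_class[idx]
  catalog <- kog_classes()
  records$category <- catalog$category[match(records$kog_class, catalog$letter)]
  records
}

#' Per-class and per-category GC3 summaries
#'
#' @param records Labeled gene records (see [label_records()]); rows with
#'   `NA` class are ignored.
#' @return A list with `classes` (one row per class: `kog_class`,
#'   `category`, `n`, `mean_gc3`, `sd_gc3`) and `categories` (per-category
#'   roll-up pooled over member genes, equal to the count-weighted mean of
#'   the class means).
#' @export
summarize_by_class <- function(records) {
  rec <- records[!is.na(records$kog_class), , drop = FALSE]
  if (nrow(rec) == 0L)
    stop_kog("no labeled records to summarize", "kogGC3_empty_input")
  catalog <- kog_classes()
  cl <- split(rec$gc3, rec$kog_class)
  classes <- data.frame(
    kog_class = names(cl),
    category = catalog$category[match(names(cl), catalog$letter)],
    n = vapply(cl, length, integer(1)),
    mean_gc3 = vapply(cl, mean, numeric(1)),
    sd_gc3 = vapply(cl, function(x) if (length(x) > 1) sd(x) else 0, numeric(1)),
    row.names = NULL)
  ca <- split(rec$gc3, rec$category)
  categories <- data.frame(
    category = names(ca),
    n = vapply(ca, length, integer(1)),
    mean_gc3 = vapply(ca, mean, numeric(1)),
    sd_gc3 = vapply(ca, function(x) if (length(x) > 1) sd(x) else 0, numeric(1)),
    row.names = NULL)
  list(classes = classes[order(classes$kog_class), ],
       categories = categories)
}
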