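# Best-reciprocal-hit orthology between a reference and a target proteome,
# and transfer of KOG class labels across the pairs.
#
# The builtin scorer is a seeded local aligner: a shared-3-mer prefilter
# narrows each query to a handful of candidate subjects, which are then
# aligned with Smith-Waterman (BLOSUM62, gap open 11 / extend 1). A
# Karlin-Altschul-style pseudo-evalue E = K * m * n_db * exp(-lambda * S)
# (gapped BLOSUM62 constants lambda = 0.267, K = 0.041) is attached for
# thresholding; it is a monotone transform of the score, not a calibrated
# BLAST e-value. Precomputed search results in 12-column tabular format
# (BLAST outfmt 6) can be imported instead.

#' Translate coding sequences to protein
#'
#' Standard genetic code; a terminal stop codon is trimmed, an internal
#' stop is an error.
#'
#' @param seq Character vector of validated CDS (length divisible by 3).
#' @return Character vector of amino-acid sequences.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(seq) {
  if (any(nchar(seq) %% 3L != 0L))
    stop_kog("translation requires lengths divisible by 3", "kogGC3_frame_error")
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(seq),
                                           if.fuzzy.codon = "solve"))
  aa <- sub("\\*$", "", aa)
  internal <- grepl("\\*", aa)
  if (any(internal))
    stop_kog(sprintf("internal stop codon in %d sequence(s)", sum(internal)),
             "kogGC3_internal_stop")
  aa
}

# Sparse protein 3-mer count matrix (rows = sequences) over a shared
# k-mer dictionary; used only as an alignment candidate prefilter.
kmer_matrix <- function(seqs, k = 3L, dict = NULL) {
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  })
  if (is.null(dict)) dict <- unique(unlist(kmers, use.names = FALSE))
  i <- rep.int(seq_along(kmers), lengths(kmers))
  j <- match(unlist(kmers, use.names = FALSE), dict)
  keep <- !is.na(j)
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(length(seqs), length(dict)))
  list(m = m, dict = dict)
}

pseudo_evalue <- function(score, qlen, db_residues, lambda = 0.267, K = 0.041) {
  K * qlen * db_residues * exp(-lambda * score)
}

#' All-vs-all protein similarity search (builtin scorer)
#'
#' For each query, candidate subjects are ranked by shared-3-mer counts and
#' the top `n_candidates` are aligned locally (Smith-Waterman, BLOSUM62).
#' Hits with pseudo-evalue above `evalue_floor` are not emitted.
#'
#' @param queries,subjects Named character vectors (or data.frames with
#'   `id` and `protein` columns) of amino-acid sequences.
#' @param n_candidates Alignment candidates per query (default 5).
#' @param evalue_floor Hits with larger pseudo-evalue are dropped
#'   (default 10, mirroring common search-tool report thresholds).
#' @return A data.frame of hits: `query_id`, `subject_id`, `score`,
#'   `evalue`, sorted within query by decreasing score.
#' @seealso [read_tabular_hits()] for importing external search output.
#' @export
all_vs_all_search <- function(queries, subjects, n_candidates = 5L,
                              evalue_floor = 10) {
  q <- as_protein_vector(queries)
  s <- as_protein_vector(subjects)
  if (length(q) == 0L || length(s) == 0L)
    stop_kog("empty query or subject set", "kogGC3_empty_input")
  km_s <- kmer_matrix(s)
  km_q <- kmer_matrix(q, dict = km_s$dict)
  shared <- as.matrix(Matrix::tcrossprod(km_q$m, km_s$m))  # queries x subjects
  db_residues <- sum(nchar(s))
  utils::data(list = "BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())

  # top shared-kmer candidates per query, then all alignments in one
  # elementwise batch
  cand <- lapply(seq_along(q), function(i) {
    sc <- shared[i, ]
    top <- order(sc, decreasing = TRUE)[seq_len(min(n_candidates, length(sc)))]
    top[sc[top] > 0 | seq_along(top) == 1L]
  })
  qi <- rep(seq_along(q), lengths(cand))
  si <- unlist(cand, use.names = FALSE)
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(q[qi]), Biostrings::AAStringSet(s[si]),
    type = "local", substitutionMatrix = blosum,
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  ev <- pseudo_evalue(scores, nchar(q)[qi], db_residues)
  keep <- ev <= evalue_floor
  hits <- data.frame(query_id = names(q)[qi][keep],
                     subject_id = names(s)[si][keep],
                     score = scores[keep], evalue = ev[keep])
  hits <- hits[order(hits$query_id, -hits$score, hits$evalue, hits$subject_id), ]
  rownames(hits) <- NULL
  hits
}

as_protein_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "protein") %in% names(x)))
    return(setNames(x$protein, x$id))
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop_kog("protein sequences must be named by gene id", "kogGC3_parse_error")
  x
}

#' Import 12-column tabular search hits
#'
#' Reads the standard 12-column tab-separated search format (qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore), e.g. BLAST `-outfmt 6`.
#'
#' @param path Path to the tabular file.
#' @return A data.frame of hits: `query_id`, `subject_id`, `score`
#'   (bitscore), `evalue`.
#' @export
read_tabular_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- tryCatch(
    read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop_kog(
      sprintf("malformed tabular hits '%s': %s", path, conditionMessage(e)),
      "kogGC3_parse_error"))
  if (ncol(tab) != 12L)
    stop_kog(sprintf("expected 12 tab-separated columns, found %d", ncol(tab)),
             "kogGC3_parse_error")
  names(tab) <- cols
  if (!is.numeric(tab$evalue) || !is.numeric(tab$bitscore))
    stop_kog("evalue/bitscore columns are not numeric", "kogGC3_parse_error")
  data.frame(query_id = as.character(tab$qseqid),
             subject_id = as.character(tab$sseqid),
             score = tab$bitscore, evalue = tab$evalue)
}

# Best hit per query with deterministic tie-breaking (score desc, evalue
# asc, subject_id lexicographic). A query with several distinct subjects at
# the exact best (score, evalue) is dropped: no unique best hit.
best_hits <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), evalue = numeric(0)))
  hits <- hits[order(hits$query_id, -hits$score, hits$evalue, hits$subject_id), ]
  n <- nrow(hits)
  fi <- which(!duplicated(hits$query_id))
  si <- fi + 1L
  ok <- si <= n
  si2 <- pmin(si, n)
  # runner-up belongs to the same query and ties the best on (score, evalue)
  # with a different subject -> no unique best hit for that query
  tied <- ok &
    hits$query_id[si2] == hits$query_id[fi] &
    hits$score[si2] == hits$score[fi] &
    hits$evalue[si2] == hits$evalue[fi] &
    hits$subject_id[si2] != hits$subject_id[fi]
  best <- hits[fi[!tied], , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Best reciprocal hits
#'
#' Keeps a pair (a, b) iff b is a's unique best forward hit, a is b's
#' unique best reverse hit, and both e-values are below `evalue_max`.
#' Ties for best (equal score and e-value, distinct subjects) drop the
#' query from pairing. The result is a partial matching: each id occurs in
#' at most one pair.
#'
#' @param forward Hits reference -> target ([all_vs_all_search()] or
#'   [read_tabular_hits()] output).
#' @param reverse Hits target -> reference.
#' @param evalue_max E-value threshold (default `1e-5`).
#' @return A data.frame of pairs: `ref_id`, `target_id`, `fwd_score`,
#'   `fwd_evalue`, `rev_score`, `rev_evalue`.
#' @export
best_reciprocal_hits <- function(forward, reverse, evalue_max = 1e-5) {
  fwd <- best_hits(forward[forward$evalue < evalue_max, , drop = FALSE])
  rev <- best_hits(reverse[reverse$evalue < evalue_max, , drop = FALSE])
  key_f <- paste(fwd$query_id, fwd$subject_id, sep = "\r")
  key_r <- paste(rev$subject_id, rev$query_id, sep = "\r")
  m <- match(key_f, key_r)
  keep <- !is.na(m)
  pairs <- data.frame(ref_id = fwd$query_id[keep],
                      target_id = fwd$subject_id[keep],
                      fwd_score = fwd$score[keep],
                      fwd_evalue = fwd$evalue[keep],
                      rev_score = rev$score[m[keep]],
                      rev_evalue = rev$evalue[m[keep]])
  pairs <- pairs[order(pairs$ref_id), ]
  rownames(pairs) <- NULL
  pairs
}

#' Transfer KOG class labels across ortholog pairs
#'
#' Each target gene acquires the KOG class of its reference partner;
#' unpaired or unlabeled targets are absent from the output.
#'
#' @param pairs Output of [best_reciprocal_hits()].
#' @param ref_map Filtered reference mapping (columns `gene_id`,
#'   `kog_class`).
#' @return A data.frame with columns `gene_id` (target), `kog_class`,
#'   `category`, `ref_id`.
#' @export
transfer_labels <- function(pairs, ref_map) {
  idx <- match(pairs$ref_id, ref_map$gene_id)
  keep <- !is.na(idx)
  catalog <- kog_classes()
  cls <- ref_map$kog_class[idx[keep]]
  data.frame(gene_id = pairs$target_id[keep],
             kog_class = cls,
             category = catalog$category[match(cls, catalog$letter)],
             ref_id = pairs$ref_id[keep],
             row.names = NULL)
}
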