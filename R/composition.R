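# Per-sequence base composition. GC is the molar fraction of G+C over
# unambiguous bases; GC3 the same restricted to third codon positions.
# Ambiguity code N is excluded from numerator and denominator of both.

#' Read a coding-sequence FASTA file
#'
#' Reads nucleotide CDS from FASTA. The first whitespace-delimited token of
#' each header is taken as the gene id; ids must be unique within the file.
#' Empty records are dropped with a warning.
#'
#' @param path Path to a FASTA file.
#' @param species Species tag attached to every record.
#' @return A data.frame with columns `id`, `species`, `seq` (upper-case).
#' @seealso [write_cds_fasta()], [validate_cds()]
#' @export
read_cds_fasta <- function(path, species) {
  if (!file.exists(path))
    stop_kog(sprintf("FASTA file not found: %s", path), "kogGC3_io_error")
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop_kog(
      sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
      "kogGC3_parse_error"))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop_kog(sprintf("FASTA '%s': record with empty id", path), "kogGC3_parse_error")
  empty <- Biostrings::width(set) == 0L
  if (any(empty)) {
    warn_kog(sprintf("FASTA '%s': skipping %d empty record(s): %s", path,
                     sum(empty), paste(ids[empty], collapse = ", ")),
             "kogGC3_empty_record")
    set <- set[!empty]; ids <- ids[!empty]
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_kog(sprintf("FASTA '%s': duplicate id(s): %s", path,
                     paste(dup, collapse = ", ")), "kogGC3_duplicate_id")
  data.frame(id = ids, species = species,
             seq = toupper(as.character(set)), row.names = NULL)
}

#' Write coding sequences as FASTA
#'
#' @param cds A data.frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  set <- Biostrings::DNAStringSet(cds$seq)
  names(set) <- cds$id
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Validate coding sequences
#'
#' Checks the nucleotide alphabet ({A,C,G,T,N}) and codon framing. Under
#' `policy = "strict"` a length not divisible by 3 is an error; under
#' `policy = "truncate"` the trailing 1-2 nt are dropped with a warning
#' (real CDS annotations occasionally carry a partial terminal codon).
#'
#' @param cds A data.frame as returned by [read_cds_fasta()].
#' @param policy `"strict"` (default) or `"truncate"`.
#' @return The validated (possibly truncated) data.frame.
#' @export
validate_cds <- function(cds, policy = c("strict", "truncate")) {
  policy <- match.arg(policy)
  bad_alpha <- grepl("[^ACGTN]", cds$seq)
  if (any(bad_alpha))
    stop_kog(sprintf("invalid characters outside {A,C,G,T,N} in: %s",
                     paste(cds$id[bad_alpha], collapse = ", ")),
             "kogGC3_alphabet_error")
  len <- nchar(cds$seq)
  off <- len %% 3L != 0L
  if (any(off)) {
    if (policy == "strict")
      stop_kog(sprintf("CDS length not divisible by 3 for: %s",
                       paste(cds$id[off], collapse = ", ")),
               "kogGC3_frame_error")
    warn_kog(sprintf("truncating trailing partial codon of %d sequence(s): %s",
                     sum(off), paste(cds$id[off], collapse = ", ")),
             "kogGC3_truncated")
    cds$seq[off] <- substr(cds$seq[off], 1L, len[off] - len[off] %% 3L)
  }
  too_short <- nchar(cds$seq) < 3L
  if (any(too_short))
    stop_kog(sprintf("CDS shorter than one codon: %s",
                     paste(cds$id[too_short], collapse = ", ")),
             "kogGC3_frame_error")
  cds
}

count_letters <- function(seq, letters) {
  x <- Biostrings::DNAStringSet(seq)
  f <- Biostrings::letterFrequency(x, letters = letters)
  f
}

#' GC content of nucleotide sequences
#'
#' Fraction (G+C)/(A+C+G+T); N excluded from numerator and denominator.
#'
#' @param seq Character vector of validated nucleotide sequences.
#' @return Numeric vector in `[0, 1]`. A sequence with no unambiguous base
#'   yields `NA` with a classed warning (`kogGC3_undefined_composition`).
#' @examples
#' gc_content(c("GCGC", "ATAT", "ACGTN"))  # 1, 0, 0.5
#' @export
gc_content <- function(seq) {
  f <- count_letters(seq, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  out <- (f[, "G"] + f[, "C"]) / denom
  if (any(denom == 0))
    warn_kog("sequence(s) with no unambiguous base: GC undefined (NA)",
             "kogGC3_undefined_composition")
  unname(out)
}

third_positions <- function(seq) {
  n <- nchar(seq)
  vapply(seq_along(seq), function(i) {
    idx <- seq.int(3L, n[i], by = 3L)
    paste(substring(seq[i], idx, idx), collapse = "")
  }, character(1))
}

#' GC3: GC content at third codon positions
#'
#' Fraction of third-codon-position bases that are G or C; third-position
#' Ns are excluded from the denominator. All codons count, including a
#' terminal stop codon if present.
#'
#' @param seq Character vector of validated sequences, each a multiple of
#'   3 nt long.
#' @return Numeric vector in `[0, 1]`; `NA` (with a classed warning) when a
#'   sequence has no countable third position.
#' @examples
#' gc3_content(c("ATG", "ATGAAA"))  # 1, 0.5
#' @export
gc3_content <- function(seq) {
  if (any(nchar(seq) %% 3L != 0L))
    stop_kog("gc3 requires lengths divisible by 3 (run validate_cds first)",
             "kogGC3_frame_error")
  thirds <- third_positions(seq)
  f <- count_letters(thirds, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  if (any(denom == 0))
    warn_kog("sequence(s) with no countable third position: GC3 undefined (NA)",
             "kogGC3_undefined_composition")
  unname((f[, "G"] + f[, "C"]) / denom)
}

#' Per-gene composition records
#'
#' Computes GC, GC3 and codon counts for a set of validated CDS, the
#' per-gene table every downstream stage consumes.
#'
#' @param cds A validated CDS data.frame (see [validate_cds()]).
#' @return A data.frame with columns `id`, `species`, `n_codons`, `gc`,
#'   `gc3`.
#' @export
gene_records <- function(cds) {
  data.frame(id = cds$id,
             species = cds$species,
             n_codons = nchar(cds$seq) %/% 3L,
             gc = gc_content(cds$seq),
             gc3 = gc3_content(cds$seq),
             row.names = NULL)
}

#' Summary statistics of a gene-record table
#'
#' @param records A data.frame with a `gc3` column (and optionally `gc`).
#' @return A list with `n`, `mean_gc3`, `sd_gc3` (sample sd, n-1
#'   denominator; 0 with `degenerate = TRUE` when n = 1), `mean_gc`.
#' @export
dataset_summary <- function(records) {
  if (is.null(records) || nrow(records) < 1L)
    stop_kog("dataset_summary requires at least one record", "kogGC3_empty_input")
  n <- nrow(records)
  list(n = n,
       mean_gc3 = mean(records$gc3),
       sd_gc3 = if (n > 1L) sd(records$gc3) else 0,
       mean_gc = if ("gc" %in% names(records)) mean(records$gc) else NA_real_,
       degenerate = n == 1L)
}

#' Write a per-gene composition table as TSV
#'
#' @param records Output of [gene_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_records <- function(records, path) {
  write_tsv(records[, c("id", "species", "n_codons", "gc", "gc3")], path)
}
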