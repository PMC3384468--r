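# Synthetic genomes with planted per-class GC3 structure, diverged
# ortholog sets and GC3-dependent band maps. Every generator is a pure
# function of (spec, seed): identical inputs give identical output.
#
# Sequences are built codon-wise from sense codons: the first two codon
# positions are drawn from the 14 dinucleotides that cannot start a stop
# codon (TA and TG excluded), so any third base keeps the codon sense. The
# requested GC3 is realized exactly (round(target * n_codons) G/C third
# positions); stochasticity enters only through the Normal draw of the
# per-gene targets.

SAFE_DUETS <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
                "GA", "GC", "GG", "GT", "TC", "TT")

#' Build a CDS with an exact GC3
#'
#' Constructs `n_codons` sense codons whose third positions contain
#' exactly `round(target * n_codons)` G or C bases; the result contains no
#' internal stop codon.
#'
#' @param target Desired GC3 in `[0, 1]`.
#' @param n_codons Number of codons (>= 1).
#' @param seed Optional integer seed; when omitted the current RNG stream
#'   is used.
#' @return A nucleotide string of length `3 * n_codons`.
#' @examples
#' gc3_content(sequence_from_gc3(0.5, 100, seed = 1))  # exactly 0.5
#' @export
sequence_from_gc3 <- function(target, n_codons, seed = NULL) {
  if (target < 0 || target > 1)
    stop_kog("target GC3 must be in [0, 1]", "kogGC3_bad_argument")
  if (n_codons < 1L)
    stop_kog("n_codons must be >= 1", "kogGC3_bad_argument")
  build <- function() {
    k <- round(target * n_codons)
    thirds <- sample(c("A", "T"), n_codons, replace = TRUE)
    if (k > 0L) {
      gc_pos <- sample.int(n_codons, k)
      thirds[gc_pos] <- sample(c("G", "C"), k, replace = TRUE)
    }
    duets <- sample(SAFE_DUETS, n_codons, replace = TRUE)
    paste0(paste0(duets, thirds), collapse = "")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Specify a synthetic genome
#'
#' @param species Species tag.
#' @param classes A data.frame with columns `letter`, `n`, `mu`, `sigma`:
#'   per-class gene count and the mean / sd of the Normal from which
#'   per-gene GC3 targets are drawn (truncated to `[0.02, 0.98]`).
#' @param n_codons CDS length in codons (>= 10, default 120).
#' @param seed Integer seed (mandatory).
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(species, classes, n_codons = 120L, seed) {
  if (missing(seed)) stop_kog("seed is mandatory", "kogGC3_bad_argument")
  stopifnot(all(c("letter", "n", "mu", "sigma") %in% names(classes)))
  if (any(classes$n < 0) || any(classes$mu <= 0) || any(classes$mu >= 1) ||
      any(classes$sigma <= 0))
    stop_kog("invalid class parameters (need n >= 0, 0 < mu < 1, sigma > 0)",
             "kogGC3_bad_argument")
  if (n_codons < 10L)
    stop_kog("n_codons must be >= 10", "kogGC3_bad_argument")
  structure(list(species = species, classes = classes,
                 n_codons = as.integer(n_codons), seed = as.integer(seed)),
            class = "genome_spec")
}

#' Reference-shaped genome specification
#'
#' A [genome_spec()] whose class sizes, GC3 means and standard deviations
#' are the published human per-class values, restricted to the 20 classes
#' that survive the dataset filters. `scale` shrinks all class sizes
#' proportionally (minimum 2 genes per class) for fast tests.
#'
#' @param species Species tag (default `"synthetic_human"`).
#' @param scale Multiplier on class sizes (default 1).
#' @param n_codons CDS length in codons.
#' @param seed Integer seed (mandatory).
#' @return A `genome_spec`.
#' @export
table1_spec <- function(species = "synthetic_human", scale = 1,
                        n_codons = 120L, seed) {
  cat <- kog_classes()
  keep <- cat$category != "POORLY_CHARACTERIZED" & !(cat$letter %in% c("M", "N", "Y"))
  cl <- data.frame(letter = cat$letter[keep],
                   n = pmax(2L, as.integer(round(cat$ref_n[keep] * scale))),
                   mu = cat$ref_mean_gc3[keep],
                   sigma = cat$ref_sd_gc3[keep])
  genome_spec(species, cl, n_codons = n_codons, seed = seed)
}

rnorm_trunc <- function(n, mu, sigma, lo = 0.02, hi = 0.98) {
  x <- rnorm(n, mu, sigma)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- rnorm(sum(bad), mu, sigma)
  x
}

#' Generate a labeled synthetic genome
#'
#' Draws per-gene GC3 targets Normal(mu, sigma) truncated to
#' `[0.02, 0.98]` for each class and realizes each as a CDS with exactly
#' that (rounded) GC3.
#'
#' @param spec A [genome_spec()].
#' @param sequences Realize each target as a CDS (default). With
#'   `FALSE`, only the truth table is produced — `gc3` is then the value a
#'   realized CDS would have (`round(target * n_codons) / n_codons`) —
#'   which keeps large value-level simulation studies cheap.
#' @return A list with `cds` (data.frame `id`, `species`, `seq`; `NULL`
#'   when `sequences = FALSE`), `truth` (data.frame `id`, `kog_class`,
#'   `category`, `gc3_target`, `gc3`), and `map` (a
#'   [load_kog_map()]-shaped gene-to-class table).
#' @export
generate_genome <- function(spec, sequences = TRUE) {
  stopifnot(inherits(spec, "genome_spec"))
  catalog <- kog_classes()
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(spec$classes)), function(i) {
      cl <- spec$classes[i, ]
      if (cl$n == 0L) return(NULL)
      targets <- rnorm_trunc(cl$n, cl$mu, cl$sigma)
      ids <- sprintf("%s_%s_%04d", spec$species, cl$letter, seq_len(cl$n))
      seqs <- if (sequences)
        vapply(targets, sequence_from_gc3, character(1),
               n_codons = spec$n_codons)
      truth <- data.frame(id = ids, kog_class = cl$letter,
                          category = catalog$category[
                            match(cl$letter, catalog$letter)],
                          gc3_target = targets,
                          gc3 = round(targets * spec$n_codons) / spec$n_codons)
      list(cds = if (sequences)
        data.frame(id = ids, species = spec$species, seq = seqs),
        truth = truth)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    cds <- do.call(rbind, lapply(rows, `[[`, "cds"))
    truth <- do.call(rbind, lapply(rows, `[[`, "truth"))
    rownames(truth) <- NULL
    if (!is.null(cds)) rownames(cds) <- NULL
    list(cds = cds, truth = truth,
         map = data.frame(gene_id = truth$id, class_letters = truth$kog_class))
  })
}

# Third-base choice that keeps the codon sense given its first two bases.
pick_third <- function(duet, want_gc) {
  opts <- if (want_gc) c("G", "C") else c("A", "T")
  if (duet == "TA") opts <- setdiff(opts, c("A", "G"))  # TAA/TAG stops
  if (duet == "TG") opts <- setdiff(opts, "A")          # TGA stop
  if (length(opts) == 1L) opts else sample(opts, 1L)
}

mutate_one <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    codon_start <- p - (p - 1L) %% 3L
    for (b in sample(setdiff(c("A", "C", "G", "T"), chars[p]))) {
      old <- chars[p]
      chars[p] <- b
      codon <- paste0(chars[codon_start + 0:2], collapse = "")
      if (!codon %in% c("TAA", "TAG", "TGA")) break
      chars[p] <- old
    }
  }
  paste0(chars, collapse = "")
}

shift_gc3 <- function(seq, delta) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars) %/% 3L
  t_idx <- 3L * seq_len(n)
  thirds <- chars[t_idx]
  is_gc <- thirds %in% c("G", "C")
  k <- sum(is_gc)
  k2 <- max(0L, min(n, as.integer(round(k + delta * n))))
  if (k2 > k) {
    flip <- sample(which(!is_gc), k2 - k)
  } else if (k2 < k) {
    flip <- sample(which(is_gc), k - k2)
  } else flip <- integer(0)
  for (i in flip) {
    duet <- paste0(chars[t_idx[i] - 2:1], collapse = "")
    chars[t_idx[i]] <- pick_third(duet, want_gc = !is_gc[i])
  }
  paste0(chars, collapse = "")
}

#' Derive a diverged ortholog genome
#'
#' Copies each CDS of a genome with random substitutions at
#' `substitution_rate` (codon-aware: a substitution never creates a stop
#' codon) and, optionally, re-balances third positions so that the copy's
#' GC3 shifts by the planted per-category increment. Returns the true
#' pairing for best-reciprocal-hit recovery tests.
#'
#' @param genome Output of [generate_genome()].
#' @param substitution_rate Per-base substitution probability in
#'   `[0, 0.5)`.
#' @param delta_gc3_by_category Optional named numeric vector (names in
#'   BLUE/BLACK/RED): GC3 of the copy = GC3 of the source + delta, so the
#'   reference-minus-target increment equals `-delta`.
#' @param seed Integer seed.
#' @param species Species tag of the derived genome.
#' @return A list with `cds`, `truth` (as in [generate_genome()], plus the
#'   realized `gc3_target` after shifting), and `pairs` (data.frame
#'   `ref_id`, `target_id`).
#' @export
mutate_orthologs <- function(genome, substitution_rate = 0.02,
                             delta_gc3_by_category = NULL, seed,
                             species = "synthetic_target") {
  if (substitution_rate < 0 || substitution_rate >= 0.5)
    stop_kog("substitution_rate must be in [0, 0.5)", "kogGC3_bad_argument")
  if (missing(seed)) stop_kog("seed is mandatory", "kogGC3_bad_argument")
  with_seed(seed, {
    src <- genome$cds
    truth <- genome$truth
    target_ids <- sprintf("%s_%04d", species, seq_len(nrow(src)))
    seqs <- vapply(src$seq, mutate_one, character(1), rate = substitution_rate,
                   USE.NAMES = FALSE)
    if (!is.null(delta_gc3_by_category)) {
      dd <- delta_gc3_by_category[truth$category]
      dd[is.na(dd)] <- 0
      seqs <- vapply(seq_along(seqs), function(i)
        shift_gc3(seqs[i], dd[i]), character(1))
    }
    list(cds = data.frame(id = target_ids, species = species, seq = seqs),
         truth = data.frame(id = target_ids, kog_class = truth$kog_class,
                            category = truth$category),
         pairs = data.frame(ref_id = src$id, target_id = target_ids))
  })
}

#' Add unrelated decoy sequences to a CDS set
#'
#' Decoys are independent random sense-codon sequences with GC3 drawn
#' uniformly; they have no planted ortholog and should never appear in a
#' best-reciprocal-hit pair.
#'
#' @param cds A CDS data.frame.
#' @param n Number of decoys.
#' @param n_codons Decoy length in codons.
#' @param seed Integer seed.
#' @param prefix Id prefix (default `"decoy"`).
#' @return The CDS data.frame with decoys appended.
#' @export
add_decoys <- function(cds, n, n_codons = 120L, seed, prefix = "decoy") {
  with_seed(seed, {
    decoys <- data.frame(
      id = sprintf("%s_%04d", prefix, seq_len(n)),
      species = cds$species[1],
      seq = vapply(runif(n), sequence_from_gc3, character(1),
                   n_codons = n_codons))
    rbind(cds, decoys)
  })
}

#' Generate a GC3-dependent chromosomal band map
#'
#' Each gene's band is drawn from a 4-way categorical distribution whose
#' log-odds toward GC-richer band types increase linearly with the gene's
#' GC3: `P(band b | gc3 g) ~ exp(slope * s_b * (g - 0.5))` with band
#' scores `s = (-0.5, -1/6, 1/6, 0.5)` over (L1+, L1-, H3-, H3+). Slope 0
#' gives uniform bands.
#'
#' @param records Gene records with `id` and `gc3`.
#' @param slope Log-odds slope (default 6, a clear but noisy gradient).
#' @param seed Integer seed.
#' @return A data.frame `gene_id`, `band` (as [load_band_map()] returns).
#' @export
generate_band_map <- function(records, slope = 6, seed) {
  if (missing(seed)) stop_kog("seed is mandatory", "kogGC3_bad_argument")
  s <- c(-0.5, -1/6, 1/6, 0.5)
  with_seed(seed, {
    g <- records$gc3 - 0.5
    logit <- outer(g, s) * slope
    pr <- exp(logit)
    pr <- pr / rowSums(pr)
    band <- apply(pr, 1L, function(p) sample(BAND_LEVELS, 1L, prob = p))
    data.frame(gene_id = records$id,
               band = factor(band, levels = BAND_LEVELS))
  })
}
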