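test_that("translation follows the standard code and rejects internal stops", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_error(translate_cds("ATGTAAAAA"), class = "kogGC3_internal_stop")
})

test_that("synthetic CDS translate to full-length proteins with no stop", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    s <- sequence_from_gc3(runif(1), n)
    aa <- translate_cds(s)
    expect_equal(nchar(aa), n)  # generator never emits stop codons
    expect_false(grepl("\\*", aa))
  }
})

make_proteins <- function(n, len = 80, seed = 1) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, setNames(
    vapply(1:n, function(i) paste0(sample(aa20, len, TRUE), collapse = ""),
           character(1)),
    sprintf("p%03d", 1:n)))
}

test_that("identical sequences dominate the builtin search", {
  prots <- make_proteins(10)
  hits <- all_vs_all_search(prots, prots)
  for (id in names(prots)) {
    h <- hits[hits$query_id == id, ]
    expect_equal(h$subject_id[which.max(h$score)], id)
    expect_lt(h$evalue[which.max(h$score)], 1e-5)
  }
})

test_that("dissimilar sequences yield no hit below the e-value floor", {
  q <- c(q1 = paste(rep("K", 60), collapse = ""))
  s <- c(s1 = paste(rep("W", 60), collapse = ""),
         s2 = paste(rep("G", 60), collapse = ""))
  hits <- all_vs_all_search(q, s, evalue_floor = 1e-5)
  expect_equal(nrow(hits), 0)
})

test_that("tabular import reads the 12-column search format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t98.5\t100\t1\t0\t1\t100\t1\t100\t1e-50\t190",
               "q2\ts2\t80.0\t90\t18\t0\t1\t90\t1\t90\t1e-20\t120"), f)
  hits <- read_tabular_hits(f)
  expect_equal(hits$query_id, c("q1", "q2"))
  expect_equal(hits$score, c(190, 120))
  expect_equal(hits$evalue, c(1e-50, 1e-20))

  writeLines("q1\ts1\t90", f)
  expect_error(read_tabular_hits(f), class = "kogGC3_parse_error")
})

hit_df <- function(...) {
  rows <- list(...)
  data.frame(query_id = vapply(rows, `[[`, "", 1),
             subject_id = vapply(rows, `[[`, "", 2),
             score = as.numeric(vapply(rows, `[[`, "", 3)),
             evalue = as.numeric(vapply(rows, `[[`, "", 4)))
}

test_that("BRH requires reciprocity and unique best hits", {
  fwd <- hit_df(c("a1", "b1", "100", "1e-30"), c("a2", "b2", "90", "1e-25"))
  rev <- hit_df(c("b1", "a1", "100", "1e-30"), c("b2", "a9", "95", "1e-28"))
  pairs <- best_reciprocal_hits(fwd, rev)
  expect_equal(pairs$ref_id, "a1")
  expect_equal(pairs$target_id, "b1")

  # a true tie for best drops the query from pairing
  fwd2 <- hit_df(c("a1", "b1", "100", "1e-30"), c("a1", "b2", "100", "1e-30"))
  rev2 <- hit_df(c("b1", "a1", "100", "1e-30"))
  expect_equal(nrow(best_reciprocal_hits(fwd2, rev2)), 0)

  # e-value threshold is strict
  fwd3 <- hit_df(c("a1", "b1", "100", "1e-5"))
  expect_equal(nrow(best_reciprocal_hits(fwd3, rev)), 0)
})

test_that("BRH of a set against itself pairs every sequence with itself", {
  prots <- make_proteins(10)
  hits <- all_vs_all_search(prots, prots)
  pairs <- best_reciprocal_hits(hits, hits)
  expect_equal(nrow(pairs), 10)
  expect_equal(pairs$ref_id, pairs$target_id)
})

test_that("BRH is symmetric and a partial matching", {
  g <- generate_genome(genome_spec("ref", data.frame(
    letter = "J", n = 40L, mu = 0.55, sigma = 0.1), n_codons = 60L, seed = 21))
  tgt <- mutate_orthologs(g, 0.05, seed = 22, species = "tgt")
  qp <- setNames(translate_cds(g$cds$seq), g$cds$id)
  sp <- setNames(translate_cds(tgt$cds$seq), tgt$cds$id)
  fwd <- all_vs_all_search(qp, sp)
  rev <- all_vs_all_search(sp, qp)
  pairs <- best_reciprocal_hits(fwd, rev)
  swapped <- best_reciprocal_hits(rev, fwd)
  expect_setequal(paste(pairs$ref_id, pairs$target_id),
                  paste(swapped$target_id, swapped$ref_id))
  expect_equal(anyDuplicated(pairs$ref_id), 0)
  expect_equal(anyDuplicated(pairs$target_id), 0)
})

test_that("planted ortholog pairs are recovered amid decoys", {
  g <- generate_genome(genome_spec("ref", data.frame(
    letter = c("J", "P"), n = c(30L, 30L), mu = c(0.5, 0.65),
    sigma = c(0.1, 0.1)), n_codons = 100L, seed = 31))
  tgt <- mutate_orthologs(g, 0.02, seed = 32, species = "tgt")
  tgt$cds <- add_decoys(tgt$cds, 20, n_codons = 100L, seed = 33)
  qp <- setNames(translate_cds(g$cds$seq), g$cds$id)
  sp <- setNames(translate_cds(tgt$cds$seq), tgt$cds$id)
  pairs <- best_reciprocal_hits(all_vs_all_search(qp, sp),
                                all_vs_all_search(sp, qp))
  truth <- paste(tgt$pairs$ref_id, tgt$pairs$target_id)
  found <- paste(pairs$ref_id, pairs$target_id)
  expect_gte(mean(truth %in% found), 0.99)
  expect_equal(sum(!found %in% truth), 0)
  expect_false(any(grepl("decoy", pairs$target_id)))
})

test_that("label transfer copies the reference class to paired targets only", {
  pairs <- data.frame(ref_id = c("h1", "h2"), target_id = c("m1", "m2"))
  ref_map <- data.frame(gene_id = c("h1", "h3"), kog_class = c("P", "K"))
  lab <- transfer_labels(pairs, ref_map)
  expect_equal(lab$gene_id, "m1")
  expect_equal(lab$kog_class, "P")
  expect_equal(lab$category, "RED")
  expect_false("m2" %in% lab$gene_id)  # reference partner unlabeled
})

test_that("label transfer across several targets never exceeds reference counts", {
  g <- generate_genome(genome_spec("ref", data.frame(
    letter = c("J", "T", "P"), n = c(15L, 15L, 15L),
    mu = c(0.5, 0.55, 0.6), sigma = rep(0.08, 3)), n_codons = 60L, seed = 41))
  ref_map <- data.frame(gene_id = g$truth$id, kog_class = g$truth$kog_class)
  ref_counts <- table(ref_map$kog_class)
  qp <- setNames(translate_cds(g$cds$seq), g$cds$id)
  for (sd in 1:3) {
    tgt <- mutate_orthologs(g, 0.03, seed = 50 + sd,
                            species = paste0("t", sd))
    sp <- setNames(translate_cds(tgt$cds$seq), tgt$cds$id)
    pairs <- best_reciprocal_hits(all_vs_all_search(qp, sp),
                                  all_vs_all_search(sp, qp))
    lab <- transfer_labels(pairs, ref_map)
    cnt <- table(factor(lab$kog_class, levels = names(ref_counts)))
    expect_true(all(cnt <= ref_counts))
  }
})
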