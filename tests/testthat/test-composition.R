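test_that("FASTA reading parses records, enforces unique ids, skips empties", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "ATGAAA", ">g2", "GGGCCC"), fa)
  cds <- read_cds_fasta(fa, "sp")
  expect_equal(cds$id, c("g1", "g2"))
  expect_equal(cds$seq, c("ATGAAA", "GGGCCC"))
  expect_equal(cds$species, c("sp", "sp"))

  writeLines(c(">g1", "ATG", ">g1", "ATG"), fa)
  expect_error(read_cds_fasta(fa, "sp"), class = "kogGC3_duplicate_id")

  writeLines(c(">g1", "ATG", ">empty", ">g2", "ATG"), fa)
  expect_warning(cds <- read_cds_fasta(fa, "sp"), class = "kogGC3_empty_record")
  expect_equal(cds$id, c("g1", "g2"))
})

test_that("a large synthetic FASTA round-trips through write + read unchanged", {
  g <- generate_genome(genome_spec("rt", data.frame(
    letter = c("J", "P"), n = c(500L, 500L), mu = c(0.5, 0.6),
    sigma = c(0.1, 0.1)), n_codons = 40L, seed = 11))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(g$cds, fa)
  back <- read_cds_fasta(fa, "rt")
  expect_identical(back$id, g$cds$id)
  expect_identical(back$seq, g$cds$seq)
})

test_that("CDS validation enforces frame and alphabet per policy", {
  cds <- data.frame(id = "g1", species = "sp", seq = "ATGAAAT")
  expect_error(validate_cds(cds, "strict"), class = "kogGC3_frame_error")
  expect_warning(out <- validate_cds(cds, "truncate"), class = "kogGC3_truncated")
  expect_equal(out$seq, "ATGAAA")

  bad <- data.frame(id = "g1", species = "sp", seq = "ATGXAA")
  expect_error(validate_cds(bad, "strict"), class = "kogGC3_alphabet_error")
  expect_error(validate_cds(bad, "truncate"), class = "kogGC3_alphabet_error")
})

test_that("GC excludes N from numerator and denominator", {
  expect_equal(gc_content(c("GCGC", "ATAT", "ACGTN")), c(1, 0, 0.5))
  expect_warning(v <- gc_content("NNN"), class = "kogGC3_undefined_composition")
  expect_true(is.na(v))
})

test_that("GC3 counts third positions, excluding third-position Ns", {
  expect_equal(gc3_content(c("ATG", "ATGAAA")), c(1, 0.5))
  # N at a third position drops it from the denominator only
  expect_equal(gc3_content("ATNATGATN"), 1)  # countable thirds: G
  expect_error(gc3_content("ATGA"), class = "kogGC3_frame_error")
  expect_warning(v <- gc3_content("ATNATN"), class = "kogGC3_undefined_composition")
  expect_true(is.na(v))
})

test_that("GC3 agrees exactly with the brute-force third-position counter", {
  set.seed(101)
  seqs <- vapply(1:1000, function(i) {
    n <- 3 * sample(5:100, 1)
    paste0(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                  prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  }, character(1))
  # guard against the rare all-N-thirds draw
  ok <- vapply(seqs, function(s) {
    th <- strsplit(s, "")[[1]][seq(3, nchar(s), 3)]
    any(th != "N")
  }, logical(1))
  seqs <- seqs[ok]
  expect_equal(gc3_content(seqs),
               vapply(seqs, oracle_gc3, numeric(1), USE.NAMES = FALSE))
})

test_that("GC3 of concatenated CDS is the codon-count-weighted mean", {
  set.seed(7)
  for (i in 1:20) {
    s1 <- sequence_from_gc3(runif(1), sample(10:50, 1))
    s2 <- sequence_from_gc3(runif(1), sample(10:50, 1))
    n1 <- nchar(s1) / 3; n2 <- nchar(s2) / 3
    expect_equal(gc3_content(paste0(s1, s2)),
                 (n1 * gc3_content(s1) + n2 * gc3_content(s2)) / (n1 + n2),
                 tolerance = 1e-12)
  }
})

test_that("dataset summaries use sample sd and flag the degenerate case", {
  rec <- data.frame(gc3 = c(0.5, 0.7), gc = c(0.5, 0.6))
  s <- dataset_summary(rec)
  expect_equal(s$mean_gc3, 0.6)
  expect_equal(s$sd_gc3, sd(c(0.5, 0.7)))
  expect_false(s$degenerate)

  s1 <- dataset_summary(data.frame(gc3 = 0.5, gc = 0.5))
  expect_equal(s1$sd_gc3, 0)
  expect_true(s1$degenerate)

  expect_error(dataset_summary(data.frame(gc3 = numeric(0))),
               class = "kogGC3_empty_input")
})

test_that("summary mean of a pooled dataset equals the count-weighted mean of parts", {
  set.seed(13)
  a <- data.frame(gc3 = runif(137), gc = runif(137))
  b <- data.frame(gc3 = runif(311), gc = runif(311))
  pooled <- dataset_summary(rbind(a, b))
  wm <- (137 * dataset_summary(a)$mean_gc3 + 311 * dataset_summary(b)$mean_gc3) / 448
  expect_equal(pooled$mean_gc3, wm, tolerance = 1e-12)
})

test_that("generated GC3 values match truncated-normal moments", {
  g <- generate_genome(genome_spec("tn", data.frame(
    letter = "J", n = 10000L, mu = 0.58, sigma = 0.16),
    n_codons = 120L, seed = 5), sequences = FALSE)
  m_exp <- truncnorm_mean(0.58, 0.16, 0.02, 0.98)
  se <- 0.16 / sqrt(10000)
  expect_lt(abs(mean(g$truth$gc3) - m_exp), 3 * se)
})
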