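test_that("Mann-Whitney matches exhaustive enumeration on small samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")

  set.seed(17)
  for (rep in 1:30) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    x <- sample(1000, n) / 7
    y <- sample(2000, m)[1:m] / 7
    if (anyDuplicated(c(x, y))) next
    mw <- mann_whitney(x, y)
    or <- oracle_mw_exact(x, y)
    expect_equal(mw$U, or$U)
    expect_equal(mw$p, or$p, tolerance = 1e-12)
  }
})

test_that("U statistics of the two orientations sum to n*m", {
  set.seed(23)
  for (rep in 1:10) {
    x <- rnorm(sample(3:40, 1)); y <- rnorm(sample(3:40, 1))
    u1 <- mann_whitney(x, y)$U
    u2 <- mann_whitney(y, x)$U
    expect_equal(u1 + u2, length(x) * length(y))
  }
})

test_that("identical samples give p = 1 and large samples use the normal branch", {
  x <- c(0.5, 0.6, 0.7)
  mw <- mann_whitney(x, x)
  expect_equal(mw$p, 1)
  big <- mann_whitney(rnorm(50), rnorm(50))
  expect_equal(big$method, "normal")
})

test_that("the hierarchy verdict detects a planted Blue < Black < Red pattern", {
  rec <- withr::with_seed(61, records_from_categories(
    rnorm(400, 0.54, 0.05), rnorm(400, 0.58, 0.05), rnorm(400, 0.62, 0.05)))
  h <- category_hierarchy_test(rec)
  expect_s3_class(h, "kog_hierarchy")
  expect_equal(h$verdict, "PATTERN")
  expect_true(all(h$comparisons$p < 0.05))
  expect_output(print(h), "PATTERN")
})

test_that("Red-only elevation gives the PARTIAL verdict", {
  rec <- withr::with_seed(62, records_from_categories(
    rnorm(500, 0.58, 0.05), rnorm(500, 0.58, 0.05), rnorm(500, 0.63, 0.05)))
  h <- category_hierarchy_test(rec)
  expect_equal(h$verdict, "PARTIAL")
})

test_that("the hierarchy test is invariant to row order and location shifts", {
  rec <- withr::with_seed(63, records_from_categories(
    rnorm(200, 0.54, 0.06), rnorm(200, 0.58, 0.06), rnorm(200, 0.62, 0.06)))
  h0 <- category_hierarchy_test(rec)
  h1 <- category_hierarchy_test(rec[sample(nrow(rec)), ])
  rec2 <- rec; rec2$gc3 <- rec2$gc3 + 0.1
  h2 <- category_hierarchy_test(rec2)
  expect_equal(h1$comparisons$p, h0$comparisons$p)
  expect_equal(h2$comparisons$p, h0$comparisons$p)
  expect_equal(h1$verdict, h0$verdict)
  expect_equal(h2$verdict, h0$verdict)

  expect_error(category_hierarchy_test(rec[rec$category != "RED", ]),
               class = "kogGC3_missing_category")
})

test_that("delta GC3 is zero and degenerate for identical genomes", {
  ref <- data.frame(id = c("a", "b"), gc3 = c(0.5, 0.6),
                    category = c("RED", "BLUE"))
  tgt <- data.frame(id = c("x", "y"), gc3 = c(0.5, 0.6))
  pairs <- data.frame(ref_id = c("a", "b"), target_id = c("x", "y"))
  d <- delta_gc3(pairs, ref, tgt)
  expect_true(d$degenerate)
  expect_true(all(d$deltas$delta == 0))
  expect_null(d$tests)

  expect_error(delta_gc3(data.frame(ref_id = "zz", target_id = "x"), ref, tgt),
               class = "kogGC3_unknown_gene")
})

test_that("delta GC3 is antisymmetric under swapping genomes", {
  set.seed(71)
  ref <- data.frame(id = sprintf("r%d", 1:50), gc3 = runif(50),
                    category = sample(c("BLUE", "BLACK", "RED"), 50, TRUE))
  tgt <- data.frame(id = sprintf("t%d", 1:50), gc3 = runif(50),
                    category = ref$category)
  pairs <- data.frame(ref_id = ref$id, target_id = tgt$id)
  fwd <- delta_gc3(pairs, ref, tgt)
  back <- delta_gc3(data.frame(ref_id = tgt$id, target_id = ref$id), tgt, ref)
  expect_equal(fwd$deltas$delta, -back$deltas$delta)
})

test_that("a planted Red increment is detected in the delta comparison", {
  set.seed(72)
  n <- 400
  cats <- rep(c("BLUE", "BLACK", "RED"), each = n)
  ref <- data.frame(id = sprintf("r%d", 1:(3 * n)), gc3 = runif(3 * n, 0.4, 0.7),
                    category = cats)
  shift <- ifelse(cats == "RED", 0.10, 0.05) + rnorm(3 * n, 0, 0.05)
  tgt <- data.frame(id = sprintf("t%d", 1:(3 * n)), gc3 = ref$gc3 - shift)
  d <- delta_gc3(data.frame(ref_id = ref$id, target_id = tgt$id), ref, tgt)
  s <- d$summary
  expect_gt(s$mean_delta[s$category == "RED"],
            s$mean_delta[s$category == "BLACK"])
  expect_lt(d$tests$red_vs_black$p, 0.05)
  expect_lt(d$tests$red_vs_blue$p, 0.05)
})

test_that("coding/non-coding GC correlations behave on constructed data", {
  x <- seq(0.3, 0.8, length.out = 50)
  tab <- data.frame(gc3 = x, gc_intron = 0.5 * x + 0.1, gc_flank = x^3)
  gcc <- gc_correlations(tab)
  expect_equal(gcc$pearson$r["gc3", "gc_intron"], 1)
  # monotone nonlinear: Spearman is perfect, Pearson is not
  expect_equal(gcc$spearman$r["gc3", "gc_flank"], 1)
  expect_lt(gcc$pearson$r["gc3", "gc_flank"], 1)
  expect_error(gc_correlations(tab[1:2, ]), class = "kogGC3_empty_input")
})

test_that("independent columns show near-zero correlation", {
  ok <- withr::with_seed(73, {
    tab <- data.frame(a = rnorm(1000), b = rnorm(1000))
    abs(gc_correlations(tab)$pearson$r["a", "b"]) < 0.1
  })
  expect_true(ok)
})
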