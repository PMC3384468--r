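test_that("the GC3 range splits into three equal intervals with upper-inclusive bounds", {
  br <- gc3_intervals(c(0.40, 0.50, 0.60))
  expect_equal(br, c(0.40, 0.40 + 0.2 / 3, 0.40 + 0.4 / 3, 0.60),
               tolerance = 1e-12)
  iv <- assign_interval(c(0.40, 0.50, 0.60), br)
  expect_equal(as.character(iv), c("Low", "Medium", "High"))
  # a value exactly on an interior boundary goes to the upper interval
  expect_equal(as.character(assign_interval(br[2], br)), "Medium")
  expect_equal(as.character(assign_interval(br[3], br)), "High")
  # endpoints: min always Low, max always High
  expect_equal(as.character(assign_interval(c(br[1], br[4]), br)),
               c("Low", "High"))
  expect_error(gc3_intervals(c(0.5, 0.5)), class = "kogGC3_degenerate_range")
  expect_error(gc3_intervals(0.5), class = "kogGC3_empty_input")
})

test_that("ternary points are category-wise interval occupancy proportions", {
  cs <- data.frame(
    kog_class = c("A", "B", "J", "K", "L", "C", "E"),
    category = c(rep("BLUE", 5), "RED", "RED"),
    mean_gc3 = c(0.40, 0.41, 0.42, 0.58, 0.59, 0.60, 0.60))
  pts <- ternary_points(cs, genome = "g1")
  blue <- pts[pts$category == "BLUE", ]
  expect_equal(c(blue$p_low, blue$p_med, blue$p_high), c(0.6, 0, 0.4))
  red <- pts[pts$category == "RED", ]
  expect_equal(c(red$p_low, red$p_med, red$p_high), c(0, 0, 1))
  expect_equal(pts$p_low + pts$p_med + pts$p_high, rep(1, nrow(pts)),
               tolerance = 1e-12)
})

test_that("count-weighted category points conserve genome-wide occupancy", {
  set.seed(81)
  cs <- data.frame(
    kog_class = LETTERS[1:20],
    category = sample(c("BLUE", "BLACK", "RED"), 20, TRUE, prob = c(.3, .4, .3)),
    mean_gc3 = runif(20, 0.45, 0.65))
  br <- gc3_intervals(cs$mean_gc3)
  pts <- ternary_points(cs, breaks = br)
  w <- pts$n_classes / sum(pts$n_classes)
  pooled <- c(sum(w * pts$p_low), sum(w * pts$p_med), sum(w * pts$p_high))
  overall <- as.numeric(table(assign_interval(cs$mean_gc3, br))) / 20
  expect_equal(pooled, overall, tolerance = 1e-12)
})

test_that("the confinement statistic has the right extremes and antisymmetry", {
  expect_equal(confinement_statistic(
    data.frame(p_low = 0, p_med = 0, p_high = 1)), 1)
  expect_equal(confinement_statistic(
    data.frame(p_low = 1 / 3, p_med = 1 / 3, p_high = 1 / 3)), 0)
  pts <- data.frame(p_low = c(0.1, 0.2), p_med = c(0.3, 0.3),
                    p_high = c(0.6, 0.5))
  mirrored <- data.frame(p_low = pts$p_high, p_med = pts$p_med,
                         p_high = pts$p_low)
  expect_equal(confinement_statistic(mirrored), -confinement_statistic(pts))
})

make_class_table <- function(n_genomes, seed, red_high = FALSE) {
  withr::with_seed(seed, do.call(rbind, lapply(seq_len(n_genomes), function(g) {
    cat <- rep(c("BLUE", "BLACK", "RED"), c(5, 7, 8))
    iv <- sample(c("Low", "Medium", "High"), 20, TRUE)
    if (red_high) iv[cat == "RED"] <- "High"
    data.frame(genome = sprintf("g%02d", g), kog_class = LETTERS[1:20],
               category = cat, interval = iv)
  })))
}

test_that("the permutation test is deterministic and floors at 1/(n_perm+1)", {
  tab <- make_class_table(5, seed = 91)
  r1 <- definetti_permutation_test(tab, n_perm = 200, seed = 7)
  r2 <- definetti_permutation_test(tab, n_perm = 200, seed = 7)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 201)
  expect_lte(r1$p_value, 1)
})

test_that("fully confined Red classes across many genomes reach the p floor", {
  tab <- make_class_table(14, seed = 92, red_high = TRUE)
  res <- definetti_permutation_test(tab, n_perm = 1000, seed = 3)
  expect_equal(res$observed_stat, 1)
  expect_equal(res$p_value, 1 / 1001)
  expect_output(print(res), "permutation")
})

test_that("intervals are computed from class means when not supplied", {
  set.seed(93)
  tab <- data.frame(genome = rep(c("g1", "g2"), each = 20),
                    kog_class = rep(LETTERS[1:20], 2),
                    category = rep(rep(c("BLUE", "BLACK", "RED"),
                                       c(5, 7, 8)), 2),
                    mean_gc3 = runif(40, 0.4, 0.7))
  res <- definetti_permutation_test(tab, n_perm = 99, seed = 5)
  expect_true(is.finite(res$observed_stat))
  expect_equal(length(res$null_stats), 99)
})

test_that("n_perm and seed arguments are validated", {
  tab <- make_class_table(2, seed = 94)
  expect_error(definetti_permutation_test(tab, n_perm = 0, seed = 1),
               class = "kogGC3_bad_argument")
  expect_error(definetti_permutation_test(tab, n_perm = 10),
               class = "kogGC3_bad_argument")
})
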