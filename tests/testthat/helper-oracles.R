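# Independent brute-force oracles, deliberately naive and separate from the
# package's implementation paths.

# GC3 by explicit looping over every third base.
oracle_gc3 <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  thirds <- chars[seq(3, length(chars), by = 3)]
  thirds <- thirds[thirds != "N"]
  sum(thirds %in% c("G", "C")) / length(thirds)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n+m, n) group assignments (no ties assumed).
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); m <- length(y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Pearson chi-square by direct sum((O - E)^2 / E).
oracle_chisq <- function(counts) {
  counts <- as.matrix(counts)
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - E)^2 / E)
}

# Mean of a Normal(mu, sigma) truncated to [lo, hi].
truncnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# A gene->class map shaped like the published human dataset: one gene row
# per catalog reference count.
reference_shaped_map <- function() {
  cat <- kog_classes()
  data.frame(
    gene_id = sprintf("g%05d", seq_len(sum(cat$ref_n))),
    class_letters = rep(cat$letter, cat$ref_n))
}

# Records with given per-category gc3 samples.
records_from_categories <- function(blue, black, red) {
  data.frame(
    id = sprintf("g%05d", seq_len(length(blue) + length(black) + length(red))),
    gc3 = c(blue, black, red),
    category = rep(c("BLUE", "BLACK", "RED"),
                   c(length(blue), length(black), length(red))),
    kog_class = rep(c("J", "T", "P"),
                    c(length(blue), length(black), length(red))))
}
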