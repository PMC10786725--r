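# Independent oracles and fixture builders used across the suite.

# Brute-force paired signed-rank p-value: enumerates all 2^n sign
# assignments of the midranks directly (no shared code with the package's
# dynamic-programming implementation).
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  lower <- mean(ws <= W_obs + 1e-9)
  upper <- mean(ws >= W_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Exact hypergeometric upper tail by direct pmf summation of binomial
# coefficients.
hyper_upper_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Closed-form OLS slope/intercept/R2 of log(signal) on time.
ols_log_oracle <- function(time, signal) {
  y <- log(signal)
  xbar <- mean(time); ybar <- mean(y)
  slope <- sum((time - xbar) * (y - ybar)) / sum((time - xbar)^2)
  intercept <- ybar - slope * xbar
  fitted <- intercept + slope * time
  r2 <- 1 - sum((y - fitted)^2) / sum((y - ybar)^2)
  list(k = slope, intercept = intercept, r2 = r2)
}

# Ten-gene toy annotation: 2 genes shorter than 1 kb and one extra pair
# separated by a 2.5 kb gap; every other neighbour gap is >= 3 kb. Laid out
# by hand so the expected filter outcome (6 kept) is enumerable.
toy_annotation <- function() {
  # (start, length) pairs on one chromosome, gaps annotated:
  spans <- list(
    g01 = c(5000, 2000),    # kept
    g02 = c(12000, 900),    # short
    g03 = c(17000, 3000),   # kept
    g04 = c(24000, 2000),   # close pair member (gap to g05 = 2500)
    g05 = c(28500, 1500),   # close pair member
    g06 = c(34000, 800),    # short
    g07 = c(39000, 4000),   # kept
    g08 = c(47000, 1000),   # kept (exactly 1 kb)
    g09 = c(52000, 2500),   # kept
    g10 = c(58000, 3500)    # kept
  )
  df <- do.call(rbind, lapply(names(spans), function(id) {
    s <- as.integer(spans[[id]])
    data.frame(gene_id = id, transcript_id = paste0(id, ".t1"),
               chrom = "chrT", strand = "+",
               start = s[1], end = s[1] + s[2], stringsAsFactors = FALSE)
  }))
  df$tss <- df$start
  df$tes <- df$end - 1L
  df$length <- df$end - df$start
  df
}

# Minimal GTF writer for hand-built fixtures (independent of write_gtf).
write_test_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, feature, start1, end1, strand, gene, tx) {
  paste(chrom, "test", feature, start1, end1, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s";', gene, tx),
        sep = "\t")
}
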