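#' Log2 pausing index
#'
#' The pausing index of a gene is the log2 ratio of promoter per-bp read
#' density to gene-body per-bp read density,
#' `log2((promoter_count + eps) / promoter_length) -
#'  log2((body_count + eps) / body_length)`,
#' where `eps` is a pseudocount keeping the index finite for empty windows.
#' PI = 0 means equal densities; PI = 1 a 2-fold promoter excess.
#'
#' @param promoter_count,body_count Fragment counts (vectorized).
#' @param promoter_length,body_length Window lengths, bp.
#' @param pseudocount Added to both counts; must be > 0 if any body count is
#'   zero.
#' @return Numeric pausing index (log2).
#' @export
pausing_index <- function(promoter_count, body_count,
                          promoter_length, body_length,
                          pseudocount = 0.5) {
  stopifnot(all(promoter_length > 0), all(body_length > 0),
            all(promoter_count >= 0), all(body_count >= 0))
  if (pseudocount == 0 && any(body_count == 0)) {
    stop("pausing index undefined: body_count == 0 with pseudocount 0")
  }
  log2((promoter_count + pseudocount) / promoter_length) -
    log2((body_count + pseudocount) / body_length)
}

#' Per-gene pausing indices for one condition from replicate counts
#'
#' Replicate promoter/body counts are averaged per gene (equivalently,
#' replicate densities are averaged, since window lengths are shared) and the
#' pausing index computed on the averaged values. Genes missing from any
#' replicate are dropped with a message.
#'
#' @param promoter_counts,body_counts Lists (one element per replicate) of
#'   data.frames from [count_fragments()] over the promoter and body windows.
#' @param condition Condition label.
#' @param pseudocount Passed to [pausing_index()].
#' @return Data.frame: `gene_id`, `condition`, averaged counts, densities and
#'   `pi`.
#' @export
condition_pi <- function(promoter_counts, body_counts,
                         condition = "condition", pseudocount = 0.5) {
  stopifnot(length(promoter_counts) >= 1L,
            length(promoter_counts) == length(body_counts))
  ids <- Reduce(intersect, c(lapply(promoter_counts, `[[`, "region_id"),
                             lapply(body_counts, `[[`, "region_id")))
  n_union <- length(unique(unlist(lapply(promoter_counts, `[[`, "region_id"))))
  if (length(ids) < n_union) {
    message(n_union - length(ids),
            " gene(s) dropped: missing in at least one replicate")
  }
  get <- function(df, col) df[[col]][match(ids, df$region_id)]
  pc <- rowMeans(do.call(cbind, lapply(promoter_counts, get, "count")))
  bc <- rowMeans(do.call(cbind, lapply(body_counts, get, "count")))
  pl <- get(promoter_counts[[1]], "length")
  bl <- get(body_counts[[1]], "length")
  data.frame(
    gene_id = ids, condition = condition,
    promoter_count = pc, body_count = bc,
    promoter_density = pc / pl, body_density = bc / bl,
    pi = pausing_index(pc, bc, pl, bl, pseudocount),
    stringsAsFactors = FALSE
  )
}

#' Fraction of genes classified as paused
#'
#' A gene is "paused" when its pausing index strictly exceeds
#' `threshold_log2` (default 1, i.e. more than 2-fold promoter excess over
#' the gene body).
#'
#' @param pi Pausing indices (vector, or a data.frame with a `pi` column).
#' @param threshold_log2 Log2 threshold; strict inequality.
#' @return List: `n_genes`, `fraction_paused`, `threshold_log2`.
#' @export
classify_paused <- function(pi, threshold_log2 = 1) {
  if (is.data.frame(pi)) pi <- pi$pi
  stopifnot(length(pi) > 0L)
  list(
    n_genes = length(pi),
    fraction_paused = mean(pi > threshold_log2),
    threshold_log2 = threshold_log2
  )
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Tests whether paired values differ between two conditions. Differences
#' `b - a` of exactly zero are dropped (standard signed-rank convention);
#' absolute differences are ranked with midranks for ties and the statistic
#' `W` is the sum of ranks of positive differences. For `n <= exact_max` the
#' two-sided p-value comes from the exact null distribution (enumerated by
#' dynamic programming over the 2^n sign assignments, valid under ties);
#' above that, a normal approximation with tie and continuity correction is
#' used.
#'
#' @param a,b Paired numeric vectors (e.g. pausing indices per gene in
#'   vehicle and treated conditions, matched by position).
#' @param exact_max Largest `n` for which the exact distribution is used.
#' @return List: `W`, `n` (non-zero pairs), `p` (two-sided), `method`.
#' @export
paired_wilcoxon <- function(a, b, exact_max = 25L) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero")
    return(list(W = 0, n = 0L, p = 1, method = "degenerate"))
  }
  r <- rank(abs(d))  # midranks
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- wilcoxon_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(W = W, n = n, p = p, method = method)
}

# Exact two-sided p for the signed-rank statistic with midranks: counts the
# subset-sum distribution of doubled ranks (integers) over all 2^n equally
# likely sign assignments.
wilcoxon_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[s + 1] = #assignments with doubled sum s
  f[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
    f <- f + shifted
  }
  f <- f / 2^length(ranks)
  w2 <- as.integer(round(2 * W))
  lower <- sum(f[seq_len(w2 + 1L)])
  upper <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(lower, upper))
}

#' Empirical cumulative distribution function as a table
#'
#' Right-continuous ECDF evaluated at the sorted unique values;
#' `F(max(values)) == 1`.
#'
#' @param values Numeric vector, non-empty.
#' @return Data.frame `value`, `cumulative_fraction`.
#' @export
ecdf_table <- function(values) {
  stopifnot(length(values) > 0L)
  v <- sort(unique(values))
  data.frame(
    value = v,
    cumulative_fraction = stats::ecdf(values)(v)
  )
}
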