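#' Consensus peaks supported by both replicates
#'
#' Keeps only peaks that overlap (by >= 1 bp) a peak called in the other
#' replicate, and merges each overlapping cluster into its union interval.
#' Symmetric in its arguments and idempotent on identical replicate sets.
#'
#' @param rep1,rep2 Data.frames of peak intervals with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return Data.frame of consensus intervals `chrom`, `start`, `end`, sorted.
#' @export
consensus_peaks <- function(rep1, rep2) {
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) {
    warning("empty replicate peak set: consensus is empty")
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  g1 <- regions_granges(rep1)
  g2 <- regions_granges(rep2)
  hits <- GenomicRanges::findOverlaps(g1, g2)
  kept <- c(g1[unique(S4Vectors::queryHits(hits))],
            g2[unique(S4Vectors::subjectHits(hits))])
  merged <- GenomicRanges::reduce(GenomicRanges::sort(kept))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    stringsAsFactors = FALSE
  )
}

#' Promoters carrying a consensus peak in at least one condition
#'
#' @param consensus_list List of consensus peak data.frames (one per
#'   condition, from [consensus_peaks()]).
#' @param promoters Promoter intervals from [make_diff_promoters()].
#' @return Character vector of `gene_id`s retained in the analysis universe.
#' @export
promoter_universe <- function(consensus_list, promoters) {
  if (nrow(promoters) == 0L) return(character())
  gp <- regions_granges(promoters)
  hit <- rep(FALSE, nrow(promoters))
  for (peaks in consensus_list) {
    if (nrow(peaks) == 0L) next
    hit <- hit | GenomicRanges::countOverlaps(gp, regions_granges(peaks)) > 0L
  }
  promoters$gene_id[hit]
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median across regions of the ratio of
#' that sample's count to the per-region geometric mean, computed over regions
#' with all-positive counts. Falls back to library-size ratios (scaled to
#' geometric mean 1) when no region has all-positive counts.
#'
#' @param mat Count matrix, regions x samples.
#' @return Positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  all_pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(all_pos)) {
    warning("no region with all-positive counts; using library-size ratios")
    ls <- colSums(mat)
    return(ls / exp(mean(log(ls))))
  }
  lg <- log(mat[all_pos, , drop = FALSE])
  log_geo <- rowMeans(lg)
  apply(lg, 2, function(x) exp(stats::median(x - log_geo)))
}

#' Negative-binomial differential promoter-enrichment test
#'
#' A documented count-based replacement for package-internal differential
#' binding machinery: counts are normalized by median-of-ratios size factors
#' (or externally supplied depth factors), a common negative-binomial
#' dispersion is estimated across promoters by a bias-corrected pooled
#' method of moments on within-condition variability, and each promoter is
#' tested with an exact conditional NB test: the per-condition count sums
#' are modelled as negative binomials sharing a common mean under the null,
#' and the two-sided p-value sums the probabilities of all allocations of
#' the observed total that are no more likely than the observed one. This
#' exact-style construction keeps type-I error close to nominal with as few
#' as two replicates per condition. P-values are Benjamini-Hochberg
#' adjusted and promoters classified at `q < alpha` by the sign of the
#' fold change.
#'
#' @param mat Count matrix, promoters x samples, with promoter ids as
#'   rownames.
#' @param condition Factor/character of length `ncol(mat)` with two levels;
#'   the first level is the reference (fold changes are second/first, e.g.
#'   treated/vehicle).
#' @param alpha BH FDR threshold for classification.
#' @param sample_size_factors Optional externally derived per-sample size
#'   factors (e.g. full library sizes scaled to geometric mean 1). By
#'   default factors are estimated from `mat` by median-of-ratios, which is
#'   appropriate when most promoters are unchanged; when a global shift is
#'   expected (the promoter-pausing regime, where the majority of promoters
#'   gain signal), normalization must come from sequencing depth instead,
#'   because promoter-composition normalization would divide the shift out.
#' @return Data.frame: `id`, condition mean normalized counts, `log2fc`,
#'   `p`, `q`, `class` in `increased`/`decreased`/`no_change`. The common
#'   dispersion is attached as attribute `"dispersion"`; all-zero promoters
#'   are dropped and listed in attribute `"dropped"`.
#' @export
differential_test <- function(mat, condition, alpha = 0.05,
                              sample_size_factors = NULL) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(condition))
  condition <- factor(condition, levels = unique(as.character(condition)))
  stopifnot(nlevels(condition) == 2L)
  if (any(table(condition) < 2L)) {
    stop("need >= 2 samples per condition to estimate dispersion")
  }
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  zero <- rowSums(mat) == 0
  dropped <- rownames(mat)[zero]
  if (any(zero)) {
    message(sum(zero), " promoter(s) dropped: zero counts in all samples")
    mat <- mat[!zero, , drop = FALSE]
  }
  sf <- if (is.null(sample_size_factors)) size_factors(mat) else {
    stopifnot(length(sample_size_factors) == ncol(mat),
              all(sample_size_factors > 0))
    sample_size_factors
  }
  norm <- sweep(mat, 2, sf, "/")
  lvl <- levels(condition)
  ia <- which(condition == lvl[1]); ib <- which(condition == lvl[2])
  a <- norm[, ia, drop = FALSE]
  b <- norm[, ib, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  # pooled method-of-moments common dispersion: Var = mu + phi * mu^2.
  # the v/n subtraction removes E[mu_hat^2] - mu^2, which otherwise
  # biases phi low and inflates type-I error
  v_a <- apply(a, 1, stats::var); v_b <- apply(b, 1, stats::var)
  num <- sum(v_a - mu_a) + sum(v_b - mu_b)
  den <- sum(mu_a^2 - v_a / na) + sum(mu_b^2 - v_b / nb)
  phi <- max(1e-8, num / den)
  eps <- 0.5
  lfc <- log(mu_b + eps) - log(mu_a + eps)
  mu0 <- rowMeans(norm)
  KA <- rowSums(mat[, ia, drop = FALSE])
  KB <- rowSums(mat[, ib, drop = FALSE])
  p <- exact_nb_test(KA, KB, mu0, sf[ia], sf[ib], phi)
  q <- bh_fdr(p)
  class <- ifelse(q < alpha, ifelse(lfc > 0, "increased", "decreased"),
                  "no_change")
  out <- data.frame(
    id = rownames(mat),
    mean_a = mu_a, mean_b = mu_b,
    log2fc = lfc / log(2), p = p, q = q, class = class,
    stringsAsFactors = FALSE, row.names = NULL
  )
  names(out)[2:3] <- paste0("mean_", lvl)
  attr(out, "dispersion") <- phi
  attr(out, "size_factors") <- sf
  attr(out, "dropped") <- dropped
  out
}

# Exact conditional NB test on per-condition count sums. Each sum is
# approximated by a negative binomial matching the mean and variance implied
# by the common null mean mu0, the sample size factors and the common
# dispersion; the two-sided p sums allocation probabilities <= the observed
# one, conditionally on the total. Falls back to a normal tail for very
# large totals where enumerating allocations buys nothing.
exact_nb_test <- function(KA, KB, mu0, sa, sb, phi, max_total = 50000L) {
  n <- length(KA)
  p <- numeric(n)
  SA <- sum(sa); SB <- sum(sb)
  for (i in seq_len(n)) {
    mA <- mu0[i] * SA
    mB <- mu0[i] * SB
    vA <- sum(mu0[i] * sa + phi * (mu0[i] * sa)^2)
    vB <- sum(mu0[i] * sb + phi * (mu0[i] * sb)^2)
    tot <- KA[i] + KB[i]
    if (tot == 0) { p[i] <- 1; next }
    if (tot > max_total) {
      z <- (KA[i] - mA * tot / (mA + mB)) / sqrt(vA * vB / (vA + vB))
      p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
      next
    }
    szA <- mA^2 / max(vA - mA, 1e-8)
    szB <- mB^2 / max(vB - mB, 1e-8)
    x <- 0:tot
    pr <- stats::dnbinom(x, mu = mA, size = szA) *
      stats::dnbinom(tot - x, mu = mB, size = szB)
    denom <- sum(pr)
    if (denom <= 0) { p[i] <- 1; next }
    p[i] <- min(1, sum(pr[pr <= pr[KA[i] + 1] * (1 + 1e-7)]) / denom)
  }
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH q-values with monotonicity enforcement (delegates to
#' [stats::p.adjust()] after validating the input range).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
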