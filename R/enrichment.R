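#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: set name, description, then member genes. Duplicate
#' genes within a set are removed (with a message); lines with fewer than
#' three fields are an error naming the line number.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> gene ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(stats::setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed GMT line ", lineno[which(nf < 3L)[1]],
         ": expected >= 3 tab-separated fields")
  }
  sets <- lapply(fields, function(x) {
    genes <- trimws(x[-(1:2)])
    genes <- genes[nzchar(genes)]
    dup <- duplicated(genes)
    if (any(dup)) {
      message("set '", x[1], "': ", sum(dup), " duplicate gene(s) removed")
    }
    genes[!dup]
  })
  stats::setNames(sets, vapply(fields, `[`, character(1), 1L))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` members of a `K`-gene set when sampling `n` genes without
#' replacement from a universe of `N`. Computed in log space via
#' [stats::phyper()] for numerical stability.
#'
#' @param k Observed overlap.
#' @param K Set size within the universe.
#' @param n Foreground (draw) size.
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(k >= 0, K <= N, n <= N, k <= min(K, n))
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric over-representation of gene sets
#'
#' Tests whether each gene set is over-represented among `foreground` genes
#' (e.g. promoters gained with treatment) relative to a universe composed of
#' the foreground plus `background` genes (e.g. unchanged + decreased
#' promoters). Each set is first intersected with the universe; sets with no
#' member in the universe are skipped. Gene ids are matched case-sensitively
#' after whitespace trimming. BH correction is applied across the tested
#' sets only.
#'
#' @param foreground,background Disjoint character vectors of gene ids.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param alpha FDR threshold for the `significant` flag.
#' @return Data.frame: `set_name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, sorted by `p`.
#' @export
enrich <- function(foreground, background, collection, alpha = 0.05) {
  foreground <- unique(trimws(foreground))
  background <- unique(trimws(background))
  if (length(intersect(foreground, background))) {
    stop("foreground and background must be disjoint")
  }
  universe <- union(foreground, background)
  stopifnot(length(universe) > 0L)
  K <- vapply(collection, function(s) length(intersect(trimws(s), universe)),
              integer(1))
  skipped <- names(collection)[K == 0L]
  if (length(skipped)) {
    message(length(skipped), " set(s) skipped: no member in universe")
  }
  tested <- names(collection)[K > 0L]
  if (length(tested) == 0L) {
    return(data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  n <- length(foreground); N <- length(universe)
  k <- vapply(collection[tested],
              function(s) length(intersect(trimws(s), foreground)),
              integer(1))
  p <- mapply(hypergeom_upper, k = k, K = K[tested],
              MoreArgs = list(n = n, N = N))
  q <- bh_fdr(p)
  out <- data.frame(
    set_name = tested, k = k, K = K[tested], n = n, N = N,
    p = p, q = q, significant = q < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$p, out$set_name), , drop = FALSE]
}
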