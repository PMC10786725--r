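#' Load a gene annotation and keep the longest transcript per gene
#'
#' Parses a GTF (1-based, inclusive) or BED12 (0-based, half-open) annotation
#' into one record per gene, retaining the longest transcript; ties are broken
#' by the lexicographically smallest transcript id. All coordinates are
#' converted to 0-based half-open internally so that interval arithmetic is
#' BED-compatible.
#'
#' For GTF input, `transcript` features are used when present; otherwise
#' transcript spans are reconstructed as the min/max over `exon` features
#' sharing a `transcript_id`. The TSS of a minus-strand gene is the coordinate
#' `end - 1` (the last covered base), so `tss` is always the strand-aware
#' 5' end and `tes` the strand-aware 3' end.
#'
#' @param path Path to the annotation file.
#' @param format Either `"gtf"` or `"bed12"`. For BED12 the `name` field is
#'   taken as `gene_id:transcript_id` when it contains a colon, otherwise the
#'   name serves as both ids.
#' @return A data.frame of gene records with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end`, `tss`, `tes`,
#'   `length` (0-based half-open coordinates, length = end - start).
#' @export
load_annotation <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tx <- switch(format,
    gtf = parse_gtf_transcripts(path),
    bed12 = parse_bed12_transcripts(path)
  )
  if (nrow(tx) == 0L) {
    return(empty_gene_records())
  }
  tx$length <- tx$end - tx$start
  # longest transcript per gene; ties -> lexicographically smallest tx id
  ord <- order(tx$gene_id, -tx$length, tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  keep <- !duplicated(tx$gene_id)
  g <- tx[keep, , drop = FALSE]
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
  g <- g[order(g$chrom, g$start, g$gene_id), c(
    "gene_id", "transcript_id", "chrom", "strand",
    "start", "end", "tss", "tes", "length"
  )]
  rownames(g) <- NULL
  g
}

empty_gene_records <- function() {
  data.frame(
    gene_id = character(), transcript_id = character(),
    chrom = character(), strand = character(),
    start = integer(), end = integer(),
    tss = integer(), tes = integer(), length = integer(),
    stringsAsFactors = FALSE
  )
}

parse_gtf_transcripts <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_gene_records()[, c("gene_id", "transcript_id", "chrom", "strand", "start", "end")])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("unparseable GTF line ", lineno[which(nf != 9L)[1]],
         ": expected 9 tab-separated fields, got ", nf[which(nf != 9L)[1]])
  }
  m <- do.call(rbind, fields)
  feature <- m[, 3]
  use <- feature %in% c("transcript", "exon")
  m <- m[use, , drop = FALSE]
  lineno <- lineno[use]
  if (nrow(m) == 0L) stop("GTF contains no transcript or exon features")
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | start1 > end1)
  if (length(bad)) {
    stop("unparseable GTF line ", lineno[bad[1]], ": invalid coordinates")
  }
  strand <- m[, 7]
  badstr <- which(!strand %in% c("+", "-"))
  if (length(badstr)) {
    stop("unknown strand symbol '", strand[badstr[1]], "' at GTF line ",
         lineno[badstr[1]])
  }
  gene_id <- gtf_attribute(m[, 9], "gene_id")
  transcript_id <- gtf_attribute(m[, 9], "transcript_id")
  badattr <- which(is.na(gene_id) | is.na(transcript_id))
  if (length(badattr)) {
    stop("GTF line ", lineno[badattr[1]],
         ": missing gene_id or transcript_id attribute")
  }
  df <- data.frame(
    gene_id = gene_id, transcript_id = transcript_id,
    chrom = m[, 1], strand = strand, feature = m[, 3],
    start = start1 - 1L, end = end1,  # to 0-based half-open
    stringsAsFactors = FALSE
  )
  # prefer explicit transcript features; otherwise assemble spans from exons
  has_tx <- df$transcript_id %in% df$transcript_id[df$feature == "transcript"]
  tx <- df[df$feature == "transcript", , drop = FALSE]
  ex <- df[!has_tx & df$feature == "exon", , drop = FALSE]
  if (nrow(ex) > 0L) {
    sp <- split(ex, ex$transcript_id)
    asm <- do.call(rbind, lapply(sp, function(e) {
      data.frame(
        gene_id = e$gene_id[1], transcript_id = e$transcript_id[1],
        chrom = e$chrom[1], strand = e$strand[1], feature = "transcript",
        start = min(e$start), end = max(e$end), stringsAsFactors = FALSE
      )
    }))
    tx <- rbind(tx, asm)
  }
  tx$feature <- NULL
  rownames(tx) <- NULL
  tx
}

gtf_attribute <- function(attr, key) {
  pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  m <- regexec(pat, attr)
  vapply(regmatches(attr, m), function(x) {
    if (length(x) >= 3L) x[3] else NA_character_
  }, character(1))
}

parse_bed12_transcripts <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_gene_records()[, c("gene_id", "transcript_id", "chrom", "strand", "start", "end")])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("unparseable BED line ", lineno[which(nf < 6L)[1]],
         ": expected >= 6 fields")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  strand <- m[, 6]
  badstr <- which(!strand %in% c("+", "-"))
  if (length(badstr)) {
    stop("unknown strand symbol '", strand[badstr[1]], "' at BED line ",
         lineno[badstr[1]])
  }
  name <- m[, 4]
  has_colon <- grepl(":", name, fixed = TRUE)
  gene_id <- ifelse(has_colon, sub(":.*$", "", name), name)
  transcript_id <- ifelse(has_colon, sub("^[^:]*:", "", name), name)
  data.frame(
    gene_id = gene_id, transcript_id = transcript_id,
    chrom = m[, 1], strand = strand,
    start = as.integer(m[, 2]), end = as.integer(m[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Exclude short genes and genes too close to a neighbour
#'
#' Applies the two exclusion rules used before pausing-index analysis: genes
#' shorter than `min_length_bp` are removed, and every gene whose genomic span
#' lies closer than `min_gap_bp` to another gene's span on the same chromosome
#' (either strand) is removed — both members of a violating pair. Proximity is
#' evaluated on the full input set, so a short gene can still disqualify its
#' neighbour.
#'
#' @param genes Gene records from [load_annotation()].
#' @param min_length_bp Minimum gene length kept, in bp. The default 1000
#'   keeps genes of exactly 1 kb (strict "< 1 kb" exclusion).
#' @param min_gap_bp Minimum intergenic gap kept, in bp (span-to-span;
#'   overlapping genes count as gap < 0).
#' @return A list with `genes` (the kept records) and `report`, a list with
#'   `n_input`, `n_kept` and an `excluded` data.frame of
#'   (`gene_id`, `reason`), reason one of `short_gene`, `proximal_pair`.
#' @export
filter_genes <- function(genes, min_length_bp = 1000L, min_gap_bp = 3000L) {
  n_input <- nrow(genes)
  if (n_input == 0L) {
    return(list(
      genes = genes,
      report = list(n_input = 0L, n_kept = 0L,
                    excluded = data.frame(gene_id = character(),
                                          reason = character(),
                                          stringsAsFactors = FALSE))
    ))
  }
  short <- genes$length < min_length_bp
  proximal <- rep(FALSE, n_input)
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    o <- idx[order(genes$start[idx])]
    s <- genes$start[o]; e <- genes$end[o]
    for (i in seq_along(o)) {
      j <- i + 1L
      while (j <= length(o) && s[j] - e[i] < min_gap_bp) {
        proximal[o[i]] <- TRUE
        proximal[o[j]] <- TRUE
        j <- j + 1L
      }
    }
  }
  excl <- short | proximal
  reason <- ifelse(short, "short_gene", "proximal_pair")[excl]
  report <- list(
    n_input = n_input,
    n_kept = sum(!excl),
    excluded = data.frame(gene_id = genes$gene_id[excl], reason = reason,
                          stringsAsFactors = FALSE)
  )
  kept <- genes[!excl, , drop = FALSE]
  rownames(kept) <- NULL
  list(genes = kept, report = report)
}

#' Construct promoter and gene-body windows for pausing analysis
#'
#' For each gene the proximal promoter spans `upstream_bp` upstream to
#' `downstream_bp` downstream of the TSS (350 bp with the defaults), and the
#' gene body runs from the promoter's downstream edge to `body_ext_bp` past
#' the gene's 3' boundary, both in the direction of transcription. Windows are
#' clipped to `[0, chrom_size)`; genes whose body is empty after clipping are
#' dropped and listed in the `dropped` attribute.
#'
#' @param genes Filtered gene records.
#' @param upstream_bp,downstream_bp Promoter extent around the TSS, bp.
#' @param body_ext_bp Extension past the gene 3' end, bp.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @return Data.frame with `gene_id`, `chrom`, `strand`, promoter and body
#'   start/end (0-based half-open) and realized `promoter_length`,
#'   `body_length`.
#' @export
make_pausing_windows <- function(genes, upstream_bp = 50L, downstream_bp = 300L,
                                 body_ext_bp = 3000L, chrom_sizes) {
  stopifnot(all(genes$chrom %in% names(chrom_sizes)))
  size <- unname(chrom_sizes[genes$chrom])
  plus <- genes$strand == "+"
  p_start <- ifelse(plus, genes$tss - upstream_bp, genes$end - downstream_bp)
  p_end   <- ifelse(plus, genes$tss + downstream_bp, genes$tss + upstream_bp + 1L)
  b_start <- ifelse(plus, genes$tss + downstream_bp, genes$start - body_ext_bp)
  b_end   <- ifelse(plus, genes$end + body_ext_bp, genes$end - downstream_bp)
  w <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    promoter_start = pmax(0L, as.integer(p_start)),
    promoter_end = pmin(size, as.integer(p_end)),
    body_start = pmax(0L, as.integer(b_start)),
    body_end = pmin(size, as.integer(b_end)),
    stringsAsFactors = FALSE
  )
  w$promoter_length <- w$promoter_end - w$promoter_start
  w$body_length <- w$body_end - w$body_start
  bad <- w$body_length <= 0L | w$promoter_length <= 0L
  dropped <- w$gene_id[bad]
  if (length(dropped)) {
    message(length(dropped), " gene(s) dropped: empty window after clipping")
  }
  w <- w[!bad, , drop = FALSE]
  rownames(w) <- NULL
  attr(w, "dropped") <- dropped
  w
}

#' Construct symmetric promoters for differential enrichment
#'
#' One interval per gene spanning `halfwidth_bp` either side of the TSS,
#' clipped to chromosome bounds, used as the counting regions for the
#' differential promoter-enrichment test.
#'
#' @inheritParams make_pausing_windows
#' @param halfwidth_bp Half-width around the TSS, bp.
#' @return Data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
make_diff_promoters <- function(genes, halfwidth_bp = 300L, chrom_sizes = NULL) {
  start <- genes$tss - halfwidth_bp
  end <- genes$tss + halfwidth_bp
  if (!is.null(chrom_sizes)) {
    stopifnot(all(genes$chrom %in% names(chrom_sizes)))
    end <- pmin(unname(chrom_sizes[genes$chrom]), end)
  }
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    start = pmax(0L, as.integer(start)), end = as.integer(end),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
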