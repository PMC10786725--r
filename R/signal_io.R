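#' Load aligned ChIP fragments
#'
#' Reads fragment intervals from a BED3/BED6 file (canonical input; 0-based
#' half-open) or, when the optional alignment adapters are installed, from a
#' BAM file. Paired-end BAM records are collapsed to template-span fragments;
#' single-end reads (BAM, or BED with `single_end = TRUE` and a strand column)
#' are extended to `single_end_extension_bp` in the read orientation.
#' Zero-length or invalid records are skipped with a message.
#'
#' @param path Input file.
#' @param format `"bed"` or `"bam"`.
#' @param single_end_extension_bp Extension length for single-end reads, bp.
#' @param single_end For BED input: treat intervals as single-end reads and
#'   extend them (requires a strand column).
#' @param sample_id Sample label; defaults to the file name.
#' @return A `fragment_set`: list with `sample_id`, `fragments` (data.frame
#'   `chrom`, `start`, `end`) and `library_size`.
#' @export
load_fragments <- function(path, format = c("bed", "bam"),
                           single_end_extension_bp = 200L,
                           single_end = FALSE,
                           sample_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fragment file not found: ", path)
  if (format == "bam") {
    return(load_fragments_bam(path, single_end_extension_bp, sample_id))
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(fragment_set(sample_id, empty_fragments()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("unparseable BED line ", which(keep)[which(nf < 3L)[1]],
         ": expected >= 3 fields")
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[`, character(1), 3L))
  if (single_end) {
    if (any(nf < 6L)) stop("single-end extension requires a BED6 strand column")
    strand <- vapply(fields, `[`, character(1), 6L)
    ext <- as.integer(single_end_extension_bp)
    end2 <- ifelse(strand == "+", start + ext, end)
    start2 <- ifelse(strand == "+", start, end - ext)
    start <- pmax(0L, as.integer(start2)); end <- as.integer(end2)
  }
  ok <- !is.na(start) & !is.na(end) & start < end
  if (any(!ok)) {
    message(sum(!ok), " invalid/zero-length record(s) skipped")
  }
  fragment_set(sample_id, data.frame(
    chrom = chrom[ok], start = start[ok], end = end[ok],
    stringsAsFactors = FALSE
  ))
}

load_fragments_bam <- function(path, ext, sample_id) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
      !requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM input requires the GenomicAlignments and Rsamtools packages")
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag)
  bf <- Rsamtools::BamFile(path)
  paired <- suppressMessages(Rsamtools::testPairedEndBam(bf))
  if (paired) {
    gp <- GenomicAlignments::readGAlignmentPairs(bf, param = param)
    gr <- GenomicRanges::granges(gp)  # template spans
  } else {
    ga <- GenomicAlignments::readGAlignments(bf, param = param)
    gr <- GenomicRanges::resize(GenomicRanges::granges(ga), as.integer(ext),
                                fix = "start")
    gr <- GenomicRanges::trim(gr)
  }
  fragment_set(sample_id, data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  ))
}

empty_fragments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Construct a fragment set
#'
#' @param sample_id Sample label.
#' @param fragments Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return A `fragment_set` list; `library_size` equals the row count.
#' @export
fragment_set <- function(sample_id, fragments) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  if (nrow(fragments) && any(fragments$start >= fragments$end)) {
    stop("fragment_set: all fragments must satisfy start < end")
  }
  structure(
    list(sample_id = sample_id,
         fragments = fragments,
         library_size = nrow(fragments)),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set '", x$sample_id, "': ", x$library_size, " fragments on ",
      length(unique(x$fragments$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

#' Count fragments in regions
#'
#' The default `midpoint` rule assigns each fragment to the region containing
#' `floor((start + end) / 2)` (half-open), so a fragment is counted at most
#' once for disjoint regions and promoter/body counts never double-count
#' across their shared boundary. `any_overlap` counts a fragment in every
#' region it overlaps by >= 1 bp.
#'
#' @param frags A [fragment_set()].
#' @param regions Data.frame with `region_id` (or `gene_id`), `chrom`,
#'   `start`, `end`.
#' @param rule Counting rule.
#' @return Data.frame `region_id`, `length`, `count`.
#' @export
count_fragments <- function(frags, regions, rule = c("midpoint", "any_overlap")) {
  rule <- match.arg(rule)
  stopifnot(inherits(frags, "fragment_set"))
  if (!"region_id" %in% names(regions) && "gene_id" %in% names(regions)) {
    regions$region_id <- regions$gene_id
  }
  stopifnot(nrow(regions) > 0L)
  f <- frags$fragments
  missing_chr <- setdiff(unique(regions$chrom), unique(f$chrom))
  if (length(missing_chr) && nrow(f)) {
    warning("no fragments on chromosome(s): ",
            paste(missing_chr, collapse = ", "), " (zero counts)")
  }
  gr_regions <- regions_granges(regions)
  counts <- integer(nrow(regions))
  if (nrow(f)) {
    if (rule == "midpoint") {
      mid <- (f$start + f$end) %/% 2L
      gr_f <- GenomicRanges::GRanges(f$chrom,
                                     IRanges::IRanges(mid + 1L, mid + 1L))
    } else {
      gr_f <- GenomicRanges::GRanges(f$chrom,
                                     IRanges::IRanges(f$start + 1L, f$end))
    }
    counts <- GenomicRanges::countOverlaps(gr_regions, gr_f)
  }
  data.frame(
    region_id = regions$region_id,
    length = regions$end - regions$start,
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
}

#' Per-bp read density
#'
#' @param counts Counts vector (or a data.frame from [count_fragments()]).
#' @param lengths Region lengths, bp (ignored when `counts` is a data.frame).
#' @param pseudocount Added to each count before dividing.
#' @return Numeric density per region, fragments/bp.
#' @export
region_density <- function(counts, lengths = NULL, pseudocount = 0) {
  if (is.data.frame(counts)) {
    lengths <- counts$length
    counts <- counts$count
  }
  stopifnot(all(lengths > 0))
  (counts + pseudocount) / lengths
}

#' Counts-per-million normalization
#'
#' @param counts Raw counts.
#' @param library_size Total fragments in the library; must be positive.
#' @return `counts * 1e6 / library_size`.
#' @export
cpm_normalize <- function(counts, library_size) {
  if (length(library_size) != 1L || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  counts * 1e6 / library_size
}

#' Strand-oriented metagene coverage profile
#'
#' Computes binned, CPM-scaled per-bp fragment coverage in a window of
#' `flank_bp` either side of each anchor (typically TSSs), oriented in the
#' anchor's strand direction. Anchors closer than `flank_bp` to a chromosome
#' edge have out-of-range bins filled with zero coverage.
#'
#' @param frags A [fragment_set()].
#' @param anchors Data.frame with `chrom`, `pos` (0-based bp) and `strand`.
#' @param flank_bp Half-window size, bp; must be divisible by `bin_bp`.
#' @param bin_bp Bin width, bp.
#' @return List with `matrix` (anchors x bins, CPM per bp) and `mean`
#'   (column means, the average profile; bin centres as names, 5' to 3').
#' @export
metagene_profile <- function(frags, anchors, flank_bp = 2000L, bin_bp = 50L) {
  stopifnot(inherits(frags, "fragment_set"),
            flank_bp %% bin_bp == 0L, nrow(anchors) > 0L)
  nbin <- as.integer(2L * flank_bp / bin_bp)
  f <- frags$fragments
  cov <- list()
  if (nrow(f)) {
    cov <- lapply(split(IRanges::IRanges(f$start + 1L, f$end), f$chrom),
                  IRanges::coverage)
  }
  mat <- matrix(0, nrow = nrow(anchors), ncol = nbin)
  win <- 2L * flank_bp
  for (i in seq_len(nrow(anchors))) {
    rle <- cov[[anchors$chrom[i]]]
    v <- numeric(win)
    if (!is.null(rle)) {
      lo <- anchors$pos[i] - flank_bp + 1L  # 1-based window start
      hi <- anchors$pos[i] + flank_bp
      from <- max(1L, lo); to <- min(length(rle), hi)
      if (from <= to) {
        v[(from - lo + 1L):(to - lo + 1L)] <- as.numeric(rle[from:to])
      }
    }
    if (anchors$strand[i] == "-") v <- rev(v)
    mat[i, ] <- colSums(matrix(v, nrow = bin_bp)) / bin_bp
  }
  mat <- mat * 1e6 / max(1L, frags$library_size)
  centers <- seq(-flank_bp + bin_bp / 2, flank_bp - bin_bp / 2, by = bin_bp)
  colnames(mat) <- centers
  list(matrix = mat, mean = colMeans(mat))
}
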