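#' Write transcripts as GTF
#'
#' Emits one `transcript` and one `exon` feature per transcript (genomic
#' spans; this package does not model splicing), converting from the
#' internal 0-based half-open coordinates to GTF's 1-based inclusive ones.
#' Output is deterministic for identical input.
#'
#' @param transcripts Data.frame with `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   transcripts$gene_id, transcripts$transcript_id)
  line <- function(feature) {
    paste(transcripts$chrom, "polpause", feature,
          transcripts$start + 1L, transcripts$end, ".",
          transcripts$strand, ".", attrs, sep = "\t")
  }
  out <- as.vector(rbind(line("transcript"), line("exon")))
  writeLines(out, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED3 by default; BED6 when a name column is available (`name_col`), with
#' score 0 and the `strand` column if present.
#'
#' @param df Data.frame with `chrom`, `start`, `end` and optionally a name
#'   column and `strand`.
#' @param path Output file.
#' @param name_col Column used for the BED name field, if any.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name_col = NULL) {
  if (is.null(name_col)) {
    out <- paste(df$chrom, df$start, df$end, sep = "\t")
  } else {
    strand <- if ("strand" %in% names(df)) df$strand else "."
    out <- paste(df$chrom, df$start, df$end, df[[name_col]], 0L, strand,
                 sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a gene-set collection as GMT
#'
#' @param collection Named list of gene-id vectors.
#' @param path Output file.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "synthetic") {
  out <- vapply(names(collection), function(nm) {
    paste(c(nm, description, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(out, path)
  invisible(path)
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path TSV with chromosome name and length columns.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  stats::setNames(df$size, df$chrom)
}
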