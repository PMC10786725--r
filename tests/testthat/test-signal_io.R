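make_frags <- function(df, id = "s1") fragment_set(id, df)

test_that("BED fragments load verbatim and library size counts records", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300\tf1", "chr1\t500\t650\tf2"), path)
  fs <- load_fragments(path, "bed")
  expect_s3_class(fs, "fragment_set")
  expect_equal(fs$library_size, 2L)
  expect_equal(fs$fragments$start, c(100L, 500L))
  expect_equal(fs$fragments$end, c(300L, 650L))
})

test_that("single-end reads are extended in read orientation", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t150\tr1\t0\t+", "chr1\t900\t950\tr2\t0\t-"), path)
  fs <- load_fragments(path, "bed", single_end = TRUE,
                       single_end_extension_bp = 200)
  expect_equal(c(fs$fragments$start[1], fs$fragments$end[1]), c(100L, 300L))
  # minus strand extends from the 5' end (the right edge) leftwards
  expect_equal(c(fs$fragments$start[2], fs$fragments$end[2]), c(750L, 950L))
})

test_that("invalid fragment records are skipped with a message", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300", "chr1\t400\t400"), path)
  expect_message(fs <- load_fragments(path, "bed"), "skipped")
  expect_equal(fs$library_size, 1L)
})

test_that("midpoint counting respects half-open boundaries", {
  frags <- make_frags(data.frame(chrom = "chr1", start = 100L, end = 300L,
                                 stringsAsFactors = FALSE))
  regions <- data.frame(region_id = "w", chrom = "chr1",
                        start = 150L, end = 250L, stringsAsFactors = FALSE)
  expect_equal(count_fragments(frags, regions)$count, 1L)  # midpoint 200
  # midpoint exactly at the window end coordinate is outside (half-open)
  regions2 <- data.frame(region_id = "w", chrom = "chr1",
                         start = 100L, end = 200L, stringsAsFactors = FALSE)
  expect_equal(count_fragments(frags, regions2)$count, 0L)
  regions3 <- data.frame(region_id = "w", chrom = "chr1",
                         start = 200L, end = 201L, stringsAsFactors = FALSE)
  expect_equal(count_fragments(frags, regions3)$count, 1L)
})

test_that("midpoint counting over a partition conserves the library", {
  set.seed(31)
  n <- 1000L
  start <- sample.int(9500L, n) - 1L
  frags <- make_frags(data.frame(chrom = "chr1", start = start,
                                 end = start + sample(50:400, n, TRUE),
                                 stringsAsFactors = FALSE))
  edges <- seq(0L, 10000L, by = 500L)
  part <- data.frame(region_id = paste0("b", seq_len(20)), chrom = "chr1",
                     start = edges[-21], end = edges[-1],
                     stringsAsFactors = FALSE)
  counts <- count_fragments(frags, part)
  expect_equal(sum(counts$count), frags$library_size)
  # order invariance
  shuf <- frags
  shuf$fragments <- shuf$fragments[sample.int(n), ]
  expect_equal(count_fragments(shuf, part)$count, counts$count)
})

test_that("any-overlap counting can hit multiple regions", {
  frags <- make_frags(data.frame(chrom = "chr1", start = 90L, end = 310L,
                                 stringsAsFactors = FALSE))
  regions <- data.frame(region_id = c("a", "b"), chrom = "chr1",
                        start = c(0L, 300L), end = c(100L, 400L),
                        stringsAsFactors = FALSE)
  expect_equal(count_fragments(frags, regions, rule = "any_overlap")$count,
               c(1L, 1L))
  expect_equal(count_fragments(frags, regions, rule = "midpoint")$count,
               c(0L, 0L))
})

test_that("densities and CPM follow their definitions", {
  expect_equal(region_density(35, 350), 0.1)
  expect_equal(region_density(0, 1000, pseudocount = 0.5), 0.0005)
  expect_equal(region_density(c(10, 20), c(100, 100)),
               2 * region_density(c(5, 10), c(100, 100)))
  expect_equal(cpm_normalize(50, 1e6), 50)
  expect_equal(cpm_normalize(50, 2e6), 25)
  expect_equal(cpm_normalize(0, 1e6), 0)
  expect_error(cpm_normalize(1, 0), "positive")
})

test_that("metagene profiles are flat for uniform coverage and peaked for a
           point fragment", {
  tile <- data.frame(chrom = "chr1", start = seq(0L, 9900L, 100L),
                     end = seq(100L, 10000L, 100L), stringsAsFactors = FALSE)
  frags <- make_frags(tile)  # perfectly uniform 1x coverage
  anchors <- data.frame(chrom = "chr1", pos = c(4000L, 6000L),
                        strand = c("+", "-"), stringsAsFactors = FALSE)
  prof <- metagene_profile(frags, anchors, flank_bp = 1000L, bin_bp = 100L)
  expect_equal(max(prof$mean) - min(prof$mean), 0, tolerance = 1e-12)
  single <- make_frags(data.frame(chrom = "chr1", start = 3990L, end = 4010L,
                                  stringsAsFactors = FALSE))
  prof1 <- metagene_profile(single,
                            anchors[1, , drop = FALSE],
                            flank_bp = 1000L, bin_bp = 100L)
  nonzero <- which(prof1$mean > 0)
  expect_true(all(nonzero %in% c(10L, 11L)))  # central bins only
})

test_that("metagene profile of reflected data is the reversed profile", {
  set.seed(7)
  L <- 20000L
  start <- sort(sample.int(L - 500L, 400L)) - 1L
  frags <- make_frags(data.frame(chrom = "chr1", start = start,
                                 end = start + 200L, stringsAsFactors = FALSE))
  refl <- make_frags(data.frame(chrom = "chr1", start = L - (start + 200L),
                                end = L - start, stringsAsFactors = FALSE))
  anchors <- data.frame(chrom = "chr1", pos = 8000L, strand = "+",
                        stringsAsFactors = FALSE)
  anchors_r <- data.frame(chrom = "chr1", pos = L - 8000L, strand = "+",
                          stringsAsFactors = FALSE)
  p1 <- metagene_profile(frags, anchors, flank_bp = 2000L, bin_bp = 50L)
  p2 <- metagene_profile(refl, anchors_r, flank_bp = 2000L, bin_bp = 50L)
  expect_equal(unname(p2$mean), unname(rev(p1$mean)))
})

test_that("paired BAM records collapse to template-span fragments", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    "r1\t99\tchr1\t101\t60\t50M\t=\t301\t250\t*\t*",
    "r1\t147\tchr1\t301\t60\t50M\t=\t101\t-250\t*\t*"
  ), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  fs <- load_fragments(bam, format = "bam")
  expect_equal(fs$library_size, 1L)
  expect_equal(fs$fragments$chrom, "chr1")
  expect_equal(c(fs$fragments$start, fs$fragments$end), c(100L, 350L))
})
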