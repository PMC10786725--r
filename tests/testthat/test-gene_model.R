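test_that("GTF loading keeps the longest isoform and converts coordinates", {
  path <- write_test_gtf(c(
    gtf_line("chr1", "transcript", 1001, 3000, "+", "G", "Ta"),   # 2000 bp
    gtf_line("chr1", "transcript", 1001, 6000, "+", "G", "Tb"),   # 5000 bp
    gtf_line("chr1", "transcript", 9001, 9500, "-", "H", "T2"),
    gtf_line("chr1", "transcript", 9001, 9500, "-", "H", "T1")    # equal length
  ))
  g <- load_annotation(path, "gtf")
  expect_equal(nrow(g), 2L)
  rec <- g[g$gene_id == "G", ]
  expect_equal(rec$transcript_id, "Tb")
  expect_equal(rec$length, 5000L)
  expect_equal(rec$start, 1000L)  # 1-based 1001 -> 0-based 1000
  expect_equal(rec$tss, 1000L)
  # equal-length tie broken by lexicographically smallest transcript id
  expect_equal(g$transcript_id[g$gene_id == "H"], "T1")
  # minus-strand TSS is the last covered base
  expect_equal(g$tss[g$gene_id == "H"], 9499L)
  expect_equal(g$tes[g$gene_id == "H"], 9000L)
})

test_that("transcript spans are assembled from exons when absent", {
  path <- write_test_gtf(c(
    gtf_line("chr1", "exon", 101, 200, "+", "G", "T1"),
    gtf_line("chr1", "exon", 501, 900, "+", "G", "T1")
  ))
  g <- load_annotation(path, "gtf")
  expect_equal(g$start, 100L)
  expect_equal(g$end, 900L)
})

test_that("malformed GTF input errors name the offending line", {
  path <- write_test_gtf(c(
    gtf_line("chr1", "transcript", 1, 100, "+", "G", "T1"),
    "chr1\tbroken line"
  ))
  expect_error(load_annotation(path, "gtf"), "line 2")
  path2 <- write_test_gtf(gtf_line("chr1", "transcript", 1, 100, "*", "G", "T1"))
  expect_error(load_annotation(path2, "gtf"), "strand")
})

test_that("kept genes survive a BED round-trip unchanged", {
  res <- filter_genes(toy_annotation())
  kept <- res$genes
  kept$name <- paste0(kept$gene_id, ":", kept$transcript_id)
  path <- tempfile(fileext = ".bed")
  write_bed(kept, path, name_col = "name")
  reread <- load_annotation(path, "bed12")
  expect_equal(reread, kept[, names(reread)], ignore_attr = TRUE)
})

test_that("length and proximity filters match the hand-enumerated toy set", {
  toy <- toy_annotation()
  res <- filter_genes(toy)
  expect_equal(res$report$n_input, 10L)
  expect_equal(res$report$n_kept, 6L)
  expect_setequal(res$genes$gene_id, c("g01", "g03", "g07", "g08", "g09", "g10"))
  excl <- res$report$excluded
  expect_setequal(excl$gene_id[excl$reason == "short_gene"], c("g02", "g06"))
  expect_setequal(excl$gene_id[excl$reason == "proximal_pair"], c("g04", "g05"))
  # report accounting invariant
  expect_equal(res$report$n_input, res$report$n_kept + nrow(excl))
  # a gene of exactly 1 kb is kept (strict "< 1 kb" exclusion)
  expect_true("g08" %in% res$genes$gene_id)
})

test_that("filter_genes is idempotent and handles empty input", {
  res1 <- filter_genes(toy_annotation())
  res2 <- filter_genes(res1$genes)
  expect_equal(res2$genes, res1$genes)
  expect_equal(res2$report$n_kept, res2$report$n_input)
  empty <- filter_genes(toy_annotation()[0, ])
  expect_equal(empty$report$n_input, 0L)
  expect_equal(nrow(empty$genes), 0L)
})

test_that("pausing windows follow the -50/+300 TSS and TES+3kb construction", {
  genes <- data.frame(
    gene_id = c("P", "M"), transcript_id = c("P.t1", "M.t1"),
    chrom = "chrT", strand = c("+", "-"),
    start = c(10000L, 20000L), end = c(15000L, 25000L),
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  genes$length <- genes$end - genes$start
  w <- make_pausing_windows(genes, chrom_sizes = c(chrT = 50000L))
  p <- w[w$gene_id == "P", ]
  expect_equal(c(p$promoter_start, p$promoter_end), c(9950L, 10300L))
  expect_equal(p$promoter_length, 350L)
  expect_equal(c(p$body_start, p$body_end), c(10300L, 18000L))
  # minus strand: mirrored in transcription direction
  m <- w[w$gene_id == "M", ]
  expect_equal(c(m$promoter_start, m$promoter_end), c(24700L, 25050L))
  expect_equal(m$promoter_length, 350L)
  expect_equal(c(m$body_start, m$body_end), c(17000L, 24700L))
  # bodies start exactly where promoters end, in transcription direction
  expect_equal(p$body_start, p$promoter_end)
  expect_equal(m$body_end, m$promoter_start)
})

test_that("windows are clipped to chromosome bounds with true lengths", {
  genes <- data.frame(
    gene_id = "G", transcript_id = "G.t1", chrom = "chrT", strand = "+",
    start = 10000L, end = 12000L, tss = 10000L, tes = 11999L, length = 2000L,
    stringsAsFactors = FALSE
  )
  w <- make_pausing_windows(genes, chrom_sizes = c(chrT = 13000L))
  expect_equal(c(w$body_start, w$body_end), c(10300L, 13000L))
  expect_equal(w$body_length, 2700L)
})

test_that("window construction is strand-symmetric under reflection", {
  cfg <- synthetic_config(seed = 11, n_genes = 40)
  ann <- simulate_annotation(cfg)
  L <- unname(ann$chrom_sizes)
  w <- make_pausing_windows(ann$genes, chrom_sizes = ann$chrom_sizes)
  refl <- ann$genes
  refl$start <- L - ann$genes$end
  refl$end <- L - ann$genes$start
  refl$strand <- ifelse(ann$genes$strand == "+", "-", "+")
  refl$tss <- ifelse(refl$strand == "+", refl$start, refl$end - 1L)
  refl$tes <- ifelse(refl$strand == "+", refl$end - 1L, refl$start)
  wr <- make_pausing_windows(refl, chrom_sizes = ann$chrom_sizes)
  i <- match(w$gene_id, wr$gene_id)
  expect_equal(wr$promoter_start[i], L - w$promoter_end)
  expect_equal(wr$promoter_end[i], L - w$promoter_start)
  expect_equal(wr$body_start[i], L - w$body_end)
  expect_equal(wr$body_end[i], L - w$body_start)
})

test_that("differential promoters span +/- 300 bp of the TSS, clipped", {
  genes <- data.frame(
    gene_id = c("A", "B"), transcript_id = c("A.t1", "B.t1"),
    chrom = "chrT", strand = "+",
    start = c(10000L, 100L), end = c(15000L, 5000L),
    tss = c(10000L, 100L), tes = c(14999L, 4999L),
    length = c(5000L, 4900L), stringsAsFactors = FALSE
  )
  pr <- make_diff_promoters(genes)
  expect_equal(nrow(pr), nrow(genes))  # bijection
  expect_equal(c(pr$start[1], pr$end[1]), c(9700L, 10300L))
  expect_equal(c(pr$start[2], pr$end[2]), c(0L, 400L))
})
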