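test_that("generators are pure functions of the config", {
  cfg <- synthetic_config(seed = 3, n_genes = 30)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  p1 <- tempfile(); p2 <- tempfile()
  write_gtf(a1$transcripts, p1)
  write_gtf(a2$transcripts, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical GTF
  f1 <- simulate_fragments(a1, cfg, "treated", replicate = 2)
  f2 <- simulate_fragments(a1, cfg, "treated", replicate = 2)
  expect_identical(f1$fragments, f2$fragments)
  d1 <- simulate_dose_response(cfg)
  d2 <- simulate_dose_response(cfg)
  expect_identical(d1, d2)
  # different replicates get different fragment streams
  f3 <- simulate_fragments(a1, cfg, "treated", replicate = 1)
  expect_false(identical(f1$fragments, f3$fragments))
})

test_that("annotation honours requested sizes and filter violations", {
  cfg <- synthetic_config(seed = 4, n_genes = 40, n_short_genes = 2,
                          n_close_pairs = 1)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 40L)
  expect_equal(sum(ann$genes$length < 1000), 2L)
  res <- filter_genes(ann$genes)
  excl <- res$report$excluded
  expect_equal(sum(excl$reason == "short_gene"), 2L)
  expect_gte(sum(excl$reason == "proximal_pair"), 2L)
  empty <- simulate_annotation(synthetic_config(seed = 4, n_genes = 0))
  expect_equal(nrow(empty$genes), 0L)
})

test_that("annotation round-trips through its GTF file", {
  cfg <- synthetic_config(seed = 5, n_genes = 25)
  ann <- simulate_annotation(cfg)
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann$transcripts, path)
  reread <- load_annotation(path, "gtf")
  expect_equal(reread, ann$genes)
})

test_that("empirical promoter fractions converge to the configured truth", {
  cfg <- synthetic_config(seed = 6, n_genes = 15, depth_per_gene = 10000,
                          background_rate = 0, multi_isoform_fraction = 0)
  ann <- simulate_annotation(cfg)
  truth <- pausing_truth(ann, cfg)
  w <- make_pausing_windows(ann$genes, chrom_sizes = ann$chrom_sizes)
  for (cond in c("vehicle", "treated")) {
    fs <- simulate_fragments(ann, cfg, cond)
    prom <- w[, c("gene_id", "chrom", "promoter_start", "promoter_end")]
    names(prom)[3:4] <- c("start", "end")
    body <- w[, c("gene_id", "chrom", "body_start", "body_end")]
    names(body)[3:4] <- c("start", "end")
    pc <- count_fragments(fs, prom)$count
    bc <- count_fragments(fs, body)$count
    phi_hat <- pc / (pc + bc)
    phi_true <- if (cond == "treated") truth$phi_treated else truth$phi_vehicle
    expect_lt(max(abs(phi_hat - phi_true)), 0.01)
  }
})

test_that("a null treatment effect leaves the truth table symmetric", {
  cfg <- synthetic_config(seed = 7, n_genes = 30, treated_effect = 1)
  ann <- simulate_annotation(cfg)
  truth <- pausing_truth(ann, cfg)
  expect_equal(truth$phi_treated, truth$phi_vehicle)
  expect_equal(truth$pi_gain, rep(0, nrow(truth)))
})

test_that("the affected set is shared across conditions and replicates", {
  cfg <- synthetic_config(seed = 8, n_genes = 50)
  ann <- simulate_annotation(cfg)
  t1 <- attr(simulate_fragments(ann, cfg, "vehicle", 1), "truth")
  t2 <- attr(simulate_fragments(ann, cfg, "treated", 2), "truth")
  expect_identical(t1$affected, t2$affected)
  expect_equal(mean(t1$affected), 0.6)
})

test_that("peak simulation reflects occupancy, jitter and thresholds", {
  cfg <- synthetic_config(seed = 9, n_genes = 30, peak_jitter_bp = 0L,
                          multi_isoform_fraction = 0)
  ann <- simulate_annotation(cfg)
  p1 <- simulate_peaks(ann, cfg, "vehicle", 1)
  p2 <- simulate_peaks(ann, cfg, "vehicle", 2)
  expect_identical(p1, p2)  # jitter 0 -> replicates identical
  expect_equal(consensus_peaks(p1, p2), p1)
  # all promoters occupied at the default depth -> peaks at all promoters
  expect_equal(nrow(p1), 30L)
  expect_equal(p1$end - p1$start, rep(600L, 30))
  none <- synthetic_config(seed = 9, n_genes = 30,
                           peak_min_expected = 1e9)
  expect_equal(nrow(simulate_peaks(ann, none, "vehicle", 1)), 0L)
})

test_that("noise-free dose-response tables sit exactly on the 4PL curve", {
  cfg <- synthetic_config(seed = 10, noise_sd_percent = 0)
  tab <- simulate_dose_response(cfg)
  tr <- attr(tab, "truth")
  nz <- tab$dose_nM > 0
  expect_equal(tab$response[nz],
               fourpl(tab$dose_nM[nz], tr$top, tr$bottom, tr$ic50, tr$hill))
  expect_equal(tab$response[!nz], rep(100, sum(!nz)))
  # mean response at the true IC50 is the curve midpoint
  at_ic50 <- fourpl(tr$ic50, tr$top, tr$bottom, tr$ic50, tr$hill)
  expect_equal(at_ic50, (tr$top + tr$bottom) / 2)
})

test_that("NB count simulation marks truth and matches its dimensions", {
  m <- simulate_promoter_counts(100, n_per_condition = 3, fraction_de = 0.4,
                                fold = 3, seed = 11)
  expect_equal(dim(m), c(100L, 6L))
  expect_equal(length(attr(m, "de")), 100L)
  expect_true(all(m >= 0))
  de <- attr(m, "de")
  ratio <- rowMeans(m[, 4:6]) / pmax(rowMeans(m[, 1:3]), 1)
  expect_gt(median(ratio[de]), 2)
  expect_lt(median(ratio[!de]), 1.5)
})
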