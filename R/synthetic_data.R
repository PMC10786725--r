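#' Configuration for the synthetic ChIP and dose-response generators
#'
#' Bundles every tunable of the seeded generators. The defaults emulate a
#' promoter-proximal pausing experiment at desk scale: genes of 4-12 kb
#' separated by 4-12 kb gaps on one synthetic chromosome, a per-gene
#' occupancy of `depth_per_gene` expected fragments split between a
#' promoter-proximal component (Gaussian pause site 40 bp downstream of the
#' TSS, sd 50 bp) and uniform gene-body signal, uniform genomic background,
#' and a treatment that multiplies the promoter rate by `treated_effect` for
#' a fraction `affected_fraction` of genes, with the total per-gene
#' occupancy held fixed (pausing redistributes polymerase; it does not add
#' it). Baseline genes have equal promoter and body densities
#' (`baseline_log2_pi = 0`).
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   the config, seed included.
#' @param n_genes Total genes placed (including injected filter violations).
#' @param gene_length_range_bp,gap_range_bp Sampling ranges for gene lengths
#'   and intergenic gaps, bp.
#' @param n_short_genes Number of genes deliberately shorter than 1 kb.
#' @param n_close_pairs Number of adjacent gene pairs given a 2.5 kb gap
#'   (violating the 3 kb proximity filter).
#' @param multi_isoform_fraction Fraction of genes given a second, shorter
#'   transcript (exercises the longest-isoform rule).
#' @param depth_per_gene Expected fragments per gene (Poisson lambda).
#' @param baseline_log2_pi True baseline pausing index of unaffected genes.
#' @param treated_effect Promoter-rate multiplier (delta) on affected genes.
#' @param affected_fraction Fraction of genes receiving the effect.
#' @param background_rate Background fragments per bp per library.
#' @param fragment_length_mean_bp,fragment_length_sd_bp Fragment length
#'   distribution (Normal, truncated at >= 50 bp).
#' @param pause_offset_bp,pause_sd_bp Pause-site position model: Normal
#'   centred `pause_offset_bp` downstream of the TSS, truncated to the
#'   promoter window.
#' @param peak_min_expected Minimum expected promoter fragments for a
#'   simulated peak call.
#' @param peak_jitter_bp Per-replicate uniform jitter on peak edges, bp.
#' @param doses_nM Nonzero dose ladder for dose-response tables.
#' @param n_dose_replicates Replicate wells per dose.
#' @param noise_sd_percent Gaussian response noise, percentage points.
#' @param fourpl_truth True 4PL parameters (`top`, `bottom`, `ic50`,
#'   `hill`).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 300L,
                             gene_length_range_bp = c(4000L, 12000L),
                             gap_range_bp = c(4000L, 12000L),
                             n_short_genes = 0L,
                             n_close_pairs = 0L,
                             multi_isoform_fraction = 0.25,
                             depth_per_gene = 200,
                             baseline_log2_pi = 0,
                             treated_effect = 4,
                             affected_fraction = 0.6,
                             background_rate = 2e-5,
                             fragment_length_mean_bp = 200,
                             fragment_length_sd_bp = 40,
                             pause_offset_bp = 40,
                             pause_sd_bp = 50,
                             peak_min_expected = 3,
                             peak_jitter_bp = 20L,
                             doses_nM = c(75, 150, 300, 600, 1200, 2400),
                             n_dose_replicates = 5L,
                             noise_sd_percent = 5,
                             fourpl_truth = list(top = 100, bottom = 0,
                                                 ic50 = 500, hill = 1.5)) {
  cfg <- as.list(environment())
  stopifnot(cfg$treated_effect > 0,
            cfg$affected_fraction >= 0, cfg$affected_fraction <= 1,
            cfg$depth_per_gene > 0,
            cfg$fourpl_truth$bottom >= 0,
            cfg$fourpl_truth$bottom <= cfg$fourpl_truth$top,
            cfg$fourpl_truth$top <= 100)
  structure(cfg, class = "synthetic_config")
}

# run code under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a gene annotation
#'
#' Places `n_genes` left-to-right on one synthetic chromosome with sampled
#' lengths and gaps and alternating strands, optionally injecting the stated
#' numbers of sub-1 kb genes and 2.5 kb-gap gene pairs so the exclusion
#' filters are exercised. A fraction of genes receive a second, shorter
#' transcript.
#'
#' @param config A [synthetic_config()].
#' @return List: `genes` (canonical longest-isoform records, as
#'   [load_annotation()] returns), `transcripts` (all isoforms),
#'   `chrom_sizes` (named vector), `chrom`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  chrom <- "chrS"
  if (n == 0L) {
    return(list(genes = empty_gene_records(),
                transcripts = empty_gene_records()[, 1:6],
                chrom_sizes = c(chrS = 10000L), chrom = chrom))
  }
  with_seed(config$seed * 13L + 1L, {
    len <- sample(config$gene_length_range_bp[1]:config$gene_length_range_bp[2],
                  n, replace = TRUE)
    gap <- sample(config$gap_range_bp[1]:config$gap_range_bp[2],
                  n, replace = TRUE)
    short_idx <- integer(0)
    if (config$n_short_genes > 0L) {
      stopifnot(config$n_short_genes <= n)
      short_idx <- sample(n, config$n_short_genes)
      len[short_idx] <- sample(300:999, config$n_short_genes, replace = TRUE)
    }
    if (config$n_close_pairs > 0L) {
      # gap[i] precedes gene i, so a close pair is (pick - 1, pick); keep
      # the pairs away from the short genes so the violation classes stay
      # disjoint
      avail <- setdiff(2:n, c(short_idx, short_idx + 1L))
      close_idx <- integer(0)
      for (j in seq_len(config$n_close_pairs)) {
        pick <- sample(avail, 1L)
        close_idx <- c(close_idx, pick)
        avail <- setdiff(avail, (pick - 1L):(pick + 1L))  # keep pairs isolated
        if (!length(avail)) break
      }
      gap[close_idx] <- 2500L
    }
    start <- cumsum(c(gap[1], len[-n] + gap[-1]))
    end <- start + len
    strand <- rep(c("+", "-"), length.out = n)
    gene_id <- sprintf("G%04d", seq_len(n))
    tx <- data.frame(
      gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
      chrom = chrom, strand = strand, start = start, end = end,
      stringsAsFactors = FALSE
    )
    multi <- which(stats::runif(n) < config$multi_isoform_fraction)
    if (length(multi)) {
      frac <- stats::runif(length(multi), 0.4, 0.8)
      short_len <- pmax(200L, as.integer(round(len[multi] * frac)))
      tx2 <- tx[multi, , drop = FALSE]
      tx2$transcript_id <- paste0(tx2$gene_id, ".t2")
      # shorter isoform shares the 5' end
      plus <- tx2$strand == "+"
      tx2$end[plus] <- tx2$start[plus] + short_len[plus]
      tx2$start[!plus] <- tx2$end[!plus] - short_len[!plus]
      tx <- rbind(tx, tx2)
    }
    tx <- tx[order(tx$start, tx$transcript_id), , drop = FALSE]
    rownames(tx) <- NULL
    chrom_len <- max(end) + max(config$gap_range_bp)
    genes <- tx[tx$transcript_id == paste0(tx$gene_id, ".t1"), , drop = FALSE]
    genes$length <- genes$end - genes$start
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
    genes <- genes[, c("gene_id", "transcript_id", "chrom", "strand",
                       "start", "end", "tss", "tes", "length")]
    rownames(genes) <- NULL
    list(genes = genes, transcripts = tx,
         chrom_sizes = stats::setNames(chrom_len, chrom), chrom = chrom)
  })
}

#' Ground-truth pausing table for a synthetic annotation
#'
#' Deterministic given the config: per gene, the vehicle promoter fraction
#' solving the configured baseline pausing index for that gene's window
#' lengths, the affected flag (drawn once from the config seed, shared by
#' all conditions and replicates), the treated promoter fraction after
#' scaling the promoter rate by `treated_effect` and renormalizing, the true
#' pausing indices of both conditions and the true promoter fold change.
#'
#' @param ann Result of [simulate_annotation()].
#' @param config The [synthetic_config()] used.
#' @return Data.frame keyed by `gene_id`.
#' @export
pausing_truth <- function(ann, config) {
  w <- make_pausing_windows(ann$genes, chrom_sizes = ann$chrom_sizes)
  ratio <- 2^config$baseline_log2_pi * w$promoter_length / w$body_length
  phi_v <- ratio / (1 + ratio)
  n <- nrow(w)
  affected <- rep(FALSE, n)
  n_aff <- round(config$affected_fraction * n)
  if (n_aff > 0L) {
    idx <- with_seed(config$seed * 13L + 2L, sample(n, n_aff))
    affected[idx] <- TRUE
  }
  d <- config$treated_effect
  phi_t <- ifelse(affected, d * phi_v / (d * phi_v + 1 - phi_v), phi_v)
  true_pi <- function(phi) {
    log2((phi / w$promoter_length) / ((1 - phi) / w$body_length))
  }
  data.frame(
    gene_id = w$gene_id,
    affected = affected,
    phi_vehicle = phi_v, phi_treated = phi_t,
    pi_vehicle = true_pi(phi_v), pi_treated = true_pi(phi_t),
    pi_gain = true_pi(phi_t) - true_pi(phi_v),
    promoter_fold = phi_t / phi_v,
    stringsAsFactors = FALSE
  )
}

#' Simulate ChIP fragments with known pausing structure
#'
#' Per gene, the fragment count is Poisson(`depth_per_gene`); each fragment
#' is promoter-proximal with the condition's true promoter fraction.
#' Promoter fragment midpoints follow a Normal centred `pause_offset_bp`
#' downstream of the TSS (sd `pause_sd_bp`) truncated to the promoter
#' window; body midpoints are uniform on the body window. Background
#' fragments are uniform genome-wide at `background_rate` per bp. Fragment
#' lengths are Normal(`fragment_length_mean_bp`, `fragment_length_sd_bp`)
#' truncated at >= 50 bp.
#'
#' @param ann Result of [simulate_annotation()].
#' @param config The [synthetic_config()].
#' @param condition `"vehicle"` or `"treated"`.
#' @param replicate Replicate number (each condition/replicate pair gets its
#'   own reproducible RNG stream).
#' @return A [fragment_set()] with the truth table attached as attribute
#'   `"truth"`.
#' @export
simulate_fragments <- function(ann, config,
                               condition = c("vehicle", "treated"),
                               replicate = 1L) {
  condition <- match.arg(condition)
  truth <- pausing_truth(ann, config)
  w <- make_pausing_windows(ann$genes, chrom_sizes = ann$chrom_sizes)
  stopifnot(identical(w$gene_id, truth$gene_id))
  chrom_len <- unname(ann$chrom_sizes[ann$chrom])
  phi <- if (condition == "treated") truth$phi_treated else truth$phi_vehicle
  seed <- config$seed * 13L + 100L * match(condition, c("vehicle", "treated")) +
    replicate
  frag <- with_seed(seed, {
    n_frag <- stats::rpois(nrow(w), config$depth_per_gene)
    gene_i <- rep(seq_len(nrow(w)), n_frag)
    is_prom <- stats::runif(length(gene_i)) < phi[gene_i]
    mid <- numeric(length(gene_i))
    # promoter: truncated normal around the pause site, strand-aware
    pi_idx <- which(is_prom)
    tss_all <- ann$genes$tss[match(w$gene_id, ann$genes$gene_id)]
    if (length(pi_idx)) {
      g <- gene_i[pi_idx]
      plus <- w$strand[g] == "+"
      mu <- ifelse(plus, tss_all[g] + config$pause_offset_bp,
                   tss_all[g] - config$pause_offset_bp)
      lo <- stats::pnorm(w$promoter_start[g], mu, config$pause_sd_bp)
      hi <- stats::pnorm(w$promoter_end[g] - 1L, mu, config$pause_sd_bp)
      u <- stats::runif(length(pi_idx), lo, hi)
      mid[pi_idx] <- stats::qnorm(u, mu, config$pause_sd_bp)
    }
    bi_idx <- which(!is_prom)
    if (length(bi_idx)) {
      g <- gene_i[bi_idx]
      mid[bi_idx] <- stats::runif(length(bi_idx), w$body_start[g],
                                  w$body_end[g] - 1L)
    }
    n_bg <- stats::rpois(1, config$background_rate * chrom_len)
    mid <- c(mid, stats::runif(n_bg, 0, chrom_len - 1L))
    # truncated-normal fragment lengths, >= 50 bp
    lo_l <- stats::pnorm(50, config$fragment_length_mean_bp,
                         config$fragment_length_sd_bp)
    u_l <- stats::runif(length(mid), lo_l, 1)
    len <- pmax(50, round(stats::qnorm(u_l, config$fragment_length_mean_bp,
                                       config$fragment_length_sd_bp)))
    start <- pmax(0L, as.integer(round(mid - len / 2)))
    end <- pmin(chrom_len, as.integer(round(mid + len / 2)))
    ok <- end > start
    data.frame(chrom = ann$chrom, start = start[ok], end = end[ok],
               stringsAsFactors = FALSE)
  })
  fs <- fragment_set(paste0(condition, "_rep", replicate), frag)
  attr(fs, "truth") <- truth
  fs
}

#' Simulate per-replicate peak calls over occupied promoters
#'
#' Emits a peak spanning the +/- 300 bp promoter of every gene whose
#' expected promoter fragment count (`depth_per_gene` times the condition's
#' true promoter fraction) reaches `peak_min_expected`, with peak edges
#' jittered uniformly within `+/- peak_jitter_bp` per replicate.
#'
#' @inheritParams simulate_fragments
#' @return Data.frame of peak intervals `chrom`, `start`, `end`.
#' @export
simulate_peaks <- function(ann, config,
                           condition = c("vehicle", "treated"),
                           replicate = 1L) {
  condition <- match.arg(condition)
  truth <- pausing_truth(ann, config)
  phi <- if (condition == "treated") truth$phi_treated else truth$phi_vehicle
  expected <- config$depth_per_gene * phi
  genes <- ann$genes[match(truth$gene_id, ann$genes$gene_id), , drop = FALSE]
  called <- expected >= config$peak_min_expected
  if (!any(called)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  g <- genes[called, , drop = FALSE]
  seed <- config$seed * 13L + 500L * match(condition, c("vehicle", "treated")) +
    replicate
  with_seed(seed, {
    j <- config$peak_jitter_bp
    js <- if (j > 0) sample(-j:j, nrow(g), replace = TRUE) else 0L
    je <- if (j > 0) sample(-j:j, nrow(g), replace = TRUE) else 0L
    out <- data.frame(
      chrom = g$chrom,
      start = pmax(0L, as.integer(g$tss - 300L + js)),
      end = as.integer(g$tss + 300L + je),
      stringsAsFactors = FALSE
    )
    out[order(out$start), , drop = FALSE]
  })
}

#' Simulate gene-set collections with one planted signal set
#'
#' Builds random gene sets from the annotation plus one planted set drawn
#' mostly from the treatment-affected genes, so over-representation analysis
#' can be exercised against known truth.
#'
#' @param ann Result of [simulate_annotation()].
#' @param config The [synthetic_config()].
#' @param n_random_sets Number of random sets.
#' @param set_size Genes per set.
#' @param planted_purity Fraction of the planted set drawn from affected
#'   genes.
#' @return Named list of gene-id vectors; the planted set is
#'   `"PLANTED_AFFECTED"`.
#' @export
simulate_gene_sets <- function(ann, config, n_random_sets = 10L,
                               set_size = 30L, planted_purity = 1) {
  truth <- pausing_truth(ann, config)
  ids <- truth$gene_id
  aff <- truth$gene_id[truth$affected]
  unaff <- truth$gene_id[!truth$affected]
  with_seed(config$seed * 13L + 3L, {
    n_aff <- min(length(aff), round(planted_purity * set_size))
    planted <- c(sample(aff, n_aff),
                 sample(unaff, min(length(unaff), set_size - n_aff)))
    sets <- lapply(seq_len(n_random_sets), function(i) {
      sample(ids, min(set_size, length(ids)))
    })
    names(sets) <- sprintf("RANDOM_%02d", seq_len(n_random_sets))
    c(list(PLANTED_AFFECTED = planted), sets)
  })
}

#' Simulate a dose-response table from a known 4PL curve
#'
#' Responses are the true four-parameter logistic curve evaluated at each
#' dose plus Gaussian noise (`noise_sd_percent` percentage points), with
#' vehicle rows (dose 0) at 100% plus noise.
#'
#' @param config A [synthetic_config()].
#' @param n_experiments Independent experiments to simulate.
#' @return Data.frame `experiment`, `dose_nM`, `replicate`, `response`, with
#'   the true parameters attached as attribute `"truth"`.
#' @export
simulate_dose_response <- function(config, n_experiments = 1L) {
  tr <- config$fourpl_truth
  doses <- c(0, config$doses_nM)
  with_seed(config$seed * 13L + 4L, {
    grid <- expand.grid(
      replicate = seq_len(config$n_dose_replicates),
      dose_nM = doses,
      experiment = seq_len(n_experiments)
    )[, c("experiment", "dose_nM", "replicate")]
    mu <- fourpl(grid$dose_nM, tr$top, tr$bottom, tr$ic50, tr$hill)
    mu[grid$dose_nM == 0] <- 100  # vehicle defines 100%
    grid$response <- mu + stats::rnorm(nrow(grid), 0, config$noise_sd_percent)
    attr(grid, "truth") <- tr
    grid
  })
}

#' Simulate a promoter count matrix with negative-binomial noise
#'
#' Generates a promoters x samples count matrix for depth-matched libraries
#' (2 conditions), with per-promoter baseline means drawn log-normally and a
#' chosen fraction of promoters given a fold-change in the second condition.
#' Used for type-I calibration (fraction_de = 0) and power/recovery studies
#' of the differential test. Because the simulated libraries are
#' depth-matched, the true size factors are all 1 (returned as attribute
#' `"size_factors"`).
#'
#' @param n_promoters Number of promoters.
#' @param n_per_condition Replicates per condition.
#' @param mean_log,sd_log Log-normal parameters of baseline mean counts.
#' @param dispersion NB dispersion (Var = mu + dispersion * mu^2).
#' @param fraction_de Fraction of promoters with a true condition effect.
#' @param fold Fold change applied to affected promoters in condition 2.
#' @param seed RNG seed.
#' @return Integer matrix with attributes `"de"` (logical truth vector) and
#'   `"size_factors"`; columns are condition 1 then condition 2 replicates.
#' @export
simulate_promoter_counts <- function(n_promoters = 2000L,
                                     n_per_condition = 2L,
                                     mean_log = log(200), sd_log = 0.5,
                                     dispersion = 0.02,
                                     fraction_de = 0, fold = 2,
                                     seed = 1L) {
  with_seed(seed, {
    mu <- stats::rlnorm(n_promoters, mean_log, sd_log)
    de <- stats::runif(n_promoters) < fraction_de
    mu2 <- ifelse(de, mu * fold, mu)
    rnb <- function(m) {
      matrix(stats::rnbinom(n_promoters * n_per_condition,
                            mu = rep(m, n_per_condition),
                            size = 1 / dispersion),
             nrow = n_promoters)
    }
    mat <- cbind(rnb(mu), rnb(mu2))
    rownames(mat) <- sprintf("P%05d", seq_len(n_promoters))
    colnames(mat) <- c(paste0("cond1_rep", seq_len(n_per_condition)),
                       paste0("cond2_rep", seq_len(n_per_condition)))
    attr(mat, "de") <- de
    attr(mat, "size_factors") <- rep(1, 2L * n_per_condition)
    mat
  })
}
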