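#' End-to-end pausing analysis on synthetic data
#'
#' Runs the whole promoter-pausing workflow on generator output: simulate an
#' annotation and per-condition replicate fragment/peak sets, apply the gene
#' filters, build pausing windows and +/- 300 bp promoters, form consensus
#' peaks per condition and the promoter universe, count fragments, compute
#' per-condition pausing indices and their paired Wilcoxon comparison,
#' run the differential promoter-enrichment test, and test gene-set
#' over-representation of the gained promoters against the unchanged +
#' decreased background.
#'
#' @param config A [synthetic_config()].
#' @param n_replicates ChIP replicates per condition.
#' @param universe `"peaks"` restricts the pausing gene universe to filtered
#'   genes whose differential promoter carries a consensus peak in at least
#'   one condition (the default analysis universe); `"all"` uses every
#'   filtered gene.
#' @param pseudocount Pausing-index pseudocount.
#' @param alpha FDR threshold for differential classification and
#'   enrichment.
#' @return List with the annotation, truth table, filter report, windows,
#'   per-condition pausing tables (`pi_vehicle`, `pi_treated`, matched by
#'   gene), `wilcoxon`, `paused_summary` (treated condition),
#'   `differential`, `enrichment`, and the consensus peak sets.
#' @export
run_chip_workflow <- function(config, n_replicates = 2L,
                              universe = c("peaks", "all"),
                              pseudocount = 0.5, alpha = 0.05) {
  universe <- match.arg(universe)
  ann <- simulate_annotation(config)
  truth <- pausing_truth(ann, config)
  flt <- filter_genes(ann$genes)
  windows <- make_pausing_windows(flt$genes, chrom_sizes = ann$chrom_sizes)
  promoters <- make_diff_promoters(flt$genes, chrom_sizes = ann$chrom_sizes)

  conditions <- c("vehicle", "treated")
  frags <- lapply(conditions, function(cond) {
    lapply(seq_len(n_replicates), function(r) {
      simulate_fragments(ann, config, condition = cond, replicate = r)
    })
  })
  names(frags) <- conditions
  peaks <- lapply(conditions, function(cond) {
    lapply(seq_len(n_replicates), function(r) {
      simulate_peaks(ann, config, condition = cond, replicate = r)
    })
  })
  names(peaks) <- conditions
  consensus <- lapply(peaks, function(p) consensus_peaks(p[[1]], p[[2]]))

  univ_ids <- if (universe == "peaks") {
    promoter_universe(consensus, promoters)
  } else {
    promoters$gene_id
  }

  prom_regions <- windows[windows$gene_id %in% univ_ids,
                          c("gene_id", "chrom", "promoter_start",
                            "promoter_end")]
  names(prom_regions)[3:4] <- c("start", "end")
  body_regions <- windows[windows$gene_id %in% univ_ids,
                          c("gene_id", "chrom", "body_start", "body_end")]
  names(body_regions)[3:4] <- c("start", "end")

  pi_tabs <- lapply(conditions, function(cond) {
    pc <- lapply(frags[[cond]], count_fragments, regions = prom_regions)
    bc <- lapply(frags[[cond]], count_fragments, regions = body_regions)
    condition_pi(pc, bc, condition = cond, pseudocount = pseudocount)
  })
  names(pi_tabs) <- conditions
  ids <- intersect(pi_tabs$vehicle$gene_id, pi_tabs$treated$gene_id)
  pi_v <- pi_tabs$vehicle[match(ids, pi_tabs$vehicle$gene_id), ]
  pi_t <- pi_tabs$treated[match(ids, pi_tabs$treated$gene_id), ]
  wx <- paired_wilcoxon(pi_v$pi, pi_t$pi)
  paused <- classify_paused(pi_t$pi)

  diff_regions <- promoters[promoters$gene_id %in% univ_ids, , drop = FALSE]
  diff_regions$region_id <- diff_regions$gene_id
  counts <- do.call(cbind, lapply(unlist(frags, recursive = FALSE),
                                  function(f) {
                                    count_fragments(f, diff_regions)$count
                                  }))
  rownames(counts) <- diff_regions$gene_id
  colnames(counts) <- vapply(unlist(frags, recursive = FALSE),
                             `[[`, character(1), "sample_id")
  cond_labels <- rep(conditions, each = n_replicates)
  # normalize to sequencing depth: a global promoter gain is real signal
  # here, so promoter-composition (median-of-ratios) factors would erase it
  lib <- vapply(unlist(frags, recursive = FALSE), `[[`, numeric(1),
                "library_size")
  lib_sf <- lib / exp(mean(log(lib)))
  diff <- differential_test(counts, cond_labels, alpha = alpha,
                            sample_size_factors = lib_sf)

  gained <- diff$id[diff$class == "increased"]
  bg <- diff$id[diff$class != "increased"]
  sets <- simulate_gene_sets(ann, config)
  enr <- if (length(gained) && length(bg)) {
    enrich(gained, bg, sets, alpha = alpha)
  } else {
    NULL
  }

  list(
    config = config, annotation = ann, truth = truth,
    filter_report = flt$report, windows = windows, promoters = promoters,
    consensus = consensus, universe = ids,
    pi_vehicle = pi_v, pi_treated = pi_t,
    wilcoxon = wx, paused_summary = paused,
    differential = diff, gene_sets = sets, enrichment = enr
  )
}
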