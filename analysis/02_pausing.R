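#!/usr/bin/env Rscript

# Step 2: pausing-index analysis.
#
# Reads the simulated annotation, fragments and peaks from step 1, applies
# the gene filters (< 1 kb length, < 3 kb proximity), builds the -50/+300 bp
# promoter and TSS+300..TES+3kb gene-body windows, counts fragment midpoints
# per window, averages replicate densities per condition, and compares the
# per-gene log2 pausing indices between conditions with a paired two-sided
# Wilcoxon test. Writes the per-gene table, the ECDFs, a TSS metagene
# profile and a JSON summary.

library(polpause)

in_dir <- "results/simulated"
out_dir <- "results/pausing"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genes <- load_annotation(file.path(in_dir, "annotation.gtf"), "gtf")
chrom_sizes <- read_chrom_sizes(file.path(in_dir, "chrom.sizes"))
flt <- filter_genes(genes)
message(sprintf("filters: %d of %d genes kept", flt$report$n_kept,
                flt$report$n_input))
write.table(flt$report$excluded, file.path(out_dir, "excluded_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

windows <- make_pausing_windows(flt$genes, chrom_sizes = chrom_sizes)
promoters <- make_diff_promoters(flt$genes, chrom_sizes = chrom_sizes)

frags <- lapply(c("vehicle", "treated"), function(cond) {
  lapply(1:2, function(r) {
    load_fragments(file.path(in_dir, sprintf("fragments_%s_rep%d.bed",
                                             cond, r)),
                   sample_id = sprintf("%s_rep%d", cond, r))
  })
})
names(frags) <- c("vehicle", "treated")
peaks <- lapply(c("vehicle", "treated"), function(cond) {
  lapply(1:2, function(r) {
    p <- read.table(file.path(in_dir, sprintf("peaks_%s_rep%d.bed", cond, r)),
                    sep = "\t", col.names = c("chrom", "start", "end"),
                    colClasses = c("character", "integer", "integer"))
    p
  })
})
names(peaks) <- c("vehicle", "treated")
consensus <- lapply(peaks, function(p) consensus_peaks(p[[1]], p[[2]]))
universe <- promoter_universe(consensus, promoters)
message(length(universe), " genes carry a consensus promoter peak in >= 1 ",
        "condition")

region_frame <- function(w, which) {
  out <- w[w$gene_id %in% universe,
           c("gene_id", "chrom", paste0(which, "_start"),
             paste0(which, "_end"))]
  names(out)[3:4] <- c("start", "end")
  out
}
pi_tab <- lapply(names(frags), function(cond) {
  pc <- lapply(frags[[cond]], count_fragments,
               regions = region_frame(windows, "promoter"))
  bc <- lapply(frags[[cond]], count_fragments,
               regions = region_frame(windows, "body"))
  condition_pi(pc, bc, condition = cond)
})
names(pi_tab) <- names(frags)

ids <- intersect(pi_tab$vehicle$gene_id, pi_tab$treated$gene_id)
pv <- pi_tab$vehicle[match(ids, pi_tab$vehicle$gene_id), ]
pt <- pi_tab$treated[match(ids, pi_tab$treated$gene_id), ]
merged <- data.frame(gene_id = ids, pi_vehicle = pv$pi, pi_treated = pt$pi,
                     delta_pi = pt$pi - pv$pi)
write.table(merged, file.path(out_dir, "pausing_index.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ecdf_table(pv$pi), file.path(out_dir, "ecdf_vehicle.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ecdf_table(pt$pi), file.path(out_dir, "ecdf_treated.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

wx <- paired_wilcoxon(pv$pi, pt$pi)
paused <- classify_paused(pt$pi)
message(sprintf(
  "pausing: %.1f%% of %d genes have PI > 1 after treatment (vehicle: %.1f%%)",
  100 * paused$fraction_paused, paused$n_genes,
  100 * classify_paused(pv$pi)$fraction_paused))
message(sprintf("paired Wilcoxon: W = %.0f, n = %d, p = %.3g (%s)",
                wx$W, wx$n, wx$p, wx$method))

# TSS metagene profile (average across both replicates of each condition)
anchors <- flt$genes[flt$genes$gene_id %in% universe, ]
anchors <- data.frame(chrom = anchors$chrom, pos = anchors$tss,
                      strand = anchors$strand)
prof <- lapply(names(frags), function(cond) {
  p1 <- metagene_profile(frags[[cond]][[1]], anchors, 2000L, 50L)$mean
  p2 <- metagene_profile(frags[[cond]][[2]], anchors, 2000L, 50L)$mean
  (p1 + p2) / 2
})
names(prof) <- names(frags)
write.table(
  data.frame(bin_center = as.integer(names(prof$vehicle)),
             vehicle_cpm = prof$vehicle, treated_cpm = prof$treated),
  file.path(out_dir, "metagene_tss.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)

jsonlite::write_json(
  list(n_genes = paused$n_genes,
       fraction_paused = paused$fraction_paused,
       wilcoxon = wx[c("W", "n", "p", "method")]),
  file.path(out_dir, "summary.json"),
  auto_unbox = TRUE, digits = NA
)
message("pausing outputs written to ", out_dir)
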