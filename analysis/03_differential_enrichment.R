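#!/usr/bin/env Rscript

# Step 3: differential promoter enrichment and gene-set over-representation.
#
# Counts fragments in the +/- 300 bp promoters of the consensus-peak
# universe for all four samples, tests each promoter for a condition effect
# (NB exact conditional test, common moment dispersion, library-size
# normalization), classifies at BH FDR < 0.05, and tests HALLMARK-style
# gene sets for over-representation among the gained promoters against the
# unchanged + decreased background.

library(polpause)

in_dir <- "results/simulated"
out_dir <- "results/differential"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genes <- load_annotation(file.path(in_dir, "annotation.gtf"), "gtf")
chrom_sizes <- read_chrom_sizes(file.path(in_dir, "chrom.sizes"))
flt <- filter_genes(genes)
promoters <- make_diff_promoters(flt$genes, chrom_sizes = chrom_sizes)

samples <- expand.grid(rep = 1:2, cond = c("vehicle", "treated"),
                       stringsAsFactors = FALSE)
frag_list <- lapply(seq_len(nrow(samples)), function(i) {
  load_fragments(
    file.path(in_dir, sprintf("fragments_%s_rep%d.bed",
                              samples$cond[i], samples$rep[i])),
    sample_id = sprintf("%s_rep%d", samples$cond[i], samples$rep[i])
  )
})
peaks <- lapply(c("vehicle", "treated"), function(cond) {
  lapply(1:2, function(r) {
    read.table(file.path(in_dir, sprintf("peaks_%s_rep%d.bed", cond, r)),
               sep = "\t", col.names = c("chrom", "start", "end"),
               colClasses = c("character", "integer", "integer"))
  })
})
names(peaks) <- c("vehicle", "treated")
consensus <- lapply(peaks, function(p) consensus_peaks(p[[1]], p[[2]]))
for (cond in names(consensus)) {
  write_bed(consensus[[cond]],
            file.path(out_dir, sprintf("consensus_%s.bed", cond)))
}
universe <- promoter_universe(consensus, promoters)

regions <- promoters[promoters$gene_id %in% universe, ]
regions$region_id <- regions$gene_id
counts <- vapply(frag_list, function(f) count_fragments(f, regions)$count,
                 integer(nrow(regions)))
rownames(counts) <- regions$gene_id
colnames(counts) <- vapply(frag_list, `[[`, character(1), "sample_id")

lib <- vapply(frag_list, `[[`, numeric(1), "library_size")
diff <- differential_test(counts, samples$cond,
                          sample_size_factors = lib / exp(mean(log(lib))))
write.table(diff, file.path(out_dir, "differential_promoters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "differential: %d promoters tested; %.1f%% increased, %.1f%% decreased (FDR < 0.05)",
  nrow(diff), 100 * mean(diff$class == "increased"),
  100 * mean(diff$class == "decreased")))

gained <- diff$id[diff$class == "increased"]
background <- diff$id[diff$class != "increased"]
sets <- read_gmt(file.path(in_dir, "gene_sets.gmt"))
enr <- enrich(gained, background, sets)
write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("enrichment: %d / %d sets significant at FDR < 0.05; top: %s (q = %.2g)",
                sum(enr$significant), nrow(enr), enr$set_name[1], enr$q[1]))
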