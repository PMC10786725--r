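#!/usr/bin/env Rscript

# Step 1: generate the synthetic study inputs.
#
# One synthetic chromosome of ~300 genes; RNAPII ChIP fragment libraries for
# vehicle and treated conditions (2 replicates each) in which the treatment
# quadruples the promoter-proximal occupancy rate of 60% of genes while the
# per-gene total stays fixed; per-replicate peak calls; a gene-set
# collection with one set planted inside the affected genes; and 4PL
# dose-response plates. Files land under results/simulated/ in standard
# formats (GTF, BED, GMT, TSV) plus the ground-truth table.

library(polpause)

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 20240601)
ann <- simulate_annotation(cfg)
write_gtf(ann$transcripts, file.path(out_dir, "annotation.gtf"))
writeLines(paste(names(ann$chrom_sizes), ann$chrom_sizes, sep = "\t"),
           file.path(out_dir, "chrom.sizes"))

truth <- pausing_truth(ann, cfg)
write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (cond in c("vehicle", "treated")) {
  for (r in 1:2) {
    fs <- simulate_fragments(ann, cfg, condition = cond, replicate = r)
    write_bed(fs$fragments,
              file.path(out_dir, sprintf("fragments_%s_rep%d.bed", cond, r)))
    pk <- simulate_peaks(ann, cfg, condition = cond, replicate = r)
    write_bed(pk, file.path(out_dir, sprintf("peaks_%s_rep%d.bed", cond, r)))
    message(sprintf("%s rep%d: %d fragments, %d peaks",
                    cond, r, fs$library_size, nrow(pk)))
  }
}

write_gmt(simulate_gene_sets(ann, cfg),
          file.path(out_dir, "gene_sets.gmt"))

doses <- do.call(rbind, lapply(1:3, function(i) {
  tab <- simulate_dose_response(synthetic_config(seed = cfg$seed + i))
  tab$experiment <- i
  tab
}))
write.table(doses, file.path(out_dir, "dose_response.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("simulated inputs written to ", out_dir)
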