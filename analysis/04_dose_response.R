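#!/usr/bin/env Rscript

# Step 4: drug-response quantification.
#
# Fits the constrained four-parameter logistic to each simulated
# proliferation assay and averages the per-experiment IC50s with a t-based
# 95% CI; fits the exponential growth model to a noisy growth curve; and
# evaluates 2^-ddCt relative expression for a worked Ct table.

library(polpause)

in_dir <- "results/simulated"
out_dir <- "results/dose_response"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

doses <- read.table(file.path(in_dir, "dose_response.tsv"), sep = "\t",
                    header = TRUE)
fits <- lapply(split(doses, doses$experiment), function(tab) {
  fit_4pl(tab$dose_nM, tab$response)
})
fit_tab <- do.call(rbind, lapply(names(fits), function(e) {
  f <- fits[[e]]
  data.frame(experiment = e, top = f$top, bottom = f$bottom, ic50 = f$ic50,
             hill = f$hill, rss = f$rss, converged = f$converged)
}))
write.table(fit_tab, file.path(out_dir, "fourpl_fits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

summ <- ic50_summary(fits)
message(sprintf("IC50 over %d assays: %.0f nM (95%% CI %.0f-%.0f)",
                summ$n, summ$mean_ic50, summ$ci_lower, summ$ci_upper))

# death ratio at endpoint for an illustrative dose ladder
dr <- data.frame(dose_nM = c(0, 150, 300, 600, 1200),
                 caspase_positive = c(30, 55, 140, 260, 300),
                 live = c(4000, 3600, 2600, 1500, 900))
dr$death_ratio <- death_ratio(dr$caspase_positive, dr$live)
write.table(dr, file.path(out_dir, "death_ratio.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# exponential growth fit on a seeded noisy curve (k_true = 0.4 / day)
set.seed(20240604)
t_days <- seq(0, 15, by = 3)
signal <- exp(0.4 * t_days + rnorm(length(t_days), 0, 0.25))
gfit <- exponential_fit(t_days, signal)
message(sprintf("growth fit: k = %.3f / day, R2 = %.3f", gfit$k, gfit$r2))

# relative expression for a worked Ct table (target vs GAPDH reference)
ct <- data.frame(
  gene = c("target_a", "target_b"),
  ct_target_treated = c(25, 23), ct_ref_treated = c(20, 20),
  ct_target_vehicle = c(24, 24), ct_ref_vehicle = c(20, 20)
)
dd <- delta_delta_ct(ct$ct_target_treated, ct$ct_ref_treated,
                     ct$ct_target_vehicle, ct$ct_ref_vehicle)
ct$delta_delta_ct <- dd$delta_delta_ct
ct$fold_change <- dd$fold_change
write.table(ct, file.path(out_dir, "relative_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

jsonlite::write_json(
  list(ic50 = summ, growth = gfit[c("k", "intercept", "r2")]),
  file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
)
message("dose-response outputs written to ", out_dir)
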