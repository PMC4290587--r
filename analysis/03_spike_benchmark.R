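#!/usr/bin/env Rscript

# Enrichment-recovery benchmark: plant one pathway detected at 80% per run
# over a flat 10% detection background and ask how often it is the
# top-ranked enrichment result in a single 50-cell-scale run. Also records
# the antitonic-fit residual of the 50-gene window-score series under the
# default monotone detection curve. Writes results/benchmarks.tsv.

library(proteopath)

n_seeds <- 20L
flat_cfg <- function(s) {
  sim_config(plateau_level = 14.48, frac_protein_only = 0,
             n_protein_only = 0L, run_depth = 0.10 * 13187, seed = s)
}
top <- vapply(seq_len(n_seeds), function(s) {
  b <- spike_pathway(simulate_bundle(flat_cfg(s)), "PATHWAY_0700", 0.8)
  h <- preprocess_report(b$reports$run1, b$aliases, b$contaminants)
  enrich_collection(h$genes, b$collection)$set_name[1L] == "PATHWAY_0700"
}, logical(1))

a <- analyze_bundle(simulate_bundle(sim_config(seed = 42L)))
ws <- a$windows$score
anti <- -stats::isoreg(-ws)$yf
rmse <- sqrt(mean((ws - anti)^2))

out <- data.frame(
  metric = c("spike_top1_rate", "window_antitonic_rmse",
             "window_score_top50_mean", "window_score_bottom50_mean"),
  value = c(mean(top), rmse, mean(ws[1:50]),
            mean(ws[(length(ws) - 49):length(ws)])))
dir.create("results", showWarnings = FALSE)
write.table(out, "results/benchmarks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(out, row.names = FALSE)
cat("\nSpiked pathway ranked first in", sum(top), "of", n_seeds, "seeds\n")
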