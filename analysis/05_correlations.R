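#!/usr/bin/env Rscript
# Correlation stage: Fisher-corrected Pearson (and Spearman) pairwise
# correlations of z-scored calcium traces, neuron-speed correlations, and
# their cumulative distributions.
# Finding to verify: both pairwise and speed correlations are lowered in
# MK-801 sessions; aripiprazole is intermediate.

suppressMessages(library(hippodesync))

manifest <- read.csv("results/manifest.csv")
pair_rows <- data.frame()
speed_rows <- data.frame()
cdf_rows <- data.frame()
for (i in seq_len(nrow(manifest))) {
  s <- read_session(manifest$path[i])
  z <- suppressMessages(zscore_traces(s$calcium))
  for (method in c("pearson", "spearman")) {
    pc <- pairwise_corr(z, method)
    pr <- pc$pairs
    pr$session_id <- s$session_id
    pr$preset <- manifest$preset[i]
    pair_rows <- rbind(pair_rows, pr)
    if (method == "pearson") {
      cdf <- empirical_cdf(pr$r)
      cdf$session_id <- s$session_id
      cdf$preset <- manifest$preset[i]
      cdf_rows <- rbind(cdf_rows, cdf)
    }
  }
  sc <- speed_corr(z, s$speed)
  sc$session_id <- s$session_id
  sc$preset <- manifest$preset[i]
  speed_rows <- rbind(speed_rows, sc)
}
write.csv(pair_rows, "results/pairwise_corr.csv", row.names = FALSE)
write.csv(speed_rows, "results/speed_corr.csv", row.names = FALSE)
write.csv(cdf_rows, "results/pairwise_corr_cdf.csv", row.names = FALSE)

pe <- pair_rows[pair_rows$method == "pearson", ]
cat("\nmean Fisher-z by preset (pairwise | speed):\n")
for (p in unique(manifest$preset))
  cat(sprintf("  %-10s %6.3f | %6.3f\n", p,
              mean(pe$fisher_z[pe$preset == p]),
              mean(speed_rows$fisher_z[speed_rows$preset == p])))
cat("tables written to results/pairwise_corr.csv, speed_corr.csv, pairwise_corr_cdf.csv\n")
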