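#!/usr/bin/env Rscript
# LFP stage: band-split each session's wideband signal, estimate the
# multitaper PSD and integrate the delta/theta/beta/gamma band powers.
# Finding to verify: theta and gamma power are raised in MK-801 sessions,
# delta and beta are not.

suppressMessages(library(hippodesync))

manifest <- read.csv("results/manifest.csv")
rows <- data.frame()
for (i in seq_len(nrow(manifest))) {
  s <- read_session(manifest$path[i])
  lfp <- suppressWarnings(bandsplit(s$lfp)$lfp)
  bp <- band_power_table(compute_psd(lfp))
  bp$session_id <- s$session_id
  bp$preset <- manifest$preset[i]
  rows <- rbind(rows, bp)
}
write.csv(rows, "results/band_power.csv", row.names = FALSE)

wide <- reshape(rows[, c("session_id", "preset", "band", "power")],
                idvar = c("session_id", "preset"), timevar = "band",
                direction = "wide")
names(wide) <- sub("^power\\.", "", names(wide))
agg <- aggregate(wide[, c("delta", "theta", "beta", "gamma")],
                 by = list(preset = wide$preset), FUN = mean)
print(agg, digits = 4)
veh <- wide[wide$preset == "VEHICLE", ]
mk <- wide[wide$preset == "MK801", ]
cat(sprintf("\ntheta power MK801/VEHICLE = %.2f, gamma = %.2f, delta = %.2f, beta = %.2f\n",
            mean(mk$theta) / mean(veh$theta), mean(mk$gamma) / mean(veh$gamma),
            mean(mk$delta) / mean(veh$delta), mean(mk$beta) / mean(veh$beta)))
cat("table written to results/band_power.csv\n")
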