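#!/usr/bin/env Rscript
# Simulate the study cohort: vehicle, MK-801 and MK-801 + aripiprazole
# sessions at matched seeds, and write them to results/sessions/ in the
# plain-text session layout. Later stages read these sessions back, so the
# whole analysis is reproducible from this script alone.

suppressMessages(library(hippodesync))

# each arm gets its own seed block: the four arms are separate animals
arm_seeds <- list(VEHICLE = 1:4, VEHICLE_ARI = 11:14,
                  MK801 = 21:24, MK801_ARI = 31:34)
duration_s <- 60

out_root <- "results/sessions"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

manifest <- data.frame()
for (p in names(arm_seeds)) for (sd in arm_seeds[[p]]) {
  s <- generate_session(p, seed = sd, duration_s = duration_s)
  stopifnot(length(validate_session(s)) == 0)
  path <- file.path(out_root, s$session_id)
  write_session(s, path)
  manifest <- rbind(manifest,
                    data.frame(path = path, preset = p, seed = sd,
                               group = s$group, treatment = s$treatment))
  cat(sprintf("wrote %-32s (%s, seed %d)\n", path, p, sd))
}
write.csv(manifest, "results/manifest.csv", row.names = FALSE)
cat(sprintf("\n%d sessions of %d s each; manifest at results/manifest.csv\n",
            nrow(manifest), duration_s))
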