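#!/usr/bin/env Rscript
# Behavior and reporting stage: open-field metrics (total distance, % time
# in the 25%-area center) per session, then the group-comparison table over
# the whole cohort: two-way ANOVA (group x treatment) with Sidak-adjusted
# post-hoc contrasts where both factors vary, Student's t otherwise.

suppressMessages(library(hippodesync))

manifest <- read.csv("results/manifest.csv")
sessions <- lapply(manifest$path, read_session)

oft <- do.call(rbind, lapply(seq_along(sessions), function(i) {
  om <- suppressWarnings(oft_metrics(sessions[[i]]$trajectory))
  data.frame(session_id = sessions[[i]]$session_id,
             preset = manifest$preset[i],
             total_distance_cm = om$total_distance_cm,
             pct_time_center = om$pct_time_center)
}))
write.csv(oft, "results/oft.csv", row.names = FALSE)
print(aggregate(cbind(total_distance_cm, pct_time_center) ~ preset, oft, mean),
      digits = 4)

# add saline vehicle/mk801 + ari arms into one 2x2 design over the cohort
gr <- group_report(sessions, extractors = list(
  oft_distance_cm = function(s)
    suppressWarnings(oft_metrics(s$trajectory))$total_distance_cm,
  speed_integral_cm = function(s) sum(s$speed$speed) / s$speed$fs,
  transient_rate_per_min = function(s)
    mean(suppressMessages(transient_stats(s$calcium))$rate_per_min)))
print(gr)
write.csv(gr$cells, "results/group_cells.csv", row.names = FALSE)
write.csv(gr$tests, "results/group_tests.csv", row.names = FALSE)
cat("tables written to results/oft.csv, group_cells.csv, group_tests.csv\n")
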