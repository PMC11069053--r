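test_that("open-field metrics are exact on closed-form trajectories", {
  # perimeter loop at 5 cm/s for 60 s: 300 cm, never in center
  fs <- 20
  per <- 2 * (55 + 40)
  pos <- ((seq_len(60 * fs) - 1) * (5 / fs)) %% per
  xy <- t(vapply(pos, function(d) {
    if (d < 55) c(d, 0)
    else if (d < 95) c(55, d - 55)
    else if (d < 150) c(55 - (d - 95), 40)
    else c(0, 40 - (d - 150))
  }, numeric(2)))
  om <- oft_metrics(trajectory(xy[, 1], xy[, 2], fs = fs), duration_s = 60)
  # 1199 discrete steps of 0.25 cm trace 299.75 of the nominal 300 cm
  expect_equal(om$total_distance_cm, 300, tolerance = 0.002)
  expect_equal(om$pct_time_center, 0)

  center <- trajectory(rep(27.5, 100), rep(20, 100), fs = 1)
  om2 <- oft_metrics(center, duration_s = 100)
  expect_equal(om2$total_distance_cm, 0)
  expect_equal(om2$pct_time_center, 100)
})

test_that("center region occupies 25% of the arena for any dimensions", {
  for (dims in list(c(55, 40), c(100, 30), c(10, 10))) {
    L <- dims[1]; W <- dims[2]
    set.seed(17)
    x <- runif(1e5, 0, L)
    y <- runif(1e5, 0, W)
    om <- oft_metrics(trajectory(x, y, fs = 1000, arena_length_cm = L,
                                 arena_width_cm = W), duration_s = 100)
    expect_equal(om$pct_time_center, 25, tolerance = 0.02 / 0.25)
    # exact geometry: center rectangle is (L/2) x (W/2)
    expect_equal((L / 2) * (W / 2) / (L * W), 0.25)
  }
})

test_that("distance is stable under trajectory resampling refinement", {
  cfg <- synth_config(duration_s = 20)
  tr <- generate_trajectory(cfg, seed = 3, duration_s = 120)
  coarse <- trajectory(tr$x[seq(1, length(tr$x), by = 2)],
                       tr$y[seq(1, length(tr$y), by = 2)], fs = tr$fs / 2)
  d_fine <- oft_metrics(tr, 120)$total_distance_cm
  d_coarse <- oft_metrics(coarse, 120)$total_distance_cm
  expect_equal(d_coarse / d_fine, 1, tolerance = 0.02)
})

test_that("short trajectories warn and fall back to the available span", {
  tr <- generate_trajectory(synth_config(duration_s = 20), seed = 1,
                            duration_s = 60)
  expect_warning(om <- oft_metrics(tr, duration_s = 1800), "available span")
  expect_equal(om$duration_s, 60)
})

test_that("the t-test branch detects planted shifts at the closed-form power", {
  rejected <- sapply(1:200, function(sd) {
    set.seed(sd)
    df <- data.frame(group = rep(c("vehicle", "mk801"), each = 8),
                     treatment = "none",
                     dist = c(rnorm(8, 0, 1), rnorm(8, 2, 1)))
    gr <- group_report(df, "dist")
    gr$tests$p[1] < 0.05
  })
  p_theory <- stats::power.t.test(n = 8, delta = 2, sd = 1,
                                  sig.level = 0.05)$power
  expect_gt(p_theory, 0.95)  # the planted design is a high-power design
  expect_lt(abs(mean(rejected) - p_theory), 0.05)
})

test_that("the 2x2 ANOVA with Sidak contrasts is quiet under the null", {
  any_sig <- sapply(1:50, function(sd) {
    set.seed(sd + 500)
    df <- expand.grid(group = c("vehicle", "mk801"),
                      treatment = c("saline", "ari"), rep = 1:5)
    df$metric <- rnorm(nrow(df))
    gr <- group_report(df, "metric")
    post <- gr$tests[gr$tests$test == "posthoc_t", ]
    any(post$p_sidak < 0.05)
  })
  expect_lt(mean(any_sig), 0.10)
})

test_that("group_report summarizes sessions through extractor functions", {
  sessions <- c(lapply(1:2, function(sd)
                  generate_session("VEHICLE", sd, duration_s = 12)),
                lapply(1:2, function(sd)
                  generate_session("MK801", sd, duration_s = 12)))
  gr <- group_report(sessions,
                     extractors = list(speed_cm = function(s)
                       sum(s$speed$speed) / s$speed$fs))
  expect_equal(nrow(gr$cells), 2)
  expect_equal(gr$tests$test, "t")
  expect_true(all(c("statistic", "df", "p") %in% names(gr$tests)))
})
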