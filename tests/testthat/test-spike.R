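make_unit <- function(rate_hz, dur_s, width_ms, seed = 1) {
  set.seed(seed)
  n <- round(rate_hz * dur_s)
  spike_unit(sort(runif(n, 0, dur_s)), trough_to_peak_ms = width_ms)
}

test_that("units classify by waveform width with rate as a consistency check", {
  rs <- classify_unit(make_unit(5, 100, 0.8), 100)
  expect_equal(as.character(rs), "RS")
  expect_true(attr(rs, "rate_consistent"))

  fs <- classify_unit(make_unit(30, 100, 0.4), 100)
  expect_equal(as.character(fs), "FS")
  expect_true(attr(fs, "rate_consistent"))

  # width wins over rate; the disagreement is flagged
  expect_message(odd <- classify_unit(make_unit(20, 100, 0.8), 100),
                 "outside the RS range")
  expect_equal(as.character(odd), "RS")
  expect_false(attr(odd, "rate_consistent"))

  expect_message(un <- classify_unit(spike_unit(c(1, 2, 3)), 100), "unclassified")
  expect_equal(as.character(un), "unclassified")
})

test_that("firing rate is exact spike count over bin duration", {
  u <- spike_unit(seq(0.05, 1.95, length.out = 10))
  r <- firing_rate(u, bin_s = 2, duration_s = 2)
  expect_equal(r$rate, 5)
  expect_equal(firing_rate(spike_unit(numeric(0)), 1, 5)$rate, rep(0, 5))
  ugrid <- spike_unit(seq(0, 4.9, by = 0.1))
  expect_equal(firing_rate(ugrid, 1, 5)$rate, rep(10, 5))
})

test_that("perfect phase-locking to a clean theta rhythm yields 100% coherence at 8 Hz", {
  fs <- 1000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  lfp <- lfp_signal(50 * sin(2 * pi * 8 * t), fs = fs, band = "lfp")
  peaks <- (which(diff(sign(diff(cos(2 * pi * 8 * t)))) < 0) + 1) / fs
  peaks <- peaks[peaks > 1 & peaks < 59]
  u <- spike_unit(peaks)
  sp <- spike_field_coherence(u, lfp, n_spikes = 100, seed = 1)
  expect_equal(sp$theta_peak_pct, 100)
  expect_equal(sp$theta_peak_freq_hz, 8, tolerance = 1.7)
  expect_equal(sp$peak_freq_hz, sp$theta_peak_freq_hz)
  expect_true(all(sp$coherence >= 0 & sp$coherence <= 100))
})

test_that("coherence of spikes independent of the field follows the 1/N averaging law", {
  # spikes spaced > 0.35 s apart give non-overlapping (independent) windows,
  # the premise under which the spike-triggered average's PSD is 1/N of the
  # mean window PSD
  fs <- 250
  lfp <- noise_lfp(600, fs, seed = 100)
  lfp <- lfp_signal(lfp$samples, fs, "lfp")
  mean_theta <- sapply(c(100, 400), function(n_spk) {
    mean(sapply(1:8, function(sd) {
      set.seed(sd)
      u <- spike_unit(1 + cumsum(0.35 + rexp(1100, 1 / 0.15)))
      spike_field_coherence(u, lfp, n_spikes = n_spk, seed = sd)$theta_peak_pct
    }))
  })
  expect_lt(mean_theta[1], 5)
  # quadrupling the spike count should cut coherence by about 4
  expect_gt(mean_theta[1] / mean_theta[2], 2)
  expect_lt(mean_theta[1] / mean_theta[2], 8)
})

test_that("coherence subsampling is seed-deterministic and stable for locked units", {
  cfg <- synth_config(duration_s = 120, n_rs = 0, n_fs = 1, kappa = 5,
                      noise_scale = 10)
  lfp <- generate_lfp(cfg, seed = 21)
  u <- generate_spikes(cfg, attr(lfp, "theta_phase"), fs = 1000, seed = 21)[[1]]
  lfp <- lfp_signal(lfp$samples, lfp$fs, "lfp")
  a <- spike_field_coherence(u, lfp, n_spikes = 200, seed = 5)
  b <- spike_field_coherence(u, lfp, n_spikes = 200, seed = 5)
  expect_identical(a$coherence, b$coherence)
  expect_gt(a$theta_peak_pct, 50)  # strongly locked
  peaks <- sapply(1:6, function(sd)
    spike_field_coherence(u, lfp, n_spikes = 200, seed = sd)$theta_peak_pct)
  expect_lt(max(peaks) - min(peaks), 10)
})

test_that("locomotion restriction and eligibility counting reject short supplies", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  lfp <- lfp_signal(sin(2 * pi * 8 * t), fs = fs, band = "lfp")
  # stationary for the first half, running for the second
  sp <- speed_trace(c(rep(0, 500), rep(10, 500)), fs = 50)
  u <- spike_unit(seq(0.5, 19.5, by = 0.1))
  counts <- eligible_spike_counts(list(u), lfp, sp)
  expect_lt(counts, 120)  # only second-half spikes are eligible
  expect_error(spike_field_coherence(u, lfp, sp, n_spikes = 150, seed = 1),
               "eligible")
})

test_that("coherent-unit summaries count peaks above threshold", {
  mk <- function(peak) structure(list(freqs = 0:20, coherence = rep(1, 21),
                                      n_spikes_used = 100, peak_value_pct = peak,
                                      peak_freq_hz = 8, theta_peak_pct = peak,
                                      theta_peak_freq_hz = 8),
                                 class = "coherence_spectrum")
  sm <- coherent_unit_summary(list(mk(43.93), mk(6.55)), threshold_pct = 20)
  expect_equal(sm$n_above_threshold, 1)
  sm0 <- coherent_unit_summary(list(mk(3), mk(5)), threshold_pct = 20)
  expect_equal(sm0$n_above_threshold, 0)
  smz <- coherent_unit_summary(list(mk(3), mk(5)), threshold_pct = 0)
  expect_equal(smz$n_above_threshold, 2)
  expect_equal(utils::tail(sm$theta_peak_cdf$cdf, 1), 1)
})
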