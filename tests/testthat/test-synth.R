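test_that("LFP generation is deterministic and respects degenerate configs", {
  cfg <- synth_config(duration_s = 12)
  a <- generate_lfp(cfg, seed = 3)
  b <- generate_lfp(cfg, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_identical(attr(a, "theta_phase"), attr(b, "theta_phase"))
  cfg0 <- synth_config(duration_s = 12,
                       osc_amp_uv = c(delta = 0, theta = 0, beta = 0, gamma = 0),
                       noise_scale = 0)
  z <- generate_lfp(cfg0, seed = 1)
  expect_true(all(z$samples == 0))
  expect_error(generate_lfp(synth_config(duration_s = 5), 1), "10 s")
})

test_that("a pure theta tone concentrates essentially all band power in theta", {
  cfg <- synth_config(duration_s = 20,
                      osc_amp_uv = c(delta = 0, theta = 50, beta = 0, gamma = 0),
                      noise_scale = 0)
  lfp <- generate_lfp(cfg, seed = 1)
  psd <- compute_psd(lfp_signal(lfp$samples, lfp$fs, "lfp"))
  tab <- band_power_table(psd)
  expect_gt(tab$relative[tab$band == "theta"], 0.99)
})

test_that("kappa = 0 gives homogeneous Poisson spiking at the configured rate", {
  cfg <- synth_config(duration_s = 600, n_rs = 1, n_fs = 0, kappa = 0,
                      rs_rate_hz = c(5, 5))
  phase <- (2 * pi * 8 * seq(0, 600, by = 1e-3)) %% (2 * pi)
  units <- generate_spikes(cfg, phase, fs = 1000, seed = 11)
  n <- length(units[[1]]$spike_times)
  expect_lt(abs(n - 5 * 600), 3 * sqrt(5 * 600))
  expect_error(generate_spikes(synth_config(kappa = -1), phase, 1000, 1))
})

test_that("von Mises locking has the right preferred phase and resultant length", {
  kappa <- 4
  cfg <- synth_config(duration_s = 240, n_rs = 1, n_fs = 0, kappa = kappa,
                      rs_rate_hz = c(8, 8), preferred_phase = 0)
  phase <- (2 * pi * 8 * seq(0, 240, by = 1e-3)) %% (2 * pi)
  ph_all <- unlist(lapply(1:5, function(sd) {
    u <- generate_spikes(cfg, phase, fs = 1000, seed = sd)[[1]]
    phase[pmin(floor(u$spike_times * 1000) + 1, length(phase))]
  }))
  expect_lt(abs(circ_mean(ph_all)), 0.15)
  # closed-form von Mises resultant length I1(k)/I0(k)
  r_expect <- besselI(kappa, 1) / besselI(kappa, 0)
  expect_lt(abs(circ_resultant(ph_all) - r_expect), 0.03)
})

test_that("spike-phase resultant length increases with kappa", {
  phase <- (2 * pi * 8 * seq(0, 120, by = 1e-3)) %% (2 * pi)
  res <- sapply(c(0, 0.5, 1, 2, 4), function(kap) {
    cfg <- synth_config(duration_s = 120, n_rs = 1, n_fs = 0, kappa = kap,
                        rs_rate_hz = c(8, 8))
    mean(sapply(1:10, function(sd) {
      u <- generate_spikes(cfg, phase, fs = 1000, seed = sd)[[1]]
      circ_resultant(phase[pmin(floor(u$spike_times * 1000) + 1, length(phase))])
    }))
  })
  expect_true(all(diff(res) > 0))
})

test_that("FS waveform templates are half the width of RS templates", {
  cfg <- synth_config(duration_s = 12, n_rs = 1, n_fs = 1)
  phase <- (2 * pi * 8 * seq(0, 12, by = 1e-3)) %% (2 * pi)
  units <- generate_spikes(cfg, phase, fs = 1000, seed = 2)
  widths <- vapply(units, `[[`, numeric(1), "trough_to_peak_ms")
  expect_equal(widths[2] / widths[1], 0.5)
  # the stored width matches the one measurable from the template itself
  for (u in units)
    expect_equal(hippodesync:::waveform_trough_to_peak_ms(u$waveform, u$fs_waveform),
                 u$trough_to_peak_ms, tolerance = 0.1)
})

test_that("calcium kernel: a planted event decays to amp/e after tau seconds", {
  tr <- planted_trace(100, frames = 50, amps = 100, tau_s = 1, fs = 10)
  expect_equal(which.max(tr), 50)
  expect_equal(tr[50], 100)
  expect_equal(tr[60], 100 * exp(-1), tolerance = 1e-6)
})

test_that("calcium generation hits rate zero and shared-latent correlation rises with loading", {
  sp <- speed_trace(rep(0, 600), fs = 10)
  cfg0 <- synth_config(duration_s = 60, transient_rate_hz = 0, trace_noise_sd = 0,
                       n_neurons_ca = 3)
  ct0 <- generate_calcium(cfg0, sp, seed = 1)
  expect_true(all(ct0$traces == 0))
  # matched seeds, loading 1 vs 0: pairwise correlation strictly larger on average
  mean_r <- function(a) {
    mean(sapply(1:20, function(sd) {
      cfg <- synth_config(duration_s = 120, latent_loading = a, speed_coupling = 0,
                          n_neurons_ca = 6, transient_rate_hz = 0.15)
      ct <- generate_calcium(cfg, speed_trace(rep(0, 6000), fs = 50), seed = sd)
      z <- suppressMessages(zscore_traces(ct))
      pairwise_corr(z)$mean_r
    }))
  }
  expect_gt(mean_r(1) - mean_r(0), 0.05)
})

test_that("speed process degenerates to zero and trajectories respect the arena", {
  cfg <- synth_config(duration_s = 20, speed_vol = 0, speed_mean_cms = 0)
  sp <- generate_speed(cfg, seed = 1)
  expect_true(all(sp$speed == 0))
  cfg2 <- synth_config(duration_s = 20)
  tr <- generate_trajectory(cfg2, seed = 5, duration_s = 5000)  # 1e5 steps
  expect_true(all(tr$x >= 0 & tr$x <= 55))
  expect_true(all(tr$y >= 0 & tr$y <= 40))
})

test_that("doubling the mean speed doubles trajectory path length within 5%", {
  dist_of <- function(v) {
    mean(sapply(1:5, function(sd) {
      cfg <- synth_config(duration_s = 20, speed_mean_cms = v)
      tr <- generate_trajectory(cfg, seed = sd, duration_s = 300)
      sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
    }))
  }
  expect_equal(dist_of(16) / dist_of(8), 2, tolerance = 0.05)
})

test_that("sessions are bit-identical for the same preset and seed", {
  a <- generate_session("MK801", seed = 9, duration_s = 12)
  b <- generate_session("MK801", seed = 9, duration_s = 12)
  expect_identical(a$lfp$samples, b$lfp$samples)
  expect_identical(lapply(a$units, `[[`, "spike_times"),
                   lapply(b$units, `[[`, "spike_times"))
  expect_identical(a$calcium$traces, b$calcium$traces)
  expect_identical(a$speed$speed, b$speed$speed)
  expect_length(validate_session(a), 0)
  expect_error(generate_session("NOSUCH", seed = 1), "arg")
})

test_that("MK801 raises theta band power at matched seeds", {
  for (sd in 1:3) {
    v <- generate_session("VEHICLE", seed = sd, duration_s = 20)
    m <- generate_session("MK801", seed = sd, duration_s = 20)
    tp <- function(s) {
      psd <- compute_psd(suppressWarnings(bandsplit(s$lfp)$lfp))
      band_power(psd, "theta")$power
    }
    expect_gt(tp(m), tp(v))
  }
})
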