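triangle_trace <- function(peaks, height, n = 300, base = 8) {
  x <- numeric(n)
  for (p in peaks) {
    for (k in 0:(base / 2)) {
      v <- height * (1 - k / (base / 2))
      x[p + k] <- pmax(x[p + k], v)
      x[p - k] <- pmax(x[p - k], v)
    }
  }
  x
}

test_that("transient detection honors height, distance and prominence rules", {
  tr <- triangle_trace(c(50, 150, 250), 50)
  ts <- detect_transients(tr)
  expect_equal(ts$peak_frames, c(50, 150, 250))
  expect_equal(ts$amplitudes, rep(50, 3))

  low <- triangle_trace(c(50, 150, 250), 10)
  expect_equal(detect_transients(low)$n_transients, 0)

  # two candidates 5 frames apart: greedy-by-height keeps the higher one
  close2 <- pmax(triangle_trace(100, 50, n = 200), triangle_trace(105, 40, n = 200))
  ts2 <- detect_transients(close2)
  expect_equal(ts2$peak_frames,
               oracle_find_peaks(close2, 20, 10, 20))
  expect_equal(ts2$peak_frames, 100)
})

test_that("detection agrees exactly with the brute-force enumeration oracle", {
  for (sd in 1:100) {
    set.seed(sd)
    # spiky random walks produce plateaus, shoulders and nested peaks
    tr <- abs(cumsum(rnorm(200, 0, 12))) + sample(0:1, 200, replace = TRUE) * 15
    expect_identical(detect_transients(tr)$peak_frames,
                     as.integer(oracle_find_peaks(tr, 20, 10, 20)))
  }
})

test_that("detection matches the reference implementation the protocol names", {
  set.seed(7)
  traces <- replicate(10, abs(cumsum(rnorm(200, 0, 12))))
  tmp_in <- tempfile(fileext = ".csv")
  tmp_out <- tempfile(fileext = ".csv")
  utils::write.table(t(traces), tmp_in, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  code <- sprintf("
import numpy as np
from scipy.signal import find_peaks
X = np.loadtxt(%s, delimiter=',')
rows = ['%%d:%%s' %% (i, ';'.join(str(p + 1) for p in
        find_peaks(x, height=20, distance=10, prominence=20)[0]))
        for i, x in enumerate(X)]
open(%s, 'w').write('\\n'.join(rows) + '\\n')
", shQuote(tmp_in), shQuote(tmp_out))
  res <- system2("python", c("-c", shQuote(code)))
  expect_equal(res, 0L)
  ref <- readLines(tmp_out)
  for (i in seq_len(10)) {
    got <- detect_transients(traces[, i])$peak_frames
    want <- strsplit(sub("^\\d+:", "", ref[i]), ";")[[1]]
    want <- if (length(want) == 1 && want == "") integer(0) else as.integer(want)
    expect_identical(got, want)
  }
})

test_that("isolation selection ranks transients by minimum neighbor gap", {
  tr <- numeric(400)
  tr[c(10, 100, 110, 300)] <- 60
  ts <- detect_transients(tr)
  expect_equal(ts$peak_frames, c(10, 100, 110, 300))  # gap 10 satisfies distance
  iso <- select_isolated(ts, k = 2)
  expect_equal(iso$peak_frames, c(10, 300))
  expect_equal(sort(iso$isolation_scores), c(90, 190))

  single <- detect_transients(planted_trace(100, 50, 60, 1))
  iso1 <- suppressMessages(select_isolated(single, k = 10))
  expect_equal(iso1$peak_frames, single$peak_frames)

  # equally spaced: ties broken by amplitude
  eq <- new_transient_set_for_test(c(100, 200, 300), c(50, 80, 50))
  iso2 <- select_isolated(eq, k = 1)
  expect_equal(iso2$peak_frames, 200)
})

test_that("decay estimation recovers planted constants and applies the 2.5 s rule", {
  tr <- planted_trace(200, 50, 100, tau_s = 1, fs = 10)
  iso <- suppressMessages(select_isolated(detect_transients(tr), 10))
  d <- estimate_decay(iso, tr, fs_ca = 10)
  g <- exp(-1 / (10 * d$tau_s))
  expect_equal(g, exp(-0.1), tolerance = 0.01)
  expect_equal(d$tau_s, 1, tolerance = 0.05)
  expect_true(d$valid)

  tr3 <- planted_trace(300, 50, 100, tau_s = 3, fs = 10)
  iso3 <- suppressMessages(select_isolated(detect_transients(tr3), 10))
  d3 <- estimate_decay(iso3, tr3, fs_ca = 10)
  expect_gt(d3$tau_s, 2.5)
  expect_false(d3$valid)

  # noisy recovery, cross-checked against an independent nonlinear fit
  taus <- sapply(1:20, function(sd) {
    set.seed(sd)
    tr <- planted_trace(1200, seq(30, 1160, by = 80), 60, tau_s = 1.5,
                        fs = 10, noise_sd = 5)
    iso <- suppressMessages(select_isolated(detect_transients(tr), 10))
    estimate_decay(iso, tr, fs_ca = 10)$tau_s
  })
  expect_equal(mean(taus), 1.5, tolerance = 0.10)
  set.seed(3)
  tr <- planted_trace(300, 50, 100, tau_s = 1.5, fs = 10, noise_sd = 2)
  nls_fit <- minpack.lm::nlsLM(y ~ A * g^n,
                               data = data.frame(y = tr[50:80], n = 0:30),
                               start = list(A = 100, g = 0.8))
  g_oracle <- coef(nls_fit)[["g"]]
  iso <- suppressMessages(select_isolated(detect_transients(tr), 10))
  tau_pkg <- estimate_decay(iso, tr, fs_ca = 10)$tau_s
  expect_equal(exp(-1 / (10 * tau_pkg)), g_oracle, tolerance = 0.03)

  flat <- new_transient_set_for_test(50, 60)
  expect_false(estimate_decay(flat, rep(-1, 100), fs_ca = 10)$valid)
})

test_that("detected rate and amplitude recover generator parameters without latent drive", {
  stats_over_seeds <- sapply(1:20, function(sd) {
    cfg <- synth_config(duration_s = 120, n_neurons_ca = 4, latent_loading = 0,
                        speed_coupling = 0, transient_rate_hz = 0.1,
                        transient_amp_mean = 60, transient_amp_sd = 5,
                        trace_noise_sd = 5)
    ct <- generate_calcium(cfg, speed_trace(rep(0, 6000), 50), seed = sd)
    st <- suppressMessages(transient_stats(ct))
    c(rate = mean(st$rate_per_min), amp = mean(st$mean_amplitude))
  })
  expect_equal(mean(stats_over_seeds["rate", ]), 0.1 * 60, tolerance = 0.10)
  expect_equal(mean(stats_over_seeds["amp", ]), 60, tolerance = 0.10)
})

test_that("z-scoring standardizes traces and excludes constant neurons", {
  ct <- calcium_traces(rbind(c(0, 10, 20), c(5, 5, 5), c(1, 4, 9)), fs = 10)
  expect_message(z <- zscore_traces(ct), "constant")
  expect_equal(nrow(z$traces), 2)
  expect_equal(rowMeans(z$traces), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(z$traces, 1, sd), c(1, 1), tolerance = 1e-12)
  expect_equal(attr(z, "excluded"), 2L)
  z2 <- zscore_traces(z)
  expect_equal(z2$traces, z$traces, tolerance = 1e-12)
})
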