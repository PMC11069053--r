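#' Canonical frequency bands
#'
#' Band edges in Hz used throughout the analysis: delta 1-4, theta 5-12,
#' beta 13-30, gamma 30-80.
#'
#' @return named list of `c(lo, hi)` pairs.
#' @export
lfp_bands <- function() {
  list(delta = c(1, 4), theta = c(5, 12), beta = c(13, 30), gamma = c(30, 80))
}

#' Band-split a wideband recording into LFP and spike bands
#'
#' Splits the raw extracellular signal into the local field potential
#' (1-300 Hz) and the spike band (300-5000 Hz) with zero-phase Butterworth
#' filtering (high-pass and low-pass sections applied forward-backward).
#' Zero-phase filtering preserves spike-field timing relationships.
#'
#' @param raw a wideband [lfp_signal()].
#' @return list with elements `lfp` (1-300 Hz) and `spikeband` (300-5000 Hz);
#'   `spikeband` is `NULL` with a warning when the sampling rate is below
#'   10 kHz (2 x 5000 Hz).
#' @export
bandsplit <- function(raw) {
  fs <- raw$fs
  if (fs < 2 * 300)
    stop("sampling rate ", fs, " Hz too low to extract the 1-300 Hz LFP band")
  lfp_out <- zerophase_bandpass(raw$samples, fs, 1, 300)
  spike_out <- NULL
  if (fs >= 2 * 5000) {
    spike_out <- lfp_signal(zerophase_bandpass(raw$samples, fs, 300, 5000),
                            fs = fs, band = "spikeband")
  } else {
    warning("sampling rate ", fs,
            " Hz below 10 kHz; spike band (300-5000 Hz) omitted")
  }
  list(lfp = lfp_signal(lfp_out, fs = fs, band = "lfp"), spikeband = spike_out)
}

# cascade of zero-phase Butterworth high-pass and low-pass sections; the
# signal is demeaned first (exact DC removal), and the 1 Hz corner uses a
# 2nd-order section because higher orders are numerically fragile at such a
# small normalized frequency
zerophase_bandpass <- function(x, fs, lo, hi) {
  x <- x - mean(x)
  ord <- if (lo / (fs / 2) < 1e-3) 2 else 4
  hp <- signal::butter(ord, lo / (fs / 2), type = "high")
  x <- signal::filtfilt(hp, x)
  if (hi < fs / 2) {
    lp <- signal::butter(4, hi / (fs / 2), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  x
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric tridiagonal
# formulation; k tapers at time-bandwidth product nw, unit energy each.
# Cached per (n, nw, k) because the eigendecomposition is the expensive step.
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 3, k = 5) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (sum(tapers[, j]) < 0) tapers[, j] <- -tapers[, j]
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectral density
#'
#' Estimates the one-sided PSD (microvolts^2 per Hz) by averaging Slepian
#' (DPSS) taper periodograms over 50%-overlapping windows. Scaling satisfies
#' Parseval: the integral of the PSD over frequency matches the signal
#' variance.
#'
#' @param lfp an [lfp_signal()] (band `"lfp"` or `"wideband"`).
#' @param window_s window length in seconds (default 2).
#' @param nw time-bandwidth product (default 3).
#' @param n_tapers number of tapers (default 5, i.e. 2*nw - 1).
#' @return list of class `power_spectrum` with `freqs` (Hz), `power`
#'   (microvolts^2/Hz) and `method` metadata.
#' @export
compute_psd <- function(lfp, window_s = 2, nw = 3, n_tapers = 5) {
  fs <- lfp$fs
  x <- lfp$samples
  nwin <- round(window_s * fs)
  if (length(x) < 2 * nwin)
    stop("record too short: need >= 2 x window_s (", 2 * window_s, " s)")
  step <- floor(nwin / 2)
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  tapers <- dpss_tapers(nwin, nw, n_tapers)
  nfreq <- floor(nwin / 2) + 1L
  freqs <- (seq_len(nfreq) - 1) * fs / nwin
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1L)]
    pk <- numeric(nfreq)
    for (j in seq_len(ncol(tapers))) {
      X <- stats::fft(seg * tapers[, j])[seq_len(nfreq)]
      p <- Mod(X)^2 / fs
      # one-sided: double everything except DC (and Nyquist for even nwin)
      sc <- rep(2, nfreq); sc[1] <- 1
      if (nwin %% 2 == 0) sc[nfreq] <- 1
      pk <- pk + p * sc
    }
    acc <- acc + pk / ncol(tapers)
  }
  structure(list(freqs = freqs, power = acc / length(starts),
                 method = list(estimator = "multitaper", window_s = window_s,
                               nw = nw, n_tapers = n_tapers,
                               n_windows = length(starts), overlap = 0.5)),
            class = "power_spectrum")
}

#' Integrated band power
#'
#' Trapezoidal integral of the PSD over one canonical band (see
#' [lfp_bands()]), in microvolts^2. Band edges falling between frequency bins
#' are included by linear interpolation of the PSD at the edges, so power is
#' additive over adjacent bands.
#'
#' @param psd a `power_spectrum` from [compute_psd()].
#' @param band `"delta"`, `"theta"`, `"beta"` or `"gamma"`, or a numeric
#'   `c(lo, hi)` in Hz.
#' @param relative if `TRUE`, also report power as a fraction of total
#'   1-80 Hz power.
#' @return list of class `band_power` with `band`, `lo_hz`, `hi_hz`, `power`
#'   (microvolts^2) and optionally `relative`.
#' @export
band_power <- function(psd, band, relative = FALSE) {
  if (is.character(band)) {
    edges <- lfp_bands()[[match.arg(band, names(lfp_bands()))]]
    bname <- band
  } else {
    edges <- band
    bname <- sprintf("%g-%g Hz", band[1], band[2])
  }
  if (edges[1] < min(psd$freqs) - 1e-9 || edges[2] > max(psd$freqs) + 1e-9)
    stop("band [", edges[1], ", ", edges[2], "] Hz outside PSD range [",
         min(psd$freqs), ", ", max(psd$freqs), "] Hz")
  p <- band_integral(psd$freqs, psd$power, edges[1], edges[2])
  out <- list(band = bname, lo_hz = edges[1], hi_hz = edges[2], power = p)
  if (relative)
    out$relative <- p / band_integral(psd$freqs, psd$power, 1, 80)
  structure(out, class = "band_power")
}

# trapezoidal integral of (f, y) restricted to [lo, hi], interpolating edges
band_integral <- function(f, y, lo, hi) {
  yi <- stats::approx(f, y, xout = c(lo, hi), rule = 2)$y
  inside <- f > lo & f < hi
  fx <- c(lo, f[inside], hi)
  yx <- c(yi[1], y[inside], yi[2])
  sum(diff(fx) * (utils::head(yx, -1) + utils::tail(yx, -1)) / 2)
}

#' Band powers for all four canonical bands
#'
#' @param psd a `power_spectrum`.
#' @return data.frame with one row per band: band, lo_hz, hi_hz, power,
#'   relative (fraction of total 1-80 Hz power).
#' @export
band_power_table <- function(psd) {
  bands <- lfp_bands()
  total <- band_integral(psd$freqs, psd$power, 1, 80)
  do.call(rbind, lapply(names(bands), function(b) {
    bp <- band_power(psd, b)
    data.frame(band = b, lo_hz = bp$lo_hz, hi_hz = bp$hi_hz,
               power = bp$power, relative = bp$power / total)
  }))
}
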