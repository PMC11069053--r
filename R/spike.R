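#' Classify a unit as regular-spiking (RS) or fast-spiking (FS)
#'
#' Classification is width-primary: the trough-to-peak width of the mean
#' waveform is compared against a boundary (default 0.45 ms; FS waveforms are
#' about half the width of RS). The firing-rate ranges (RS below 1-15
#' spikes/s, FS 15-50 spikes/s) serve as a consistency check only, because
#' the ranges share the 15 spikes/s boundary; an inconsistent rate is flagged
#' but does not override the width. Units with no usable waveform are
#' unclassified.
#'
#' @param unit a [spike_unit()].
#' @param session_duration_s session length in seconds (for the mean rate).
#' @param width_boundary_ms RS/FS boundary on trough-to-peak width (ms).
#' @return character scalar `"RS"`, `"FS"` or `"unclassified"` with attributes
#'   `rate_hz` and `rate_consistent`.
#' @export
classify_unit <- function(unit, session_duration_s, width_boundary_ms = 0.45) {
  rate <- length(unit$spike_times) / session_duration_s
  width <- unit$trough_to_peak_ms
  if (is.na(width) && !is.null(unit$waveform) && !is.null(unit$fs_waveform))
    width <- waveform_trough_to_peak_ms(unit$waveform, unit$fs_waveform)
  if (is.na(width)) {
    message("unit unclassified: no waveform / trough-to-peak width available")
    return(structure("unclassified", rate_hz = rate, rate_consistent = NA))
  }
  cls <- if (width >= width_boundary_ms) "RS" else "FS"
  consistent <- if (cls == "RS") rate <= 15 else (rate >= 15 && rate <= 50)
  if (!consistent)
    message(sprintf(
      "unit classified %s by width (%.2f ms) but rate %.1f spikes/s is outside the %s range",
      cls, width, rate, cls))
  structure(cls, rate_hz = rate, rate_consistent = consistent)
}

# trough-to-peak width (ms) from a mean waveform: global minimum to the
# following maximum
waveform_trough_to_peak_ms <- function(waveform, fs_waveform) {
  it <- which.min(waveform)
  if (it >= length(waveform)) return(NA_real_)
  ip <- it + which.max(waveform[(it + 1):length(waveform)])
  (ip - it) / fs_waveform * 1000
}

#' Instantaneous firing rate (spike count / bin duration)
#'
#' Counts spikes in half-open bins `[t, t + bin_s)` and divides by the bin
#' duration; a shorter final bin (when the duration is not a multiple of
#' `bin_s`) is divided by its actual length.
#'
#' @param unit a [spike_unit()].
#' @param bin_s bin width in seconds.
#' @param duration_s session duration in seconds.
#' @return list of class `rate_series` with `bin_edges` (length nbins + 1)
#'   and `rate` (spikes/s).
#' @export
firing_rate <- function(unit, bin_s, duration_s) {
  stopifnot(bin_s > 0, duration_s > 0)
  edges <- seq(0, duration_s, by = bin_s)
  if (utils::tail(edges, 1) < duration_s) edges <- c(edges, duration_s)
  counts <- graphics::hist(unit$spike_times,
                           breaks = edges, plot = FALSE, right = FALSE)$counts
  structure(list(bin_edges = edges, rate = counts / diff(edges)),
            class = "rate_series")
}

#' Locomotion indicator from a speed trace
#'
#' Movement is defined as median-smoothed speed (0.5 s window) exceeding a
#' threshold (default 1 cm/s).
#'
#' @param speed a [speed_trace()].
#' @param threshold_cms speed threshold in cm/s.
#' @param smooth_s median smoothing window in seconds.
#' @return logical vector on the speed clock.
#' @export
locomotion_mask <- function(speed, threshold_cms = 1, smooth_s = 0.5) {
  k <- max(1L, round(smooth_s * speed$fs))
  if (k %% 2 == 0) k <- k + 1L
  sm <- if (k > 1) stats::runmed(speed$speed, k) else speed$speed
  sm > threshold_cms
}

#' Spike-field coherence from spike-triggered LFP averages
#'
#' For each of `n_spikes` randomly selected spikes during locomotion, the
#' 300 ms of LFP centered on the spike is extracted; the power spectral
#' density of the spike-triggered average (STA) is divided, frequency by
#' frequency, by the mean PSD of the individual windows and expressed in
#' percent (clipped to 0-100). A perfectly phase-locked unit yields identical
#' windows and 100% coherence; spikes independent of the field yield
#' approximately 100/n_spikes percent. Using the same `n_spikes` for every
#' unit makes coherence comparable across units. The theta-band coherence is
#' the maximum over 5-12 Hz.
#'
#' Windows use a single Hann-taper periodogram (about 3.3 Hz resolution at
#' 300 ms, sufficient to localize a theta peak). Peak ties are broken toward
#' the frequency with greater STA power, then toward the lower frequency.
#'
#' @param unit a [spike_unit()].
#' @param lfp an [lfp_signal()] (the 1-300 Hz LFP band).
#' @param speed optional [speed_trace()]; when supplied, only spikes during
#'   locomotion (see [locomotion_mask()]) are eligible.
#' @param n_spikes number of spikes to use; `NULL` uses all eligible spikes.
#'   Callers comparing units should pass the minimum eligible count across
#'   units.
#' @param seed integer seed for the spike subsample.
#' @param window_s STA window length in seconds (default 0.3).
#' @return list of class `coherence_spectrum`: `freqs`, `coherence` (percent),
#'   `n_spikes_used`, `peak_value_pct`, `peak_freq_hz`, `theta_peak_pct`,
#'   `theta_peak_freq_hz`.
#' @export
spike_field_coherence <- function(unit, lfp, speed = NULL, n_spikes = NULL,
                                  seed = 1, window_s = 0.3) {
  fs <- lfp$fs
  nwin <- round(window_s * fs)
  half <- floor(nwin / 2)
  st <- unit$spike_times
  if (!is.null(speed)) {
    mask <- locomotion_mask(speed)
    tsp <- (seq_along(speed$speed) - 1) / speed$fs
    at_spike <- stats::approx(tsp, as.numeric(mask), xout = st,
                              method = "constant", rule = 2)$y
    st <- st[at_spike > 0.5]
  }
  ctr <- round(st * fs) + 1L
  ok <- (ctr - half) >= 1L & (ctr - half + nwin - 1L) <= length(lfp$samples)
  ctr <- ctr[ok]
  n_eligible <- length(ctr)
  if (is.null(n_spikes)) n_spikes <- n_eligible
  if (n_eligible < max(n_spikes, 50))
    stop("only ", n_eligible, " eligible spikes (need >= ", max(n_spikes, 50),
         "); equalize n_spikes to the minimum across units")
  sel <- with_seed(seed, sort(sample(n_eligible, n_spikes)))
  idx0 <- ctr[sel] - half
  win <- vapply(idx0, function(i) lfp$samples[i:(i + nwin - 1L)],
                numeric(nwin))
  sta <- rowMeans(win)
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))
  nfreq <- floor(nwin / 2) + 1L
  freqs <- (seq_len(nfreq) - 1) * fs / nwin
  pgram <- function(x) Mod(stats::fft(x * h)[seq_len(nfreq)])^2
  psd_sta <- pgram(sta)
  psd_mean <- rowMeans(apply(win, 2L, pgram))
  coh <- ifelse(psd_mean > 0, 100 * psd_sta / psd_mean, 0)
  coh <- pmin(pmax(coh, 0), 100)
  pick_peak <- function(band_idx) {
    cmax <- max(coh[band_idx])
    tied <- band_idx[coh[band_idx] >= cmax - 1e-12]
    tied[order(-psd_sta[tied], freqs[tied])][1]
  }
  nz <- which(freqs > 0)
  ip <- pick_peak(nz)
  th <- which(freqs >= 5 & freqs <= 12)
  it <- if (length(th) > 0) pick_peak(th) else NA_integer_
  structure(list(
    freqs = freqs, coherence = coh, n_spikes_used = n_spikes,
    peak_value_pct = coh[ip], peak_freq_hz = freqs[ip],
    theta_peak_pct = if (is.na(it)) NA_real_ else coh[it],
    theta_peak_freq_hz = if (is.na(it)) NA_real_ else freqs[it]),
    class = "coherence_spectrum")
}

#' Count eligible spikes per unit for coherence equalization
#'
#' @param units list of [spike_unit()].
#' @param lfp the LFP signal used for coherence.
#' @param speed optional speed trace (locomotion restriction).
#' @param window_s STA window length in seconds.
#' @return integer vector of eligible spike counts; `min()` of it is the
#'   equalized `n_spikes`.
#' @export
eligible_spike_counts <- function(units, lfp, speed = NULL, window_s = 0.3) {
  fs <- lfp$fs
  nwin <- round(window_s * fs)
  half <- floor(nwin / 2)
  mask <- if (!is.null(speed)) locomotion_mask(speed) else NULL
  vapply(units, function(u) {
    st <- u$spike_times
    if (!is.null(mask)) {
      tsp <- (seq_along(speed$speed) - 1) / speed$fs
      keep <- stats::approx(tsp, as.numeric(mask), xout = st,
                            method = "constant", rule = 2)$y > 0.5
      st <- st[keep]
    }
    ctr <- round(st * fs) + 1L
    sum((ctr - half) >= 1L & (ctr - half + nwin - 1L) <= length(lfp$samples))
  }, integer(1))
}

#' Summarize coherent units across a population
#'
#' Counts units whose peak coherence exceeds a threshold (default 20%), and
#' tabulates the peak-frequency distribution and the empirical CDF of
#' theta-band coherence.
#'
#' @param spectra list of `coherence_spectrum` objects.
#' @param threshold_pct peak-coherence threshold in percent.
#' @return list with `n_units`, `n_above_threshold`, `frac_above_threshold`,
#'   `peak_freqs_hz`, `theta_peaks_pct` and `theta_peak_cdf` (a data.frame
#'   from [empirical_cdf()]).
#' @export
coherent_unit_summary <- function(spectra, threshold_pct = 20) {
  stopifnot(length(spectra) >= 1L)
  peaks <- vapply(spectra, `[[`, numeric(1), "peak_value_pct")
  pf <- vapply(spectra, `[[`, numeric(1), "peak_freq_hz")
  tp <- vapply(spectra, `[[`, numeric(1), "theta_peak_pct")
  list(n_units = length(spectra),
       n_above_threshold = sum(peaks > threshold_pct),
       frac_above_threshold = mean(peaks > threshold_pct),
       peak_values_pct = peaks,
       peak_freqs_hz = pf,
       theta_peaks_pct = tp,
       theta_peak_cdf = empirical_cdf(tp))
}
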