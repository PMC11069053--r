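#' Full analysis panel for one session
#'
#' Runs every analysis stage the group comparisons draw on and returns one
#' row of scalar metrics: integrated band powers (delta/theta/beta/gamma),
#' mean RS and FS firing rates, mean theta-band spike-field coherence (spike
#' counts equalized across units), calcium transient rate / amplitude /
#' decay, mean Fisher-z pairwise and neuron-speed correlations, the running
#' distance surrogate (time integral of treadmill speed), and open-field
#' metrics when a trajectory is present.
#'
#' @param s an `hd_session` with at least the LFP modality.
#' @param sfc_seed seed for the spike-subsampling step of the coherence
#'   estimator.
#' @param n_spikes_cap upper bound on the equalized spike count (keeps the
#'   estimator comparable across sessions of different lengths).
#' @param psd_window_s multitaper window length in seconds.
#' @return one-row data.frame of metrics (NA where a modality is absent).
#' @export
session_metrics <- function(s, sfc_seed = 1, n_spikes_cap = 200,
                            psd_window_s = 2) {
  out <- data.frame(session_id = s$session_id, group = s$group,
                    treatment = s$treatment)
  lfp <- NULL
  if (!is.null(s$lfp)) {
    lfp <- if (s$lfp$band == "wideband") {
      suppressWarnings(bandsplit(s$lfp)$lfp)
    } else s$lfp
    psd <- compute_psd(lfp, window_s = psd_window_s)
    bp <- band_power_table(psd)
    out$delta_power <- bp$power[bp$band == "delta"]
    out$theta_power <- bp$power[bp$band == "theta"]
    out$beta_power <- bp$power[bp$band == "beta"]
    out$gamma_power <- bp$power[bp$band == "gamma"]
  }
  out$rs_rate_hz <- out$fs_rate_hz <- NA_real_
  out$theta_sfc_rs <- out$theta_sfc_fs <- out$theta_sfc_all <- NA_real_
  if (!is.null(s$units) && !is.null(lfp)) {
    dur <- duration_s(lfp)
    cls <- vapply(s$units, function(u)
      as.character(suppressMessages(classify_unit(u, dur))), character(1))
    rates <- vapply(s$units, function(u) length(u$spike_times) / dur, numeric(1))
    out$rs_rate_hz <- mean(rates[cls == "RS"])
    out$fs_rate_hz <- mean(rates[cls == "FS"])
    counts <- eligible_spike_counts(s$units, lfp, s$speed)
    usable <- counts >= 50
    if (any(usable)) {
      n_eq <- min(min(counts[usable]), n_spikes_cap)
      theta <- rep(NA_real_, length(s$units))
      for (k in which(usable)) {
        sp <- spike_field_coherence(s$units[[k]], lfp, s$speed,
                                    n_spikes = n_eq, seed = sfc_seed + k)
        theta[k] <- sp$theta_peak_pct
      }
      out$theta_sfc_rs <- mean(theta[cls == "RS"], na.rm = TRUE)
      out$theta_sfc_fs <- mean(theta[cls == "FS"], na.rm = TRUE)
      out$theta_sfc_all <- mean(theta, na.rm = TRUE)
      out$n_spikes_equalized <- n_eq
    }
  }
  out$transient_rate_per_min <- out$transient_amplitude <-
    out$decay_tau_s <- NA_real_
  out$pairwise_corr_z <- out$speed_corr_z <- NA_real_
  if (!is.null(s$calcium)) {
    st <- suppressMessages(transient_stats(s$calcium))
    out$transient_rate_per_min <- mean(st$rate_per_min)
    out$transient_amplitude <- mean(st$mean_amplitude, na.rm = TRUE)
    out$decay_tau_s <- mean(st$decay_tau_s[st$decay_valid %in% TRUE])
    z <- suppressMessages(zscore_traces(s$calcium))
    out$pairwise_corr_z <- pairwise_corr(z)$mean_fisher_z
    if (!is.null(s$speed))
      out$speed_corr_z <- mean(speed_corr(z, s$speed)$fisher_z)
  }
  if (!is.null(s$speed))
    out$speed_integral_cm <- sum(s$speed$speed) / s$speed$fs
  if (!is.null(s$trajectory)) {
    om <- suppressWarnings(oft_metrics(s$trajectory))
    out$oft_distance_cm <- om$total_distance_cm
    out$oft_pct_center <- om$pct_time_center
  }
  out
}

#' Analysis panels for a cohort of synthetic sessions
#'
#' Generates one session per (preset, seed) combination and stacks their
#' [session_metrics()] rows. Matched seeds across presets share all
#' condition-independent generator draws, so preset contrasts isolate the
#' condition effects.
#'
#' @param presets character vector of preset names (see [condition_preset()]).
#' @param seeds integer vector of session seeds.
#' @param duration_s session duration in seconds.
#' @param ... forwarded to [generate_session()].
#' @return data.frame with one row per preset x seed, column `preset` added.
#' @export
cohort_metrics <- function(presets, seeds, duration_s = 120, ...) {
  rows <- list()
  for (p in presets) for (sd in seeds) {
    s <- generate_session(p, seed = sd, duration_s = duration_s, ...)
    r <- session_metrics(s, sfc_seed = sd)
    r$preset <- p
    r$seed <- sd
    rows[[length(rows) + 1L]] <- r
  }
  cols <- Reduce(union, lapply(rows, names))
  do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  }))
}
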