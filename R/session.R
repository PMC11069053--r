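#' Recording-session data model
#'
#' A session bundles the simultaneously recorded modalities of one animal on
#' one day: wideband or band-split LFP, sorted spike units, calcium traces,
#' treadmill speed and an open-field trajectory, together with the group
#' (vehicle / MK-801) and treatment (saline / aripiprazole / none) labels.
#' All time series share one clock with t = 0 at session start and carry
#' their sampling rate explicitly.
#'
#' @param session_id character scalar identifying the session.
#' @param group one of `"vehicle"`, `"mk801"`.
#' @param treatment one of `"saline"`, `"ari"`, `"none"`.
#' @param lfp optional [lfp_signal()].
#' @param units optional list of [spike_unit()].
#' @param calcium optional [calcium_traces()].
#' @param speed optional [speed_trace()].
#' @param trajectory optional [trajectory()].
#' @param provenance free-form named list (generator preset, seed, ...).
#' @return An object of class `hd_session`.
#' @seealso [validate_session()], [write_session()], [read_session()]
#' @export
session <- function(session_id, group = c("vehicle", "mk801"),
                    treatment = c("none", "saline", "ari"),
                    lfp = NULL, units = NULL, calcium = NULL,
                    speed = NULL, trajectory = NULL,
                    provenance = list()) {
  group <- match.arg(group)
  treatment <- match.arg(treatment)
  s <- structure(list(
    session_id = as.character(session_id),
    group = group, treatment = treatment,
    lfp = lfp, units = units, calcium = calcium,
    speed = speed, trajectory = trajectory,
    provenance = provenance
  ), class = "hd_session")
  v <- validate_session(s)
  if (length(v) > 0L) stop("invalid session: ", paste(v, collapse = "; "))
  s
}

#' Local field potential signal
#'
#' @param samples numeric vector, amplitude in microvolts.
#' @param fs sampling rate in Hz.
#' @param band `"wideband"` (raw), `"lfp"` (1-300 Hz) or `"spikeband"`
#'   (300-5000 Hz).
#' @return Object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, fs, band = c("wideband", "lfp", "spikeband")) {
  band <- match.arg(band)
  stopifnot(is.numeric(samples), length(samples) > 0L, is.numeric(fs), fs > 0)
  if (!all(is.finite(samples))) stop("lfp samples must be finite")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs), band = band),
            class = "lfp_signal")
}

#' Duration of a time series object in seconds
#' @param x an `lfp_signal`, `speed_trace`, `calcium_traces` or `trajectory`.
#' @return duration in seconds.
#' @export
duration_s <- function(x) {
  n <- if (!is.null(x$samples)) length(x$samples)
       else if (!is.null(x$speed)) length(x$speed)
       else if (!is.null(x$traces)) ncol(x$traces)
       else length(x$x)
  n / x$fs
}

#' Sorted spike unit
#'
#' @param spike_times strictly increasing spike times in seconds.
#' @param waveform numeric vector, mean spike waveform (microvolts).
#' @param fs_waveform sampling rate of the waveform in Hz.
#' @param trough_to_peak_ms waveform width, trough to following peak, in ms.
#' @param unit_class `"RS"`, `"FS"` or `"unclassified"`.
#' @return Object of class `spike_unit`.
#' @export
spike_unit <- function(spike_times, waveform = NULL, fs_waveform = NULL,
                       trough_to_peak_ms = NA_real_,
                       unit_class = c("unclassified", "RS", "FS")) {
  unit_class <- match.arg(unit_class)
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 1L && any(diff(spike_times) <= 0))
    stop("spike_times must be strictly increasing")
  structure(list(spike_times = spike_times, waveform = waveform,
                 fs_waveform = fs_waveform,
                 trough_to_peak_ms = as.numeric(trough_to_peak_ms),
                 unit_class = unit_class),
            class = "spike_unit")
}

#' Calcium fluorescence traces
#'
#' @param traces numeric matrix, neurons x frames, raw fluorescence (a.u.).
#' @param fs frame rate in frames per second (typically 10).
#' @return Object of class `calcium_traces`.
#' @export
calcium_traces <- function(traces, fs = 10) {
  traces <- as.matrix(traces)
  stopifnot(nrow(traces) >= 1L, fs > 0)
  if (!all(is.finite(traces))) stop("calcium traces must be finite")
  structure(list(traces = traces, fs = as.numeric(fs)), class = "calcium_traces")
}

#' Treadmill speed trace
#'
#' @param speed numeric vector, cm/s, non-negative.
#' @param fs sampling rate in Hz.
#' @return Object of class `speed_trace`.
#' @export
speed_trace <- function(speed, fs) {
  stopifnot(is.numeric(speed), fs > 0)
  structure(list(speed = as.numeric(speed), fs = as.numeric(fs)),
            class = "speed_trace")
}

#' Open-field trajectory
#'
#' @param x,y position in cm within the arena.
#' @param fs sampling rate in Hz.
#' @param arena_length_cm,arena_width_cm arena dimensions in cm (55 x 40 open
#'   field by default).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(x, y, fs, arena_length_cm = 55, arena_width_cm = 40) {
  stopifnot(length(x) == length(y), fs > 0)
  structure(list(x = as.numeric(x), y = as.numeric(y), fs = as.numeric(fs),
                 arena_length_cm = as.numeric(arena_length_cm),
                 arena_width_cm = as.numeric(arena_width_cm)),
            class = "trajectory")
}

#' Validate a session against the data-model invariants
#'
#' Pure function: violations are returned as data, not raised. Each violation
#' names the offending field and the rule it breaks. An empty character vector
#' means the session is valid.
#'
#' @param s an `hd_session` (or a bare list with the same fields).
#' @return character vector of violations (empty if valid).
#' @export
validate_session <- function(s) {
  v <- character(0)
  modalities <- c("lfp", "units", "calcium", "speed", "trajectory")
  if (all(vapply(modalities, function(m) is.null(s[[m]]), logical(1))))
    v <- c(v, "session: empty session (no modality present)")
  if (!s$group %in% c("vehicle", "mk801"))
    v <- c(v, sprintf("group: '%s' not in {vehicle, mk801}", s$group))
  if (!s$treatment %in% c("saline", "ari", "none"))
    v <- c(v, sprintf("treatment: '%s' not in {saline, ari, none}", s$treatment))
  if (!is.null(s$lfp)) {
    if (!all(is.finite(s$lfp$samples))) v <- c(v, "lfp$samples: non-finite values")
    if (s$lfp$fs <= 0) v <- c(v, "lfp$fs: must be > 0")
    minfs <- if (identical(s$lfp$band, "wideband")) 1000 else 200
    if (s$lfp$fs < minfs)
      v <- c(v, sprintf("lfp$fs: %g Hz below the %g Hz minimum for band '%s'",
                        s$lfp$fs, minfs, s$lfp$band))
  }
  if (!is.null(s$units)) {
    dur <- session_duration(s)
    for (k in seq_along(s$units)) {
      u <- s$units[[k]]
      if (length(u$spike_times) > 1L && any(diff(u$spike_times) <= 0))
        v <- c(v, sprintf("units[[%d]]$spike_times: not strictly increasing", k))
      if (!is.na(dur) && length(u$spike_times) > 0L &&
          (min(u$spike_times) < 0 || max(u$spike_times) > dur))
        v <- c(v, sprintf("units[[%d]]$spike_times: outside session duration [0, %g]",
                          k, dur))
      if (!is.na(u$trough_to_peak_ms) && u$trough_to_peak_ms <= 0)
        v <- c(v, sprintf("units[[%d]]$trough_to_peak_ms: must be > 0", k))
    }
  }
  if (!is.null(s$calcium)) {
    if (!all(is.finite(s$calcium$traces)))
      v <- c(v, "calcium$traces: non-finite values")
    if (s$calcium$fs <= 0) v <- c(v, "calcium$fs: must be > 0")
  }
  if (!is.null(s$speed)) {
    if (any(s$speed$speed < 0))
      v <- c(v, "speed$speed: negative values (speed must be >= 0 cm/s)")
  }
  if (!is.null(s$trajectory)) {
    tr <- s$trajectory
    if (any(tr$x < 0 | tr$x > tr$arena_length_cm))
      v <- c(v, sprintf("trajectory$x: outside arena bound [0, %g] cm",
                        tr$arena_length_cm))
    if (any(tr$y < 0 | tr$y > tr$arena_width_cm))
      v <- c(v, sprintf("trajectory$y: outside arena bound [0, %g] cm",
                        tr$arena_width_cm))
  }
  v
}

# Longest modality duration; NA when no continuous modality is present.
session_duration <- function(s) {
  cand <- c(
    if (!is.null(s$lfp)) duration_s(s$lfp),
    if (!is.null(s$calcium)) duration_s(s$calcium),
    if (!is.null(s$speed)) duration_s(s$speed),
    if (!is.null(s$trajectory)) duration_s(s$trajectory)
  )
  if (length(cand) == 0L) NA_real_ else max(cand)
}

#' @export
print.hd_session <- function(x, ...) {
  cat(sprintf("<hd_session> %s  group=%s treatment=%s\n",
              x$session_id, x$group, x$treatment))
  if (!is.null(x$lfp))
    cat(sprintf("  lfp: %s, %.1f s @ %g Hz\n", x$lfp$band,
                duration_s(x$lfp), x$lfp$fs))
  if (!is.null(x$units))
    cat(sprintf("  units: %d (%s)\n", length(x$units),
                paste(table(vapply(x$units, `[[`, "", "unit_class")),
                      names(table(vapply(x$units, `[[`, "", "unit_class"))),
                      collapse = " ")))
  if (!is.null(x$calcium))
    cat(sprintf("  calcium: %d neurons x %d frames @ %g Hz\n",
                nrow(x$calcium$traces), ncol(x$calcium$traces), x$calcium$fs))
  if (!is.null(x$speed))
    cat(sprintf("  speed: %.1f s @ %g Hz\n", duration_s(x$speed), x$speed$fs))
  if (!is.null(x$trajectory))
    cat(sprintf("  trajectory: %.1f s @ %g Hz in %g x %g cm arena\n",
                duration_s(x$trajectory), x$trajectory$fs,
                x$trajectory$arena_length_cm, x$trajectory$arena_width_cm))
  invisible(x)
}
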