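#' Detect calcium transients on a raw fluorescence trace
#'
#' Finds local maxima and applies, in order: a minimum height, a minimum
#' inter-peak distance (smaller peaks are removed first until all remaining
#' peaks are at least `distance` frames apart), and a minimum topographic
#' prominence (height of the peak above the higher of the two flanking
#' minima, where each flank extends to the nearest higher sample or the
#' signal edge). Plateau maxima are reported at the plateau midpoint
#' (rounding left). Defaults (20, 10, 20) are in raw-trace units and frames
#' at the 10 Hz frame rate.
#'
#' @param trace numeric vector, raw fluorescence of one neuron.
#' @param height minimum trace value at the peak (a.u.).
#' @param distance minimum inter-peak separation in frames.
#' @param prominence minimum topographic prominence (a.u.).
#' @param fs frame rate (Hz), used only to report the rate per minute.
#' @param neuron_id optional identifier carried through.
#' @return list of class `transient_set`: `neuron_id`, `peak_frames`
#'   (1-based), `amplitudes` (trace value at each peak), `n_transients`,
#'   `rate_per_min`, `isolation_scores` (filled by [select_isolated()]),
#'   `decay_tau_s`, `decay_valid` (filled by [estimate_decay()]).
#' @export
detect_transients <- function(trace, height = 20, distance = 10,
                              prominence = 20, fs = 10, neuron_id = NA) {
  stopifnot(all(is.finite(trace)))
  peaks <- local_maxima(trace)
  peaks <- peaks[trace[peaks] >= height]
  peaks <- enforce_distance(peaks, trace[peaks], distance)
  if (length(peaks) > 0) {
    prom <- vapply(peaks, function(p) peak_prominence(trace, p), numeric(1))
    peaks <- peaks[prom >= prominence]
  }
  new_transient_set(neuron_id, peaks, trace[peaks],
                    rate_per_min = length(peaks) / (length(trace) / fs) * 60)
}

new_transient_set <- function(neuron_id, peak_frames, amplitudes, rate_per_min,
                              isolation_scores = NULL, decay_tau_s = NA_real_,
                              decay_valid = NA) {
  structure(list(neuron_id = neuron_id,
                 peak_frames = as.integer(peak_frames),
                 amplitudes = as.numeric(amplitudes),
                 n_transients = length(peak_frames),
                 rate_per_min = rate_per_min,
                 isolation_scores = isolation_scores,
                 decay_tau_s = decay_tau_s, decay_valid = decay_valid),
            class = "transient_set")
}

# local maxima with plateau midpoints (1-based indices)
local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i - 1L] < x[i]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        out <- c(out, (i + j) %/% 2L)
        i <- j + 1L
      } else {
        i <- j  # still ascending (or plateau ran to the edge); resume at j+1
      }
    }
    i <- i + 1L
  }
  out
}

# greedy-by-height suppression: keep higher peaks, drop any peak closer than
# `distance` frames to an already-kept one (ties by height keep the earlier)
enforce_distance <- function(peaks, heights, distance) {
  if (length(peaks) <= 1L) return(peaks)
  ord <- order(-heights, peaks)
  keep <- logical(length(peaks))
  for (i in ord) {
    if (!any(keep & abs(peaks - peaks[i]) < distance)) keep[i] <- TRUE
  }
  sort(peaks[keep])
}

# topographic prominence of the peak at index p
peak_prominence <- function(x, p) {
  n <- length(x)
  left <- p
  lmin <- x[p]
  while (left > 1L && x[left - 1L] <= x[p]) {
    left <- left - 1L
    lmin <- min(lmin, x[left])
  }
  right <- p
  rmin <- x[p]
  while (right < n && x[right + 1L] <= x[p]) {
    right <- right + 1L
    rmin <- min(rmin, x[right])
  }
  # a flank that ran to the signal edge without meeting a higher sample
  # contributes its minimum; bases are the higher of the two flank minima
  x[p] - max(lmin, rmin)
}

#' Select the best-isolated transients of a neuron
#'
#' The isolation score of a transient is its minimum frame gap to any
#' neighboring detected transient (first/last transients use their single
#' neighbor; a lone transient scores infinite). The `k` highest-scoring
#' transients are returned, ties broken by larger amplitude, then earlier
#' frame. With fewer than `k` transients all are returned with a note.
#'
#' @param ts a `transient_set` from [detect_transients()].
#' @param k number of transients to select (10 per the decay protocol).
#' @return A `transient_set` restricted to the selected transients, with
#'   `isolation_scores` filled; attribute `"all_peak_frames"` keeps the full
#'   detected peak list for decay segmentation.
#' @export
select_isolated <- function(ts, k = 10) {
  stopifnot(ts$n_transients >= 1L)
  p <- ts$peak_frames
  score <- if (length(p) == 1L) Inf else {
    gaps_prev <- c(Inf, diff(p))
    gaps_next <- c(diff(p), Inf)
    s <- pmin(gaps_prev, gaps_next)
    s[1] <- gaps_next[1]
    s[length(p)] <- gaps_prev[length(p)]
    s
  }
  if (ts$n_transients < k)
    message("only ", ts$n_transients, " transients available (k = ", k,
            "); returning all")
  ord <- order(-score, -ts$amplitudes, p)
  sel <- sort(ord[seq_len(min(k, length(p)))])
  out <- new_transient_set(ts$neuron_id, p[sel], ts$amplitudes[sel],
                           rate_per_min = ts$rate_per_min,
                           isolation_scores = score[sel])
  attr(out, "all_peak_frames") <- p
  out
}

#' Estimate the calcium decay constant of a neuron
#'
#' For each selected transient, the post-peak segment (from the peak to the
#' next detected transient or 3 s, whichever comes first) is fit to
#' A * g^n by log-linear least squares in two passes: an unweighted fit on
#' the first frames gives a preliminary curve, which then selects the fitted
#' samples above 20% of the peak and supplies the weights (squared fitted
#' values, the delta-method inverse variance of a log-transformed sample).
#' Selecting and weighting by the fitted rather than the observed values
#' keeps noise fluctuations from correlating with the weights, and the log
#' values carry a first-order Jensen correction (+sigma^2 / 2 y^2, with the
#' noise SD estimated from frame differences); both guards keep the slope
#' estimate unbiased across signal-to-noise levels. The per-neuron decay
#' factor g is the
#' amplitude-weighted mean over transients — larger transients carry higher
#' signal-to-noise — and tau = -(1/fs) / ln(g). Estimated decays over
#' `tau_max_s` (2.5 s) are flagged as failed extractions.
#'
#' @param ts_isolated a `transient_set` from [select_isolated()].
#' @param trace the neuron's raw fluorescence trace.
#' @param fs_ca frame rate, Hz.
#' @param max_fit_s maximum post-peak fit span, seconds.
#' @param tau_max_s validity bound on the decay constant, seconds.
#' @param rise_cut fit truncation threshold (a.u.): the fitted tail ends at
#'   the first rise of more than this amount above the running minimum,
#'   guarding against events hidden below the detection threshold.
#' @return list with `tau_s` and `valid` (`FALSE` when estimation failed or
#'   `tau_s > tau_max_s`).
#' @export
estimate_decay <- function(ts_isolated, trace, fs_ca, max_fit_s = 3,
                           tau_max_s = 2.5, rise_cut = 20) {
  stopifnot(ts_isolated$n_transients >= 1L)
  all_peaks <- attr(ts_isolated, "all_peak_frames")
  if (is.null(all_peaks)) all_peaks <- ts_isolated$peak_frames
  max_fr <- round(max_fit_s * fs_ca)
  # frame-difference MAD noise estimate (robust to sparse transients)
  sigma <- stats::mad(diff(trace)) / sqrt(2)
  gs <- amps <- numeric(0)
  for (i in seq_along(ts_isolated$peak_frames)) {
    p <- ts_isolated$peak_frames[i]
    nxt <- all_peaks[all_peaks > p]
    end <- min(if (length(nxt)) nxt[1] - 1L else length(trace),
               p + max_fr, length(trace))
    seg <- trace[p:end]
    # truncate at the first clear re-rise above the running minimum: a jump
    # of more than `rise_cut` flags a hidden (sub-threshold or suppressed)
    # event contaminating the tail
    rise <- seg - cummin(seg)
    hit <- which(rise > rise_cut)
    if (length(hit) > 0L) seg <- seg[seq_len(hit[1] - 1L)]
    if (length(seg) < 3L) next
    g <- loglinear_decay(seg, sigma)
    if (is.finite(g) && g > 0 && g < 1) {
      gs <- c(gs, g)
      amps <- c(amps, ts_isolated$amplitudes[i])
    }
  }
  if (length(gs) == 0L)
    return(list(tau_s = NA_real_, valid = FALSE))
  gbar <- sum(gs * amps) / sum(amps)
  tau <- -(1 / fs_ca) / log(gbar)
  list(tau_s = tau, valid = is.finite(tau) && tau <= tau_max_s)
}


# two-pass log-linear exponential-decay fit; returns per-frame factor g
loglinear_decay <- function(seg, sigma = 0) {
  nidx <- seq_along(seg) - 1L
  n0 <- min(8L, length(seg))
  # the peak frame itself (n = 0) is excluded: peak picking selects upward
  # noise there, which would steepen the fitted slope
  ok0 <- seq_len(n0)[seg[seq_len(n0)] > 0 & nidx[seq_len(n0)] > 0]
  if (length(ok0) < 3L) return(NA_real_)
  g0 <- exp(stats::coef(stats::lm(log(seg[ok0]) ~ nidx[ok0]))[2])
  if (!is.finite(g0) || g0 <= 0 || g0 >= 1) return(NA_real_)
  yhat <- seg[1] * g0^nidx
  ok <- yhat >= 0.2 * seg[1] & seg > 0 & nidx > 0
  if (sum(ok) < 3L) return(g0)
  # first-order Jensen correction: E[log(y + e)] = log(y) - sigma^2/(2 y^2)
  yl <- log(seg[ok]) + sigma^2 / (2 * yhat[ok]^2)
  exp(stats::coef(stats::lm(yl ~ nidx[ok], weights = yhat[ok]^2))[2])
}

#' Z-score calcium traces neuron by neuron
#'
#' Standardizes each neuron's trace to mean 0, SD 1. Constant traces cannot
#' be standardized and are excluded (with their ids recorded) rather than
#' propagating NaN.
#'
#' @param ct a [calcium_traces()].
#' @return A [calcium_traces()] of standardized traces; attribute
#'   `"excluded"` lists the row indices of removed constant traces.
#' @export
zscore_traces <- function(ct) {
  m <- ct$traces
  sds <- apply(m, 1L, stats::sd)
  excl <- which(sds == 0 | !is.finite(sds))
  if (length(excl) > 0L) {
    message("excluding ", length(excl), " constant trace(s): neurons ",
            paste(excl, collapse = ", "))
    m <- m[-excl, , drop = FALSE]
    sds <- sds[-excl]
  }
  if (nrow(m) == 0L) stop("no traces left after excluding constant traces")
  z <- (m - rowMeans(m)) / sds
  out <- calcium_traces(z, fs = ct$fs)
  attr(out, "excluded") <- excl
  out
}

#' Per-neuron transient statistics for a session
#'
#' Runs [detect_transients()], [select_isolated()] and [estimate_decay()]
#' over every neuron and collects the per-neuron summaries the group
#' comparisons operate on.
#'
#' @param ct a [calcium_traces()].
#' @param height,distance,prominence detection parameters.
#' @param k number of best-isolated transients for the decay fit.
#' @return data.frame with one row per neuron: `neuron`, `n_transients`,
#'   `rate_per_min`, `mean_amplitude`, `decay_tau_s`, `decay_valid`.
#' @export
transient_stats <- function(ct, height = 20, distance = 10, prominence = 20,
                            k = 10) {
  rows <- lapply(seq_len(nrow(ct$traces)), function(j) {
    tr <- ct$traces[j, ]
    ts <- detect_transients(tr, height, distance, prominence, fs = ct$fs,
                            neuron_id = j)
    tau <- NA_real_; valid <- NA
    if (ts$n_transients >= 1L) {
      iso <- suppressMessages(select_isolated(ts, k))
      dec <- estimate_decay(iso, tr, fs_ca = ct$fs)
      tau <- dec$tau_s; valid <- dec$valid
    }
    data.frame(neuron = j, n_transients = ts$n_transients,
               rate_per_min = ts$rate_per_min,
               mean_amplitude = if (ts$n_transients > 0) mean(ts$amplitudes)
                                else NA_real_,
               decay_tau_s = tau, decay_valid = valid)
  })
  do.call(rbind, rows)
}
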