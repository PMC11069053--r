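# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementation (exhaustive scans, iterative
# removal, explicit sums) so that agreement is evidence, not tautology.

# Brute-force peak enumeration: for every index, decide peak-hood by scanning
# outward over equal samples; prominence by explicit range scans; distance by
# iteratively deleting the smallest peak involved in any violation.
oracle_find_peaks <- function(x, height, distance, prominence) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    l <- i
    while (l > 1 && x[l - 1] == x[i]) l <- l - 1
    r <- i
    while (r < n && x[r + 1] == x[i]) r <- r + 1
    if (l == 1 || r == n) next
    if (x[l - 1] < x[i] && x[r + 1] < x[i] && i == (l + r) %/% 2)
      cand <- c(cand, i)
  }
  cand <- cand[x[cand] >= height]
  # distance: walk peaks in descending height (earlier position wins ties)
  # and invalidate every not-yet-kept peak within `distance` of a kept one
  if (length(cand) > 1) {
    status <- rep("open", length(cand))
    for (k in order(-x[cand], cand)) {
      if (status[k] == "dead") next
      status[k] <- "kept"
      status[status == "open" & abs(cand - cand[k]) < distance] <- "dead"
    }
    cand <- cand[status == "kept"]
  }
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    p <- cand[k]
    il <- p - 1
    lmin <- x[p]
    while (il >= 1 && x[il] <= x[p]) {
      lmin <- min(lmin, x[il])
      il <- il - 1
    }
    ir <- p + 1
    rmin <- x[p]
    while (ir <= n && x[ir] <= x[p]) {
      rmin <- min(rmin, x[ir])
      ir <- ir + 1
    }
    keep[k] <- (x[p] - max(lmin, rmin)) >= prominence
  }
  cand[keep]
}

# Explicit double-loop Pearson correlation matrix from raw sums.
oracle_corr_matrix <- function(m) {
  nr <- nrow(m)
  out <- diag(1, nr)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (i == j) next
    a <- m[i, ]; b <- m[j, ]
    na <- length(a)
    num <- sum(a * b) - na * mean(a) * mean(b)
    den <- sqrt((sum(a^2) - na * mean(a)^2) * (sum(b^2) - na * mean(b)^2))
    out[i, j] <- num / den
  }
  out
}

# Planted calcium trace: impulses of given amplitudes at given frames,
# exponential kernel with decay constant tau_s, optional Gaussian noise.
planted_trace <- function(n_frames, frames, amps, tau_s, fs = 10,
                          noise_sd = 0) {
  g <- exp(-1 / (fs * tau_s))
  imp <- numeric(n_frames)
  imp[frames] <- amps
  tr <- as.numeric(stats::filter(imp, g, method = "recursive"))
  if (noise_sd > 0) tr <- tr + stats::rnorm(n_frames, 0, noise_sd)
  tr
}

# Pink-noise-only LFP at a given sampling rate (no oscillatory components).
noise_lfp <- function(duration_s, fs, seed, scale = 20) {
  cfg <- synth_config(duration_s = duration_s, fs_lfp = fs,
                      osc_amp_uv = c(delta = 0, theta = 0, beta = 0, gamma = 0),
                      noise_scale = scale)
  generate_lfp(cfg, seed)
}

# Circular summaries for spike-phase tests.
circ_mean <- function(ph) atan2(mean(sin(ph)), mean(cos(ph)))
circ_resultant <- function(ph) sqrt(mean(sin(ph))^2 + mean(cos(ph))^2)

# Bare transient_set constructor for synthetic test scenarios.
new_transient_set_for_test <- function(frames, amps) {
  hippodesync:::new_transient_set(NA, frames, amps,
                                  rate_per_min = length(frames))
}
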