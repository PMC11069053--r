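#' Synthetic session configuration
#'
#' Collects every generative parameter for a synthetic recording session:
#' LFP oscillation amplitudes, 1/f noise, spike-unit counts and rates, theta
#' phase-locking concentration, calcium transient statistics, the shared
#' latent drive and locomotion coupling of the calcium traces, the treadmill
#' speed process, and the open-field arena. The defaults describe a healthy
#' (vehicle) animal; condition presets ([condition_preset()]) override the
#' parameters that the MK-801 model perturbs.
#'
#' @param duration_s session length in seconds (electrophysiology + imaging).
#' @param fs_lfp LFP sampling rate, Hz.
#' @param osc_freq_hz,osc_amp_uv center frequencies and amplitudes (microvolts)
#'   of the delta/theta/beta/gamma oscillatory components.
#' @param noise_exponent spectral slope of the 1/f background (power ~ f^-exp).
#' @param noise_scale standard deviation of the 1/f background, microvolts.
#' @param n_rs,n_fs number of regular-spiking and fast-spiking units.
#' @param rs_rate_hz,fs_rate_hz mean-rate ranges (min, max) the unit rates are
#'   drawn from; RS 1-15 spikes/s, FS 15-50 spikes/s.
#' @param kappa von Mises concentration of spike phase-locking to theta
#'   (>= 0; 0 = no locking).
#' @param preferred_phase preferred theta phase of spiking, radians.
#' @param n_neurons_ca number of imaged neurons.
#' @param fs_ca imaging frame rate, Hz (10 for the emulated microscope).
#' @param transient_rate_hz mean calcium transient rate per neuron, Hz.
#' @param transient_amp_mean,transient_amp_sd transient amplitude distribution
#'   (normal truncated at 0), arbitrary fluorescence units. The default mean of
#'   60 a.u. sits well above the detection height threshold of 20.
#' @param tau_decay_s calcium indicator decay constant, seconds.
#' @param latent_loading loading a in [0, 1] of each neuron's log event rate on
#'   the shared standardized latent process (drives pairwise correlation).
#' @param latent_tau_s autocorrelation time of the shared latent, seconds.
#' @param speed_coupling coupling beta (>= 0, per cm/s) of log event rate on
#'   locomotion speed (drives neuron-speed correlation).
#' @param trace_noise_sd additive Gaussian noise SD on each trace, a.u.
#' @param fs_speed treadmill speed sampling rate, Hz.
#' @param speed_mean_cms mean running speed during movement bouts, cm/s.
#' @param speed_relax_hz mean-reversion rate of the speed process, 1/s.
#' @param speed_vol volatility of the speed process, cm/s per sqrt(s).
#' @param move_frac long-run fraction of time in movement bouts.
#' @param bout_move_s mean movement-bout duration, seconds.
#' @param fs_traj open-field tracking rate, Hz.
#' @param duration_oft_s open-field test duration, seconds (30 min assay).
#' @param heading_sd heading random-walk SD, radians per sqrt(s).
#' @param arena_length_cm,arena_width_cm open-field arena dimensions, cm.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 600,
                         fs_lfp = 1000,
                         osc_freq_hz = c(delta = 2, theta = 8, beta = 20, gamma = 40),
                         osc_amp_uv = c(delta = 40, theta = 50, beta = 15, gamma = 10),
                         noise_exponent = 1,
                         noise_scale = 20,
                         n_rs = 6, n_fs = 4,
                         rs_rate_hz = c(1, 15), fs_rate_hz = c(15, 50),
                         kappa = 2, preferred_phase = 0,
                         n_neurons_ca = 15, fs_ca = 10,
                         transient_rate_hz = 0.1,
                         transient_amp_mean = 60, transient_amp_sd = 15,
                         tau_decay_s = 0.7,
                         latent_loading = 0.9, latent_tau_s = 3,
                         speed_coupling = 0.15,
                         trace_noise_sd = 5,
                         fs_speed = 50,
                         speed_mean_cms = 8, speed_relax_hz = 0.5,
                         speed_vol = 4, move_frac = 0.6, bout_move_s = 8,
                         fs_traj = 20, duration_oft_s = 1800,
                         heading_sd = 1.2,
                         arena_length_cm = 55, arena_width_cm = 40) {
  cfg <- as.list(environment())
  stopifnot(cfg$kappa >= 0, cfg$tau_decay_s > 0,
            cfg$latent_loading >= 0, cfg$latent_loading <= 1,
            all(cfg$osc_amp_uv >= 0), cfg$transient_rate_hz >= 0,
            cfg$speed_coupling >= 0, cfg$fs_ca > 0, cfg$fs_lfp > 0)
  class(cfg) <- "synth_config"
  cfg
}

#' Condition presets for the emulated experiment
#'
#' Returns a `synth_config` for one of the four experimental conditions.
#' Relative to `VEHICLE`, the `MK801` preset raises theta and gamma LFP
#' amplitude, lowers the theta phase-locking concentration kappa, raises the
#' calcium transient rate and amplitude, lowers the shared-latent loading and
#' the speed coupling, and raises running speed (hyperlocomotion); delta and
#' beta amplitudes and the calcium decay constant are left unchanged.
#' `MK801_ARI` returns every perturbed parameter halfway back toward the
#' vehicle value; `VEHICLE_ARI` equals `VEHICLE` (the drug leaves healthy
#' animals unchanged on all emulated metrics).
#'
#' @param name one of `"VEHICLE"`, `"MK801"`, `"VEHICLE_ARI"`, `"MK801_ARI"`.
#' @param ... overrides passed to [synth_config()] before the preset scaling
#'   is applied (e.g. `duration_s`).
#' @return A `synth_config`.
#' @export
condition_preset <- function(name = c("VEHICLE", "MK801", "VEHICLE_ARI", "MK801_ARI"),
                             ...) {
  name <- match.arg(name)
  base <- synth_config(...)
  # w = 1 full MK-801 effect, w = 0.5 partial restoration under aripiprazole
  w <- switch(name, VEHICLE = 0, VEHICLE_ARI = 0, MK801 = 1, MK801_ARI = 0.5)
  if (w > 0) {
    mix <- function(veh, mk) veh + w * (mk - veh)
    base$osc_amp_uv["theta"] <- mix(base$osc_amp_uv["theta"],
                                    1.5 * base$osc_amp_uv["theta"])
    base$osc_amp_uv["gamma"] <- mix(base$osc_amp_uv["gamma"],
                                    1.5 * base$osc_amp_uv["gamma"])
    base$kappa <- mix(base$kappa, 0.35 * base$kappa)
    base$transient_rate_hz <- mix(base$transient_rate_hz,
                                  1.4 * base$transient_rate_hz)
    base$transient_amp_mean <- mix(base$transient_amp_mean,
                                   1.3 * base$transient_amp_mean)
    base$latent_loading <- mix(base$latent_loading, 0.35 * base$latent_loading)
    base$speed_coupling <- mix(base$speed_coupling, 0.3 * base$speed_coupling)
    base$speed_mean_cms <- mix(base$speed_mean_cms, 1.6 * base$speed_mean_cms)
  }
  attr(base, "preset") <- name
  base
}

# run expr with a private RNG stream; global .Random.seed restored afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic sub-seed per modality, kept below 2^31
sub_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k

#' Generate a synthetic LFP
#'
#' The signal is a sum of delta/theta/beta/gamma sinusoids with random phases
#' plus 1/f ("pink") background noise shaped in the frequency domain
#' (amplitude ~ f^(-noise_exponent/2), standardized to `noise_scale`
#' microvolts SD). The analytic theta phase series (2 pi f_theta t + phase
#' offset, wrapped to [0, 2 pi)) is attached as attribute `"theta_phase"`
#' and serves as ground truth for phase-locked spike generation.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return An [lfp_signal()] (band `"wideband"`) with attribute `theta_phase`.
#' @export
generate_lfp <- function(config, seed) {
  if (config$duration_s < 10)
    stop("duration_s must be >= 10 s for spectral analysis")
  fs <- config$fs_lfp
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(sub_seed(seed, 1L), {
    phases <- stats::runif(length(config$osc_freq_hz), 0, 2 * pi)
    x <- numeric(n)
    for (b in seq_along(config$osc_freq_hz))
      x <- x + config$osc_amp_uv[[b]] *
        sin(2 * pi * config$osc_freq_hz[[b]] * t + phases[b])
    if (config$noise_scale > 0) {
      w <- stats::rnorm(n)
      W <- stats::fft(w)
      f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
      shape <- c(0, f[-1]^(-config$noise_exponent / 2))
      pink <- Re(stats::fft(W * shape, inverse = TRUE)) / n
      pink <- (pink - mean(pink)) / stats::sd(pink) * config$noise_scale
      x <- x + pink
    } else {
      stats::rnorm(n)  # keep RNG stream alignment across noise settings
    }
    out <- lfp_signal(x, fs = fs, band = "wideband")
    ith <- which(names(config$osc_freq_hz) == "theta")
    attr(out, "theta_phase") <-
      (2 * pi * config$osc_freq_hz[[ith]] * t + phases[ith] ) %% (2 * pi)
    out
  })
}

# biphasic waveform template; trough-to-peak width in ms sets the timescale
make_waveform <- function(trough_to_peak_ms, fs_wf = 25000) {
  ttp <- trough_to_peak_ms / 1000
  tt <- seq(-1.5 * ttp, 3 * ttp, by = 1 / fs_wf)
  w <- -exp(-(tt / (0.4 * ttp))^2) + 0.45 * exp(-((tt - ttp) / (0.7 * ttp))^2)
  list(waveform = 80 * w, fs_waveform = fs_wf)
}

#' Generate theta-phase-locked spike units
#'
#' Each unit is an inhomogeneous Poisson process with von Mises-modulated
#' intensity lambda(t) = r0 * exp(kappa * cos(theta(t) - phi0)) / I0(kappa),
#' sampled exactly by thinning. The I0 normalization makes the time-averaged
#' rate equal r0 regardless of kappa, so synchrony manipulations leave firing
#' rates unchanged. RS units get broad waveform templates (0.8 ms
#' trough-to-peak) and rates drawn from 1-15 spikes/s; FS units get templates
#' half as wide (0.4 ms) and rates from 15-50 spikes/s.
#'
#' @param config a [synth_config()].
#' @param theta_phase theta phase series in radians on the LFP clock
#'   (attribute of [generate_lfp()] output).
#' @param fs sampling rate of `theta_phase`, Hz.
#' @param seed integer seed.
#' @return list of [spike_unit()]; attribute `"r0"` carries the ground-truth
#'   mean rates.
#' @export
generate_spikes <- function(config, theta_phase, fs, seed) {
  if (config$kappa < 0) stop("kappa must be >= 0")
  n_units <- config$n_rs + config$n_fs
  dur <- length(theta_phase) / fs
  with_seed(sub_seed(seed, 2L), {
    # rates drawn before any spike sampling so they are condition-invariant
    r0 <- c(stats::runif(config$n_rs, config$rs_rate_hz[1], config$rs_rate_hz[2]),
            stats::runif(config$n_fs, config$fs_rate_hz[1], config$fs_rate_hz[2]))
    is_fs <- c(rep(FALSE, config$n_rs), rep(TRUE, config$n_fs))
    units <- vector("list", n_units)
    for (k in seq_len(n_units)) {
      lam_max <- r0[k] * exp(config$kappa) / besselI(config$kappa, 0)
      n_cand <- stats::rpois(1, lam_max * dur)
      cand <- sort(stats::runif(n_cand, 0, dur))
      idx <- pmin(floor(cand * fs) + 1L, length(theta_phase))
      accept <- stats::runif(n_cand) <
        exp(config$kappa * (cos(theta_phase[idx] - config$preferred_phase) - 1))
      st <- cand[accept]
      ttp <- if (is_fs[k]) 0.4 else 0.8
      wf <- make_waveform(ttp)
      units[[k]] <- spike_unit(st, waveform = wf$waveform,
                               fs_waveform = wf$fs_waveform,
                               trough_to_peak_ms = ttp)
    }
    attr(units, "r0") <- r0
    units
  })
}

#' Generate a treadmill speed trace
#'
#' Alternating movement/rest bouts with exponentially distributed durations;
#' within movement bouts the speed follows a mean-reverting
#' (Ornstein-Uhlenbeck) process around `speed_mean_cms`, rectified at zero;
#' during rest the speed is zero.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param duration_s optional override of `config$duration_s`.
#' @return A [speed_trace()].
#' @export
generate_speed <- function(config, seed, duration_s = config$duration_s) {
  fs <- config$fs_speed
  n <- round(duration_s * fs)
  dt <- 1 / fs
  with_seed(sub_seed(seed, 3L), {
    moving <- bout_mask(n, fs, config$move_frac, config$bout_move_s)
    s <- numeric(n)
    cur <- config$speed_mean_cms
    for (i in seq_len(n)) {
      if (moving[i]) {
        cur <- cur + config$speed_relax_hz * (config$speed_mean_cms - cur) * dt +
          config$speed_vol * sqrt(dt) * stats::rnorm(1)
        cur <- max(cur, 0)
        s[i] <- cur
      } else {
        cur <- config$speed_mean_cms  # re-enter bouts near typical speed
        s[i] <- 0
      }
    }
    speed_trace(s, fs = fs)
  })
}

# alternating move/rest bout indicator over n samples
bout_mask <- function(n, fs, move_frac, bout_move_s) {
  if (move_frac >= 1) return(rep(TRUE, n))
  if (move_frac <= 0) return(rep(FALSE, n))
  bout_rest_s <- bout_move_s * (1 - move_frac) / move_frac
  mask <- logical(n)
  i <- 1L
  moving <- stats::runif(1) < move_frac
  while (i <= n) {
    len <- max(1L, round(stats::rexp(1, 1 / (if (moving) bout_move_s else bout_rest_s)) * fs))
    j <- min(n, i + len - 1L)
    mask[i:j] <- moving
    moving <- !moving
    i <- j + 1L
  }
  mask
}

#' Generate calcium fluorescence traces
#'
#' Per neuron, per-frame event counts are Poisson with
#' log rate = const + a * L(t) + beta * speed(t), where L is a shared
#' standardized latent (AR(1), autocorrelation time `latent_tau_s`) and the
#' constant is set so the time-averaged event rate equals
#' `transient_rate_hz`. Events receive amplitudes from a normal distribution
#' truncated at zero and are convolved with an exponential-decay kernel
#' exp(-t/tau); the kernel value at the event frame equals the amplitude, so
#' on the near-zero baseline the detection thresholds operate in raw-trace
#' units. Gaussian noise of SD `trace_noise_sd` is added.
#'
#' @param config a [synth_config()].
#' @param speed a [speed_trace()] covering the session (resampled internally
#'   to the imaging frame clock).
#' @param seed integer seed.
#' @return A [calcium_traces()]; attribute `"latent"` carries the shared
#'   latent series (ground truth).
#' @export
generate_calcium <- function(config, speed, seed) {
  if (config$fs_ca <= 0) stop("fs_ca must be > 0")
  fs <- config$fs_ca
  n_fr <- round(duration_s(speed) * fs)
  tf <- (seq_len(n_fr) - 1) / fs
  ts <- (seq_along(speed$speed) - 1) / speed$fs
  sp <- stats::approx(ts, speed$speed, xout = tf, rule = 2)$y
  g <- exp(-1 / (fs * config$tau_decay_s))
  with_seed(sub_seed(seed, 4L), {
    rho <- exp(-1 / (fs * config$latent_tau_s))
    L <- as.numeric(stats::filter(stats::rnorm(n_fr, 0, sqrt(1 - rho^2)),
                                  rho, method = "recursive"))
    L <- (L - mean(L)) / stats::sd(L)
    eta <- config$latent_loading * L + config$speed_coupling * sp
    lam <- if (config$transient_rate_hz > 0) {
      config$transient_rate_hz / fs * exp(eta) / mean(exp(eta))
    } else rep(0, n_fr)
    traces <- matrix(0, config$n_neurons_ca, n_fr)
    for (j in seq_len(config$n_neurons_ca)) {
      counts <- stats::rpois(n_fr, lam)
      impulse <- numeric(n_fr)
      m <- sum(counts)
      if (m > 0) {
        # inverse-CDF truncated normal: fixed RNG consumption per event
        p0 <- stats::pnorm(0, config$transient_amp_mean, config$transient_amp_sd)
        amps <- stats::qnorm(p0 + stats::runif(m) * (1 - p0),
                             config$transient_amp_mean, config$transient_amp_sd)
        frame_of_event <- rep(seq_len(n_fr), counts)
        sums <- rowsum(amps, frame_of_event)
        impulse[as.integer(rownames(sums))] <- sums[, 1]
      }
      tr <- as.numeric(stats::filter(impulse, g, method = "recursive"))
      if (config$trace_noise_sd > 0)
        tr <- tr + stats::rnorm(n_fr, 0, config$trace_noise_sd)
      traces[j, ] <- tr
    }
    out <- calcium_traces(traces, fs = fs)
    attr(out, "latent") <- L
    out
  })
}

#' Generate an open-field trajectory
#'
#' Integrates a smooth heading random walk at the animal's running speed
#' (mean-reverting around `speed_mean_cms`) inside the arena, with reflecting
#' walls. Deterministic given (config, seed).
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param duration_s trajectory length in seconds (defaults to the 30-min
#'   open-field assay).
#' @return A [trajectory()].
#' @export
generate_trajectory <- function(config, seed, duration_s = config$duration_oft_s) {
  fs <- config$fs_traj
  n <- round(duration_s * fs)
  dt <- 1 / fs
  with_seed(sub_seed(seed, 5L), {
    v <- numeric(n); x <- numeric(n); y <- numeric(n)
    cur_v <- config$speed_mean_cms
    heading <- stats::runif(1, 0, 2 * pi)
    dheading <- stats::rnorm(n, 0, config$heading_sd * sqrt(dt))
    px <- config$arena_length_cm / 2
    py <- config$arena_width_cm / 2
    noise_v <- stats::rnorm(n)
    for (i in seq_len(n)) {
      cur_v <- cur_v + config$speed_relax_hz * (config$speed_mean_cms - cur_v) * dt +
        config$speed_vol * sqrt(dt) * noise_v[i]
      cur_v <- max(cur_v, 0)
      heading <- heading + dheading[i]
      px <- px + cur_v * cos(heading) * dt
      py <- py + cur_v * sin(heading) * dt
      # reflecting walls
      if (px < 0) { px <- -px; heading <- pi - heading }
      if (px > config$arena_length_cm) {
        px <- 2 * config$arena_length_cm - px; heading <- pi - heading
      }
      if (py < 0) { py <- -py; heading <- -heading }
      if (py > config$arena_width_cm) {
        py <- 2 * config$arena_width_cm - py; heading <- -heading
      }
      px <- min(max(px, 0), config$arena_length_cm)
      py <- min(max(py, 0), config$arena_width_cm)
      x[i] <- px; y[i] <- py
    }
    trajectory(x, y, fs = fs,
               arena_length_cm = config$arena_length_cm,
               arena_width_cm = config$arena_width_cm)
  })
}

#' Generate a complete synthetic session for a condition preset
#'
#' Composes [generate_lfp()], [generate_spikes()], [generate_speed()],
#' [generate_calcium()] and [generate_trajectory()] into a validated
#' [session()], with provenance recording the preset and seed. The same
#' (preset, seed) pair always yields a bit-identical session.
#'
#' @param preset preset name (see [condition_preset()]) or a `synth_config`.
#' @param seed integer seed.
#' @param duration_s session duration in seconds (default from config).
#' @param ... further overrides forwarded to [condition_preset()].
#' @return An `hd_session`.
#' @export
generate_session <- function(preset, seed, duration_s = NULL, ...) {
  cfg <- if (inherits(preset, "synth_config")) preset
         else condition_preset(preset, ...)
  if (!is.null(duration_s)) cfg$duration_s <- duration_s
  lfp <- generate_lfp(cfg, seed)
  units <- generate_spikes(cfg, attr(lfp, "theta_phase"), fs = cfg$fs_lfp,
                           seed = seed)
  speed <- generate_speed(cfg, seed)
  calcium <- generate_calcium(cfg, speed, seed)
  traj <- generate_trajectory(cfg, seed)
  pname <- attr(cfg, "preset")
  grp <- if (!is.null(pname) && startsWith(pname, "MK801")) "mk801" else "vehicle"
  trt <- if (!is.null(pname) && endsWith(pname, "_ARI")) "ari" else "saline"
  s <- session(
    session_id = sprintf("synth-%s-seed%d",
                         if (is.null(pname)) "custom" else tolower(pname), seed),
    group = grp, treatment = trt,
    lfp = lfp, units = units, calcium = calcium, speed = speed,
    trajectory = traj,
    provenance = list(synthetic = TRUE,
                      preset = if (is.null(pname)) "custom" else pname,
                      seed = seed))
  attr(s, "theta_phase") <- attr(lfp, "theta_phase")
  attr(s, "config") <- cfg
  s
}
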