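#' Read and write sessions on disk
#'
#' Sessions are stored as one directory per session in a plain-text layout
#' that mirrors the modality structure: `meta.json` holds labels, sampling
#' rates and provenance; numeric series live in CSV files (`lfp.csv`,
#' `speed.csv`, `trajectory.csv`, `calcium.csv`, `units/unit_<k>_*.csv`).
#' All numbers are serialized with 17 significant digits so that a write /
#' read round trip reproduces every double bit-exactly. Absent modalities are
#' simply absent from disk; on read they come back as `NULL` ("not recorded"),
#' never as empty arrays.
#'
#' @param s an `hd_session`.
#' @param path directory to create (write) or read.
#' @param format storage dialect; only `"csvdir"` is implemented.
#' @return `write_session` returns `path` invisibly; `read_session` returns an
#'   `hd_session`.
#' @examples
#' s <- generate_session("VEHICLE", seed = 1, duration_s = 12)
#' p <- file.path(tempdir(), "ses-demo")
#' write_session(s, p)
#' s2 <- read_session(p)
#' stopifnot(identical(s$lfp$samples, s2$lfp$samples))
#' @export
write_session <- function(s, path, format = "csvdir") {
  format <- match.arg(format, "csvdir")
  if (length(validate_session(s)) > 0L)
    stop("refusing to write invalid session: ",
         paste(validate_session(s), collapse = "; "))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)

  meta <- list(session_id = s$session_id, group = s$group,
               treatment = s$treatment, provenance = s$provenance)
  if (!is.null(s$lfp)) meta$lfp <- list(fs = s$lfp$fs, band = s$lfp$band)
  if (!is.null(s$calcium)) meta$calcium <- list(fs = s$calcium$fs,
                                                n_neurons = nrow(s$calcium$traces))
  if (!is.null(s$speed)) meta$speed <- list(fs = s$speed$fs)
  if (!is.null(s$trajectory))
    meta$trajectory <- list(fs = s$trajectory$fs,
                            arena_length_cm = s$trajectory$arena_length_cm,
                            arena_width_cm = s$trajectory$arena_width_cm)
  if (!is.null(s$units))
    meta$units <- lapply(s$units, function(u)
      list(trough_to_peak_ms = u$trough_to_peak_ms, unit_class = u$unit_class,
           fs_waveform = u$fs_waveform))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if (!is.null(s$lfp)) write_num_csv(data.frame(samples = s$lfp$samples),
                                     file.path(path, "lfp.csv"))
  if (!is.null(s$speed)) write_num_csv(data.frame(speed = s$speed$speed),
                                       file.path(path, "speed.csv"))
  if (!is.null(s$trajectory))
    write_num_csv(data.frame(x = s$trajectory$x, y = s$trajectory$y),
                  file.path(path, "trajectory.csv"))
  if (!is.null(s$calcium)) {
    # frames as rows, neurons as columns
    m <- t(s$calcium$traces)
    colnames(m) <- sprintf("neuron_%03d", seq_len(ncol(m)))
    write_num_csv(as.data.frame(m), file.path(path, "calcium.csv"))
  }
  if (!is.null(s$units)) {
    udir <- file.path(path, "units")
    dir.create(udir, showWarnings = FALSE)
    for (k in seq_along(s$units)) {
      u <- s$units[[k]]
      write_num_csv(data.frame(spike_times = u$spike_times),
                    file.path(udir, sprintf("unit_%03d_spikes.csv", k)))
      if (!is.null(u$waveform))
        write_num_csv(data.frame(waveform = u$waveform),
                      file.path(udir, sprintf("unit_%03d_waveform.csv", k)))
    }
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, format = "csvdir") {
  format <- match.arg(format, "csvdir")
  mpath <- file.path(path, "meta.json")
  if (!file.exists(mpath)) stop("not a session directory (missing meta.json): ", path)
  meta <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  for (f in c("session_id", "group", "treatment"))
    if (is.null(meta[[f]])) stop("format error: meta.json missing field '", f, "'")

  lfp <- units <- calcium <- speed <- traj <- NULL
  if (!is.null(meta$lfp)) {
    d <- read_num_csv(file.path(path, "lfp.csv"))
    lfp <- lfp_signal(d$samples, fs = meta$lfp$fs, band = meta$lfp$band)
  }
  if (!is.null(meta$speed)) {
    d <- read_num_csv(file.path(path, "speed.csv"))
    speed <- speed_trace(d$speed, fs = meta$speed$fs)
  }
  if (!is.null(meta$trajectory)) {
    d <- read_num_csv(file.path(path, "trajectory.csv"))
    traj <- trajectory(d$x, d$y, fs = meta$trajectory$fs,
                       arena_length_cm = meta$trajectory$arena_length_cm,
                       arena_width_cm = meta$trajectory$arena_width_cm)
  }
  if (!is.null(meta$calcium)) {
    d <- read_num_csv(file.path(path, "calcium.csv"))
    calcium <- calcium_traces(t(as.matrix(d)), fs = meta$calcium$fs)
    dimnames(calcium$traces) <- NULL
  }
  if (!is.null(meta$units)) {
    units <- vector("list", length(meta$units))
    for (k in seq_along(meta$units)) {
      mu <- meta$units[[k]]
      st <- read_num_csv(file.path(path, "units",
                                   sprintf("unit_%03d_spikes.csv", k)))$spike_times
      wpath <- file.path(path, "units", sprintf("unit_%03d_waveform.csv", k))
      wf <- if (file.exists(wpath)) read_num_csv(wpath)$waveform else NULL
      units[[k]] <- spike_unit(st, waveform = wf,
                               fs_waveform = null2na(mu$fs_waveform),
                               trough_to_peak_ms = null2na(mu$trough_to_peak_ms),
                               unit_class = mu$unit_class)
    }
  }
  prov <- meta$provenance
  if (is.null(prov) || length(prov) == 0L) prov <- list()
  s <- session(meta$session_id, group = meta$group, treatment = meta$treatment,
               lfp = lfp, units = units, calcium = calcium, speed = speed,
               trajectory = traj, provenance = prov)
  v <- validate_session(s)
  if (length(v) > 0L) stop("validation error: ", paste(v, collapse = "; "))
  s
}

null2na <- function(x) if (is.null(x)) NA_real_ else x

# CSV with full double precision: %.17g round-trips IEEE doubles exactly.
write_num_csv <- function(df, file) {
  fmt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  lines <- c(paste(names(df), collapse = ","),
             apply(fmt, 1L, paste, collapse = ","))
  writeLines(lines, file)
}

read_num_csv <- function(file) {
  if (!file.exists(file)) stop("format error: missing data file ", file)
  utils::read.csv(file, colClasses = "numeric")
}
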