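#' Fisher z transform of correlation coefficients
#'
#' Variance-stabilizing transform z = atanh(r). Coefficients are clipped to
#' |r| <= 1 - 1e-6 before the transform so that perfectly correlated pairs
#' map to a large finite value instead of infinity.
#'
#' @param r numeric vector of correlation coefficients in [-1, 1].
#' @return numeric vector of Fisher z values (finite).
#' @export
fisher_z <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  atanh(pmin(pmax(r, -1 + 1e-6), 1 - 1e-6))
}

#' Pairwise neuron-neuron correlations of calcium dynamics
#'
#' Correlates every pair of z-scored traces (Pearson, or Spearman as Pearson
#' on average ranks). Returns both the full symmetric matrix and a tidy table
#' of the unique off-diagonal pairs with their Fisher-z values; the unit
#' diagonal is excluded from all summaries.
#'
#' @param zct standardized traces from [zscore_traces()] (a
#'   [calcium_traces()]), or a bare neurons x frames matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `pairwise_corr`: `matrix` (neurons x neurons),
#'   `pairs` (data.frame: `i`, `j`, `method`, `r`, `fisher_z`),
#'   `mean_r`, `mean_fisher_z`.
#' @export
pairwise_corr <- function(zct, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (inherits(zct, "calcium_traces")) zct$traces else as.matrix(zct)
  if (nrow(m) < 2L) stop("need >= 2 neurons for pairwise correlation")
  if (ncol(m) < 30L) stop("need >= 30 frames for pairwise correlation")
  cm <- stats::cor(t(m), method = method)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(i = ut[, 1], j = ut[, 2], method = method,
                      r = cm[ut], fisher_z = fisher_z(cm[ut]))
  structure(list(matrix = cm, pairs = pairs,
                 mean_r = mean(pairs$r),
                 mean_fisher_z = mean(pairs$fisher_z)),
            class = "pairwise_corr")
}

#' Neuron-speed correlations
#'
#' Correlates each z-scored trace with locomotion speed linearly interpolated
#' onto the calcium frame clock.
#'
#' @param zct standardized traces ([zscore_traces()] output).
#' @param speed a [speed_trace()] overlapping the imaging period.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame with one row per neuron: `neuron`, `method`, `r`,
#'   `fisher_z`.
#' @export
speed_corr <- function(zct, speed, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (inherits(zct, "calcium_traces")) zct$traces else as.matrix(zct)
  fs <- if (inherits(zct, "calcium_traces")) zct$fs else
    stop("speed_corr needs a calcium_traces object to know the frame clock")
  tf <- (seq_len(ncol(m)) - 1) / fs
  tsp <- (seq_along(speed$speed) - 1) / speed$fs
  n_overlap <- sum(tf <= max(tsp))
  if (n_overlap < 30L)
    stop("only ", n_overlap, " overlapping frames (need >= 30)")
  sp <- stats::approx(tsp, speed$speed, xout = tf, rule = 2)$y
  r <- apply(m, 1L, function(tr) stats::cor(tr, sp, method = method))
  data.frame(neuron = seq_len(nrow(m)), method = method, r = r,
             fisher_z = fisher_z(r))
}

#' Empirical cumulative distribution function table
#'
#' Right-continuous step CDF of a sample, as a table suitable for plotting
#' cumulative distributions of correlation or coherence values.
#'
#' @param values numeric vector (length >= 1).
#' @return data.frame with `x` (sorted unique values) and `cdf`
#'   (P(X <= x); final value 1).
#' @export
empirical_cdf <- function(values) {
  stopifnot(length(values) >= 1L)
  x <- sort(unique(values))
  data.frame(x = x, cdf = stats::ecdf(values)(x))
}
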