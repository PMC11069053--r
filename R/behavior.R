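#' Open-field test metrics from a trajectory
#'
#' Computes total distance traveled (sum of Euclidean steps) and the
#' percentage of time spent in the center region over the analysis window
#' (default 30 min, the standard assay duration). The center is the
#' axis-aligned rectangle concentric with the arena with each side scaled by
#' 0.5, so its area is exactly 25% of the arena for any dimensions.
#'
#' @param traj a [trajectory()].
#' @param duration_s analysis window in seconds; when the trajectory is
#'   shorter, metrics are computed on the available span with a warning.
#' @return list of class `oft_metrics`: `total_distance_cm`,
#'   `pct_time_center`, `duration_s`.
#' @export
oft_metrics <- function(traj, duration_s = 1800) {
  n_want <- round(duration_s * traj$fs)
  n <- length(traj$x)
  if (n < n_want) {
    warning(sprintf("trajectory covers %.1f s < %.1f s window; using available span",
                    n / traj$fs, duration_s))
    n_want <- n
  }
  x <- traj$x[seq_len(n_want)]
  y <- traj$y[seq_len(n_want)]
  dist <- sum(sqrt(diff(x)^2 + diff(y)^2))
  L <- traj$arena_length_cm
  W <- traj$arena_width_cm
  inside <- x >= L / 4 & x <= 3 * L / 4 & y >= W / 4 & y <= 3 * W / 4
  structure(list(total_distance_cm = dist,
                 pct_time_center = 100 * mean(inside),
                 duration_s = n_want / traj$fs),
            class = "oft_metrics")
}

#' Group comparison report over sessions
#'
#' The thin reporting stage: per-cell descriptive statistics (mean, SD) and
#' the appropriate inferential comparison for each metric. Designs with a
#' single varying factor (vehicle vs MK-801) are compared with Student's
#' two-sample t-test; 2 x 2 designs (group x treatment, the aripiprazole
#' experiments) use a two-way ANOVA with Sidak-adjusted post-hoc contrasts of
#' treatment within each group (via emmeans). Inference is delegated to
#' standard routines; this stage only organizes inputs and outputs.
#'
#' @param x either a data.frame with columns `group`, `treatment` and one
#'   numeric column per metric, or a list of `hd_session` objects together
#'   with `extractors`.
#' @param metrics character vector of metric column names (default: all
#'   numeric columns).
#' @param extractors named list of functions `session -> scalar`, used when
#'   `x` is a list of sessions.
#' @return list of class `group_table` with `cells` (metric, group,
#'   treatment, n, mean, sd) and `tests` (metric, test, contrast, statistic,
#'   df, p, p_sidak).
#' @export
group_report <- function(x, metrics = NULL, extractors = NULL) {
  if (!is.data.frame(x)) {
    stopifnot(is.list(x), !is.null(extractors))
    rows <- lapply(x, function(s) {
      vals <- lapply(extractors, function(f) f(s))
      cbind(data.frame(group = s$group, treatment = s$treatment),
            as.data.frame(vals))
    })
    x <- do.call(rbind, rows)
    metrics <- names(extractors)
  }
  if (is.null(metrics))
    metrics <- setdiff(names(x)[vapply(x, is.numeric, logical(1))],
                       c("group", "treatment"))
  cells <- do.call(rbind, lapply(metrics, function(m) {
    agg <- stats::aggregate(x[[m]], by = list(group = x$group,
                                              treatment = x$treatment),
                            FUN = function(v) c(n = sum(!is.na(v)),
                                                mean = mean(v, na.rm = TRUE),
                                                sd = stats::sd(v, na.rm = TRUE)))
    data.frame(metric = m, group = agg$group, treatment = agg$treatment,
               n = agg$x[, "n"], mean = agg$x[, "mean"], sd = agg$x[, "sd"])
  }))
  two_by_two <- length(unique(x$group)) > 1L && length(unique(x$treatment)) > 1L
  tests <- do.call(rbind, lapply(metrics, function(m) {
    d <- x[!is.na(x[[m]]), c("group", "treatment", m)]
    names(d)[3] <- "value"
    if (!two_by_two) {
      if (length(unique(d$group)) < 2L) {
        message("metric '", m, "': only one group level; comparison skipped")
        return(NULL)
      }
      tt <- stats::t.test(value ~ group, data = d, var.equal = TRUE)
      return(data.frame(metric = m, test = "t",
                        contrast = paste(sort(unique(d$group)), collapse = " vs "),
                        statistic = unname(tt$statistic),
                        df = unname(tt$parameter), p = tt$p.value,
                        p_sidak = NA_real_))
    }
    tab <- table(d$group, d$treatment)
    if (any(tab < 2L)) {
      message("metric '", m, "': a design cell has < 2 sessions; ANOVA skipped")
      return(NULL)
    }
    d$group <- factor(d$group)
    d$treatment <- factor(d$treatment)
    fit <- stats::aov(value ~ group * treatment, data = d)
    an <- summary(fit)[[1]]
    main <- data.frame(metric = m, test = "anova",
                       contrast = trimws(rownames(an)[1:3]),
                       statistic = an[1:3, "F value"],
                       df = an[1:3, "Df"], p = an[1:3, "Pr(>F)"],
                       p_sidak = NA_real_)
    emm <- emmeans::emmeans(fit, ~ treatment | group)
    ct <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
    msk <- nrow(ct)  # Sidak family: treatment contrast within each group
    post <- data.frame(metric = m, test = "posthoc_t",
                       contrast = paste(ct$contrast, "|", ct$group),
                       statistic = ct$t.ratio, df = ct$df, p = ct$p.value,
                       p_sidak = 1 - (1 - ct$p.value)^msk)
    rbind(main, post)
  }))
  structure(list(cells = cells, tests = tests), class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat("Cell summaries (mean ± SD):\n")
  print(transform(x$cells,
                  summary = sprintf("%.3g ± %.3g (n=%d)", mean, sd, n))[,
                  c("metric", "group", "treatment", "summary")], row.names = FALSE)
  cat("\nComparisons:\n")
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}
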