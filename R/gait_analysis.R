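#' Segment joint-angle streams into gait cycles at heel strikes
#'
#' One gait cycle is the interval between consecutive heel strikes of the
#' same foot; the first `n_keep` complete cycles after the first detected
#' heel strike are extracted (default 30 per trial).
#'
#' @param hs_times Numeric vector of heel-strike times in seconds
#'   (ascending).
#' @param angles Data frame with a `t` column and one column per joint
#'   angle (degrees).
#' @param n_keep Number of cycles to keep (default 30).
#' @return List of `n_keep` data frames, each the samples of one cycle
#'   (boundary samples included on both ends).
#' @export
segment_cycles <- function(hs_times, angles, n_keep = 30) {
  hs_times <- sort(hs_times)
  avail <- length(hs_times) - 1L
  if (avail < n_keep) {
    stop(sprintf("insufficient data: %d complete cycle(s) available, %d requested",
                 max(avail, 0L), n_keep), call. = FALSE)
  }
  stopifnot("t" %in% names(angles))
  lapply(seq_len(n_keep), function(i) {
    sel <- angles$t >= hs_times[i] & angles$t <= hs_times[i + 1]
    cyc <- angles[sel, , drop = FALSE]
    if (nrow(cyc) < 2) {
      stop("insufficient data: cycle ", i, " has fewer than 2 samples",
           call. = FALSE)
    }
    rownames(cyc) <- NULL
    cyc
  })
}

#' Time-normalize one gait cycle to 0-100% of the cycle
#'
#' Resamples each joint-angle column onto 101 evenly spaced points between
#' the cycle's first and last sample by linear interpolation, so cycles of
#' different durations become comparable on a common 0-100% grid.
#'
#' @param cycle Data frame with `t` and joint-angle columns (>= 2 rows).
#' @param n_points Number of grid points (default 101, i.e. every 1% of
#'   the cycle).
#' @return Data frame with column `pct` (0-100) and the interpolated
#'   joint columns; exactly 101 rows, endpoints equal to the cycle's
#'   boundary values.
#' @export
normalize_cycle <- function(cycle, n_points = 101L) {
  stopifnot(nrow(cycle) >= 2, "t" %in% names(cycle))
  grid <- seq(min(cycle$t), max(cycle$t), length.out = n_points)
  out <- data.frame(pct = seq(0, 100, length.out = n_points))
  for (col in setdiff(names(cycle), "t")) {
    out[[col]] <- stats::approx(cycle$t, cycle[[col]], xout = grid,
                                ties = "ordered")$y
  }
  out
}

#' Per-cycle range-of-motion statistics
#'
#' For each normalized cycle and joint, the maximum, minimum and range of
#' movement (RoM = max - min) over the 101 samples.
#'
#' @param cycles List of normalized cycles from [normalize_cycle()] (or a
#'   single one).
#' @return Data frame with columns `cycle`, `joint`, `max`, `min`, `rom`.
#' @export
compute_stats <- function(cycles) {
  if (is.data.frame(cycles)) cycles <- list(cycles)
  stopifnot(length(cycles) > 0)
  joints <- setdiff(names(cycles[[1]]), "pct")
  n <- length(cycles)
  mx <- matrix(0, n, length(joints), dimnames = list(NULL, joints))
  mn <- mx
  for (i in seq_len(n)) {
    cyc <- cycles[[i]]
    for (k in seq_along(joints)) {
      v <- cyc[[joints[k]]]
      mx[i, k] <- max(v)
      mn[i, k] <- min(v)
    }
  }
  data.frame(cycle = rep(seq_len(n), each = length(joints)),
             joint = rep(joints, n),
             max = as.vector(t(mx)), min = as.vector(t(mn)),
             rom = as.vector(t(mx - mn)), row.names = NULL)
}

# two-sample t on one parameter; degenerate zero-variance case: equal
# means give t = 0, p = 1 (no evidence of a difference from constant data)
.t_compare <- function(a, b, var_equal = TRUE) {
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Compare per-cycle statistics between two walking conditions
#'
#' Two-sample t-tests (pooled variance by default) on every joint x
#' parameter combination (`rom`, `max`, `min`), with the significance
#' level corrected for the number of comparisons. The shipped default
#' corrected level is 0.004; supplying `n_comparisons` instead derives
#' `alpha_corrected = alpha / n_comparisons` (Bonferroni).
#'
#' @param statsA,statsB Per-cycle statistics data frames from
#'   [compute_stats()] for the two conditions (each >= 2 cycles).
#' @param alpha Nominal significance level (default 0.05).
#' @param n_comparisons Optional Bonferroni divisor; overrides
#'   `alpha_corrected` when given.
#' @param alpha_corrected Corrected per-comparison level (default 0.004).
#' @param var_equal Use the pooled-variance t-test (default `TRUE`);
#'   `FALSE` selects the Welch variant.
#' @return Data frame with one row per joint x parameter: group means,
#'   mean difference (A - B), `t`, `df`, two-sided `p`, and `significant`
#'   (`p < alpha_corrected`). The corrected level is attached as attribute
#'   `"alpha_corrected"`.
#' @export
compare_conditions <- function(statsA, statsB, alpha = 0.05,
                               n_comparisons = NULL, alpha_corrected = 0.004,
                               var_equal = TRUE) {
  if (!is.null(n_comparisons)) alpha_corrected <- alpha / n_comparisons
  stopifnot(alpha_corrected <= alpha)
  joints <- intersect(unique(statsA$joint), unique(statsB$joint))
  params <- c("rom", "max", "min")
  rows <- list()
  for (j in joints) {
    for (p in params) {
      a <- statsA[[p]][statsA$joint == j]
      b <- statsB[[p]][statsB$joint == j]
      if (length(a) < 2 || length(b) < 2) {
        stop("insufficient data: need >= 2 cycles per condition", call. = FALSE)
      }
      ts <- .t_compare(a, b, var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        joint = j, parameter = p,
        mean_a = mean(a), mean_b = mean(b), diff = mean(a) - mean(b),
        t = ts$t, df = ts$df, p = ts$p,
        significant = ts$p < alpha_corrected)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha_corrected") <- alpha_corrected
  out
}

#' Write per-cycle statistics and the condition comparison report
#'
#' @param stats Data frame from [compute_stats()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stats_csv
#' @param comparison Data frame from [compare_conditions()].
#' @param text_path Optional path for a human-readable summary.
#' @export
write_comparison_report <- function(comparison, path, text_path = NULL) {
  utils::write.csv(comparison, path, row.names = FALSE)
  if (!is.null(text_path)) {
    ac <- attr(comparison, "alpha_corrected")
    lines <- c(sprintf("Condition comparison (two-sample t-test, corrected p < %g)", ac),
               "",
               sprintf("%-6s %-4s  %9s %9s %9s %8s %9s %s",
                       "joint", "par", "mean A", "mean B", "diff",
                       "t", "p", "sig"),
               sprintf("%-6s %-4s  %9.3f %9.3f %9.3f %8.3f %9.4g %s",
                       comparison$joint, comparison$parameter,
                       comparison$mean_a, comparison$mean_b, comparison$diff,
                       comparison$t, comparison$p,
                       ifelse(comparison$significant, "*", "")))
    writeLines(lines, text_path)
  }
  invisible(path)
}
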