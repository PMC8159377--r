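# Beat-cycle machinery: segmentation in the B1-B2 shape-coefficient phase
# plane, phase-normalized mean cycles, and pooled cycle statistics.

#' Segment beat cycles in the B1-B2 phase plane
#'
#' A cycle starts where the polar angle atan2(B2, B1) crosses zero, i.e. where
#' B2 changes sign while B1 > 0, so the shape at the start of each cycle is
#' always a positive multiple of the first mode. The loop traverses that locus
#' in one direction per recording; `direction = "auto"` uses upward (- to +)
#' crossings when present and falls back to downward ones (the two differ only
#' by the arbitrary POD sign of mode 2). Crossing times are refined by linear
#' interpolation between samples; crossings closer than `min_period_frac`
#' times the median inter-crossing interval are treated as noise and merged.
#' Partial cycles at the record ends are discarded.
#'
#' @param B1,B2 shape-coefficient time series on a uniform time grid.
#' @param t_grid time grid (s).
#' @param min_period_frac debounce threshold as a fraction of the median
#'   period (default 0.25).
#' @param direction `"auto"`, `"up"` (B2 from - to +) or `"down"`.
#' @return data.frame with columns `cycle`, `t0` (start time, s) and `T`
#'   (period, s).
#' @export
segment_cycles <- function(B1, B2, t_grid, min_period_frac = 0.25,
                           direction = c("auto", "up", "down")) {
  stopifnot(length(B1) == length(t_grid), length(B2) == length(t_grid))
  direction <- match.arg(direction)
  n <- length(t_grid)
  up <- which(B2[-n] < 0 & B2[-1] >= 0 & B1[-n] > 0)
  down <- which(B2[-n] > 0 & B2[-1] <= 0 & B1[-n] > 0)
  i <- switch(direction,
              up = up, down = down,
              auto = if (length(up) >= length(down)) up else down)
  if (length(i) < 2) stop("no complete cycle: fewer than 2 zero crossings")
  frac <- -B2[i] / (B2[i + 1] - B2[i])
  tc <- t_grid[i] + frac * (t_grid[i + 1] - t_grid[i])
  minp <- min_period_frac * stats::median(diff(tc))
  keep <- tc[1]
  for (k in tc[-1]) if (k - keep[length(keep)] >= minp) keep <- c(keep, k)
  if (length(keep) < 2) stop("no complete cycle after debouncing")
  data.frame(cycle = seq_len(length(keep) - 1),
             t0 = keep[-length(keep)], T = diff(keep))
}

#' Phase-normalized mean cycle of a time series
#'
#' Each cycle is resampled by linear interpolation onto a common phase grid
#' tau in [0, 1); the mean and standard error across cycles are returned at
#' each tau.
#'
#' @param t time grid of `x`.
#' @param x time series.
#' @param cycles data.frame from [segment_cycles()].
#' @param n_phase number of phase stations (default 100).
#' @return data.frame with `tau`, `mean`, `sem`, and attribute `n_cycles`.
#' @export
phase_mean_cycle <- function(t, x, cycles, n_phase = 100) {
  if (nrow(cycles) < 2) stop("need at least 2 cycles")
  tau <- seq(0, 1 - 1 / n_phase, length.out = n_phase)
  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    t0 <- cycles$t0[i]; Ti <- cycles$T[i]
    if (sum(t >= t0 & t <= t0 + Ti) < 3) return(NULL)
    interp_lin(t, x, t0 + tau * Ti)
  })
  m <- do.call(rbind, rows)
  out <- data.frame(tau = tau, mean = colMeans(m),
                    sem = apply(m, 2, stats::sd) / sqrt(nrow(m)))
  attr(out, "n_cycles") <- nrow(m)
  out
}

significance_tier <- function(p) {
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "n.s."
}

#' Compare pooled cycle-means of two groups
#'
#' Welch (unequal-variance) unpaired two-tailed t-test between the pooled
#' per-cycle means of two genotypes, with the conventional significance tiers.
#' When groups are given as lists of per-sample vectors, a one-way ANOVA of
#' sample versus pooled population is also run within each group.
#'
#' @param groupA,groupB numeric vectors of cycle-means, or lists of per-sample
#'   numeric vectors.
#' @return list with `p`, `tier`, the `t_test` object, group means, and (when
#'   applicable) `anova_A`, `anova_B` p-values for within-group sample effects.
#' @export
pool_and_compare <- function(groupA, groupB) {
  pool <- function(g) if (is.list(g)) unlist(g, use.names = FALSE) else g
  a <- pool(groupA); b <- pool(groupB)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    tt <- NULL
  } else {
    tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
    p <- tt$p.value
  }
  res <- list(p = p, tier = significance_tier(p), t_test = tt,
              mean_A = mean(a), mean_B = mean(b))
  one_way <- function(g) {
    if (!is.list(g) || length(g) < 2) return(NA_real_)
    d <- data.frame(value = unlist(g),
                    sample = factor(rep(seq_along(g), lengths(g))))
    stats::anova(stats::aov(value ~ sample, data = d))[["Pr(>F)"]][1]
  }
  res$anova_A <- one_way(groupA)
  res$anova_B <- one_way(groupB)
  res
}

#' Notched box-plot statistics
#'
#' Quartiles use the linear-interpolation convention (R quantile type 7);
#' outliers lie more than 1.5 IQR beyond the box edges; whiskers reach the
#' most extreme non-outlier points; the notch half-width is
#' 1.57 (q3 - q1) / sqrt(n).
#'
#' @param values numeric vector (n >= 1).
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `notch_low`, `notch_high`, `n`.
#' @export
boxplot_stats <- function(values) {
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  nw <- 1.57 * iqr / sqrt(length(values))
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = values[!inside],
       notch_low = q[2] - nw, notch_high = q[2] + nw, n = length(values))
}
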