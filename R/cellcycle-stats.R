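#' Summarize a sample of phase lengths
#'
#' Computes n, mean, standard deviation (n-1 denominator), range, coefficient
#' of variation (sd/mean) and a histogram over `[floor(min), ceiling(max)]`.
#'
#' @param values Positive phase lengths in hours.
#' @param bin_width Histogram bin width in hours (default 1, matching typical
#'   single-cell G1 histograms).
#' @return An object of class `g1dist_summary`: a list with `n`, `mean_h`,
#'   `sd_h`, `min_h`, `max_h`, `cv`, and `histogram` (`breaks`, `counts`).
#' @export
summarize_lengths <- function(values, bin_width = 1) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA; drop censored lengths first")
  if (length(values) < 2) stop("insufficient data: need n >= 2 for sd/cv")
  if (any(values <= 0)) stop("phase lengths must be positive")
  breaks <- seq(floor(min(values)), ceiling(max(values)), by = bin_width)
  if (breaks[length(breaks)] < max(values)) breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + bin_width)
  # right-open bins, except the last which is closed so the maximum is counted
  counts <- vapply(seq_len(length(breaks) - 1L), function(i) {
    hi_closed <- i == length(breaks) - 1L
    sum(values >= breaks[i] & (if (hi_closed) values <= breaks[i + 1] else values < breaks[i + 1]))
  }, integer(1))
  out <- list(
    n = length(values),
    mean_h = mean(values),
    sd_h = sd(values),
    min_h = min(values),
    max_h = max(values),
    cv = sd(values) / mean(values),
    histogram = list(breaks = breaks, counts = counts)
  )
  class(out) <- "g1dist_summary"
  out
}

#' @export
print.g1dist_summary <- function(x, ...) {
  cat(sprintf("Phase-length summary: n = %d\n", x$n))
  cat(sprintf("  mean %.3f h, sd %.3f h, range [%.2f, %.2f] h\n",
              x$mean_h, x$sd_h, x$min_h, x$max_h))
  cat(sprintf("  CV %.1f%%\n", 100 * x$cv))
  invisible(x)
}

#' Split G1 lengths at a cutoff
#'
#' Partitions values (or records with a `g1_hours` column) into the group
#' below the cutoff and the group at or above it, and summarizes each group
#' where it holds at least two values. The default 6 h cutoff separates the
#' short-G1 regime typical of high-WNT media from the long-G1 tail.
#'
#' @param x Numeric G1 lengths, or a records `data.frame` from
#'   [derive_phase_lengths()] (censored G1 rows are dropped).
#' @param cutoff_hours Cutoff in hours (default 6).
#' @return List with `below`, `above` (numeric vectors: `< cutoff` and
#'   `>= cutoff`), and `summary_below`, `summary_above`
#'   ([summarize_lengths()] output, or `NULL` when a group has fewer than two
#'   values).
#' @export
split_by_cutoff <- function(x, cutoff_hours = 6) {
  values <- if (is.data.frame(x)) x$g1_hours[!x$g1_censored] else as.numeric(x)
  values <- values[!is.na(values)]
  below <- values[values < cutoff_hours]
  above <- values[values >= cutoff_hours]
  safe_summary <- function(v) if (length(v) >= 2) summarize_lengths(v) else NULL
  list(below = below, above = above,
       summary_below = safe_summary(below),
       summary_above = safe_summary(above))
}

#' Format a p-value with the conventional reporting floor
#'
#' Values below 2.2e-16 are reported as `"< 2.2e-16"`; the raw float is kept
#' alongside in all result objects.
#'
#' @param p A p-value.
#' @return Character label.
#' @export
format_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 4)
}

two_sample_result <- function(test_name, statistic, p_value, n1, n2, method = NULL) {
  out <- list(test_name = test_name, statistic = statistic,
              p_value = p_value, p_label = format_p(p_value),
              n1 = n1, n2 = n2, method = method)
  class(out) <- "g1dist_test"
  out
}

#' @export
print.g1dist_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %s (n1 = %d, n2 = %d%s)\n",
              x$test_name, x$statistic, x$p_label, x$n1, x$n2,
              if (is.null(x$method)) "" else paste0(", ", x$method)))
  invisible(x)
}

# Asymptotic two-sided Kolmogorov distribution tail:
# P(sup|B(t)| > lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
ks_p_asymptotic <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic D is the supremum over the pooled sample points of the absolute
#' difference between the two empirical CDFs. The two-sided p-value uses the
#' asymptotic Kolmogorov distribution (the choice is recorded in the result's
#' `method` field).
#'
#' @param a,b Numeric samples.
#' @return A `g1dist_test` with `statistic` = D in `[0, 1]`, the raw
#'   `p_value`, and `p_label` applying the `< 2.2e-16` reporting floor.
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) < 1 || length(b) < 1) stop("insufficient data: both samples must be non-empty")
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  d <- max(abs(fa - fb))
  n1 <- length(a); n2 <- length(b)
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
  two_sample_result("KS", d, ks_p_asymptotic(lambda), n1, n2,
                    method = "asymptotic")
}

# Exact permutation distribution of the rank sum of group 1, over the midrank
# multiset. Midranks are doubled so they are integers; f[j+1, s+1] counts
# subsets of size j with doubled-rank sum s. Counts stay well below 2^53 for
# the n1*n2 <= 400 regime where this is used.
ranksum_count_dp <- function(ranks2, n1) {
  total <- sum(ranks2)
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in ranks2) {
    jmax <- n1
    for (j in seq.int(jmax, 1L)) {
      src <- f[j, seq_len(total + 1L - r)]
      f[j + 1L, (r + 1L):(total + 1L)] <- f[j + 1L, (r + 1L):(total + 1L)] + src
    }
  }
  f[n1 + 1L, ]  # index s+1 = count of subsets of size n1 with doubled sum s
}

#' Two-sample Mann-Whitney U test
#'
#' U counts the pairs in which a value of `a` exceeds a value of `b`, with
#' ties counted 1/2 (midranks). The two-sided p-value comes from the exact
#' permutation distribution of the rank sum whenever `n1 * n2 <=
#' exact_limit` (computed by dynamic programming over the midrank multiset,
#' so ties are handled exactly), and otherwise from the normal approximation
#' with tie-corrected variance.
#'
#' @param a,b Numeric samples.
#' @param exact_limit Use the exact permutation distribution when
#'   `n1 * n2` does not exceed this (default 400).
#' @return A `g1dist_test` with `statistic` = U in `[0, n1*n2]`.
#' @export
mannwhitney_u <- function(a, b, exact_limit = 400) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("insufficient data: both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  m <- n1 * n2
  if (m <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    counts <- ranksum_count_dp(ranks2, n1)
    # doubled rank sum s corresponds to U = s/2 - n1(n1+1)/2
    s_obs <- as.integer(round(2 * (u + n1 * (n1 + 1) / 2)))
    dev <- abs(seq_along(counts) - 1 - sum(ranks2) * n1 / (n1 + n2))
    p <- sum(counts[dev >= dev[s_obs + 1L] - 1e-9]) / sum(counts)
    method <- "exact permutation"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- m / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - m / 2) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation, tie-corrected"
  }
  two_sample_result("MannWhitneyU", u, p, n1, n2, method = method)
}

#' Two-sample Student t test
#'
#' Convenience wrapper for the two-tailed Student t test used in bar-plot
#' style comparisons; equal variances assumed by default (`welch = TRUE`
#' switches to the Welch correction).
#'
#' @param a,b Numeric samples.
#' @param welch Use the Welch degrees-of-freedom correction (default FALSE).
#' @return A `g1dist_test` with `statistic` = t.
#' @export
student_t_test <- function(a, b, welch = FALSE) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2) stop("insufficient data: need n >= 2 per group")
  tt <- t.test(a, b, var.equal = !welch)
  two_sample_result("StudentT", unname(tt$statistic), tt$p.value,
                    length(a), length(b),
                    method = if (welch) "Welch" else "pooled variance")
}

#' Correlation between paired G1 and S/G2/M lengths
#'
#' Pearson correlation with the two-sided p-value from the t transform, for
#' cells in which both phases were measured. A negative correlation indicates
#' compensatory conservation of total cell-cycle length.
#'
#' @param g1_hours,sg2m_hours Paired phase lengths (same cells, same order).
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_phases <- function(g1_hours, sg2m_hours) {
  keep <- !is.na(g1_hours) & !is.na(sg2m_hours)
  x <- as.numeric(g1_hours[keep]); y <- as.numeric(sg2m_hours[keep])
  if (length(x) != length(y)) stop("phases must be paired")
  if (length(x) < 3) stop("insufficient data: need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
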