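test_that("summaries compute mean, sd, cv and a consistent histogram", {
  s <- summarize_lengths(c(4, 4, 4))
  expect_equal(s$mean_h, 4)
  expect_equal(s$sd_h, 0)
  expect_equal(s$cv, 0)

  s2 <- summarize_lengths(c(2, 4, 6))
  expect_equal(s2$mean_h, 4)
  expect_equal(s2$sd_h, 2)  # n-1 denominator
  expect_equal(s2$cv, 0.5)
  expect_equal(sum(s2$histogram$counts), s2$n)

  expect_error(summarize_lengths(5), "insufficient")
  expect_error(summarize_lengths(c(1, -2)), "positive")
})

test_that("summaries are scale-equivariant and histograms always total n", {
  set.seed(42)
  for (i in 1:20) {
    v <- rgamma(sample(5:60, 1), shape = 3, rate = 0.5) + 0.5
    k <- runif(1, 0.2, 5)
    s <- summarize_lengths(v)
    sk <- summarize_lengths(k * v)
    expect_equal(sk$mean_h, k * s$mean_h)
    expect_equal(sk$sd_h, k * s$sd_h)
    expect_equal(sk$cv, s$cv)
    expect_equal(sum(s$histogram$counts), length(v))
  }
})

test_that("cutoff splits partition the sample", {
  sp <- split_by_cutoff(c(5, 5.5, 7, 9), cutoff_hours = 6)
  expect_equal(sp$below, c(5, 5.5))
  expect_equal(sp$above, c(7, 9))

  all_short <- split_by_cutoff(c(3, 4, 5), cutoff_hours = 6)
  expect_length(all_short$above, 0)
  expect_null(all_short$summary_above)

  # long-G1 subgroup of a simulated low-WNT population is the more variable one
  cfg <- sim_config(seed = 5)
  tr <- simulate_population(cfg, data.frame(label = "mtesr1",
                                            axin2_level = 3.6e-4,
                                            n_cells = 400L))
  rec <- derive_phase_lengths(tr)
  sp2 <- split_by_cutoff(rec, 6)
  expect_gt(sp2$summary_above$cv, sp2$summary_below$cv)
})

test_that("KS statistic matches the brute-force ECDF oracle and edge cases", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disjoint <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(disjoint$statistic, 1)

  set.seed(7)
  for (i in 1:200) {
    a <- sample(1:6, sample(2:8, 1), replace = TRUE) + (i %% 2) * runif(1)
    b <- sample(1:6, sample(2:8, 1), replace = TRUE)
    res <- ks_two_sample(a, b)
    expect_equal(res$statistic, brute_force_ks_d(a, b))
    # symmetry in the arguments
    rev <- ks_two_sample(b, a)
    expect_equal(rev$statistic, res$statistic)
    expect_equal(rev$p_value, res$p_value)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "insufficient")
})

test_that("KS p agrees with stats::ks.test on continuous data", {
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(20:80, 1))
    b <- rnorm(sample(20:80, 1), mean = runif(1, 0, 1))
    res <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(res$statistic, unname(ref$statistic))
    # the reference evaluates the Kolmogorov tail via a dual series; agreement
    # is to ~1e-5, far below any decision threshold
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("KS type-I error is near nominal on same-distribution samples", {
  set.seed(99)
  reject <- replicate(2000, {
    ks_two_sample(rnorm(500), rnorm(500))$p_value < 0.05
  })
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(reject) - 0.05), 3 * se)
})

test_that("Mann-Whitney U handles ties by midranks and is symmetric", {
  res <- mannwhitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)

  tied <- mannwhitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tied$statistic, 4.5)  # n1*n2/2 under complete ties

  set.seed(13)
  for (i in 1:50) {
    a <- sample(1:5, sample(2:6, 1), replace = TRUE)
    b <- sample(1:5, sample(2:6, 1), replace = TRUE)
    ab <- mannwhitney_u(a, b)
    ba <- mannwhitney_u(b, a)
    expect_equal(ab$statistic, brute_force_u(a, b))
    expect_equal(ba$statistic, length(a) * length(b) - ab$statistic)
    expect_equal(ab$p_value, ba$p_value)
  }
  expect_error(mannwhitney_u(numeric(0), 1), "insufficient")
})

test_that("exact Mann-Whitney p matches full enumeration and wilcox.test", {
  set.seed(21)
  for (i in 1:150) {
    a <- sample(1:6, sample(2:6, 1), replace = TRUE)
    b <- sample(1:6, sample(2:6, 1), replace = TRUE)
    res <- mannwhitney_u(a, b)
    expect_equal(res$p_value, enumeration_u_p(a, b), tolerance = 1e-12)
  }
  # cross-check against the reference exact distribution on tie-free samples
  for (i in 1:30) {
    a <- sample(1:1000, sample(3:8, 1))
    b <- sample(seq(1.5, 1000.5, by = 1), sample(3:8, 1))
    res <- mannwhitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal tail", {
  set.seed(3)
  a <- round(rnorm(80, 5, 1), 1)
  b <- round(rnorm(80, 5.6, 1), 1)
  res <- mannwhitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("p-value labels apply the reporting floor", {
  expect_identical(format_p(1e-20), "< 2.2e-16")
  expect_identical(format_p(0.03), format(0.03, digits = 4))
})

test_that("phase correlation recovers exact linear relations", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate_phases(x, -x)$r, -1)
  expect_equal(correlate_phases(x, x)$r, 1)
  expect_error(correlate_phases(x, rep(2, 4)), "zero variance")
  expect_error(correlate_phases(1:2, 2:1), "insufficient")
})

test_that("total-cycle conservation induces a negative G1 vs S/G2/M correlation", {
  cfg <- sim_config(seed = 19, movie_span_h = 120)  # long movie: no censoring
  tr <- simulate_population(cfg, data.frame(label = "mtesr1",
                                            axin2_level = 3.6e-4,
                                            n_cells = 1000L))
  rec <- derive_phase_lengths(tr)
  res <- correlate_phases(rec$g1_hours, rec$sg2m_hours)
  expect_lt(res$r, 0)
  expect_lt(res$p_value, 0.05)

  # at the published panel size (n = 30) the negative sign is detected in
  # nearly all replicates
  signs <- vapply(1:60, function(i) {
    cfg_i <- sim_config(seed = 1000 + i, movie_span_h = 120)
    tr_i <- simulate_population(cfg_i, data.frame(label = "sub",
                                                  axin2_level = 3.6e-4,
                                                  n_cells = 30L))
    rec_i <- derive_phase_lengths(tr_i)
    correlate_phases(rec_i$g1_hours, rec_i$sg2m_hours)$r < 0
  }, logical(1))
  expect_gt(mean(signs), 0.8)
})

test_that("Student t wrapper reproduces the pooled-variance test", {
  set.seed(4)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  res <- student_t_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})
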