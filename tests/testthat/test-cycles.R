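test_that("circular phase trajectory yields the analytic cycle count and period", {
  t <- seq(0, 2, by = 1 / 400)
  B1 <- cos(2 * pi * 5 * t + 0.1)
  B2 <- sin(2 * pi * 5 * t + 0.1)
  cyc <- segment_cycles(B1, B2, t)
  expect_true(nrow(cyc) %in% c(9, 10))
  expect_lt(max(abs(cyc$T - 0.2)), 1 / 400)
})

test_that("radial amplitude modulation does not move crossing times", {
  t <- seq(0, 2, by = 1 / 400)
  B1 <- cos(2 * pi * 5 * t + 0.1); B2 <- sin(2 * pi * 5 * t + 0.1)
  set.seed(2)
  r <- 1 + 0.4 * abs(sin(2 * pi * 0.7 * t)) + 0.1
  c1 <- segment_cycles(B1, B2, t)
  c2 <- segment_cycles(r * B1, r * B2, t)
  # sub-sample linear interpolation feels the local amplitude slope, so the
  # crossing times agree to O(dt^2), not exactly
  expect_lt(max(abs(c1$t0 - c2$t0)), 1e-5)
})

test_that("segmentation is invariant to uniform positive rescaling", {
  pod <- default_pod()
  c1 <- segment_cycles(pod$B[, 1], pod$B[, 2], pod$t_grid)
  c2 <- segment_cycles(3.7 * pod$B[, 1], 3.7 * pod$B[, 2], pod$t_grid)
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("fewer than two crossings is an error", {
  t <- seq(0, 1, by = 0.01)
  expect_error(segment_cycles(rep(1, 101), rep(-1, 101), t), "no complete cycle")
})

test_that("identical cycles give zero SEM and the cycle itself as mean", {
  t <- seq(0, 3, by = 1 / 200)
  x <- sin(2 * pi * 4 * t)
  cyc <- segment_cycles(cos(2 * pi * 4 * t), sin(2 * pi * 4 * t), t)
  mc <- phase_mean_cycle(t, x, cyc)
  expect_lt(max(mc$sem), 1e-6)
  expect_equal(mc$mean, sin(2 * pi * mc$tau + pi / 2 * 0), tolerance = 0.02)
})

test_that("SEM scales as sigma/sqrt(n) for noisy identical cycles", {
  set.seed(9)
  f <- 5; n_cyc <- 50
  t <- seq(0, n_cyc / f, by = 1 / 250)
  sigma <- 0.3
  x <- sin(2 * pi * f * t) + rnorm(length(t), sd = sigma)
  cyc <- segment_cycles(cos(2 * pi * f * t), sin(2 * pi * f * t), t)
  mc <- phase_mean_cycle(t, x, cyc)
  expect_equal(mean(mc$sem), sigma / sqrt(attr(mc, "n_cycles")),
               tolerance = 0.2)
})

test_that("duration-weighted cycle means reproduce the record average", {
  pod <- default_pod()
  pw <- integrate_powers(power_densities(default_mechanics()))
  cyc <- segment_cycles(pod$B[, 1], pod$B[, 2], pod$t_grid)
  cs <- cycle_energy_summary(pw, cyc)
  t0 <- cyc$t0[1]; t1 <- cyc$t0[nrow(cyc)] + cyc$T[nrow(cyc)]
  direct <- flagpower:::cycle_time_mean(pw$t, pw$P_hd, t0, t1)
  weighted <- sum(cs$P_hd * cs$T) / sum(cs$T)
  expect_equal(weighted, direct, tolerance = 1e-10)
})

test_that("pooled comparison flags separated means and not identical groups", {
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50, mean = 2)
  res <- pool_and_compare(a, b)
  expect_lt(res$p, 1e-4)
  expect_equal(res$tier, "****")
  same <- pool_and_compare(a, a)
  expect_gt(same$p, 0.99)
  # degenerate variance shortcut
  expect_equal(pool_and_compare(rep(1, 5), rep(1, 5))$p, 1)
  expect_equal(pool_and_compare(rep(1, 5), rep(2, 5))$tier, "****")
})

test_that("power simulation: N(0,1) vs N(2,1) at n = 50 is detected reliably", {
  set.seed(11)
  hits <- 0
  for (i in 1:100) {
    p <- pool_and_compare(rnorm(50), rnorm(50, 2))$p
    hits <- hits + (p < 1e-4)
  }
  expect_gte(hits, 99)
})

test_that("within-genotype ANOVA detects sample-level shifts", {
  set.seed(4)
  gA <- lapply(c(0, 1.5, 3), function(m) rnorm(60, m))
  gB <- lapply(c(0, 0, 0), function(m) rnorm(60, m))
  res <- pool_and_compare(gA, gB)
  expect_lt(res$anova_A, 1e-4)
  expect_gt(res$anova_B, 0.001)
})

test_that("box-plot statistics follow the linear quartile convention", {
  bs <- boxplot_stats(1:100)
  expect_equal(bs$median, 50.5)
  expect_equal(bs$q3 - bs$q1, 49.5)
  expect_equal(bs$notch_high - bs$median, 7.7715)
  expect_length(bs$outliers, 0)
  # constant data: zero-width box
  bc <- boxplot_stats(rep(4, 9))
  expect_equal(bc$q1, bc$q3)
  expect_length(bc$outliers, 0)
  # single point
  b1 <- boxplot_stats(5)
  expect_equal(b1$median, 5)
  expect_equal(b1$notch_high, 5)
  # outliers beyond 1.5 IQR
  bo <- boxplot_stats(c(1:20, 100))
  expect_equal(bo$outliers, 100)
  expect_equal(bo$whisker_high, 20)
})

test_that("KO-like amplitude scaling lowers every dissipation magnitude", {
  pod <- default_pod()
  model <- material_model(L = 120, sN = pod$sN, sT = pod$sT, s_e = 0.05)
  cyc <- segment_cycles(pod$B[, 1], pod$B[, 2], pod$t_grid)
  pw_wt <- integrate_powers(power_densities(flagellar_mechanics(pod, model)))
  cs_wt <- cycle_energy_summary(pw_wt, cyc)
  # "knockout": same motion pattern with amplitude scaled by 0.7
  pod_ko <- pod
  pod_ko$B <- 0.7 * pod$B
  pod_ko$mean_alpha <- pod$mean_alpha
  pw_ko <- integrate_powers(power_densities(flagellar_mechanics(pod_ko, model)))
  cyc_ko <- segment_cycles(pod_ko$B[, 1], pod_ko$B[, 2], pod$t_grid)
  cs_ko <- cycle_energy_summary(pw_ko, cyc_ko)
  for (cn in c("P_hd", "P_id", "P_md")) {
    res <- pool_and_compare(abs(cs_wt[[cn]]), abs(cs_ko[[cn]]))
    expect_lt(res$p, 0.05)
    expect_gt(res$mean_A, res$mean_B)
  }
})
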