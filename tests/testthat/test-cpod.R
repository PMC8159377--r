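# reconstruct the rescaled coefficients from the decomposition
cpod_alpha <- function(pod) {
  sweep(pod$B %*% t(pod$V), 2, pod$mean_alpha, `+`)
}

test_that("covariance trace equals the mean squared deviation norm", {
  sig <- make_pod_test_signal(3, c(4, 2, 1), P = 20, seed = 5)
  alpha <- attr(sig, "alpha")
  cv <- build_covariance(alpha)
  d <- sweep(alpha, 2, cv$mean_alpha)
  expect_equal(sum(diag(cv$A)), mean(rowSums(d^2)), tolerance = 1e-10)
})

test_that("planted two-mode signal is recovered exactly (whitened draws)", {
  sig <- make_pod_test_signal(2, c(4, 1), P = 20, seed = 2)
  pod <- cpod(attr(sig, "alpha"), M = 2)
  expect_equal(pod$lambda[1:2], c(4, 1), tolerance = 1e-8)
  expect_lt(max(abs(pod$lambda[-(1:2)])), 1e-10)
  # subspace match: principal angles between planted and recovered modes
  V_true <- attr(sig, "modes")
  sv <- svd(t(V_true) %*% pod$V[, 1:2])$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
  expect_equal(capture_efficiency(pod, 2), 1, tolerance = 1e-10)
})

test_that("degenerate spectrum still recovers the planted subspace", {
  sig <- make_pod_test_signal(2, c(1, 1), P = 12, seed = 9)
  pod <- cpod(attr(sig, "alpha"), M = 2)
  sv <- svd(t(attr(sig, "modes")) %*% pod$V[, 1:2])$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
})

test_that("single planted mode captures everything with M = 1", {
  sig <- make_pod_test_signal(1, 2.5, P = 10, seed = 3)
  pod <- cpod(attr(sig, "alpha"), M = 1)
  expect_equal(capture_efficiency(pod, 1), 1, tolerance = 1e-12)
})

test_that("spectral identities hold on the synthetic waveform", {
  pod <- default_pod()
  fitted_alpha <- cpod_alpha(pod)
  # sum of eigenvalues equals total variance of the deviation field
  d <- sweep(fitted_alpha, 2, pod$mean_alpha)
  expect_equal(sum(pod$lambda), mean(rowSums(d^2)), tolerance = 1e-8)
  # shape coefficients are orthogonal in time with variances lambda
  G <- crossprod(pod$B) / nrow(pod$B)
  expect_lt(max(abs(G - diag(pod$lambda))), 1e-8)
  # capture efficiency is nondecreasing and reaches exactly 1 at P + 1
  expect_true(all(diff(pod$gamma_M) >= -1e-12))
  expect_equal(pod$gamma_M[pod$P + 1], 1, tolerance = 1e-12)
})

test_that("reconstruction error identity: <|psi - psi~|^2> = sum of tail eigenvalues", {
  pod <- default_pod()
  alpha <- cpod_alpha(pod)
  for (M in c(2, 4, 8)) {
    alpha_M <- sweep(pod$B[, 1:M, drop = FALSE] %*% t(pod$V[, 1:M, drop = FALSE]),
                     2, pod$mean_alpha, `+`)
    mse <- mean(rowSums((alpha - alpha_M)^2))
    expect_equal(mse, sum(pod$lambda[(M + 1):length(pod$lambda)]),
                 tolerance = 1e-8)
  }
})

test_that("full reconstruction M = P + 1 reproduces the fitted waveform", {
  pod <- default_pod()
  fit <- fit_waveform(default_field())
  s <- seq(pod$sN, pod$sT, length.out = 57)
  psi_full <- predict(pod, s = s, M = pod$P + 1)
  psi_fit <- cheb_eval(fit$a, s_to_xi(s, pod$sN, pod$sT))
  expect_lt(max(abs(psi_full - psi_fit)), 1e-10)
})

test_that("POD subspace beats random rotations of the leading subspace", {
  sig <- make_pod_test_signal(4, c(4, 2, 1, 0.5), P = 12, seed = 8)
  alpha <- attr(sig, "alpha")
  pod <- cpod(alpha, M = 2)
  d <- sweep(alpha, 2, pod$mean_alpha)
  err2 <- function(V2) mean(rowSums((d - d %*% V2 %*% t(V2))^2))
  e_pod <- err2(pod$V[, 1:2])
  set.seed(21)
  for (i in 1:100) {
    Q <- qr.Q(qr(matrix(rnorm(ncol(alpha) * 2), ncol(alpha))))
    expect_gte(err2(Q) + 1e-10, e_pod)
  }
})

test_that("smooth derivatives agree with dense finite differences", {
  pod <- default_pod()
  set.seed(4)
  s0 <- runif(20, pod$sN + 0.02, pod$sT - 0.02)
  h <- 1e-5
  d1 <- predict(pod, s = s0, d_s = 1)
  num <- (predict(pod, s = s0 + h) - predict(pod, s = s0 - h)) / (2 * h)
  expect_lt(max(abs(d1 - num)) / max(abs(d1)), 1e-6)
  d2 <- predict(pod, s = s0, d_s = 2)
  num2 <- (predict(pod, s = s0 + h) - 2 * predict(pod, s = s0) +
             predict(pod, s = s0 - h)) / h^2
  expect_lt(max(abs(d2 - num2)) / max(abs(d2)), 1e-4)
})

test_that("a pure T_2 basis has constant second xi-derivative 4", {
  P <- 6
  alpha <- matrix(0, 50, P + 1)
  alpha[, 3] <- sin(seq_len(50)) * sqrt(cheb_gamma(P)[3])
  pod <- cpod(alpha, M = 1, t_grid = seq(0, 0.49, by = 0.01))
  xi <- seq(-1, 1, 0.1)
  # reconstructed deviation is B1(t) T_2(xi); second derivative of T_2 is 4
  d2 <- predict(pod, xi = xi, d_s = 2, M = 1) *
    ((pod$sT - pod$sN) / 2)^2 # back to xi units
  ratio <- d2 / predict(pod, xi = 0, M = 1)[, 1] # remove B1(t) scale,
  # T_2(0) = -1 so the ratio is 4 / T_2(0) = -4
  expect_lt(max(abs(ratio + 4)), 1e-8)
})

test_that("angular velocity and curvature rate are compatible", {
  pod <- default_pod()
  set.seed(12)
  s0 <- sort(runif(20, pod$sN, pod$sT))
  # d(omega)/ds via s-derivative of the time rate, dC/dt via time rate of the
  # s-derivative; both evaluated from the same smooth representation
  dw_ds <- predict(pod, s = s0, d_s = 1, d_t = 1, physical = TRUE)
  # independent route: finite-difference in time of the curvature field
  Cfield <- predict(pod, s = s0, d_s = 1, physical = TRUE)
  dt <- diff(pod$t_grid[1:2])
  dC_dt_fd <- apply(Cfield, 2, function(col) {
    n <- length(col)
    c(NA, (col[3:n] - col[1:(n - 2)]) / (2 * dt), NA)
  })
  i <- 2:(nrow(Cfield) - 1)
  expect_lt(max(abs(dw_ds[i, ] - dC_dt_fd[i, ])), 1e-8)
})
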