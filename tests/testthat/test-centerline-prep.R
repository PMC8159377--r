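make_cl <- function(x, y) {
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  structure(data.frame(x_um = x, y_um = y, s_um = s),
            contour_length = max(s), class = c("centerline", "data.frame"))
}

test_that("canonical orientation recovers a known rotation", {
  s <- seq(0, 100, 1)
  base <- lapply(1:5, function(i) make_cl(s, 3 * sin(s / 15 + i / 5) - 0.05 * s))
  # hook-down head: curve downwards near the start
  o1 <- canonical_orient(base)
  expect_lt(abs(attr(o1, "rotation")) %% pi, 0.06)
  a <- 30 * pi / 180
  rot <- lapply(base, function(cl) {
    make_cl(cos(a) * cl$x_um - sin(a) * cl$y_um,
            sin(a) * cl$x_um + cos(a) * cl$y_um)
  })
  o2 <- canonical_orient(rot)
  # the time-averaged end-to-end vector is horizontal after orientation
  ee <- sapply(o2[1:5], function(cl) {
    n <- nrow(cl)
    c(cl$x_um[n] - cl$x_um[1], cl$y_um[n] - cl$y_um[1])
  })
  v <- rowMeans(ee)
  expect_lt(abs(atan2(v[2], v[1])), 1e-9)
  # recovered rotation undoes the applied 30 degrees (mod the hook reflection)
  expect_equal(abs(attr(o2, "rotation") - attr(o1, "rotation")) %% (2 * pi),
               a, tolerance = 1e-6)
})

test_that("orientation is idempotent and resolves the hook reflection", {
  s <- seq(0, 100, 1)
  hook_up <- lapply(1:3, function(i) make_cl(s, 0.002 * s^2))   # curves up
  hook_dn <- lapply(1:3, function(i) make_cl(s, -0.002 * s^2))  # curves down
  ou <- canonical_orient(hook_up)
  od <- canonical_orient(hook_dn)
  expect_true(attr(ou, "reflected"))
  expect_false(attr(od, "reflected"))
  # idempotence
  ou2 <- canonical_orient(ou)
  for (i in 1:3) {
    expect_equal(ou2[[i]]$x_um, ou[[i]]$x_um, tolerance = 1e-9)
    expect_equal(ou2[[i]]$y_um, ou[[i]]$y_um, tolerance = 1e-9)
  }
})

test_that("resampling places stations uniformly and fills missing frames", {
  cl <- make_cl(seq(0, 10, 0.5), rep(0, 21))
  pos <- resample_and_fill(list(cl, NULL, cl), L = 10,
                           t_grid = c(0, 0.01, 0.02), n_points = 11)
  expect_equal(pos$x[1, ], seq(0, 10, 1))
  # missing middle frame between identical neighbors is the same frame
  expect_equal(pos$x[2, ], pos$x[1, ])
  expect_equal(pos$provenance, c("observed", "interpolated", "observed"))
  # gap longer than max_gap aborts
  expect_error(resample_and_fill(list(cl, NULL, NULL, NULL, NULL, cl), L = 10,
                                 t_grid = seq(0, 0.05, 0.01), n_points = 11),
               "gap")
})

test_that("resampled chords on a quarter circle are uniform", {
  th <- seq(0, pi / 2, length.out = 400)
  R <- 50
  cl <- make_cl(R * cos(th), R * sin(th))
  pos <- resample_and_fill(list(cl, cl), L = attr(cl, "contour_length"),
                           t_grid = c(0, 0.01), n_points = 80)
  chords <- sqrt(diff(pos$x[1, ])^2 + diff(pos$y[1, ])^2)
  expect_lt(diff(range(chords)) / mean(chords), 1e-4)
})

test_that("tangent profile is exact for lines and circles", {
  # straight horizontal line -> psi = 0
  cl <- make_cl(seq(0, 100, 0.5), rep(0, 201))
  pos <- resample_and_fill(list(cl, cl), L = 100, t_grid = c(0, 0.01),
                           n_points = 150)
  fld <- tangent_profile(pos)
  expect_lt(max(abs(fld$psi)), 1e-9)
  # circular arc of radius R: d(psi)/ds (normalized) = L / R in the passband
  R <- 120
  th <- seq(0, 0.9, length.out = 500) # arc length = R * 0.9 = 108
  cl2 <- make_cl(R * sin(th), R * (1 - cos(th)))
  L <- attr(cl2, "contour_length")
  pos2 <- resample_and_fill(list(cl2, cl2), L = L, t_grid = c(0, 0.01),
                            n_points = 200)
  fld2 <- tangent_profile(pos2)
  ds <- diff(fld2$s_grid[1:2])
  slope <- diff(fld2$psi[1, ]) / ds
  interior <- 20:170
  expect_equal(mean(slope[interior]), L / R, tolerance = 0.01)
  expect_lt(stats::sd(slope[interior]) / (L / R), 0.01)
})

test_that("spatial filter attenuates injected high-frequency angle noise", {
  s <- seq(0, 100, length.out = 200)
  base <- 0.5 * sin(2 * pi * s / 100)
  noisy <- base + 0.2 * sin(2 * pi * 0.35 * seq_along(s)) # 0.35 cyc/sample
  sm <- flagpower:::lowpass_path(noisy, 0.2, 4)
  resid_hi <- sm - base
  # >= 20 dB attenuation of the out-of-band component
  expect_lt(rms(resid_hi[20:180]), 0.1 * 0.2 / sqrt(2))
})

test_that("re-integrating tangent angles reproduces the input positions", {
  fld <- default_field()
  ds <- diff(fld$s_grid[1:2]) * fld$L
  i <- 25
  x_re <- fld$x[i, 1] + c(0, cumsum((cos(fld$psi[i, -1]) +
                                       cos(fld$psi[i, -200])) / 2 * ds))
  err <- max(abs(x_re - fld$x[i, ]))
  expect_lt(err, 1e-3 * fld$L)
})
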