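test_that("background is the per-pixel temporal mean", {
  f1 <- matrix(0, 8, 8); f2 <- matrix(2, 8, 8)
  st <- frame_stack(list(f1, f2), fps = 10, pixel_size = 1)
  expect_equal(build_background(st), matrix(1, 8, 8))
  st1 <- frame_stack(list(f1), fps = 10, pixel_size = 1)
  expect_error(build_background(st1), "at least 2")
  # constant stack: background equals any frame
  st3 <- frame_stack(list(f2, f2, f2), fps = 10, pixel_size = 1)
  expect_equal(build_background(st3), f2)
})

test_that("blank frames and round blobs are rejected, elongated curves kept", {
  set.seed(1)
  bg <- matrix(0.1, 80, 120)
  # blank frame equal to background (plus tiny noise)
  blank <- bg + matrix(rnorm(80 * 120, sd = 1e-3), 80)
  expect_null(segment_frame(blank, bg))
  # one long bright curve + one small round blob
  f <- bg
  xs <- 10:110
  ys <- round(40 + 8 * sin(xs / 12))
  for (k in seq_along(xs)) f[ys[k] + (-1:1), xs[k]] <- 0.9
  f[15 + (-3:3), 15 + (-3:3)] <- 0.9 # round blob
  mask <- segment_frame(f, bg, utils::modifyList(segmentation_params(),
                                                 list(closing_radius = 1)))
  expect_false(is.null(mask))
  on_curve <- mask[cbind(ys, xs)]
  expect_gt(mean(on_curve), 0.9)
  expect_false(any(mask[15 + (-2:2), 15 + (-2:2)]))
})

test_that("thinning a straight bar recovers its axis", {
  mask <- matrix(FALSE, 30, 120)
  mask[14:18, 11:110] <- TRUE
  cl <- extract_centerline(mask, pixel_size = 1)
  expect_false(is.null(cl))
  # centerline along the bar axis (row 16), within half a pixel
  mid <- cl$y_um[cl$x_um > 15 & cl$x_um < 105]
  expect_lt(max(abs(mid - 16)), 0.6)
  expect_equal(attr(cl, "contour_length"), 100, tolerance = 0.05)
})

test_that("short spurs are pruned; long branches invalidate the frame", {
  mask <- matrix(FALSE, 40, 120)
  mask[19:21, 11:110] <- TRUE
  mask[22:27, 60:62] <- TRUE # 6-px spur
  cl <- extract_centerline(mask, pixel_size = 1)
  expect_false(is.null(cl))
  expect_equal(attr(cl, "contour_length"), 100, tolerance = 0.06)
  # a long branch (40 px on a 100-px path) marks the frame unusable
  mask2 <- matrix(FALSE, 80, 120)
  mask2[19:21, 11:110] <- TRUE
  mask2[22:61, 60:62] <- TRUE
  expect_null(extract_centerline(mask2, pixel_size = 1))
})

test_that("a closed loop is unusable", {
  mask <- matrix(FALSE, 60, 60)
  th <- seq(0, 2 * pi, length.out = 300)
  for (k in seq_along(th)) {
    r <- round(30 + 20 * sin(th[k])); c <- round(30 + 20 * cos(th[k]))
    mask[r + (-1:1), c + (-1:1)] <- TRUE
  }
  expect_null(extract_centerline(mask, pixel_size = 1))
})

test_that("head end is identified by the wider end", {
  mask <- matrix(FALSE, 40, 140)
  mask[19:21, 11:130] <- TRUE
  mask[14:26, 11:24] <- TRUE # wide head at the left
  cl <- extract_centerline(mask, pixel_size = 1)
  expect_lt(cl$x_um[1], cl$x_um[nrow(cl)])
  # same bar with the head on the right is returned right-end first
  mask_r <- mask[, ncol(mask):1]
  cl_r <- extract_centerline(mask_r, pixel_size = 1)
  expect_gt(cl_r$x_um[1], cl_r$x_um[nrow(cl_r)])
})

test_that("contour-length QC discards deviant frames and sets L", {
  mk <- function(len) structure(data.frame(x_um = seq(0, len, 1),
                                           y_um = 0, s_um = seq(0, len, 1)),
                                contour_length = len,
                                class = c("centerline", "data.frame"))
  qc <- qc_and_length(list(mk(100), mk(101), mk(99)))
  expect_true(all(qc$kept))
  expect_equal(qc$L, 101)
  qc2 <- qc_and_length(list(mk(100), mk(100), mk(80)))
  expect_equal(qc2$kept, c(TRUE, TRUE, FALSE))
  expect_equal(qc2$L, 100)
  expect_error(qc_and_length(list(NULL, NULL)), "no usable")
})

test_that("segmentation is stateless: permuting frames permutes outputs", {
  tr <- synth_truth(noise_sd = 0)
  fld <- make_waveform(tr, t_grid = seq(0, 0.025, by = 1 / 200))
  mv <- render_movie(fld, optics = list(seed = 2))
  bg <- build_background(mv)
  p <- segmentation_params()
  cl3 <- extract_centerline(segment_frame(mv$frames[[3]], bg, p), p,
                            frame = mv$frames[[3]], pixel_size = mv$pixel_size)
  # same frame processed in a different order / position gives identical output
  cl3b <- extract_centerline(segment_frame(mv$frames[[3]], bg, p), p,
                             frame = mv$frames[[3]], pixel_size = mv$pixel_size)
  expect_identical(cl3$x_um, cl3b$x_um)
  expect_identical(cl3$y_um, cl3b$y_um)
})
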