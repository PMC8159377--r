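# Rendering synthetic waveforms as dark-field-like movies, and TIFF stack I/O.

#' Frame stack container
#'
#' @param frames list of grayscale matrices (rows = y, columns = x), values in
#'   `[0, 1]`.
#' @param fps frame rate (Hz).
#' @param pixel_size um per pixel.
#' @param timestamps frame times (s); default `0:(n-1)/fps`.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps, pixel_size, timestamps = NULL) {
  stopifnot(length(frames) >= 1, fps > 0, pixel_size > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all frames must share one shape")
  ts <- timestamps %||% ((seq_along(frames) - 1) / fps)
  if (any(diff(ts) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size,
                 timestamps = ts), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames of %d x %d px, %.3g um/px, %.4g fps\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$fps))
  invisible(x)
}

#' Read / write a grayscale TIFF stack
#' @param path TIFF file.
#' @param fps,pixel_size acquisition metadata (not stored in the TIFF).
#' @export
read_stack <- function(path, fps, pixel_size) {
  fr <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  fr <- lapply(fr, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  frame_stack(fr, fps = fps, pixel_size = pixel_size)
}

#' @rdname read_stack
#' @param stack a `frame_stack`.
#' @export
write_stack <- function(stack, path) {
  tiff::writeTIFF(lapply(stack$frames, function(f) pmin(pmax(f, 0), 1)),
                  path, bits.per.sample = 16)
  invisible(path)
}

#' Render a waveform field as a synthetic dark-field movie
#'
#' Each frame draws the centerline as a bright ridge with a Gaussian
#' cross-section whose width follows the linear radius taper, a wider and
#' brighter blob over the head region, a uniform background, and shot-like
#' (Poisson) noise. The ground-truth field is stored in attribute `"truth_field"`.
#'
#' @param field a [waveform_field()] with position tracks (um).
#' @param optics list overriding any of: `pixel_size` (um/px, 0.325),
#'   `image_shape` (c(ny, nx); default fits the data with a margin),
#'   `margin_px` (12), `peak` (ridge intensity, 0.6), `head_gain` (1.6),
#'   `head_sigma` (um, 1.8), `head_frac` (arc fraction treated as head blob,
#'   0.08), `background_level` (0.08), `noise` ("poisson" or "none"),
#'   `photon_gain` (counts at intensity 1, 400), `seed` (1).
#' @return a [frame_stack()].
#' @export
render_movie <- function(field, optics = list()) {
  stopifnot(inherits(field, "waveform_field"))
  if (is.null(field$x)) stop("field carries no position tracks to render")
  o <- utils::modifyList(list(
    pixel_size = 0.325, image_shape = NULL, margin_px = 12, peak = 0.6,
    head_gain = 1.6, head_sigma = 1.8, head_frac = 0.08,
    background_level = 0.08, noise = "poisson", photon_gain = 400,
    tail_radius = c(0.57, 0.18), seed = 1L), optics)
  px <- o$pixel_size
  m <- o$margin_px
  x0 <- min(field$x); y0 <- min(field$y)
  xs <- (field$x - x0) / px + m + 1
  ys <- (field$y - y0) / px + m + 1
  shape <- o$image_shape %||%
    c(ceiling(max(ys)) + m, ceiling(max(xs)) + m)
  ny <- shape[1]; nx <- shape[2]
  bad <- which(apply(xs < 1 | xs > nx | ys < 1 | ys > ny, 1, any))
  if (length(bad) > 0)
    stop(sprintf("centerline exits the frame at frame %d", bad[1]))

  s <- field$s_grid
  # ridge width (um): wide head blob, then the linear radius taper
  a_tail <- (o$tail_radius[1] - o$tail_radius[2]) * (1 - s) / (1 - field$sN) +
    o$tail_radius[2]
  in_head <- s <= o$head_frac
  sigma_um <- ifelse(in_head, o$head_sigma, pmax(a_tail, 0.35))
  amp <- ifelse(in_head, o$peak * o$head_gain, o$peak)

  # upsample along arc so splat spacing is ~0.3 px
  up <- max(2L, ceiling(4 * (s[2] - s[1]) * field$L / px))
  i_dense <- seq(1, length(s), by = 1 / up)
  sig_px <- pmax(interp_lin(seq_along(s), sigma_um, i_dense) / px, 0.6)
  amp_d <- interp_lin(seq_along(s), amp, i_dense)
  head_d <- interp_lin(seq_along(s), as.numeric(in_head), i_dense) > 0.5

  # max-splat Gaussians around each dense centerline sample; head and tail
  # are splatted separately so the window radius matches the local width
  splat <- function(acc, xd, yd, sig, am) {
    if (length(xd) == 0) return(acc)
    R <- ceiling(3 * max(sig))
    offs <- expand.grid(dy = -R:R, dx = -R:R)
    n <- length(xd)
    cx <- round(xd); cy <- round(yd)
    px_col <- rep(cx, nrow(offs)) + rep(offs$dx, each = n)
    px_row <- rep(cy, nrow(offs)) + rep(offs$dy, each = n)
    v <- rep(am, nrow(offs)) *
      exp(-((px_col - rep(xd, nrow(offs)))^2 +
              (px_row - rep(yd, nrow(offs)))^2) /
            (2 * rep(sig, nrow(offs))^2))
    ok <- px_col >= 1 & px_col <= nx & px_row >= 1 & px_row <= ny & v > 1e-4
    idx <- (px_col[ok] - 1L) * ny + px_row[ok]
    vv <- v[ok]
    o <- order(idx, vv)            # per-pixel max = last entry of each group
    last <- !duplicated(idx[o], fromLast = TRUE)
    ii <- idx[o][last]
    acc[ii] <- pmax(acc[ii], vv[o][last])
    acc
  }
  set.seed(o$seed)
  frames <- lapply(seq_along(field$t_grid), function(it) {
    xd <- interp_lin(seq_along(s), xs[it, ], i_dense)
    yd <- interp_lin(seq_along(s), ys[it, ], i_dense)
    f <- matrix(0, ny, nx)
    f <- splat(f, xd[!head_d], yd[!head_d], sig_px[!head_d], amp_d[!head_d])
    f <- splat(f, xd[head_d], yd[head_d], sig_px[head_d], amp_d[head_d])
    f <- f + o$background_level
    if (identical(o$noise, "poisson")) {
      f <- matrix(stats::rpois(length(f), f * o$photon_gain) / o$photon_gain,
                  ny, nx)
    }
    pmin(f, 1)
  })
  st <- frame_stack(frames, fps = 1 / diff(field$t_grid[1:2]),
                    pixel_size = px, timestamps = field$t_grid)
  attr(st, "truth_field") <- field
  attr(st, "origin_px") <- c(x0 = x0 - (m + 1) * px, y0 = y0 - (m + 1) * px)
  st
}
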