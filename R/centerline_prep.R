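# From raw centerlines to the canonical uniformly sampled tangent-angle field.

#' Canonical orientation of a set of centerlines
#'
#' One global rotation (computed from the time-averaged end-to-end vector)
#' aligns the mean body axis with the x-axis, head on the left; one global
#' reflection about the x-axis is applied if the head hook is concave upwards
#' (positive mean signed curvature over the head region). The operation is
#' idempotent.
#'
#' @param centerlines list of `centerline` objects (`NULL` entries are kept).
#' @param head_frac arc fraction used for the hook-concavity test.
#' @return list of centerlines with attributes `rotation` (radians applied)
#'   and `reflected`.
#' @export
canonical_orient <- function(centerlines, head_frac = 0.1) {
  ok <- !vapply(centerlines, is.null, logical(1))
  if (!any(ok)) stop("no usable centerlines")
  ee <- vapply(centerlines[ok], function(cl) {
    n <- nrow(cl)
    c(cl$x_um[n] - cl$x_um[1], cl$y_um[n] - cl$y_um[1])
  }, numeric(2))
  v <- rowMeans(ee)
  if (sqrt(sum(v^2)) < 1e-9) stop("degenerate time-averaged end-to-end vector")
  ang <- atan2(v[2], v[1])
  rot <- function(cl, a, reflect = FALSE) {
    ca <- cos(a); sa <- sin(a)
    x <- ca * cl$x_um + sa * cl$y_um
    y <- -sa * cl$x_um + ca * cl$y_um
    if (reflect) y <- -y
    cl$x_um <- x; cl$y_um <- y
    cl
  }
  out <- lapply(centerlines, function(cl) if (is.null(cl)) cl else rot(cl, ang))
  # hook test: mean signed curvature over the head region
  curv <- vapply(out[ok], function(cl) {
    i <- which(cl$s_um <= head_frac * max(cl$s_um))
    if (length(i) < 5) return(NA_real_)
    psi <- atan2(fd_gradient(cl$y_um[i], 1), fd_gradient(cl$x_um[i], 1))
    mean(fd_gradient(unwrap_angle(psi), 1) / fd_gradient(cl$s_um[i], 1))
  }, numeric(1))
  reflected <- isTRUE(mean(curv, na.rm = TRUE) > 0)
  if (reflected)
    out <- lapply(out, function(cl) {
      if (!is.null(cl)) cl$y_um <- -cl$y_um
      cl
    })
  attr(out, "rotation") <- -ang
  attr(out, "reflected") <- reflected
  out
}

# Register all frames to a common arc datum through the tether point.
# The tether is the arc station whose lab position varies least over time;
# its true arc coordinate is frame-independent (rigid head), so any per-frame
# spread in the arc position of the closest approach to the static tether
# point is head-tip localization error, removed by shifting the arc origin.
register_arc_origin <- function(x, y, s_phys) {
  head_idx <- which(s_phys <= 0.3 * max(s_phys))
  v <- apply(x[, head_idx, drop = FALSE], 2, stats::var) +
    apply(y[, head_idx, drop = FALSE], 2, stats::var)
  i0 <- head_idx[which.min(v)]
  p <- c(stats::median(x[, i0]), stats::median(y[, i0]))
  a <- vapply(seq_len(nrow(x)), function(i) {
    d2 <- (x[i, head_idx] - p[1])^2 + (y[i, head_idx] - p[2])^2
    j <- which.min(d2)
    # quadratic sub-sample refinement of the closest approach
    if (j > 1 && j < length(head_idx)) {
      num <- d2[j - 1] - d2[j + 1]
      den <- 2 * (d2[j - 1] - 2 * d2[j] + d2[j + 1])
      frac <- if (abs(den) > 1e-12) num / den else 0
      s_phys[head_idx[j]] + frac * (s_phys[2] - s_phys[1])
    } else s_phys[head_idx[j]]
  }, numeric(1))
  shift <- a - stats::median(a)
  for (i in seq_len(nrow(x))) {
    if (abs(shift[i]) < 1e-9) next
    x[i, ] <- interp_lin(s_phys, x[i, ], s_phys + shift[i])
    y[i, ] <- interp_lin(s_phys, y[i, ], s_phys + shift[i])
  }
  list(x = x, y = y, shift = shift)
}

# unwrap a phase sequence (jumps > pi folded back)
unwrap_angle <- function(p) {
  d <- diff(p)
  p + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Resample centerlines onto a common uniform arc-length grid and fill gaps
#'
#' Each frame's x, y are linearly interpolated onto `n_points` stations spaced
#' uniformly in arc length from 0 to sT * L, where L is the body length and
#' sT (the imaged tail end) is the largest normalized arc length available in
#' every kept frame. Frames missing from the time grid are filled by linear
#' interpolation between their neighbors and flagged.
#'
#' @param centerlines oriented centerlines (NULL where unusable/discarded).
#' @param L body length (um) from [qc_and_length()].
#' @param t_grid frame times (s).
#' @param n_points number of arc stations (default 200).
#' @param max_gap maximum run of consecutive missing frames tolerated.
#' @param register_arc if TRUE (default), frames are registered to a common
#'   arc-length datum through the tether: the tether is a material point of
#'   the rigid head, so its arc position must be identical in every frame;
#'   per-frame head-tip localization jitter is removed by shifting each
#'   frame's arc origin so the closest approach to the (static) tether point
#'   sits at the same arc length.
#' @return list of class `position_field`: matrices `x`, `y` (time x station),
#'   `s_grid` (normalized), `t_grid`, `L`, `sT`, `provenance`.
#' @export
resample_and_fill <- function(centerlines, L, t_grid, n_points = 200,
                              max_gap = 3, register_arc = TRUE) {
  stopifnot(length(centerlines) == length(t_grid))
  ok <- !vapply(centerlines, is.null, logical(1))
  if (!any(ok)) stop("no usable centerlines")
  gaps <- rle(!ok)
  if (any(gaps$lengths[gaps$values] > max_gap))
    stop(sprintf("gap of more than %d consecutive missing frames", max_gap))
  if (!ok[1] || !ok[length(ok)]) {
    # trim record so it starts and ends on observed frames
    first <- which(ok)[1]; last <- max(which(ok))
    centerlines <- centerlines[first:last]
    t_grid <- t_grid[first:last]
    ok <- ok[first:last]
  }
  sT <- min(vapply(centerlines[ok], function(cl) max(cl$s_um), numeric(1))) / L
  s_grid <- seq(0, sT, length.out = n_points)
  s_phys <- s_grid * L
  nt <- length(t_grid)
  x <- matrix(NA_real_, nt, n_points)
  y <- matrix(NA_real_, nt, n_points)
  for (i in which(ok)) {
    cl <- centerlines[[i]]
    x[i, ] <- interp_lin(cl$s_um, cl$x_um, s_phys)
    y[i, ] <- interp_lin(cl$s_um, cl$y_um, s_phys)
  }
  for (j in seq_len(n_points)) {
    if (anyNA(x[, j])) {
      x[, j] <- stats::approx(t_grid[ok], x[ok, j], xout = t_grid)$y
      y[, j] <- stats::approx(t_grid[ok], y[ok, j], xout = t_grid)$y
    }
  }
  if (register_arc && nt >= 3) {
    reg <- register_arc_origin(x, y, s_phys)
    x <- reg$x; y <- reg$y
  }
  structure(list(x = x, y = y, s_grid = s_grid, t_grid = t_grid, L = L,
                 sT = sT, sN = 0.1,
                 provenance = ifelse(ok, "observed", "interpolated")),
            class = "position_field")
}

#' Tangent-angle field from resampled positions
#'
#' Tangent angles atan2(dy/ds, dx/ds) are computed by central differences
#' along the uniform arc grid, unwrapped along s from head to tail, made
#' temporally continuous at the neck, and smoothed along s by a zero-phase
#' Butterworth low-pass filter.
#'
#' @param pos a `position_field` from [resample_and_fill()].
#' @param order,cutoff Butterworth order and normalized cutoff
#'   (cycles/sample), defaults 4 and 0.2, applied forward-backward.
#' @return a [waveform_field()] with position tracks attached.
#' @export
tangent_profile <- function(pos, order = 4, cutoff = 0.2) {
  stopifnot(inherits(pos, "position_field"))
  ds <- diff(pos$s_grid[1:2])
  nt <- nrow(pos$x)
  psi <- matrix(0, nt, ncol(pos$x))
  for (i in seq_len(nt)) {
    dx <- fd_gradient(pos$x[i, ], ds)
    dy <- fd_gradient(pos$y[i, ], ds)
    psi[i, ] <- unwrap_angle(atan2(dy, dx))
  }
  # temporal continuity of the branch choice, anchored at the neck station
  i_neck <- which.min(abs(pos$s_grid - pos$sN))
  for (i in 2:nt) {
    k <- round((psi[i, i_neck] - psi[i - 1, i_neck]) / (2 * pi))
    if (k != 0) psi[i, ] <- psi[i, ] - 2 * pi * k
  }
  for (i in seq_len(nt)) psi[i, ] <- lowpass_path(psi[i, ], cutoff, order)
  waveform_field(psi, pos$s_grid, pos$t_grid, sN = pos$sN, sT = pos$sT,
                 L = pos$L, x = pos$x, y = pos$y,
                 provenance = pos$provenance)
}
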