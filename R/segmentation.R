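# Per-frame extraction of a single-pixel-wide, unbranched, smoothed centerline
# of the sperm body: background subtraction, contrast stretch, median and
# Gaussian filtering, Otsu binarization, component classification by size and
# eccentricity, morphological thinning, branch pruning, head-first ordering
# and low-pass smoothing.

#' Default segmentation parameters
#' @export
segmentation_params <- function() {
  list(median_sizes = c(1, 2),   # EBImage medianFilter radii (3 px, 5 px)
       gaussian_sigma = 1,
       stretch = c(0.01, 0.99),  # linear percentile contrast stretch
       min_contrast = 0.05,      # minimum 99th-percentile foreground excess
       eccentricity_min = 0.9,
       closing_radius = 3,       # bridge gaps left by the static tether zone
       area_min = 60,
       prune_max_frac = 0.25,    # branches longer than this x main path: fail
       min_path_px = 20,
       smooth_cutoff = 0.15)     # cycles/sample, zero-phase
}

#' Temporal-mean background image
#' @param stack a [frame_stack()] with at least 2 frames.
#' @return matrix of per-pixel temporal means.
#' @export
build_background <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(stack$frames) < 2) stop("need at least 2 frames")
  Reduce(`+`, stack$frames) / length(stack$frames)
}

# second-moment eccentricity of a pixel set
pixel_eccentricity <- function(rows, cols) {
  if (length(rows) < 3) return(0)
  S <- stats::cov(cbind(rows, cols))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(1 - ev[2] / ev[1], 0))
}

#' Segment the sperm body in one frame
#'
#' Background-subtracted, contrast-stretched, median- then Gaussian-filtered
#' image is thresholded by Otsu's method; connected components are classified
#' by area and fitted-ellipse eccentricity and the largest sufficiently
#' elongated component is returned.
#'
#' @param frame,background matrices of the same shape.
#' @param params list from [segmentation_params()].
#' @return logical mask matrix, or `NULL` if the frame is unusable.
#' @export
segment_frame <- function(frame, background, params = segmentation_params()) {
  stopifnot(all(dim(frame) == dim(background)))
  d <- pmax(frame - background, 0)
  q <- stats::quantile(d, params$stretch, names = FALSE)
  if (q[2] - q[1] <= params$min_contrast) return(unusable("blank frame"))
  d <- pmin(pmax((d - q[1]) / (q[2] - q[1]), 0), 1)
  for (r in params$median_sizes) d <- EBImage::medianFilter(d, r)
  d <- as.matrix(EBImage::gblur(d, sigma = params$gaussian_sigma))
  th <- EBImage::otsu(EBImage::Image(d), range = c(0, 1))
  bw <- EBImage::Image(d > th)
  # close small gaps (the near-tether pixels are static and vanish under
  # mean-background subtraction, splitting the body)
  if (params$closing_radius > 0)
    bw <- EBImage::closing(bw,
                           EBImage::makeBrush(2 * params$closing_radius + 1,
                                              "disc"))
  lab <- EBImage::bwlabel(bw)
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  if (nlab == 0) return(unusable("no foreground"))
  best <- 0L; best_area <- 0
  for (k in seq_len(nlab)) {
    idx <- which(lab == k)
    if (length(idx) < params$area_min) next
    rows <- (idx - 1) %% nrow(lab) + 1
    cols <- (idx - 1) %/% nrow(lab) + 1
    if (pixel_eccentricity(rows, cols) < params$eccentricity_min) next
    if (length(idx) > best_area) { best <- k; best_area <- length(idx) }
  }
  if (best == 0L) return(unusable("no elongated component"))
  matrix(lab == best, nrow(lab), ncol(lab))
}

unusable <- function(reason) {
  # frames are marked unusable by a NULL entry; the reason is logged upstream
  NULL
}

#' Zhang--Suen morphological thinning
#'
#' Iteratively deletes boundary pixels while preserving connectivity and
#' endpoints, yielding a single-pixel-wide 8-connected skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of the skeleton.
#' @export
thin_mask <- function(mask) {
  img <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  img[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  nr <- nrow(img); nc <- ncol(img)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  shift <- function(m, dr, dc) m[ri + dr, ci + dc]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P1 <- img[ri, ci]
      P2 <- shift(img, -1, 0); P3 <- shift(img, -1, 1)
      P4 <- shift(img, 0, 1);  P5 <- shift(img, 1, 1)
      P6 <- shift(img, 1, 0);  P7 <- shift(img, 1, -1)
      P8 <- shift(img, 0, -1); P9 <- shift(img, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        del <- P1 == 1 & B >= 2 & B <= 6 & A == 1 &
          P2 * P4 * P6 == 0 & P4 * P6 * P8 == 0
      } else {
        del <- P1 == 1 & B >= 2 & B <= 6 & A == 1 &
          P2 * P4 * P8 == 0 & P2 * P6 * P8 == 0
      }
      if (any(del)) {
        sub <- img[ri, ci]
        sub[del] <- 0L
        img[ri, ci] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[ri, ci] == 1L
}

# skeleton pixel graph: vertices are skeleton pixels, edges join 8-neighbors
# weighted by Euclidean distance; diagonal edges that shortcut an existing
# orthogonal 2-step are dropped to avoid spurious triangles.
skeleton_graph <- function(skel) {
  idx <- which(skel)
  nr <- nrow(skel)
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  key <- paste(rows, cols)
  id <- seq_along(idx)
  lookup <- stats::setNames(id, key)
  edges <- NULL; weights <- NULL
  nbrs <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  for (nb in nbrs) {
    k2 <- paste(rows + nb[1], cols + nb[2])
    j <- lookup[k2]
    ok <- !is.na(j)
    if (nb[3] > 1) {
      # drop the diagonal if either orthogonal intermediate pixel is present
      mid1 <- !is.na(lookup[paste(rows + nb[1], cols)])
      mid2 <- !is.na(lookup[paste(rows, cols + nb[2])])
      ok <- ok & !(mid1 | mid2)
    }
    if (any(ok)) {
      edges <- rbind(edges, cbind(id[ok], j[ok]))
      weights <- c(weights, rep(nb[3], sum(ok)))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = weights)
  if (igraph::vcount(g) < length(id))
    g <- igraph::add_vertices(g, length(id) - igraph::vcount(g))
  list(g = g, rows = rows, cols = cols)
}

#' Extract an ordered centerline from a segmented mask
#'
#' Thins the mask to a skeleton, verifies it is a simple path after pruning
#' short branches, orders the points head-first (the head end has the larger
#' mean mask width over the first 10% of path length; ties broken by the
#' brighter end), low-pass smooths x(i) and y(i), and accumulates arc length
#' in physical units.
#'
#' @param mask logical mask of a single connected component.
#' @param params list from [segmentation_params()].
#' @param frame optional intensity image for the brightness tie-break.
#' @param pixel_size um per pixel.
#' @param frame_index stored in the result for bookkeeping.
#' @return object of class `centerline` (data.frame with `x_um`, `y_um`,
#'   `s_um`), or `NULL` if the frame is unusable.
#' @export
extract_centerline <- function(mask, params = segmentation_params(),
                               frame = NULL, pixel_size = 1,
                               frame_index = NA_integer_) {
  skel <- thin_mask(mask)
  if (sum(skel) < 3) return(unusable("skeleton too small"))
  sg <- skeleton_graph(skel)
  g <- sg$g
  comp <- igraph::components(g)
  if (comp$no > 1) {
    main <- which.max(comp$csize)
    keep <- which(comp$membership == main)
    g <- igraph::induced_subgraph(g, keep)
    sg$rows <- sg$rows[keep]; sg$cols <- sg$cols[keep]
  }
  if (igraph::ecount(g) >= igraph::vcount(g))
    return(unusable("skeleton contains a loop"))
  deg <- igraph::degree(g)
  ends <- which(deg == 1)
  if (length(ends) < 2) return(unusable("skeleton has no endpoints"))
  D <- igraph::distances(g, v = ends, to = ends)
  best <- which(D == max(D), arr.ind = TRUE)[1, ]
  path <- igraph::shortest_paths(g, from = ends[best[1]],
                                 to = ends[best[2]])$vpath[[1]]
  path <- as.integer(path)
  main_len <- max(D)
  if (main_len < params$min_path_px) return(unusable("path too short"))
  # branch audit: anything off the main path
  off <- setdiff(seq_len(igraph::vcount(g)), path)
  if (length(off) > 0) {
    sub <- igraph::induced_subgraph(g, off)
    sizes <- igraph::components(sub)$csize
    if (any(sizes > params$prune_max_frac * main_len))
      return(unusable("branch longer than pruning threshold"))
  }
  xs <- sg$cols[path]; ys <- sg$rows[path]

  # head-first ordering by mean local mask width over the leading 10%
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask)))
  n10 <- max(3, round(0.1 * length(path)))
  w_start <- mean(dm[cbind(ys[seq_len(n10)], xs[seq_len(n10)])])
  iend <- seq(length(path) - n10 + 1, length(path))
  w_end <- mean(dm[cbind(ys[iend], xs[iend])])
  flip <- if (abs(w_start - w_end) > 1e-9) {
    w_end > w_start
  } else if (!is.null(frame)) {
    mean(frame[cbind(ys[iend], xs[iend])]) >
      mean(frame[cbind(ys[seq_len(n10)], xs[seq_len(n10)])])
  } else FALSE
  if (flip) { xs <- rev(xs); ys <- rev(ys) }

  # thinning erodes blunt ends: extend both endpoints along the local
  # direction until the path leaves the mask
  ext_head <- extend_end(xs[1], ys[1], xs[min(6, length(xs))],
                         ys[min(6, length(ys))], mask)
  n <- length(xs)
  ext_tail <- extend_end(xs[n], ys[n], xs[max(1, n - 5)], ys[max(1, n - 5)],
                         mask)
  xs <- c(rev(ext_head$x), xs, ext_tail$x)
  ys <- c(rev(ext_head$y), ys, ext_tail$y)

  xs <- lowpass_path(xs, params$smooth_cutoff)
  ys <- lowpass_path(ys, params$smooth_cutoff)
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  s <- c(0, cumsum(seg)) * pixel_size
  structure(data.frame(x_um = xs * pixel_size, y_um = ys * pixel_size,
                       s_um = s),
            contour_length = s[length(s)], frame_index = frame_index,
            class = c("centerline", "data.frame"))
}

# step from an endpoint away from its inward neighbor while staying inside
# the mask, in unit steps
extend_end <- function(x0, y0, x_in, y_in, mask) {
  d <- c(x0 - x_in, y0 - y_in)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) return(list(x = numeric(0), y = numeric(0)))
  d <- d / nd
  xs <- ys <- numeric(0)
  for (k in 1:30) {
    x <- x0 + k * d[1]; y <- y0 + k * d[2]
    r <- round(y); c <- round(x)
    if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask) || !mask[r, c])
      break
    xs <- c(xs, x); ys <- c(ys, y)
  }
  list(x = xs, y = ys)
}

# zero-phase Butterworth low-pass along the sample index, with reflection
# padding to suppress end transients
lowpass_path <- function(v, cutoff, order = 2) {
  n <- length(v)
  if (n < 12) return(v)
  p <- min(n - 1, 25)
  padded <- c(2 * v[1] - rev(v[2:(p + 1)]), v, 2 * v[n] - rev(v[(n - p):(n - 1)]))
  bf <- signal::butter(order, 2 * cutoff)
  out <- signal::filtfilt(bf, padded)
  out[(p + 1):(p + n)]
}

#' Segment every frame of a stack
#'
#' @param stack a [frame_stack()].
#' @param params list from [segmentation_params()].
#' @return list of `centerline` objects (or `NULL` for unusable frames).
#' @export
segment_stack <- function(stack, params = segmentation_params()) {
  bg <- build_background(stack)
  lapply(seq_along(stack$frames), function(i) {
    mask <- segment_frame(stack$frames[[i]], bg, params)
    if (is.null(mask)) return(mask)
    extract_centerline(mask, params, frame = stack$frames[[i]],
                       pixel_size = stack$pixel_size, frame_index = i)
  })
}

#' Quality control and body-length estimate
#'
#' Frames whose contour length deviates more than `tol` from the mean contour
#' length are discarded; the body length L is the maximum contour length over
#' the kept frames.
#'
#' @param centerlines list from [segment_stack()].
#' @param tol relative deviation threshold (default 0.1).
#' @return list with `kept` (logical per frame), `L` (um), `discarded_fraction`
#'   and `lengths`.
#' @export
qc_and_length <- function(centerlines, tol = 0.1) {
  lens <- vapply(centerlines, function(cl)
    if (is.null(cl)) NA_real_ else attr(cl, "contour_length"), numeric(1))
  usable <- !is.na(lens)
  if (!any(usable)) stop("no usable centerline in any frame")
  mu <- mean(lens[usable])
  kept <- usable & abs(lens - mu) <= tol * mu
  if (!any(kept)) stop("all frames discarded by the contour-length criterion")
  list(kept = kept, L = max(lens[kept]),
       discarded_fraction = 1 - sum(kept) / length(centerlines),
       lengths = lens)
}
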