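# Small numerical helpers shared across the pipeline. All grids are assumed
# uniform where stated; callers are responsible for checking.

#' First derivative on a uniform grid (second order)
#'
#' Central differences in the interior, second-order one-sided stencils at the
#' two ends. Used for time derivatives of shape coefficients and of the rigid
#' head angle.
#'
#' @param y numeric vector or matrix (differentiated along rows if a matrix).
#' @param h grid spacing.
#' @return object of the same shape as `y`.
#' @keywords internal
fd_gradient <- function(y, h) {
  if (is.matrix(y)) return(apply(y, 2, fd_gradient, h = h))
  n <- length(y)
  if (n < 3) stop("need at least 3 samples for second-order differences")
  g <- numeric(n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
  g[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h)
  g[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * h)
  g
}

#' Fourth-order first derivative on a uniform grid
#'
#' Five-point central stencil in the interior; fourth-order one-sided stencils
#' at the four boundary points. Used for the arc-length derivative of the
#' stress-power flux terms, which are not polynomial in the Chebyshev basis.
#'
#' @keywords internal
fd_gradient4 <- function(y, h) {
  if (is.matrix(y)) return(t(apply(y, 1, fd_gradient4, h = h)))
  n <- length(y)
  if (n < 6) return(fd_gradient(y, h))
  g <- numeric(n)
  i <- 3:(n - 2)
  g[i] <- (-y[i + 2] + 8 * y[i + 1] - 8 * y[i - 1] + y[i - 2]) / (12 * h)
  one_sided <- c(-25, 48, -36, 16, -3) / 12
  g[1] <- sum(one_sided * y[1:5]) / h
  g[2] <- sum(c(-3, -10, 18, -6, 1) / 12 * y[1:5]) / h
  g[n] <- -sum(one_sided * y[n:(n - 4)]) / h
  g[n - 1] <- -sum(c(-3, -10, 18, -6, 1) / 12 * y[n:(n - 4)]) / h
  g
}

#' Check that a grid is uniform
#' @keywords internal
is_uniform_grid <- function(x, tol = 1e-8) {
  if (length(x) < 2) return(TRUE)
  d <- diff(x)
  max(abs(d - d[1])) <= tol * max(abs(d[1]), .Machine$double.eps)
}

#' Trapezoid weights for a uniform grid
#'
#' Returns weights w such that sum(w * f) equals the composite-trapezoid
#' integral of f. Needed so that min/max splits of an integrand keep the
#' identity integral(min) + integral(max) = integral exactly.
#' @keywords internal
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  if (n < 2) return(w)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

#' Linear interpolation wrapper with extrapolation by end values
#' @keywords internal
interp_lin <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

#' Cubic interpolation (natural spline through the samples)
#' @keywords internal
interp_cubic <- function(x, y, xout) {
  stats::spline(x, y, xout = xout, method = "natural")$y
}

# Conversion from internal power units (Pa um^3/s) to femtowatts.
# 1 Pa um^3 = 1e-18 J, so 1 Pa um^3/s = 1e-18 W = 1e-3 fW.
PA_UM3_S_TO_FW <- 1e-3
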