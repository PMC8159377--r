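# Proper orthogonal decomposition in Chebyshev coefficient space (C-POD).
# Because the normalized polynomials tau_k = T_k/sqrt(gamma_k) are orthonormal
# under the Chebyshev weight, the continuous two-point correlation eigenproblem
# reduces to the eigendecomposition of the (P+1) x (P+1) covariance of the
# rescaled coefficients alpha_k = sqrt(gamma_k) a_k. Shape modes are smooth
# polynomials, so curvature and higher derivatives are free of grid noise.

#' Covariance of the rescaled Chebyshev coefficients
#'
#' Time averages use the 1/N convention so that trace(A) equals the
#' time-averaged squared norm of the deviation field (Parseval).
#'
#' @param alpha matrix of rescaled coefficients, frames x (P+1).
#' @return list with `mean_alpha` and the symmetric covariance `A`.
#' @export
build_covariance <- function(alpha) {
  alpha <- as.matrix(alpha)
  if (nrow(alpha) < 2) stop("need at least 2 frames")
  if (nrow(alpha) < ncol(alpha) + 1)
    warning("fewer frames than coefficients + 1: covariance is rank-deficient")
  mean_alpha <- colMeans(alpha)
  d <- sweep(alpha, 2, mean_alpha)
  list(mean_alpha = mean_alpha, A = crossprod(d) / nrow(alpha))
}

#' C-POD of a fitted waveform
#'
#' Diagonalizes the coefficient covariance A = V Lambda V'. Columns of V hold
#' the rescaled Chebyshev coefficients of the shape modes (orthonormal under
#' the Chebyshev-weighted inner product); the shape coefficients are
#' B_m(t) = sum_k dAlpha_k(t) V_km. The sign of each mode is fixed so its
#' largest-magnitude coefficient is positive.
#'
#' @param object a `cheb_fit` from [fit_waveform()], or a matrix of rescaled
#'   coefficients alpha (frames x (P+1)).
#' @param M number of modes used by downstream evaluation (default 4).
#' @param t_grid time grid, required when `object` is a bare matrix.
#' @return object of class `cpod` with eigenvalues `lambda` (descending),
#'   mode matrix `V`, shape coefficients `B`, capture-efficiency curve
#'   `gamma_M`, and the head fit when available.
#' @export
cpod <- function(object, M = 4, t_grid = NULL) {
  if (inherits(object, "cheb_fit")) {
    alpha <- object$alpha
    meta <- object[c("P", "sN", "sT", "L", "t_grid")]
    head <- object$head
  } else {
    alpha <- as.matrix(object)
    meta <- list(P = ncol(alpha) - 1, sN = 0.1, sT = 0.85, L = NA_real_,
                 t_grid = t_grid %||% seq_len(nrow(alpha)))
    head <- NULL
  }
  if (M > meta$P + 1) stop("M must be at most P + 1")
  cv <- build_covariance(alpha)
  if (max(abs(cv$A - t(cv$A))) > 1e-10) stop("covariance is not symmetric")
  eg <- eigen(cv$A, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  V <- eg$vectors
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2, flip, `*`)
  d <- sweep(alpha, 2, cv$mean_alpha)
  B <- d %*% V
  structure(c(list(mean_alpha = cv$mean_alpha, A = cv$A, lambda = lambda,
                   V = V, B = B, M = M, head = head,
                   gamma_M = cumsum(lambda) / sum(lambda)),
              meta),
            class = "cpod")
}

#' Capture efficiency of an M-mode representation
#'
#' Gamma_M = sum_{m <= M} lambda_m / sum_m lambda_m, the fraction of
#' tangent-angle variance explained by the first M shape modes.
#'
#' @param lambda eigenvalue spectrum (descending, nonnegative) or a `cpod`
#'   object.
#' @param M number of modes.
#' @export
capture_efficiency <- function(lambda, M) {
  if (inherits(lambda, "cpod")) lambda <- lambda$lambda
  stopifnot(all(lambda >= -1e-12), !is.unsorted(rev(lambda)))
  tot <- sum(lambda)
  if (tot <= 0) stop("all-zero spectrum: capture efficiency undefined")
  sum(lambda[seq_len(M)]) / tot
}

# Chebyshev coefficients (a-space) of the mean profile and of each mode.
cpod_mode_coefs <- function(object) {
  g <- sqrt(cheb_gamma(object$P))
  list(mean_a = object$mean_alpha / g, Va = object$V / g)
}

#' Evaluate the C-POD waveform and its derivatives
#'
#' Reconstructs psi = psi0 + sum_{m<=M} B_m(t) psi_m and evaluates it, or its
#' xi-derivatives (via the Chebyshev derivative recurrence) and/or its time
#' derivative (via central-difference rates of the shape coefficients), at
#' arbitrary points of the tail domain.
#'
#' @param object a `cpod` fit.
#' @param s normalized arc-length points in `[sN, sT]` (ignored if `xi` given).
#' @param xi alternative evaluation points in `[-1, 1]`.
#' @param d_s order of the arc-length derivative (0--3).
#' @param d_t 0 or 1; `d_t = 1` returns the local rate
#'   (omega = dpsi/dt for `d_s = 0`, dC/dt for `d_s = 1`, ...).
#' @param M number of modes (defaults to the fit's M).
#' @param physical if TRUE, arc-length derivatives are per um (using L);
#'   otherwise per unit normalized arc length.
#' @param ... unused.
#' @return matrix frames x points.
#' @export
predict.cpod <- function(object, s = NULL, xi = NULL, d_s = 0, d_t = 0,
                         M = object$M, physical = FALSE, ...) {
  stopifnot(d_s %in% 0:3, d_t %in% 0:1, M <= object$P + 1)
  if (is.null(xi)) {
    if (is.null(s)) s <- seq(object$sN, object$sT, length.out = 200)
    xi <- s_to_xi(s, object$sN, object$sT)
  }
  if (any(xi < -1 - 1e-9 | xi > 1 + 1e-9)) stop("evaluation outside [-1, 1]")
  mc <- cpod_mode_coefs(object)
  co <- cbind(mc$mean_a, mc$Va[, seq_len(M), drop = FALSE]) # (P+1) x (M+1)
  if (d_s > 0) for (i in seq_len(d_s)) co <- apply(co, 2, cheb_deriv)
  vals <- t(cheb_eval(t(co), xi)) # points x (M+1)
  Bm <- object$B[, seq_len(M), drop = FALSE]
  if (d_t == 0) {
    W <- cbind(1, Bm)
  } else {
    dt <- diff(object$t_grid[1:2])
    W <- cbind(0, fd_gradient(Bm, dt))
  }
  out <- W %*% t(vals)
  scale <- (2 / (object$sT - object$sN))^d_s
  if (physical) scale <- scale / object$L^d_s
  out * scale
}

#' @export
coef.cpod <- function(object, ...) object$B

#' @export
print.cpod <- function(x, ...) {
  cat(sprintf("C-POD fit: P = %d, %d frames, M = %d modes\n",
              x$P, nrow(x$B), x$M))
  cat(sprintf("  capture efficiency Gamma_%d = %.4f\n", x$M, x$gamma_M[x$M]))
  invisible(x)
}

#' @export
summary.cpod <- function(object, ...) {
  n <- min(8, length(object$lambda))
  tab <- data.frame(mode = seq_len(n),
                    lambda = object$lambda[seq_len(n)],
                    gamma_M = object$gamma_M[seq_len(n)])
  structure(list(table = tab, M = object$M, P = object$P,
                 total_variance = sum(object$lambda)), class = "summary.cpod")
}

#' @export
print.summary.cpod <- function(x, ...) {
  cat(sprintf("C-POD eigenvalue spectrum (P = %d); total variance %.4g\n",
              x$P, x$total_variance))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot C-POD shape modes and the B1-B2 phase plane
#' @param x a `cpod` fit.
#' @param modes which shape modes to draw.
#' @param ... passed to `matplot`.
#' @export
plot.cpod <- function(x, modes = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  s <- seq(x$sN, x$sT, length.out = 200)
  mc <- cpod_mode_coefs(x)
  vals <- cheb_eval(t(mc$Va[, modes, drop = FALSE]), s_to_xi(s, x$sN, x$sT))
  graphics::matplot(s, t(vals), type = "l", lty = 1, xlab = "s / L",
                    ylab = "shape mode (rad)", ...)
  graphics::legend("topleft", legend = paste0("mode ", modes), lty = 1,
                   col = seq_along(modes), bty = "n")
  graphics::plot(x$B[, 1], x$B[, 2], type = "l", xlab = "B1", ylab = "B2")
  graphics::abline(h = 0, v = 0, col = "grey")
  invisible(x)
}
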