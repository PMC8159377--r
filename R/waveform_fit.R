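# Stage 1 of the data processing: the raw tangent angle psi_hat is replaced
# by an intermediate profile psi_tilde that is exactly a rigid-body rotation
# in the head region and a degree-20 Chebyshev series in the imaged tail,
# C2-continuous across the neck.

#' Fit rigid-body head kinematics
#'
#' The head region (s <= sN) of the raw tangent angle is replaced by
#' psi_tilde(s, t) = psi0(s) + B0(t), where psi0 is the time-averaged raw
#' profile and B0(t) = psi_hat(sN, t) - psi0(sN). This enforces
#' dC/dt = d(omega)/ds = 0 across the head exactly, as required for a rigid
#' body rotating about the tether. The neck angle and its first two
#' arc-length derivatives (from second-order backward differences of psi0 on
#' the uniform grid) provide the boundary data for the tail fit.
#'
#' @param field a [waveform_field()] of raw tangent angles.
#' @param sN normalized neck position; defaults to the field marker.
#' @return object of class `head_fit` with elements `psi0_head`, `B0`,
#'   `omega_head` (rad/s, central differences), `psi_n`, `psi_n1`, `psi_n2`
#'   (neck angle and s-derivatives, normalized-s units) and `neck_index`.
#' @export
fit_rigid_head <- function(field, sN = field$sN) {
  stopifnot(inherits(field, "waveform_field"))
  ih <- which(field$s_grid <= sN + 1e-9)
  if (length(ih) < 4)
    stop("head region missing from grid (need >= 4 stations at s <= sN)")
  if (length(field$t_grid) < 3) stop("need at least 3 frames")
  psi0 <- colMeans(field$psi[, ih, drop = FALSE])
  nn <- length(ih) # neck station: last head sample
  B0 <- field$psi[, ih[nn]] - psi0[nn]
  ds <- diff(field$s_grid[1:2])
  psi_n1 <- (3 * psi0[nn] - 4 * psi0[nn - 1] + psi0[nn - 2]) / (2 * ds)
  psi_n2 <- (2 * psi0[nn] - 5 * psi0[nn - 1] + 4 * psi0[nn - 2] -
               psi0[nn - 3]) / ds^2
  dt <- diff(field$t_grid[1:2])
  structure(list(psi0_head = psi0, B0 = B0,
                 omega_head = fd_gradient(B0, dt),
                 psi_n = psi0[nn] + B0, psi_n1 = psi_n1, psi_n2 = psi_n2,
                 neck_index = ih[nn], head_index = ih,
                 s_head = field$s_grid[ih], sN = field$s_grid[ih[nn]]),
            class = "head_fit")
}

# Constraint matrix (3 x (P+1)) and the Lagrange system pieces shared by all
# frames: rows are T_k(-1), T_k'(-1), T_k''(-1).
cheb_constraint_matrix <- function(P) {
  rbind(cheb_boundary(P, 0), cheb_boundary(P, 1), cheb_boundary(P, 2))
}

#' Constrained Chebyshev least-squares fit of one tail profile
#'
#' Minimizes the Chebyshev-weighted mean-square error between the sampled
#' tangent angle and a degree-P series, subject to prescribed value, first and
#' second xi-derivative at xi = -1 (C2-continuity with the rigid head). The
#' unconstrained coefficients come from the discrete Chebyshev transform at
#' the P+1 Gauss--Chebyshev nodes; the equality-constrained minimizer is then
#' obtained from the exact KKT system, which is diagonal in coefficient space:
#' a = a* + G^{-1} C' lambda with G = diag(gamma_k).
#'
#' @param y_nodes samples of the target at `cheb_nodes(P)` (vector, or matrix
#'   with one frame per row).
#' @param b length-3 constraint vector (value, d/dxi, d2/dxi2 at xi = -1), or
#'   a matrix with one row per frame.
#' @param P polynomial order (default 20).
#' @return coefficient vector (or matrix, frames x (P+1)).
#' @export
constrained_cheb_fit <- function(y_nodes, b, P = 20) {
  vec <- !is.matrix(y_nodes)
  if (vec) { y_nodes <- matrix(y_nodes, 1); b <- matrix(b, 1) }
  stopifnot(ncol(y_nodes) == P + 1, ncol(b) == 3, nrow(b) == nrow(y_nodes))
  a_star <- cheb_transform(y_nodes)
  Cm <- cheb_constraint_matrix(P)
  g <- cheb_gamma(P)
  # KKT: (C G^-1 C') mult = b - C a*; a = a* + G^-1 C' mult
  S <- Cm %*% (t(Cm) / g)
  rhs <- t(b) - Cm %*% t(a_star)
  mult <- solve(S, rhs)
  a <- a_star + t((t(Cm) / g) %*% mult)
  resid <- abs(a %*% t(Cm) - b)
  if (max(resid) > 1e-8)
    stop("constraint residual exceeds 1e-8 after KKT solve")
  if (vec) drop(a) else a
}

#' Fit the intermediate tangent-angle profile for all frames
#'
#' Runs the rigid-head fit, interpolates each frame's tail samples from the
#' uniform s grid onto the Gauss--Chebyshev nodes (cubic), assembles the neck
#' boundary values with the (sT - sN)/2 chain-rule factors and solves the
#' constrained fit frame by frame.
#'
#' @param field a [waveform_field()] of raw tangent angles.
#' @param P Chebyshev order (default 20).
#' @return object of class `cheb_fit`: coefficients `a` (frames x (P+1)),
#'   rescaled coefficients `alpha` = sqrt(gamma) a, the `head_fit`, grid
#'   markers and time grid.
#' @export
fit_waveform <- function(field, P = 20) {
  stopifnot(inherits(field, "waveform_field"))
  head <- fit_rigid_head(field)
  sN <- head$sN
  sT <- field$sT
  it <- which(field$s_grid >= sN - 1e-9 & field$s_grid <= sT + 1e-9)
  if (length(it) < P + 2) stop("too few tail stations for the requested order")
  s_tail <- field$s_grid[it]
  xi_nodes <- cheb_nodes(P)
  s_nodes <- xi_to_s(xi_nodes, sN, sT)
  y_nodes <- t(apply(field$psi[, it, drop = FALSE], 1, function(row)
    interp_cubic(s_tail, row, s_nodes)))
  half <- (sT - sN) / 2
  b <- cbind(head$psi_n, half * head$psi_n1, half^2 * head$psi_n2)
  a <- constrained_cheb_fit(y_nodes, b, P = P)
  structure(list(a = a, alpha = sweep(a, 2, sqrt(cheb_gamma(P)), `*`),
                 head = head, P = P, sN = sN, sT = sT, L = field$L,
                 t_grid = field$t_grid, s_grid = field$s_grid,
                 field = field),
            class = "cheb_fit")
}

#' @export
print.cheb_fit <- function(x, ...) {
  cat(sprintf("Constrained Chebyshev waveform fit: order P = %d, %d frames\n",
              x$P, nrow(x$a)))
  cat(sprintf("  tail domain s in [%.2f, %.2f], L = %.1f um\n",
              x$sN, x$sT, x$L))
  invisible(x)
}
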