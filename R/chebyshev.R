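# Chebyshev machinery for the tail-region waveform representation.
#
# The imaged tail s in [sN, sT] (normalized arc length) is mapped to
# xi in [-1, 1] by xi = 2 (s - sN)/(sT - sN) - 1. Tangent-angle profiles are
# degree-P Chebyshev series psi(xi) = sum_k a_k T_k(xi). Inner products use
# the Chebyshev weight w(xi) = 1/sqrt(1 - xi^2), under which
# (T_0, T_0) = pi and (T_k, T_k) = pi/2 for k > 0; these constants normalize
# the basis (tau_k = T_k / sqrt(gamma_k)) so that coefficient space is
# Euclidean and Parseval holds.

#' Map normalized arc length to the Chebyshev variable
#' @param s normalized arc length in `[sN, sT]`.
#' @param sN,sT neck and imaged-tail-end positions (normalized).
#' @return xi in `[-1, 1]`.
#' @export
s_to_xi <- function(s, sN, sT) 2 * (s - sN) / (sT - sN) - 1

#' @rdname s_to_xi
#' @param xi Chebyshev variable.
#' @export
xi_to_s <- function(xi, sN, sT) sN + (xi + 1) * (sT - sN) / 2

#' Continuous Chebyshev norms gamma_k = (T_k, T_k)
#' @param P polynomial order.
#' @return numeric vector of length P + 1: pi, pi/2, ..., pi/2.
#' @export
cheb_gamma <- function(P) c(pi, rep(pi / 2, P))

#' Gauss--Chebyshev nodes (roots of T_{P+1})
#' @param P polynomial order; returns P + 1 nodes in increasing order.
#' @export
cheb_nodes <- function(P) {
  rev(cos(pi * (seq_len(P + 1) - 0.5) / (P + 1)))
}

#' Evaluate the first P + 1 Chebyshev polynomials
#'
#' Three-term recurrence T_{k+1} = 2 xi T_k - T_{k-1}.
#'
#' @param xi evaluation points.
#' @param P maximum order.
#' @return matrix `length(xi) x (P + 1)` with column k + 1 holding T_k(xi).
#' @export
cheb_matrix <- function(xi, P) {
  n <- length(xi)
  T <- matrix(0, n, P + 1)
  T[, 1] <- 1
  if (P >= 1) T[, 2] <- xi
  if (P >= 2) for (k in 2:P) T[, k + 1] <- 2 * xi * T[, k] - T[, k - 1]
  T
}

#' Evaluate a Chebyshev series
#' @param a coefficient vector (a_0, ..., a_P) or matrix with one series per row.
#' @param xi evaluation points.
#' @return numeric vector (or matrix, series x points).
#' @export
cheb_eval <- function(a, xi) {
  if (is.matrix(a)) {
    Tm <- cheb_matrix(xi, ncol(a) - 1)
    return(a %*% t(Tm))
  }
  drop(cheb_matrix(xi, length(a) - 1) %*% a)
}

#' Discrete Chebyshev transform at the Gauss--Chebyshev nodes
#'
#' For samples y_i = f(xi_i) at the P + 1 nodes, returns coefficients
#' a_k = (2 - delta_k0)/(P + 1) * sum_i y_i T_k(xi_i). Exact for any
#' polynomial of degree <= P.
#'
#' @param y samples at `cheb_nodes(P)` (vector) or matrix time x (P + 1).
#' @export
cheb_transform <- function(y) {
  vec <- !is.matrix(y)
  if (vec) y <- matrix(y, 1)
  P <- ncol(y) - 1
  Tm <- cheb_matrix(cheb_nodes(P), P)
  a <- y %*% Tm
  a <- sweep(a, 2, c(1, rep(2, P)) / (P + 1), `*`)
  if (vec) drop(a) else a
}

#' Differentiate a Chebyshev series with respect to xi
#'
#' Standard backward recurrence for the derivative coefficients:
#' d_{k-1} = d_{k+1} + 2 k a_k, with the k = 0 entry halved.
#'
#' @param a coefficients (a_0, ..., a_P).
#' @return coefficients of the derivative, padded to the same length.
#' @export
cheb_deriv <- function(a) {
  P <- length(a) - 1
  d <- numeric(P + 1)
  if (P == 0) return(d)
  dd <- numeric(P + 2) # dd[k + 1] = d_k, two trailing zeros
  for (k in P:1) dd[k] <- dd[k + 2] + 2 * k * a[k + 1]
  dd[1] <- dd[1] / 2
  d[1:P] <- dd[1:P]
  d
}

#' Boundary values of T_k and derivatives at xi = -1
#'
#' Closed forms T_k(-1) = (-1)^k, T_k'(-1) = (-1)^{k+1} k^2,
#' T_k''(-1) = (-1)^k k^2 (k^2 - 1)/3, used to assemble the C2-continuity
#' constraints of the tail fit.
#'
#' @param P polynomial order.
#' @param order derivative order, 0, 1 or 2.
#' @return numeric vector of length P + 1.
#' @export
cheb_boundary <- function(P, order = 0) {
  k <- 0:P
  switch(as.character(order),
    "0" = (-1)^k,
    "1" = (-1)^(k + 1) * k^2,
    "2" = (-1)^k * k^2 * (k^2 - 1) / 3,
    stop("order must be 0, 1 or 2")
  )
}
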