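# Synthetic ground truth: a rigid hook-shaped head rocking about a fixed
# tether point and a flexible tail carrying a traveling tangent-angle wave.
# This is the minimal structure the downstream analysis assumes (rigid head,
# C2-smooth tail), so every stage can be tested against known truth.

#' Define a synthetic beating-sperm truth model
#'
#' The tangent angle is psi(s, t) = psi0(s) + theta(t) in the head region
#' (s <= sN) and, in the tail,
#' psi = psi0(s) + theta(t) h(s) + sum_m A_m(s) sin(2 pi m (s - sN)/lambda_w
#' - 2 pi f t + phi_m), where h(s) is a C2 blend that carries the rigid head
#' rotation smoothly into the proximal tail and the envelopes A_m(s) vanish
#' to second order at the neck so the field is C2 across s = sN.
#'
#' @param f beat frequency (Hz).
#' @param lambda_w wavelength of the traveling wave in units of body length.
#' @param mode_amp peak amplitude (radians) of each traveling wave harmonic.
#' @param psi0 mean tangent-angle profile, a function of normalized s.
#' @param envelope amplitude envelope on the tail, a function of
#'   u = (s - sN)/(1 - sN) in `[0, 1]`; must vanish to second order at u = 0.
#'   The default rises steeply over the proximal quarter (mouse sperm bend
#'   strongly just distal to the neck) and decays mildly toward the tip.
#' @param standing_ratio amplitude of the counter-propagating (reflected) wave
#'   relative to the outgoing one. The clamped head reflects bending waves, so
#'   tethered beats are partially standing; the B1-B2 phase loop becomes
#'   elliptic and power flows are modulated within each cycle.
#' @param theta_amp amplitude (radians) of the rigid head rocking.
#' @param sN,sT normalized neck / imaged-end positions.
#' @param s_e normalized tether position (inside the head).
#' @param L body length (um).
#' @param noise_sd white angular noise added to every sample (radians).
#' @param blend length (normalized s) over which the head rotation is blended
#'   into the tail.
#' @param seed integer seed from which all stochastic draws derive.
#' @return object of class `synth_truth`.
#' @export
synth_truth <- function(f = 7, lambda_w = 0.8, mode_amp = c(0.55, 0.48),
                        psi0 = function(s) 0.5 * sin(pi * s) - 0.2 * s,
                        envelope = function(u)
                          smoothstep5(u / 0.25) *
                            (1 - 0.6 * smoothstep5((u - 0.5) / 0.5)),
                        standing_ratio = 0.6,
                        theta_amp = 0.4, sN = 0.1, sT = 0.85, s_e = 0.05,
                        L = 120, noise_sd = 0, blend = 0.15, seed = 1L) {
  stopifnot(lambda_w > 0, f > 0, sN < sT, s_e <= sN, L > 0, noise_sd >= 0,
            standing_ratio >= 0, standing_ratio <= 1)
  structure(list(f = f, lambda_w = lambda_w, mode_amp = mode_amp, psi0 = psi0,
                 envelope = envelope, standing_ratio = standing_ratio,
                 theta_amp = theta_amp, sN = sN, sT = sT,
                 s_e = s_e, L = L, noise_sd = noise_sd, blend = blend,
                 seed = as.integer(seed)),
            class = "synth_truth")
}

# Quintic smoothstep: 0 at u<=0, 1 at u>=1, C2 at both ends.
smoothstep5 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

#' Evaluate the noise-free truth tangent angle
#' @param truth a [synth_truth()] object.
#' @param s normalized arc length (vector).
#' @param t time (vector); result is `length(t) x length(s)`.
#' @keywords internal
truth_psi <- function(truth, s, t) {
  phi <- truth_phases(truth)
  theta <- truth$theta_amp * sin(2 * pi * truth$f * t)
  psi0 <- truth$psi0(s)
  head_blend <- ifelse(s <= truth$sN, 1,
                       1 - smoothstep5((s - truth$sN) / truth$blend))
  u <- pmax((s - truth$sN) / (1 - truth$sN), 0)
  env <- ifelse(s <= truth$sN, 0, truth$envelope(u))
  psi <- outer(theta, head_blend) +
    matrix(psi0, length(t), length(s), byrow = TRUE)
  rho <- truth$standing_ratio %||% 0
  for (m in seq_along(truth$mode_amp)) {
    ks <- 2 * pi * m * (s - truth$sN) / truth$lambda_w
    wt <- 2 * pi * truth$f * t
    arg_out <- outer(-wt, ks, `+`) + phi[m]
    amp <- truth$mode_amp[m] * env
    wave <- sin(arg_out)
    if (rho > 0) wave <- wave + rho * sin(outer(wt, ks, `+`) + phi[m])
    wave <- wave * matrix(amp, length(t), length(s), byrow = TRUE)
    wave[, s <= truth$sN] <- 0
    psi <- psi + wave
  }
  psi
}

truth_phases <- function(truth) {
  set.seed(truth$seed + 1000L)
  stats::runif(length(truth$mode_amp), 0, 2 * pi)
}

#' Generate a synthetic tangent-angle waveform field
#'
#' @param truth a [synth_truth()] object.
#' @param s_grid uniform normalized arc-length grid in `[0, 1]`.
#' @param t_grid uniform time grid (s).
#' @return a [waveform_field()] carrying the truth object in attribute
#'   `"truth"`; centerline coordinates (um) are included, with the tether
#'   point held fixed at the origin.
#' @export
make_waveform <- function(truth, s_grid = seq(0, 0.85, length.out = 200),
                          t_grid = seq(0, 1.5, by = 1 / 200)) {
  stopifnot(inherits(truth, "synth_truth"))
  if (!is_uniform_grid(s_grid)) stop("s_grid must be uniform")
  if (!is_uniform_grid(t_grid)) stop("t_grid must be uniform")
  if (truth$lambda_w <= 0) stop("lambda_w must be positive")
  psi <- truth_psi(truth, s_grid, t_grid)
  if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    psi <- psi + matrix(stats::rnorm(length(psi), sd = truth$noise_sd),
                        nrow(psi), ncol(psi))
  }
  xy <- integrate_positions(psi, s_grid, truth$s_e, truth$L)
  fld <- waveform_field(psi, s_grid, t_grid, sN = truth$sN,
                        sT = min(truth$sT, max(s_grid)), L = truth$L,
                        x = xy$x, y = xy$y)
  attr(fld, "truth") <- truth
  fld
}

# Integrate (cos psi, sin psi) along s (physical um), anchoring the tether
# station s_e at the origin.
integrate_positions <- function(psi, s_grid, s_e, L) {
  ds <- diff(s_grid[1:2]) * L
  x <- t(apply(cos(psi), 1, pracma::cumtrapz, x = s_grid * L))
  y <- t(apply(sin(psi), 1, pracma::cumtrapz, x = s_grid * L))
  ie <- which.min(abs(s_grid - s_e))
  list(x = x - x[, ie], y = y - y[, ie])
}

#' Synthesize a waveform with a known POD structure
#'
#' Constructs psi(xi, t) = psi0 + sum_m B_m(t) psi_m(xi) where the shape modes
#' psi_m are a random rotation of the normalized Chebyshev basis (hence
#' exactly orthonormal under the Chebyshev weight) and the sampled shape
#' coefficients are whitened so their sample covariance is exactly
#' diag(eigenvalues). The C-POD of the returned signal is known analytically.
#'
#' @param n_modes number of planted modes.
#' @param eigenvalues positive, descending variances of the planted modes.
#' @param P Chebyshev order of the representation.
#' @param seed integer seed.
#' @param n_time number of time samples.
#' @param sN,sT domain markers.
#' @return a [waveform_field()]; attributes `alpha` (time x (P+1) rescaled
#'   coefficients), `modes` (columns = planted rescaled-coefficient vectors),
#'   `B` (planted coefficients) and `lambda` carry the ground truth.
#' @export
make_pod_test_signal <- function(n_modes, eigenvalues, P = 20, seed = 1L,
                                 n_time = 400, sN = 0.1, sT = 0.85) {
  if (n_modes > P + 1) stop("n_modes must be at most P + 1")
  stopifnot(length(eigenvalues) == n_modes, all(eigenvalues > 0),
            !is.unsorted(rev(eigenvalues)))
  set.seed(seed)
  V <- qr.Q(qr(matrix(stats::rnorm((P + 1)^2), P + 1)))[, seq_len(n_modes), drop = FALSE]
  B <- matrix(stats::rnorm(n_time * n_modes), n_time)
  B <- sweep(B, 2, colMeans(B))
  # whiten to exact sample covariance (time-average convention), then scale
  S <- crossprod(B) / n_time
  B <- B %*% solve(chol(S))
  B <- sweep(B, 2, sqrt(eigenvalues), `*`)
  mean_alpha <- stats::rnorm(P + 1, sd = 0.2)
  alpha <- matrix(mean_alpha, n_time, P + 1, byrow = TRUE) + B %*% t(V)
  a <- sweep(alpha, 2, sqrt(cheb_gamma(P)), `/`)
  s_grid <- seq(sN, sT, length.out = 200)
  psi <- cheb_eval(a, s_to_xi(s_grid, sN, sT))
  fld <- waveform_field(psi, s_grid, seq(0, by = 0.005, length.out = n_time),
                        sN = sN, sT = sT, L = 120)
  attr(fld, "alpha") <- alpha
  attr(fld, "modes") <- V
  attr(fld, "B") <- B
  attr(fld, "lambda") <- eigenvalues
  fld
}
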