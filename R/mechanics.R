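# Geometry -> kinematics -> forces. Internal unit system: Pa, um, s.
# Force/length is Pa um, force Pa um^2, torque Pa um^3, power density
# Pa um^2/s, integrated power Pa um^3/s (= 1e-3 fW).

#' Material and hydrodynamic parameters of the flagellum
#'
#' Defaults are the study conditions for mouse sperm in aqueous medium near a
#' wall: viscosity 1e-3 Pa s; neck/tip radii 0.57 / 0.18 um with a linear
#' taper; bending stiffness 7e4 Pa um^4 at the neck; internal (Kelvin--Voigt)
#' friction 1e3 Pa s um^4 at the neck; both stiffness and friction scale as
#' the fourth power of the local radius. The wall distance h equals the neck
#' radius, giving near-wall resistive-force-theory drag coefficients
#' zeta_t = 2 pi mu / ln(2h/a) and zeta_n = 4 pi mu / ln(2h/a) (so
#' zeta_n/zeta_t = 2 exactly).
#'
#' @param mu medium viscosity (Pa s).
#' @param kappa_N bending stiffness at the neck (Pa um^4).
#' @param eta_N internal friction coefficient at the neck (Pa s um^4, >= 0).
#' @param a_N,a_T cross-sectional radii at neck and tail tip (um).
#' @param h wall distance (um); defaults to `a_N`.
#' @param L body length (um).
#' @param sN,sT,s_e normalized neck, imaged-end and tether positions.
#' @return object of class `material_model`.
#' @export
material_model <- function(mu = 1e-3, kappa_N = 7e4, eta_N = 1e3,
                           a_N = 0.57, a_T = 0.18, h = a_N, L = 120,
                           sN = 0.1, sT = 0.85, s_e = 0.05) {
  stopifnot(mu > 0, kappa_N > 0, eta_N >= 0, a_N > 0, a_T > 0, a_T <= a_N,
            h > 0, L > 0)
  structure(list(mu = mu, kappa_N = kappa_N, eta_N = eta_N, a_N = a_N,
                 a_T = a_T, h = h, L = L, sN = sN, sT = sT, s_e = s_e),
            class = "material_model")
}

#' Taper, stiffness, friction and drag profiles along the tail
#'
#' Linear radius taper a(s) = (a_N - a_T)(L - s)/(L - s_N) + a_T (physical s);
#' kappa and eta scale as (a/a_N)^4; near-wall drag coefficients use the local
#' radius.
#'
#' @param model a [material_model()].
#' @param s normalized arc length (tail region).
#' @return list with vectors `a`, `kappa`, `eta`, `zeta_t`, `zeta_n`.
#' @export
material_profiles <- function(model, s) {
  a <- (model$a_N - model$a_T) * (1 - s) / (1 - model$sN) + model$a_T
  ratio <- 2 * model$h / a
  if (any(ratio <= 1)) stop("2h/a <= 1: unphysical wall distance or radius")
  lg <- log(ratio)
  list(a = a,
       kappa = model$kappa_N * (a / model$a_N)^4,
       eta = model$eta_N * (a / model$a_N)^4,
       zeta_t = 2 * pi * model$mu / lg,
       zeta_n = 4 * pi * model$mu / lg)
}

#' Estimate the tether location from centerline tracks
#'
#' The tether is taken as the head-region arc station whose lab-frame position
#' has the smallest temporal variance.
#'
#' @param field a [waveform_field()] with `x`, `y` tracks.
#' @return normalized arc length of the tether point.
#' @export
estimate_tether <- function(field) {
  if (is.null(field$x)) stop("field carries no position tracks")
  ih <- which(field$s_grid <= field$sN + 1e-9)
  v <- apply(field$x[, ih, drop = FALSE], 2, stats::var) +
    apply(field$y[, ih, drop = FALSE], 2, stats::var)
  field$s_grid[ih[which.min(v)]]
}

#' Kinematics and internal forces from a C-POD fit
#'
#' Evaluates the smooth waveform on the tail grid, reconstructs positions and
#' velocities by arc-length quadrature (the tether station has zero velocity),
#' applies resistive force theory for the hydrodynamic force density, and
#' integrates it from the imaged free end for the internal force resultant.
#' Bending moments follow the Kelvin--Voigt constitutive law
#' M = kappa(s) C + eta(s) d(omega)/ds.
#'
#' @param pod a `cpod` fit (must carry a head fit, i.e. come from
#'   [fit_waveform()]).
#' @param model a [material_model()].
#' @param n_s number of tail arc stations.
#' @param s_e normalized tether position; defaults to the model's.
#' @return object of class `mechanics_field` with all fields on the
#'   (time x tail-station) grid.
#' @export
flagellar_mechanics <- function(pod, model, n_s = 160, s_e = model$s_e) {
  stopifnot(inherits(pod, "cpod"), inherits(model, "material_model"))
  if (is.null(pod$head)) stop("cpod fit lacks a head fit; use fit_waveform()")
  if (s_e > pod$sN + 1e-9) warning("tether point lies outside the head region")
  L <- model$L
  s_tail <- seq(pod$sN, pod$sT, length.out = n_s)
  nt <- nrow(pod$B)

  psi <- predict(pod, s = s_tail)
  C <- predict(pod, s = s_tail, d_s = 1, physical = TRUE)
  dC_dt <- predict(pod, s = s_tail, d_s = 1, d_t = 1, physical = TRUE)
  omega <- predict(pod, s = s_tail, d_t = 1)
  domega_ds <- dC_dt # compatibility: shared representation

  # head-region profile for the velocity quadrature from the tether
  head <- pod$head
  s_head <- head$s_head[head$s_head >= s_e - 1e-9]
  s_head <- s_head[s_head < pod$sN]
  psi_head <- outer(head$B0, rep(1, length(s_head))) +
    matrix(interp_lin(head$s_head, head$psi0_head, s_head),
           nt, length(s_head), byrow = TRUE)
  omega_head <- matrix(head$omega_head, nt, length(s_head))

  s_comb <- c(s_head, s_tail)
  psi_c <- cbind(psi_head, psi)
  om_c <- cbind(omega_head, omega)
  sp <- s_comb * L
  ie <- which.min(abs(s_comb - s_e))
  cum_x <- t(apply(-om_c * sin(psi_c), 1, pracma::cumtrapz, x = sp))
  cum_y <- t(apply(om_c * cos(psi_c), 1, pracma::cumtrapz, x = sp))
  vx_c <- cum_x - cum_x[, ie]
  vy_c <- cum_y - cum_y[, ie]
  # positions anchored at the (fixed) tether station
  px <- t(apply(cos(psi_c), 1, pracma::cumtrapz, x = sp))
  py <- t(apply(sin(psi_c), 1, pracma::cumtrapz, x = sp))
  px <- px - px[, ie]
  py <- py - py[, ie]

  itail <- seq(length(s_head) + 1, length(s_comb))
  vx <- vx_c[, itail]; vy <- vy_c[, itail]
  x <- px[, itail]; y <- py[, itail]

  prof <- material_profiles(model, s_tail)
  hf <- rft_force(vx, vy, psi, prof)

  # F(s, t) = integral_s^{sT} f_h ds' (imaged end treated as free)
  Fx <- rev_cumint(hf$fx, s_tail * L)
  Fy <- rev_cumint(hf$fy, s_tail * L)
  M_el <- sweep(C, 2, prof$kappa, `*`)
  M_id <- sweep(domega_ds, 2, prof$eta, `*`)

  structure(list(s = s_tail, t_grid = pod$t_grid, L = L,
                 sN = pod$sN, sT = pod$sT, s_e = s_e,
                 psi = psi, C = C, dC_dt = dC_dt, omega = omega,
                 domega_ds = domega_ds,
                 x = x, y = y, vx = vx, vy = vy, vt = hf$vt, vn = hf$vn,
                 fhx = hf$fx, fhy = hf$fy, Fx = Fx, Fy = Fy,
                 M_el = M_el, M_id = M_id, M = M_el + M_id,
                 profiles = prof, model = model),
            class = "mechanics_field")
}

#' Resistive-force-theory force density
#'
#' f_h = -(zeta_t v_t t + zeta_n v_n n) with local drag coefficients; the
#' power density v . f_h is nonpositive by construction.
#'
#' @param vx,vy velocity components (um/s), time x station matrices.
#' @param psi tangent angle (rad), same shape.
#' @param prof profiles from [material_profiles()] at the same stations.
#' @return list with `fx`, `fy` (Pa um) and the projections `vt`, `vn`.
#' @export
rft_force <- function(vx, vy, psi, prof) {
  tx <- cos(psi); ty <- sin(psi)
  vt <- vx * tx + vy * ty
  vn <- -vx * ty + vy * tx
  ft <- -sweep(vt, 2, prof$zeta_t, `*`)
  fn <- -sweep(vn, 2, prof$zeta_n, `*`)
  list(fx = ft * tx - fn * ty, fy = ft * ty + fn * tx, vt = vt, vn = vn)
}

# Integral from s to the end of the grid, by trapezoid (rows = time).
rev_cumint <- function(f, s_phys) {
  cum <- t(apply(f, 1, pracma::cumtrapz, x = s_phys))
  cum[, length(s_phys)] - cum
}

#' @export
print.mechanics_field <- function(x, ...) {
  cat(sprintf("Mechanics field: %d frames x %d tail stations, s in [%.2f, %.2f]\n",
              nrow(x$psi), ncol(x$psi), x$sN, x$sT))
  invisible(x)
}
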