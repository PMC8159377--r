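# Energy balance of the soft internally driven Kirchhoff rod on the imaged
# tail: elastic storage rate, hydrodynamic and passive-internal dissipation,
# stress-power flux, and the motor power density obtained by closure.

#' Power densities on the tail grid
#'
#' eps_dot = kappa C dC/dt (elastic storage rate), p_id = -eta (domega/ds)^2
#' (passive internal dissipation), p_hd = v . f_h (hydrodynamic dissipation),
#' p_s = d(v . F)/ds + d(omega M)/ds (stress power, fourth-order finite
#' differences on the uniform grid), and the motor power density by energy
#' closure p_a = eps_dot - p_s - p_hd - p_id. Densities are in Pa um^2/s.
#'
#' @param mech a `mechanics_field` from [flagellar_mechanics()].
#' @return object of class `power_fields` holding the five density matrices
#'   (time x station), the grid, and the head power time series.
#' @export
power_densities <- function(mech) {
  stopifnot(inherits(mech, "mechanics_field"))
  prof <- mech$profiles
  eps_dot <- sweep(mech$C * mech$dC_dt, 2, prof$kappa, `*`)
  p_id <- -sweep(mech$domega_ds^2, 2, prof$eta, `*`)
  p_hd <- mech$vx * mech$fhx + mech$vy * mech$fhy
  h <- diff(mech$s[1:2]) * mech$L
  vF <- mech$vx * mech$Fx + mech$vy * mech$Fy
  omM <- mech$omega * mech$M
  p_s <- fd_gradient4(vF, h) + fd_gradient4(omM, h)
  p_a <- eps_dot - p_s - p_hd - p_id
  structure(list(s = mech$s, t_grid = mech$t_grid, L = mech$L,
                 sN = mech$sN, sT = mech$sT,
                 eps_dot = eps_dot, p_hd = p_hd, p_id = p_id, p_s = p_s,
                 p_a = p_a, P_Hd = head_power(mech), mech = mech),
            class = "power_fields")
}

#' Power dissipated by the head against hydrodynamic and tether forces
#'
#' P_Hd(t) = -(v_N . F_N + omega_N M_N) with neck values taken from the tail
#' side (F and M are continuous across the neck junction). Returned in
#' Pa um^3/s.
#'
#' @param mech a `mechanics_field`.
#' @export
head_power <- function(mech) {
  -(mech$vx[, 1] * mech$Fx[, 1] + mech$vy[, 1] * mech$Fy[, 1] +
      mech$omega[, 1] * mech$M[, 1])
}

#' Region-integrated instantaneous powers
#'
#' Arc integrals of the power densities over a region of the tail, reported in
#' femtowatts. The motor density is split pointwise before applying the same
#' trapezoid weights, so `P_md + P_mi` equals the integral of `p_a` exactly.
#'
#' @param pf a `power_fields` object.
#' @param region normalized arc-length interval, default the whole imaged tail.
#' @return data.frame with columns `t`, `E_dot`, `P_hd`, `P_id`, `P_s`, `P_a`,
#'   `P_md`, `P_mi`, `P_Hd` (fW).
#' @export
integrate_powers <- function(pf, region = c(pf$sN, pf$sT)) {
  stopifnot(inherits(pf, "power_fields"))
  idx <- region_index(pf$s, region[1], region[2])
  if (length(idx) < 2) stop("empty integration region")
  w <- trapz_weights(pf$s[idx] * pf$L)
  int <- function(m) as.vector(m[, idx, drop = FALSE] %*% w)
  pa <- pf$p_a[, idx, drop = FALSE]
  data.frame(t = pf$t_grid,
             E_dot = int(pf$eps_dot) * PA_UM3_S_TO_FW,
             P_hd = int(pf$p_hd) * PA_UM3_S_TO_FW,
             P_id = int(pf$p_id) * PA_UM3_S_TO_FW,
             P_s = int(pf$p_s) * PA_UM3_S_TO_FW,
             P_a = int(pf$p_a) * PA_UM3_S_TO_FW,
             P_md = as.vector(pmin(pa, 0) %*% w) * PA_UM3_S_TO_FW,
             P_mi = as.vector(pmax(pa, 0) %*% w) * PA_UM3_S_TO_FW,
             P_Hd = pf$P_Hd * PA_UM3_S_TO_FW)
}

# time-mean of x(t) over [t0, t1] by trapezoid with interpolated endpoints
cycle_time_mean <- function(t, x, t0, t1) {
  inside <- t > t0 & t < t1
  tt <- c(t0, t[inside], t1)
  xx <- c(interp_lin(t, x, t0), x[inside], interp_lin(t, x, t1))
  pracma::trapz(tt, xx) / (t1 - t0)
}

#' Per-cycle energy summary
#'
#' Cycle-means (time averages over each beat cycle) of the instantaneous
#' powers, plus the energy-balance estimate of the motor input,
#' Pmi_balance = -(P_Hd + P_hd + P_id + P_md) per cycle (the storage-rate
#' cycle-mean, reported in column `E_dot`, is neglected in that estimate but
#' not dropped from the table).
#'
#' @param powers data.frame from [integrate_powers()].
#' @param cycles data.frame from [segment_cycles()].
#' @return data.frame, one row per cycle, with a `"record_means"` attribute
#'   holding the average of the cycle-means (the record time average).
#' @export
cycle_energy_summary <- function(powers, cycles) {
  cols <- setdiff(names(powers), "t")
  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    t0 <- cycles$t0[i]; t1 <- t0 + cycles$T[i]
    ns <- sum(powers$t >= t0 & powers$t <= t1)
    if (ns < 3) {
      warning(sprintf("cycle %d shorter than 3 samples: skipped", i))
      return(NULL)
    }
    m <- vapply(cols, function(cn)
      cycle_time_mean(powers$t, powers[[cn]], t0, t1), numeric(1))
    data.frame(cycle = i, t0 = t0, T = cycles$T[i], t(m))
  })
  out <- do.call(rbind, rows)
  out$Pmi_balance <- -(out$P_Hd + out$P_hd + out$P_id + out$P_md)
  attr(out, "record_means") <- colMeans(out[, -(1:2)])
  out
}
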