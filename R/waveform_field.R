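# The canonical container passed between pipeline stages: the tangent angle
# psi(s, t) on a uniform normalized-arc-length x time grid, with the neck (sN)
# and imaged-tail-end (sT) markers and the physical body length L.

#' Construct a waveform field
#'
#' @param psi matrix of tangent angles (radians), time in rows, arc length in
#'   columns.
#' @param s_grid uniform normalized arc-length grid in `[0, 1]`.
#' @param t_grid uniform time grid (s).
#' @param sN normalized neck position (head/tail boundary), default 0.1.
#' @param sT normalized imaged tail end, default 0.85.
#' @param L body length (um).
#' @param x,y optional centerline coordinate matrices (um), same shape as `psi`.
#' @param provenance optional per-frame flags ("observed" or "interpolated").
#' @return object of class `waveform_field`.
#' @export
waveform_field <- function(psi, s_grid, t_grid, sN = 0.1, sT = 0.85, L,
                           x = NULL, y = NULL, provenance = NULL) {
  psi <- as.matrix(psi)
  stopifnot(nrow(psi) == length(t_grid), ncol(psi) == length(s_grid))
  if (!is_uniform_grid(s_grid)) stop("s_grid must be uniform")
  if (!is_uniform_grid(t_grid)) stop("t_grid must be uniform")
  if (any(s_grid < -1e-12 | s_grid > 1 + 1e-12)) stop("s_grid must lie in [0, 1]")
  if (!(sN < sT && sT <= 1 + 1e-12)) stop("need sN < sT <= 1")
  if (!all(is.finite(psi))) stop("psi must be finite everywhere")
  structure(
    list(psi = psi, s_grid = s_grid, t_grid = t_grid, sN = sN, sT = sT, L = L,
         x = x, y = y,
         provenance = provenance %||% rep("observed", length(t_grid))),
    class = "waveform_field"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.waveform_field <- function(x, ...) {
  cat("Waveform field: ", length(x$t_grid), " frames x ", length(x$s_grid),
      " arc stations\n", sep = "")
  cat(sprintf("  s in [%.3f, %.3f] (sN = %.2f, sT = %.2f), L = %.1f um\n",
              min(x$s_grid), max(x$s_grid), x$sN, x$sT, x$L))
  cat(sprintf("  t in [%.3f, %.3f] s (dt = %.4g s)\n",
              min(x$t_grid), max(x$t_grid), diff(x$t_grid[1:2])))
  invisible(x)
}

#' Indices of the head, tail and arbitrary regions of the s grid
#' @keywords internal
region_index <- function(s_grid, from, to) {
  which(s_grid >= from - 1e-9 & s_grid <= to + 1e-9)
}
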