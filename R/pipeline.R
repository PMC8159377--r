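# End-to-end orchestration: movie (or centerline table) in, energy budget out.

#' Default run configuration
#'
#' All physical constants are configuration, never hard-coded downstream:
#' viscosity, taper radii, stiffness and internal friction at the neck, the
#' region markers (neck 0.1, imaged end 0.85, mid-piece 0.1-0.3, principal
#' piece 0.3-0.85), the Chebyshev order P = 20 and mode count M = 4.
#'
#' @param ... overrides for any top-level field.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    schema = "flagpower/1",
    input = NULL,            # TIFF stack path, centerline CSV, or "synthetic"
    pixel_size = 0.325,      # um/px
    fps = 200,
    out_dir = NULL,
    seed = 1L,
    P = 20L, M = 4L,
    n_points = 200L,
    mu = 1e-3, kappa_N = 7e4, eta_N = 1e3,
    a_N = 0.57, a_T = 0.18,
    sN = 0.1, sT_max = 0.85,
    regions = list(tail = c(0.1, 0.85), midpiece = c(0.1, 0.3),
                   principal = c(0.3, 0.85)),
    tangent_filter = list(order = 4L, cutoff = 0.2),
    segmentation = segmentation_params(),
    synthetic = list(duration = 0.8, noise_sd = 0.01)
  )
  utils::modifyList(cfg, list(...))
}

#' Read / write a run configuration (YAML)
#' @param path YAML file.
#' @export
load_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  cfg$regions <- lapply(cfg$regions, as.numeric)
  cfg
}

#' @rdname load_config
#' @param config a configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write / read per-frame centerlines as CSV
#'
#' Long format: frame, point_index, x_um, y_um, s_um. Unusable frames are
#' simply absent.
#' @param centerlines list of `centerline` objects (NULLs allowed).
#' @param path CSV file.
#' @export
write_centerlines_csv <- function(centerlines, path) {
  rows <- lapply(seq_along(centerlines), function(i) {
    cl <- centerlines[[i]]
    if (is.null(cl)) return(NULL)
    data.frame(frame = i, point_index = seq_len(nrow(cl)),
               x_um = cl$x_um, y_um = cl$y_um, s_um = cl$s_um)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerlines_csv
#' @param n_frames total frame count (missing frames become NULL entries);
#'   defaults to the maximum frame index present.
#' @export
read_centerlines_csv <- function(path, n_frames = NULL) {
  d <- utils::read.csv(path)
  n <- n_frames %||% max(d$frame)
  out <- vector("list", n)
  for (i in unique(d$frame)) {
    sub <- d[d$frame == i, ]
    out[[i]] <- structure(
      data.frame(x_um = sub$x_um, y_um = sub$y_um, s_um = sub$s_um),
      contour_length = max(sub$s_um), frame_index = i,
      class = c("centerline", "data.frame"))
  }
  out
}

#' Run the full measurement chain
#'
#' Stages: segmentation (skipped for centerline input) -> QC and orientation ->
#' uniform resampling and tangent angles -> rigid-head + constrained Chebyshev
#' fit -> C-POD -> mechanics -> power densities and region integrals ->
#' beat-cycle segmentation and per-cycle energy summaries. When `out_dir` is
#' set, CSV/JSON artifacts and a provenance record are written.
#'
#' @param config list from [default_config()] or [load_config()]; `input` may
#'   be a TIFF path, a centerline CSV path, a [frame_stack()], a list of
#'   centerlines, or `"synthetic"` (renders the default synthetic movie).
#' @return object of class `flagpower_run`.
#' @export
run_pipeline <- function(config = default_config()) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  input <- config$input
  t_grid <- NULL
  if (identical(input, "synthetic")) {
    truth <- synth_truth(noise_sd = config$synthetic$noise_sd,
                         seed = config$seed)
    fld <- make_waveform(truth,
                         s_grid = seq(0, 0.9, length.out = config$n_points),
                         t_grid = seq(0, config$synthetic$duration,
                                      by = 1 / config$fps))
    input <- render_movie(fld, optics = list(pixel_size = config$pixel_size,
                                             seed = config$seed))
    note("stage simulate: rendered %d frames", length(input$frames))
  }
  if (is.character(input) && grepl("\\.tiff?$", input, ignore.case = TRUE))
    input <- read_stack(input, fps = config$fps, pixel_size = config$pixel_size)

  if (inherits(input, "frame_stack")) {
    t_grid <- input$timestamps
    centerlines <- segment_stack(input, config$segmentation)
    note("stage segment: %d/%d frames usable",
         sum(!vapply(centerlines, is.null, logical(1))), length(centerlines))
  } else if (is.character(input)) {
    centerlines <- read_centerlines_csv(input)
  } else if (is.list(input)) {
    centerlines <- input
  } else stop("unrecognized input")
  if (is.null(t_grid))
    t_grid <- (seq_along(centerlines) - 1) / config$fps

  qc <- qc_and_length(centerlines)
  centerlines[!qc$kept] <- list(NULL)
  note("stage qc: L = %.1f um, discarded %.1f%% of frames",
       qc$L, 100 * qc$discarded_fraction)
  centerlines <- canonical_orient(centerlines)
  pos <- resample_and_fill(centerlines, L = qc$L, t_grid = t_grid,
                           n_points = config$n_points)
  pos$sN <- config$sN
  pos$sT <- min(pos$sT, config$sT_max)
  field <- tangent_profile(pos, order = config$tangent_filter$order,
                           cutoff = config$tangent_filter$cutoff)
  field$sT <- min(field$sT, config$sT_max)
  note("stage prep: field %d frames x %d stations, sT = %.3f",
       length(field$t_grid), length(field$s_grid), field$sT)

  fit <- fit_waveform(field, P = config$P)
  pod <- cpod(fit, M = config$M)
  note("stage cpod: Gamma_%d = %.4f", config$M, pod$gamma_M[config$M])

  model <- material_model(mu = config$mu, kappa_N = config$kappa_N,
                          eta_N = config$eta_N, a_N = config$a_N,
                          a_T = config$a_T, L = qc$L, sN = config$sN,
                          sT = field$sT, s_e = estimate_tether(field))
  mech <- flagellar_mechanics(pod, model)
  pf <- power_densities(mech)
  powers <- integrate_powers(pf)
  cycles <- segment_cycles(pod$B[, 1], pod$B[, 2], pod$t_grid)
  note("stage cycles: %d complete cycles, median period %.3f s",
       nrow(cycles), stats::median(cycles$T))
  cyc_sum <- cycle_energy_summary(powers, cycles)
  region_powers <- lapply(config$regions, function(r)
    integrate_powers(pf, region = c(max(r[1], pf$sN), min(r[2], pf$sT))))
  region_summ <- lapply(region_powers, cycle_energy_summary, cycles = cycles)

  run <- structure(list(config = config, field = field, fit = fit, pod = pod,
                        model = model, mech = mech, power_fields = pf,
                        powers = powers, cycles = cycles,
                        cycle_summary = cyc_sum,
                        region_summary = region_summ, qc = qc, log = log),
                   class = "flagpower_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.flagpower_run <- function(x, ...) {
  cat("flagpower run\n")
  cat(sprintf("  %d frames, L = %.1f um, %d beat cycles\n",
              length(x$field$t_grid), x$model$L, nrow(x$cycles)))
  rm <- attr(x$cycle_summary, "record_means")
  cat(sprintf("  Gamma_%d = %.3f, mean period %.3f s (%.2f Hz)\n",
              x$pod$M, x$pod$gamma_M[x$pod$M], mean(x$cycles$T),
              1 / mean(x$cycles$T)))
  cat(sprintf("  record means (fW): P_hd = %.3g, P_id = %.3g, P_md = %.3g, P_mi = %.3g, P_Hd = %.3g\n",
              rm["P_hd"], rm["P_id"], rm["P_md"], rm["P_mi"], rm["P_Hd"]))
  invisible(x)
}

# write CSV/JSON artifacts and a provenance record
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(t = run$pod$t_grid, run$pod$B[, 1:run$pod$M]),
                   file.path(out_dir, "shape_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(mode = seq_along(run$pod$lambda),
                              lambda = run$pod$lambda,
                              gamma_M = run$pod$gamma_M),
                   file.path(out_dir, "eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(run$powers, file.path(out_dir, "powers.csv"),
                   row.names = FALSE)
  utils::write.csv(run$cycles, file.path(out_dir, "cycles.csv"),
                   row.names = FALSE)
  utils::write.csv(run$cycle_summary, file.path(out_dir, "cycle_summary.csv"),
                   row.names = FALSE)
  prov <- list(schema = run$config$schema, seed = run$config$seed,
               config = run$config[!vapply(run$config, is.object, logical(1))],
               r_version = as.character(getRversion()),
               n_frames = length(run$field$t_grid),
               n_cycles = nrow(run$cycles), log = run$log)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Export a kymograph of a power density
#'
#' @param run a `flagpower_run`.
#' @param quantity one of `"p_hd"`, `"eps_dot"`, `"p_id"`, `"p_a"`, `"p_s"`.
#' @param path output file; `.csv` writes the dense time x station matrix
#'   (fW/um), `.png` renders it with a diverging palette centered at zero.
#' @export
export_kymograph <- function(run, quantity = c("p_hd", "eps_dot", "p_id",
                                               "p_a", "p_s"), path) {
  quantity <- match.arg(quantity)
  m <- run$power_fields[[quantity]] * PA_UM3_S_TO_FW # fW/um
  if (grepl("\\.png$", path)) {
    grDevices::png(path, width = 900, height = 500)
    on.exit(grDevices::dev.off())
    lim <- max(abs(m))
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(255)
    graphics::image(run$power_fields$t_grid, run$power_fields$s,
                    m, zlim = c(-lim, lim), col = pal,
                    xlab = "t (s)", ylab = "s / L", main = quantity)
  } else {
    df <- as.data.frame(m)
    names(df) <- sprintf("s_%.4f", run$power_fields$s)
    df <- cbind(t = run$power_fields$t_grid, df)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
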