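#' Stable time step for the 2D staggered scheme
#'
#' CFL condition of the 2nd-order staggered grid in two dimensions:
#' `dt = cfl * dx / (c_max * sqrt(2))`.
#'
#' @param dx grid step, m.
#' @param c_max fastest longitudinal velocity on the grid, m/s.
#' @param cfl Courant number in (0, 1], default 0.95.
#' @return time step in s.
#' @export
stable_time_step <- function(dx, c_max, cfl = 0.95) {
  if (dx <= 0 || c_max <= 0) stop("dx and c_max must be positive")
  if (cfl <= 0 || cfl > 1) stop("cfl must be in (0, 1]")
  cfl * dx / (c_max * sqrt(2))
}

#' Source toneburst
#'
#' Hann-windowed sinusoid of the given center frequency and duration,
#' normalized to unit peak amplitude and exactly zero outside
#' `[0, duration]`.
#'
#' @param f0 center frequency, Hz (default 1 MHz).
#' @param duration emission duration, s (default 3 us).
#' @param dt sample interval, s; must give at least 10 samples per period.
#' @param n_total total series length in samples (padded with zeros); by
#'   default just covers the burst.
#' @return numeric vector of source amplitudes sampled at `k*dt`.
#' @export
make_source_waveform <- function(f0 = 1e6, duration = 3e-6, dt,
                                 n_total = NULL) {
  if (duration < 1 / f0) stop("duration must cover at least one period")
  if (dt > 1 / (10 * f0)) stop("dt too coarse: need >= 10 samples per period")
  nb <- floor(duration / dt) + 1L
  if (is.null(n_total)) n_total <- nb
  t <- (seq_len(n_total) - 1L) * dt
  w <- ifelse(t <= duration, sin(2 * pi * f0 * t) * sin(pi * t / duration)^2, 0)
  w / max(abs(w))
}

#' Construct a source specification
#'
#' @param aperture_mm aperture length on the top surface, mm (10), or
#'   `"full"` for a laterally uniform (plane-wave) source spanning the
#'   whole padded grid.
#' @param f0 center frequency, Hz.
#' @param duration emission duration, s.
#' @param amplitude peak injected stress amplitude (arbitrary units).
#' @return list of class `source_spec`.
#' @export
source_spec <- function(aperture_mm = 10, f0 = 1e6, duration = 3e-6,
                        amplitude = 1) {
  structure(list(aperture_mm = aperture_mm, f0 = f0, duration = duration,
                 amplitude = amplitude), class = "source_spec")
}

#' One receiver's pressure time series
#' @param label receiver label.
#' @param dt sample interval, s.
#' @param samples numeric pressure series.
#' @return list of class `waveform_record`.
#' @export
waveform_record <- function(label, dt, samples) {
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(label = label, dt = dt, samples = as.numeric(samples)),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %s: %d samples, dt=%.3g s, peak=%.3g\n",
              x$label, length(x$samples), x$dt, max(abs(x$samples))))
  invisible(x)
}

#' Run the elastodynamic FDTD simulation
#'
#' Propagates the source toneburst through the rasterized model and
#' records pressure (negative mean in-plane normal stress,
#' `-(sigma_xx+sigma_zz)/2`) at every receiver. The material grid is
#' padded on all four sides by `pml_cells` edge-replicated cells carrying
#' a split-field perfectly matched layer; with `boundary = "reflecting"`
#' no padding or damping is applied and the rigid outer edge reflects all
#' energy (used for conservation checks).
#'
#' @param grid a `model_grid` from [rasterize_model()].
#' @param source a `source_spec`.
#' @param duration recording duration, s (default 20 us).
#' @param cfl Courant number (default 0.95).
#' @param pml_cells PML thickness in cells (default 40).
#' @param boundary `"pml"` or `"reflecting"`.
#' @param record_energy also record total discrete energy
#'   (kinetic + strain) at every step.
#' @param source_row,source_cols,receivers overrides for point-source /
#'   custom-receiver experiments: 1-based unpadded row/col indices;
#'   `receivers` a data frame with columns `label`, `row`, `col`.
#' @param dt time step override, s (default from [stable_time_step()]).
#' @return `simulation_run`: list with `records` (list of
#'   `waveform_record`), `dt`, `dx`, `time`, `energy` (or NULL), `grid`,
#'   `source`, `params`.
#' @export
fdtd_run <- function(grid, source = source_spec(), duration = 20e-6,
                     cfl = 0.95, pml_cells = 40,
                     boundary = c("pml", "reflecting"),
                     record_energy = FALSE, source_row = 1L,
                     source_cols = NULL, receivers = NULL, dt = NULL) {
  boundary <- match.arg(boundary)
  mats <- grid$materials
  used <- sort(unique(as.vector(grid$mat)))
  c_max <- max(mats$c_l[used])
  dx_m <- grid$dx * 1e-3
  if (is.null(dt)) dt <- stable_time_step(dx_m, c_max, cfl)
  nsteps <- as.integer(round(duration / dt))

  # a laterally uniform ("full") source is a plane-wave run: the field is
  # x-invariant, so the side boundaries stay rigid with no lateral PML
  full_src <- is.null(source_cols) && identical(source$aperture_mm, "full")
  npml_z <- if (boundary == "pml") as.integer(pml_cells) else 0L
  npml_x <- if (full_src) 0L else npml_z
  nr <- nrow(grid$mat); nc <- ncol(grid$mat)
  ri <- c(rep(1L, npml_z), seq_len(nr), rep(nr, npml_z))
  ci <- c(rep(1L, npml_x), seq_len(nc), rep(nc, npml_x))
  matp <- grid$mat[ri, ci, drop = FALSE]

  if (is.null(receivers)) receivers <- grid$receivers[, c("label", "row", "col")]
  rec_rows <- as.integer(receivers$row) + npml_z - 1L
  rec_cols <- as.integer(receivers$col) + npml_x - 1L

  if (is.null(source_cols)) {
    if (full_src) {
      src_cols <- seq_len(ncol(matp)) - 1L
    } else {
      xc <- (seq_len(nc) - 0.5) * grid$dx
      src_cols <- which(abs(xc - grid$width / 2) <= source$aperture_mm / 2) +
        npml_x - 1L
    }
  } else src_cols <- as.integer(source_cols) + npml_x - 1L
  src_row <- as.integer(source_row) + npml_z - 1L

  wave <- make_source_waveform(source$f0, source$duration, dt) *
    source$amplitude
  d0 <- if (npml_z > 0) 3 * c_max * log(1e6) / (2 * npml_z * dx_m) else 0

  out <- fdtd_kernel(matp, mats$c11, mats$c12, mats$c33, mats$rho,
                     dx_m, dt, nsteps, wave, src_row, src_cols,
                     rec_rows, rec_cols, npml_z, npml_x, d0,
                     record_energy, 1e3)

  records <- lapply(seq_len(ncol(out$pressure)), function(k)
    waveform_record(receivers$label[k], dt, out$pressure[, k]))
  names(records) <- receivers$label
  structure(list(records = records, dt = dt, dx = grid$dx,
                 time = (seq_len(nsteps) - 1L) * dt,
                 energy = if (record_energy)
                   data.frame(time = (seq_len(nsteps) - 1L) * dt,
                              total = out$energy, kinetic = out$kinetic,
                              strain = out$strain) else NULL,
                 grid = grid, source = source,
                 params = list(cfl = cfl, pml_cells = npml_z,
                               boundary = boundary, duration = duration,
                               c_max = c_max, nsteps = nsteps)),
            class = "simulation_run")
}

#' @export
print.simulation_run <- function(x, ...) {
  cat(sprintf("<simulation_run> %d receivers, %d steps (dt=%.3g s), dx=%g mm, %s boundary\n",
              length(x$records), x$params$nsteps, x$dt, x$dx,
              x$params$boundary))
  invisible(x)
}

#' Write receiver traces as delimited text
#' @param run a `simulation_run`.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_traces <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(run$records, function(r) {
    p <- file.path(dir, paste0("trace_", r$label, ".tsv"))
    utils::write.table(
      data.frame(time_s = run$time, pressure = r$samples), p,
      sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}
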