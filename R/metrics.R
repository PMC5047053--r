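#' First-arriving-signal onset with parabolic sub-sample refinement
#'
#' Finds the first sample whose absolute amplitude exceeds
#' `threshold_fraction` of the record's own peak, fits a least-squares
#' parabola through the five absolute-amplitude points centered there,
#' and returns the parabola's threshold crossing. The refinement is
#' clamped to within one sample of the raw crossing.
#'
#' @param record a `waveform_record` (or numeric vector with `dt`).
#' @param threshold_fraction fraction of the record peak in (0, 1),
#'   default 0.05.
#' @param dt sample interval when `record` is a bare numeric vector.
#' @return onset time in s (time of sample k is `k*dt`, zero-based).
#' @export
detect_fas <- function(record, threshold_fraction = 0.05, dt = NULL) {
  if (inherits(record, "waveform_record")) {
    x <- record$samples; dt <- record$dt
  } else {
    x <- as.numeric(record)
    if (is.null(dt)) stop("dt required for a bare numeric record")
  }
  if (length(x) == 0) stop("empty record")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  a <- abs(x)
  peak <- max(a)
  thr <- threshold_fraction * peak
  if (peak == 0) stop("no arrival: record is identically zero")
  ic <- which(a >= thr)[1]           # first threshold crossing (1-based)
  if (is.na(ic)) stop("no arrival: record never exceeds threshold")
  # five points centered on the crossing, clipped at the record ends
  lo <- max(1L, ic - 2L); hi <- min(length(a), ic + 2L)
  k <- lo:hi
  t_c <- (ic - 1) * dt
  if (length(k) >= 3) {
    tt <- (k - ic)                    # sample offsets from the crossing
    fit <- stats::lm.fit(cbind(1, tt, tt^2), a[k])
    cf <- fit$coefficients
    if (is.finite(cf[3]) && abs(cf[3]) > .Machine$double.eps * peak) {
      disc <- cf[2]^2 - 4 * cf[3] * (cf[1] - thr)
      if (disc >= 0) {
        roots <- (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
        r <- roots[which.min(abs(roots))]
        if (is.finite(r)) t_c <- (ic - 1 + max(-1, min(1, r))) * dt
      }
    } else if (is.finite(cf[2]) && abs(cf[2]) > 0) {
      r <- (thr - cf[1]) / cf[2]
      t_c <- (ic - 1 + max(-1, min(1, r))) * dt
    }
  }
  max(0, t_c)
}

#' Sound pressure level relative to a reference record
#'
#' `20*log10(peak_k / peak_ref)` with peaks taken as maximum absolute
#' amplitude; the reference is receiver R1 in the standard pipeline.
#'
#' @param record_k,record_ref `waveform_record`s or numeric vectors.
#' @return level in dB (−Inf for an identically zero `record_k`).
#' @export
spl <- function(record_k, record_ref) {
  pk <- max(abs(if (inherits(record_k, "waveform_record"))
    record_k$samples else record_k))
  pr <- max(abs(if (inherits(record_ref, "waveform_record"))
    record_ref$samples else record_ref))
  if (pr == 0) stop("reference record has zero peak")
  if (pk == 0) return(-Inf)
  20 * log10(pk / pr)
}

#' Windowed RMS amplitude after the first arriving signal
#'
#' Root mean square of the record over `[fas, fas + window]`; `N` is the
#' number of samples inside the window. A window extending past the end
#' of the record is truncated with a warning.
#'
#' @param record a `waveform_record` or numeric vector.
#' @param fas window start (the detected onset), s.
#' @param window window length, s (default 10.9 us).
#' @param dt sample interval for bare vectors.
#' @return RMS amplitude in the record's units.
#' @export
rms_amplitude <- function(record, fas, window = 10.9e-6, dt = NULL) {
  if (inherits(record, "waveform_record")) {
    x <- record$samples; dt <- record$dt
  } else {
    x <- as.numeric(record)
    if (is.null(dt)) stop("dt required for a bare numeric record")
  }
  n <- length(x)
  i0 <- max(1L, as.integer(floor(fas / dt)) + 1L)
  i1 <- i0 + as.integer(round(window / dt)) - 1L   # half-open [fas, fas+window)
  if (i1 > n) {
    warning("RMS window truncated at the end of the record")
    i1 <- n
  }
  if (i0 > i1) stop("empty RMS window")
  sqrt(mean(x[i0:i1]^2))
}

#' Analytic vertical travel time through a layer stack
#'
#' Cumulative `sum(thickness_i / c_i)` of a vertical ray from the top
#' surface down to `depth`, an independent oracle for the simulated
#' first-arrival times.
#'
#' @param stack a `layer_stack`.
#' @param depth_mm target depth, mm.
#' @param velocities named numeric vector, m/s, one entry per tissue name
#'   appearing in the stack.
#' @return travel time in s.
#' @export
layered_travel_time <- function(stack, depth_mm, velocities) {
  if (depth_mm < 0 || depth_mm > stack_total(stack) + 1e-9)
    stop("depth outside the stack")
  bounds <- c(0, cumsum(stack$thickness_mm))
  tt <- 0
  for (k in seq_len(nrow(stack))) {
    seg <- min(depth_mm, bounds[k + 1]) - bounds[k]
    if (seg <= 0) break
    c_k <- velocities[[stack$tissue[k]]]
    if (is.null(c_k) || is.na(c_k)) stop("no velocity for ", stack$tissue[k])
    tt <- tt + seg * 1e-3 / c_k
  }
  tt
}

#' Per-receiver metrics table for a simulation run
#'
#' Computes TOF_FAS, SPL (dB re the R1 peak) and windowed RMS for every
#' receiver. R1's time-of-flight is reported but flagged non-comparable
#' (the reference receiver sits inside the source aperture), so the TOF
#' series is meaningful from R2 onward.
#'
#' @param run a `simulation_run`.
#' @param threshold_fraction onset threshold (default 0.05).
#' @param rms_window RMS window length, s (default 10.9 us).
#' @param reference label of the reference receiver (default `"R1"`).
#' @return data frame of class `receiver_metrics`: `receiver`,
#'   `depth_mm`, `tof_fas_s`, `spl_db`, `rms`, `tof_comparable`.
#' @export
analyze_run <- function(run, threshold_fraction = 0.05,
                        rms_window = 10.9e-6, reference = "R1") {
  recs <- run$records
  ref <- recs[[reference]]
  if (is.null(ref)) stop("reference receiver not found: ", reference)
  depth <- run$grid$receivers$depth_mm[match(names(recs),
                                             run$grid$receivers$label)]
  rows <- lapply(seq_along(recs), function(k) {
    r <- recs[[k]]
    fas <- tryCatch(detect_fas(r, threshold_fraction), error = function(e) NA_real_)
    data.frame(receiver = r$label,
               depth_mm = depth[k],
               tof_fas_s = fas,
               spl_db = spl(r, ref),
               rms = if (is.na(fas)) NA_real_ else
                 suppressWarnings(rms_amplitude(r, fas, rms_window)),
               tof_comparable = r$label != reference,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("receiver_metrics", "data.frame")
  attr(out, "threshold_fraction") <- threshold_fraction
  attr(out, "rms_window") <- rms_window
  out
}

#' Therapy dose specification
#'
#' @param intensity_sata spatial-average temporal-average intensity,
#'   mW/cm^2 (default 40, the physiotherapy-equipment setting).
#' @param prf pulse repetition frequency, Hz (default 100).
#' @param pulse_width pulse width, s (default 2 ms).
#' @param frequency carrier frequency, Hz (default 1 MHz).
#' @return list of class `dose_spec` with the derived `duty` cycle.
#' @export
dose_spec <- function(intensity_sata = 40, prf = 100, pulse_width = 2e-3,
                      frequency = 1e6) {
  duty <- prf * pulse_width
  if (duty <= 0 || duty > 1) stop("duty = prf * pulse_width must be in (0, 1]")
  structure(list(intensity_sata = intensity_sata, duty = duty, prf = prf,
                 pulse_width = pulse_width, frequency = frequency),
            class = "dose_spec")
}

#' Temporal-average intensity during the on-phase of a pulsed dose
#'
#' `SATA / duty`: a 40 mW/cm^2 SATA dose at 20 % duty cycle delivers
#' 200 mW/cm^2 while the pulse is on.
#'
#' @param dose a `dose_spec`.
#' @return on-phase intensity, mW/cm^2.
#' @export
sata_to_pulse_intensity <- function(dose) {
  if (dose$duty <= 0) stop("duty must be positive")
  dose$intensity_sata / dose$duty
}
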