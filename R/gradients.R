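#' Gradient hardware limit sets
#'
#' `whole_body_limits()` describes the whole-body gradient system: 40 mT/m
#' amplitude and a 200 T/m/s slew ceiling in conventional mode; quiet mode
#' runs the same amplitude ceiling at a reduced slew rate (default
#' 100 T/m/s) to lower the acoustic output.
#'
#' @param max_amplitude Maximum gradient amplitude, mT/m.
#' @param max_slew Maximum slew rate, T/m/s.
#' @param mode `"conventional"` or `"quiet"`; sets the default slew.
#' @return An object of class `gradient_limits`.
#' @export
whole_body_limits <- function(mode = c("conventional", "quiet"),
                              max_amplitude = 40,
                              max_slew = NULL) {
  mode <- match.arg(mode)
  if (is.null(max_slew)) max_slew <- if (mode == "quiet") 100 else 200
  if (max_amplitude <= 0 || max_slew <= 0)
    stop_invalid("gradient limits must be positive")
  structure(list(max_amplitude = max_amplitude, max_slew = max_slew,
                 mode = mode),
            class = "gradient_limits")
}

#' Silent (resonant 20 kHz) gradient coil specification
#'
#' The head-insert z-gradient oscillates sinusoidally at `frequency`; its
#' peak slew rate is `2 * pi * frequency * amplitude` and must stay within
#' the coil's 5,200 T/m/s ceiling. The default drive amplitude of 28.6 mT/m
#' (below the coil's 40 mT/m maximum) reflects amplifier duty-cycle limits
#' in a high-duty MPRAGE readout.
#'
#' @param frequency Oscillation frequency, kHz.
#' @param amplitude Drive amplitude, mT/m.
#' @param max_amplitude Coil amplitude ceiling, mT/m.
#' @param max_slew Coil slew ceiling, T/m/s.
#' @return An object of class `silent_gradient_spec`.
#' @examples
#' spec <- silent_gradient_spec()
#' silent_peak_slew(spec)  # about 3594 T/m/s
#' @export
silent_gradient_spec <- function(frequency = 20, amplitude = 28.6,
                                 max_amplitude = 40, max_slew = 5200) {
  check_scalar(frequency, "frequency"); check_scalar(amplitude, "amplitude")
  if (frequency <= 0) stop_invalid("frequency must be positive")
  if (amplitude < 0) stop_invalid("amplitude must be non-negative")
  spec <- structure(list(frequency = frequency, amplitude = amplitude,
                         max_amplitude = max_amplitude, max_slew = max_slew,
                         axis = "z"),
                    class = "silent_gradient_spec")
  if (amplitude > max_amplitude)
    stop_infeasible("silent gradient amplitude ", amplitude,
                    " mT/m exceeds the coil maximum of ", max_amplitude)
  if (silent_peak_slew(spec) > max_slew)
    stop_infeasible("silent gradient peak slew ",
                    round(silent_peak_slew(spec)),
                    " T/m/s exceeds the coil maximum of ", max_slew)
  spec
}

#' @rdname silent_gradient_spec
#' @details `silent_peak_slew()` returns the analytic peak slew
#'   `2 * pi * f * A` in T/m/s.
#' @param spec A `silent_gradient_spec`.
#' @export
silent_peak_slew <- function(spec) {
  2 * pi * (spec$frequency * 1e3) * (spec$amplitude * 1e-3)
}

#' Time-sampled gradient waveform
#'
#' @param samples Gradient amplitudes, mT/m.
#' @param raster Sample spacing, microseconds.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param max_amplitude,max_slew Optional limits checked on construction
#'   (mT/m and T/m/s).
#' @return An object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(samples, raster, axis = c("x", "y", "z"),
                              max_amplitude = NULL, max_slew = NULL) {
  axis <- match.arg(axis)
  check_scalar(raster, "raster")
  if (raster <= 0) stop_invalid("raster must be positive")
  if (!all(is.finite(samples))) stop_invalid("waveform samples must be finite")
  wf <- structure(list(samples = as.numeric(samples), raster = raster,
                       axis = axis),
                  class = "gradient_waveform")
  if (!is.null(max_amplitude) && max(abs(samples)) > max_amplitude + 1e-9)
    stop_infeasible("waveform exceeds amplitude limit of ", max_amplitude,
                    " mT/m")
  if (!is.null(max_slew) && length(samples) > 1L &&
      waveform_peak_slew(wf) > max_slew * (1 + 1e-9))
    stop_infeasible("waveform exceeds slew limit of ", max_slew, " T/m/s")
  wf
}

#' @rdname gradient_waveform
#' @details `waveform_peak_slew()` returns the peak finite-difference slew
#'   rate in T/m/s; `waveform_area()` the integral of the waveform in
#'   mT/m * ms; `waveform_duration()` the duration in ms.
#' @param wf A `gradient_waveform`.
#' @export
waveform_peak_slew <- function(wf) {
  if (length(wf$samples) < 2L) return(0)
  # (mT/m) per us == 1000 T/m/s
  max(abs(diff(wf$samples))) / wf$raster * 1000
}

#' @rdname gradient_waveform
#' @export
waveform_area <- function(wf) sum(wf$samples) * wf$raster * 1e-3

#' @rdname gradient_waveform
#' @export
waveform_duration <- function(wf) length(wf$samples) * wf$raster * 1e-3

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf(paste0("<gradient waveform, axis %s> %d samples @ %g us ",
                     "(%.3f ms), peak %.3g mT/m, peak slew %.4g T/m/s\n"),
              x$axis, length(x$samples), x$raster, waveform_duration(x),
              max(abs(x$samples)), waveform_peak_slew(x)))
  invisible(x)
}

#' Shortest slew- and amplitude-limited trapezoid of given area
#'
#' Designs the minimum-duration trapezoidal (or triangular) gradient lobe
#' whose time integral equals `area`, respecting the amplitude and slew
#' limits, sampled on the raster. The sampled lobe is rescaled so its
#' numerical integral matches `area` exactly.
#'
#' @param area Requested gradient-time area, mT/m * ms (equivalently the
#'   k-space increment divided by the reduced gyromagnetic ratio).
#' @param limits A [whole_body_limits()] object.
#' @param raster Raster time, microseconds.
#' @param axis Gradient axis.
#' @return A [gradient_waveform()].
#' @export
make_trapezoid <- function(area, limits = whole_body_limits(),
                           raster = 4, axis = "x") {
  check_scalar(area, "area")
  if (raster <= 0) stop_invalid("raster must be positive")
  if (area == 0)
    return(gradient_waveform(numeric(0), raster, axis))
  sgn <- sign(area)
  a <- abs(area)                       # mT/m * ms
  slew <- limits$max_slew              # T/m/s == mT/m per ms
  amp <- limits$max_amplitude          # mT/m
  g_tri <- sqrt(a * slew)              # peak of the triangular solution
  if (g_tri <= amp) {
    ramp_ms <- g_tri / slew
    flat_ms <- 0
    peak <- g_tri
  } else {
    ramp_ms <- amp / slew
    flat_ms <- (a - amp^2 / slew) / amp
    peak <- amp
  }
  dt <- raster * 1e-3                  # ms
  n_ramp <- max(1L, ceiling(ramp_ms / dt))
  n_flat <- ceiling(flat_ms / dt)
  up <- peak * seq_len(n_ramp) / n_ramp
  shape <- c(up, rep(peak, n_flat), rev(up)[-1L], 0)
  got <- sum(shape) * dt
  shape <- shape * (a / got)           # exact area; scaling is always <= 1
  if (max(shape) > amp * (1 + 1e-9) ||
      max(abs(diff(c(0, shape)))) / dt > slew * (1 + 1e-9))
    stop_infeasible("requested area not reachable within gradient limits")
  gradient_waveform(sgn * shape, raster, axis,
                    max_amplitude = amp, max_slew = slew)
}

#' Silent-gradient sinusoid waveform
#'
#' A pure sinusoid at the silent coil's frequency, starting from zero
#' amplitude, sampled on the raster for the requested duration. Feasibility
#' against the coil's amplitude and slew ceilings is checked on
#' construction.
#'
#' @param spec A [silent_gradient_spec()].
#' @param duration Duration, ms.
#' @param raster Raster time, microseconds; should divide the oscillation
#'   period (2.5 us does at 20 kHz).
#' @return A [gradient_waveform()] on the z axis.
#' @export
make_silent_gradient <- function(spec, duration, raster = 2.5) {
  stopifnot(inherits(spec, "silent_gradient_spec"))
  check_scalar(duration, "duration")
  if (duration <= 0) stop_invalid("duration must be positive")
  if (silent_peak_slew(spec) > spec$max_slew)
    stop_infeasible("silent gradient spec violates the coil slew ceiling")
  n <- round(duration * 1000 / raster)
  t_us <- (seq_len(n) - 1L) * raster
  g <- spec$amplitude * sin(2 * pi * spec$frequency * 1e-3 * t_us)
  gradient_waveform(g, raster, "z")
}

# Readout gradient amplitude (mT/m) that traverses n_x / fov_x (1/m) of
# k-space in flat_ms milliseconds.
readout_amplitude <- function(n_x, fov_x, flat_ms) {
  dk <- n_x / fov_x                       # 1/m
  dk / (GAMMA_BAR * flat_ms * 1e-3) * 1e3 # mT/m
}

#' Construct the per-TR quiet (or conventional) readout waveform set
#'
#' Builds one TR's readout: a slew-limited whole-body trapezoid on the x
#' (frequency-encode) axis whose flat top traverses the full kx extent of
#' the imaging grid, and — in quiet mode — a simultaneous silent sinusoid on
#' z spanning an integer number of oscillation periods (the flat top is
#' extended to the next whole period). A z "prewinder" offset of half the
#' silent excursion is accounted for in the returned kz modulation so the
#' oscillation is centred on each kz phase encode.
#'
#' @param n_x Readout matrix size.
#' @param fov_x Readout field of view, m.
#' @param limits [whole_body_limits()] for the whole-body axes.
#' @param spec [silent_gradient_spec()] or `NULL`/zero-amplitude for a
#'   conventional readout.
#' @param flat_ms Nominal flat-top (sampling) duration, ms. The default
#'   (`NULL`) uses 1.25 silent-gradient periods per kx sample when the
#'   silent gradient is active — a non-integer periods-per-sample ratio is
#'   essential, otherwise every kx sample strobes the oscillation at the
#'   same phase and the kz zig-zag collapses to a constant offset — and
#'   1 ms for a conventional readout.
#' @param raster Raster time, microseconds.
#' @return A list of class `readout_waveforms` with elements `gx`
#'   (trapezoid), `gz` (silent sinusoid or `NULL`), `flat_start`/`flat_end`
#'   (sample indices of the flat top), `kz_mod` (kz modulation in 1/m at
#'   each of the `n_x` readout sample times, centred on zero) and the
#'   construction parameters.
#' @export
make_quiet_readout <- function(n_x, fov_x, limits = whole_body_limits("quiet"),
                               spec = silent_gradient_spec(),
                               flat_ms = NULL, raster = 2.5) {
  if (n_x < 2L) stop_invalid("n_x must be >= 2")
  if (fov_x <= 0) stop_invalid("fov_x must be positive")
  silent_on <- !is.null(spec) && spec$amplitude > 0
  dt <- raster * 1e-3
  if (silent_on) {
    period_ms <- 1 / spec$frequency     # kHz -> ms
    if (is.null(flat_ms)) {
      # ~1.2 periods per kx sample; keep the count incommensurate with n_x
      # so successive kx samples strobe the oscillation at distinct phases
      # (an integer periods-per-sample ratio collapses the zig-zag)
      n_per <- round(1.2 * n_x)
      if (n_per %% n_x == 0L) n_per <- n_per + 1L
    } else {
      n_per <- max(1, round(flat_ms / period_ms))
    }
    flat_ms <- n_per * period_ms        # integer number of silent periods
    if (abs(period_ms / dt - round(period_ms / dt)) > 1e-9)
      stop_invalid("raster must divide the silent-gradient period; ",
                   "use 2.5 us at 20 kHz")
  } else if (is.null(flat_ms)) {
    flat_ms <- 1.0
  }
  n_flat <- round(flat_ms / dt)
  amp <- readout_amplitude(n_x, fov_x, flat_ms)
  if (amp > limits$max_amplitude)
    stop_infeasible("readout amplitude ", signif(amp, 3),
                    " mT/m exceeds the whole-body limit; minimum feasible ",
                    "flat top is ",
                    signif(readout_amplitude(n_x, fov_x, 1) /
                           limits$max_amplitude, 3), " ms")
  ramp_ms <- amp / limits$max_slew
  n_ramp <- max(1L, ceiling(ramp_ms / dt))
  up <- amp * seq_len(n_ramp) / n_ramp
  gx <- c(up, rep(amp, n_flat), rev(up)[-1L], 0)
  gx_wf <- gradient_waveform(gx, raster, "x",
                             max_amplitude = limits$max_amplitude,
                             max_slew = limits$max_slew)
  flat_start <- n_ramp + 1L
  flat_end <- n_ramp + n_flat
  gz_wf <- NULL
  kz_mod <- rep(0, n_x)
  if (silent_on) {
    gz <- numeric(length(gx))
    t_us <- (seq_len(n_flat) - 1L) * raster
    gz[flat_start:flat_end] <-
      spec$amplitude * sin(2 * pi * spec$frequency * 1e-3 * t_us)
    gz_wf <- gradient_waveform(gz, raster, "z")
    # kz(t) = gamma_bar * A/(2 pi f) * (1 - cos(2 pi f t)); subtracting the
    # mean excursion (prewinder) centres it: kz_mod = -k_amp * cos(...)
    k_amp <- GAMMA_BAR * spec$amplitude * 1e-3 /
      (2 * pi * spec$frequency * 1e3)   # 1/m
    t_samp <- (seq_len(n_x) - 0.5) / n_x * flat_ms * 1e-3  # s, within flat
    kz_mod <- -k_amp * cos(2 * pi * spec$frequency * 1e3 * t_samp)
  }
  structure(list(gx = gx_wf, gz = gz_wf, flat_start = flat_start,
                 flat_end = flat_end, kz_mod = kz_mod, n_x = n_x,
                 fov_x = fov_x, flat_ms = flat_ms, raster = raster,
                 spec = if (silent_on) spec else NULL, limits = limits),
            class = "readout_waveforms")
}

#' Integrate gradient waveforms into a k-space trajectory
#'
#' Computes `k(t) = gamma_bar * integral(G dt)` per axis by cumulative
#' trapezoidal-free (rectangle) integration on the common raster, starting
#' from k = 0 at the excitation.
#'
#' @param waveforms A single [gradient_waveform()], a list of them (one per
#'   axis), or a `readout_waveforms` set.
#' @return An object of class `k_trajectory` with fields `time` (ms), `kx`,
#'   `ky`, `kz` (1/m) and `raster` (us).
#' @export
k_trajectory <- function(waveforms) {
  if (inherits(waveforms, "readout_waveforms"))
    waveforms <- Filter(Negate(is.null), list(waveforms$gx, waveforms$gz))
  if (inherits(waveforms, "gradient_waveform")) waveforms <- list(waveforms)
  if (!length(waveforms)) stop_invalid("no waveforms given")
  lens <- vapply(waveforms, function(w) length(w$samples), integer(1))
  rasters <- vapply(waveforms, function(w) w$raster, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(rasters)) != 1L)
    stop_invalid("waveforms must share a common length and raster")
  n <- lens[1L]; raster <- rasters[1L]
  k <- list(x = rep(0, n), y = rep(0, n), z = rep(0, n))
  for (w in waveforms) {
    # mT/m * us -> T/m * s : 1e-3 * 1e-6
    k[[w$axis]] <- GAMMA_BAR * cumsum(w$samples) * raster * 1e-9
  }
  structure(list(time = seq_len(n) * raster * 1e-3, kx = k$x, ky = k$y,
                 kz = k$z, raster = raster),
            class = "k_trajectory")
}

#' @export
print.k_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<k trajectory> %d samples @ %g us, |k|max = ",
                     "(%.1f, %.1f, %.1f) 1/m\n"),
              length(x$time), x$raster, max(abs(x$kx)), max(abs(x$ky)),
              max(abs(x$kz))))
  invisible(x)
}

#' CAIPI (sheared-lattice) sampling pattern
#'
#' Undersamples a `n_ky x n_kz` phase-encode grid by factors `Ry` and `Rz`,
#' shifting the kz offset by `shift` positions between successive sampled ky
#' columns, which spreads residual aliasing and reduces SENSE noise
#' amplification relative to a rectangular lattice.
#'
#' @param n_ky,n_kz Grid sizes.
#' @param Ry,Rz Integer acceleration factors, >= 1.
#' @param shift Integer kz shift per sampled ky column; values >= `Rz` are
#'   reduced modulo `Rz` with a warning.
#' @return An object of class `caipi_pattern`: logical `mask`
#'   (`n_ky x n_kz`), the factors and shift.
#' @examples
#' p <- caipi_pattern(8, 8, Ry = 2, Rz = 2, shift = 1)
#' sum(p$mask)  # 16
#' @export
caipi_pattern <- function(n_ky, n_kz, Ry = 1L, Rz = 1L, shift = 0L) {
  n_ky <- as.integer(n_ky); n_kz <- as.integer(n_kz)
  Ry <- as.integer(Ry); Rz <- as.integer(Rz); shift <- as.integer(shift)
  if (Ry < 1L || Rz < 1L) stop_invalid("Ry and Rz must be >= 1")
  if (shift >= Rz && Rz >= 1L && shift != 0L) {
    warning("shift >= Rz; reduced modulo Rz", call. = FALSE)
    shift <- shift %% Rz
  }
  mask <- matrix(FALSE, n_ky, n_kz)
  ky_cols <- seq(1L, n_ky, by = Ry)
  for (j in seq_along(ky_cols)) {
    off <- ((j - 1L) * shift) %% Rz
    mask[ky_cols[j], seq(1L + off, n_kz, by = Rz)] <- TRUE
  }
  structure(list(mask = mask, Ry = Ry, Rz = Rz, shift = shift,
                 n_ky = n_ky, n_kz = n_kz),
            class = "caipi_pattern")
}

#' Total acquisition duration of a shot-based sequence
#'
#' @param protocol An [mprage_protocol()].
#' @param n_shots Number of shots, >= 0.
#' @param lead_in Preparation time before the first shot, seconds.
#' @return Duration in seconds.
#' @examples
#' sequence_duration(conventional_protocol(), 48)  # 144 s = 2:24
#' @export
sequence_duration <- function(protocol, n_shots, lead_in = 0) {
  if (n_shots < 0) stop_invalid("n_shots must be >= 0")
  n_shots * protocol$shot_interval * 1e-3 + lead_in
}

#' Write or read waveforms/trajectories as plain text
#'
#' The on-disk dialect is shared by computed and externally measured
#' (field-camera style) trajectories: comment headers `# raster_us=...` and
#' `# kind=waveform|trajectory`, then whitespace-separated columns
#' `t_ms gx gy gz` (mT/m) or `t_ms kx ky kz` (1/m).
#'
#' @param traj A `k_trajectory`.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   [load_measured_trajectory()] (in the reconstruction module) reads the
#'   same dialect back.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "k_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# raster_us=%.12g", traj$raster),
               "# kind=trajectory", "# columns=t_ms kx ky kz"), con)
  utils::write.table(
    data.frame(t = sprintf("%.12g", traj$time),
               kx = sprintf("%.12g", traj$kx),
               ky = sprintf("%.12g", traj$ky),
               kz = sprintf("%.12g", traj$kz)),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
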