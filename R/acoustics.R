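#' Sound-pressure time series
#'
#' @param samples Sound pressure samples, Pa (or arbitrary units before
#'   calibration).
#' @param fs Sampling rate, Hz.
#' @return An object of class `pressure_series`.
#' @export
pressure_series <- function(samples, fs) {
  check_scalar(fs, "fs")
  if (fs <= 0) stop_invalid("fs must be positive")
  if (!length(samples)) stop_invalid("empty pressure series")
  if (!all(is.finite(samples))) stop_invalid("pressure samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs),
            class = "pressure_series")
}

#' @export
print.pressure_series <- function(x, ...) {
  cat(sprintf("<pressure series> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' A-weighting gain
#'
#' Closed-form IEC 61672 A-weighting magnitude response, normalised so the
#' gain at 1 kHz is exactly 0 dB.
#'
#' @param f Frequency, Hz (vectorised; must be positive).
#' @return Gain in dB.
#' @examples
#' a_weight_gain(1000)   # 0
#' a_weight_gain(20000)  # about -9.3
#' @export
a_weight_gain <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop_invalid("frequencies must be positive and finite")
  20 * log10(a_weight_linear(f) / a_weight_linear(1000))
}

# Linear (amplitude) A-weighting response, unnormalised.
a_weight_linear <- function(f) {
  f2 <- f^2
  12194^2 * f2^2 /
    ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
}

#' A-weighted exponential-time-weighted sound level meter
#'
#' Applies the A-weighting response in the frequency domain, then a running
#' exponential RMS detector with the standard meter time constants (fast:
#' 125 ms, slow: 1 s), and reports the sound pressure level in dB(A)
#' re 20 uPa over time together with its peak.
#'
#' @param series A [pressure_series()] in Pa.
#' @param time_weighting `"fast"` (tau = 125 ms) or `"slow"` (tau = 1 s).
#' @param floor_db Level reported where the detector output is zero
#'   (silence), dB.
#' @return A list with `spl` (dB(A) per sample), `peak` (max dB(A)), `time`
#'   (s) and the settings used.
#' @examples
#' fs <- 48000
#' tone <- pressure_series(sqrt(2) * sin(2 * pi * 1000 * (1:fs) / fs), fs)
#' spl_meter(tone)$peak  # 93.98 dB(A): the 94 dB calibrator level
#' @export
spl_meter <- function(series, time_weighting = c("fast", "slow"),
                      floor_db = -120) {
  stopifnot(inherits(series, "pressure_series"))
  time_weighting <- match.arg(time_weighting)
  tau <- if (time_weighting == "fast") 0.125 else 1.0
  w <- apply_a_weighting(series)
  a <- exp(-1 / (series$fs * tau))
  ms <- stats::filter((1 - a) * w^2, filter = a, method = "recursive")
  ms <- as.numeric(ms)
  p_ref2 <- (20e-6)^2
  spl <- ifelse(ms > 0, 10 * log10(ms / p_ref2), floor_db)
  spl <- pmax(spl, floor_db)
  list(spl = spl, peak = max(spl),
       time = seq_along(spl) / series$fs,
       time_weighting = time_weighting, tau = tau, floor_db = floor_db)
}

# Frequency-domain A-weighting of a pressure series; returns the weighted
# time-domain samples. DC is removed (A-weighting vanishes at 0 Hz).
apply_a_weighting <- function(series) {
  x <- series$samples
  n <- length(x)
  X <- stats::fft(x)
  f <- seq_len(n) - 1L
  f <- ifelse(f > n / 2, f - n, f) * series$fs / n
  gain <- numeric(n)
  nz <- f != 0
  gain[nz] <- a_weight_linear(abs(f[nz])) / a_weight_linear(1000)
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

#' Calibrate a recording against a reference tone level
#'
#' Given a recording of a steady calibrator tone in arbitrary units, returns
#' the scale factor that maps the recording to physical pascals such that
#' the metered level equals the reference level (default 94 dB, the standard
#' acoustic calibrator).
#'
#' @param recording A [pressure_series()] in arbitrary units.
#' @param reference_level Calibrator level, dB re 20 uPa.
#' @param time_weighting Meter time weighting used for the measurement.
#' @return Scale factor (multiply the recording by it to obtain Pa).
#' @export
calibrate <- function(recording, reference_level = 94,
                      time_weighting = "fast") {
  stopifnot(inherits(recording, "pressure_series"))
  if (all(recording$samples == 0))
    stop_invalid("cannot calibrate from a zero-energy recording")
  measured <- spl_meter(recording, time_weighting)$peak
  10^((reference_level - measured) / 20)
}

#' Gradient-to-pressure transfer model
#'
#' Linear transfer function from gradient slew rate (T/m/s) to sound
#' pressure (Pa), evaluated on an arbitrary frequency grid. The default
#' synthetic model is a second-order band-pass resonance (1.2 kHz, Q = 2)
#' with an additional -40 dB/decade roll-off above 8 kHz, a documented
#' stand-in for a measured scanner-bore response; it vanishes at 0 Hz. A
#' tabulated measured response can be supplied instead via `frequency` and
#' `gain`.
#'
#' @param frequency Optional frequency grid, Hz, for a tabulated model.
#' @param gain Optional complex gain (Pa per T/m/s) on `frequency`.
#' @param resonance_hz,q,rolloff_hz,peak_gain Parameters of the synthetic
#'   model (`peak_gain` in Pa per T/m/s at resonance).
#' @return An object of class `transfer_model`: a function mapping a
#'   frequency vector to complex gain, plus its parameters.
#' @export
transfer_model <- function(frequency = NULL, gain = NULL,
                           resonance_hz = 1200, q = 2, rolloff_hz = 8000,
                           peak_gain = 0.02) {
  if (!is.null(frequency)) {
    if (is.null(gain) || length(gain) != length(frequency))
      stop_invalid("tabulated model needs matching frequency and gain")
    if (any(frequency < 0)) stop_invalid("frequencies must be >= 0")
    if (any(!is.finite(Mod(gain)))) stop_invalid("gains must be finite")
    ord <- order(frequency)
    fr <- frequency[ord]; gn <- gain[ord]
    fun <- function(f) {
      g <- stats::approx(fr, Re(gn), xout = abs(f), rule = 2)$y +
        1i * stats::approx(fr, Im(gn), xout = abs(f), rule = 2)$y
      g[f == 0] <- 0
      g
    }
    kind <- "tabulated"
  } else {
    fun <- function(f) {
      s <- 1i * abs(f) / resonance_hz
      bp <- (s / q) / (1 + s / q + s^2)
      lp <- 1 / (1 + (abs(f) / rolloff_hz)^2)
      g <- peak_gain * bp * lp
      g[f == 0] <- 0
      g
    }
    kind <- "synthetic"
  }
  structure(list(gain_fun = fun, kind = kind,
                 params = list(resonance_hz = resonance_hz, q = q,
                               rolloff_hz = rolloff_hz,
                               peak_gain = peak_gain)),
            class = "transfer_model")
}

#' Predict the acoustic pressure generated by gradient waveforms
#'
#' Computes each waveform's slew-rate series, filters it through the
#' transfer model in the frequency domain, and sums the axis contributions
#' into a single predicted pressure series. The prediction is linear in the
#' gradient amplitude.
#'
#' @param waveforms A [gradient_waveform()], a list of them, or a
#'   `readout_waveforms` set. All must share one raster.
#' @param model A [transfer_model()].
#' @param repeats Number of times the waveform block is tiled before
#'   filtering (a readout repeats every TR; metering needs a few hundred
#'   milliseconds of signal).
#' @return A [pressure_series()] at `fs = 1e6 / raster` Hz.
#' @export
predict_pressure <- function(waveforms, model = transfer_model(),
                             repeats = 1L) {
  stopifnot(inherits(model, "transfer_model"))
  if (inherits(waveforms, "readout_waveforms"))
    waveforms <- Filter(Negate(is.null), list(waveforms$gx, waveforms$gz))
  if (inherits(waveforms, "gradient_waveform")) waveforms <- list(waveforms)
  rasters <- unique(vapply(waveforms, function(w) w$raster, numeric(1)))
  if (length(rasters) != 1L)
    stop_invalid("waveforms must share a common raster")
  fs <- 1e6 / rasters
  n <- max(vapply(waveforms, function(w) length(w$samples), integer(1)))
  total <- numeric(n * max(1L, as.integer(repeats)))
  for (w in waveforms) {
    g <- c(w$samples, numeric(n - length(w$samples))) * 1e-3  # T/m
    g <- rep(g, max(1L, as.integer(repeats)))
    slew <- c(0, diff(g)) * fs                                # T/m/s
    S <- stats::fft(slew)
    m <- length(S)
    f <- seq_len(m) - 1L
    f <- ifelse(f > m / 2, f - m, f) * fs / m
    gain <- model$gain_fun(abs(f))
    gain[f == 0] <- 0
    total <- total + Re(stats::fft(S * gain, inverse = TRUE)) / m
  }
  pressure_series(total, fs)
}

#' Read a pressure recording from WAV or plain text
#'
#' Plain-text files hold one sample per line with a `# fs=<Hz>` header.
#' WAV files must be mono RIFF/WAVE, PCM (16/24/32 bit) or IEEE float;
#' integer samples are mapped to `[-1, 1)`.
#'
#' @param path File path; format chosen by extension (`.wav` vs anything
#'   else).
#' @return A [pressure_series()].
#' @export
read_pressure <- function(path) {
  if (grepl("\\.wav$", path, ignore.case = TRUE)) read_wav(path)
  else read_pressure_text(path)
}

read_pressure_text <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fs_line <- grep("fs=", hdr, value = TRUE)
  if (!length(fs_line)) stop_invalid("text recording lacks a '# fs=' header")
  fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", fs_line[1L]))
  x <- as.numeric(lines[!grepl("^#", lines) & nzchar(lines)])
  pressure_series(x, fs)
}

read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop_invalid("not a RIFF/WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!length(id) || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        fs = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      data <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop_invalid("incomplete WAV file")
  if (fmt$channels != 1L) stop_invalid("only mono WAV files are supported")
  x <- switch(as.character(fmt$bits),
    "16" = readBin(data, "integer", length(data) / 2, 2,
                   endian = "little") / 32768,
    "32" = if (fmt$audio_format == 3L)
             readBin(data, "double", length(data) / 4, 4, endian = "little")
           else
             readBin(data, "integer", length(data) / 4, 4,
                     endian = "little") / 2147483648,
    stop_invalid("unsupported WAV bit depth: ", fmt$bits))
  pressure_series(x, fmt$fs)
}

#' @rdname read_pressure
#' @param series A [pressure_series()] to write.
#' @details `write_pressure_text()` writes the plain-text dialect.
#' @export
write_pressure_text <- function(series, path) {
  stopifnot(inherits(series, "pressure_series"))
  writeLines(c(sprintf("# fs=%.10g", series$fs),
               sprintf("%.9g", series$samples)), path)
  invisible(path)
}
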