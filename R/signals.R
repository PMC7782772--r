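#' Sound signals and synthetic chirps
#'
#' A `sound_signal` is a uniformly sampled real-valued waveform with a
#' sample rate. All test inputs of the package are synthetic chirps built
#' by [make_chirp()], so the whole pipeline is exercisable without any
#' external audio.
#'
#' @param samples numeric vector of (dimensionless) amplitudes.
#' @param rate sample rate in Hz.
#' @return An object of class `sound_signal` with fields `samples` and
#'   `rate`.
#' @export
sound_signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (length(samples) < 1L)
    stop("`samples` must be non-empty")
  if (!all(is.finite(samples)))
    stop("`samples` must be finite")
  structure(list(samples = samples, rate = rate), class = "sound_signal")
}

#' @export
print.sound_signal <- function(x, ...) {
  cat(sprintf("<sound_signal> %d samples @ %g Hz (%.4g s), peak %.4g\n",
              length(x$samples), x$rate,
              length(x$samples) / x$rate, max(abs(x$samples))))
  invisible(x)
}

#' Duration of a sound signal in seconds
#' @param s a `sound_signal`.
#' @export
signal_duration <- function(s) length(s$samples) / s$rate

#' Specification of a synthetic chirp
#'
#' Describes one of four families of test sounds: a linear chirp (the
#' instantaneous frequency grows linearly in time), the same chirp
#' interrupted by a hard gap of silence, the sum of two crossing linear
#' chirps with opposite slopes, and a sinusoidally frequency-modulated
#' chirp. Defaults keep every instantaneous frequency well inside the
#' Nyquist band and let the ridge span many analysis windows.
#'
#' @param kind one of `"linear"`, `"interrupted"`, `"crossing"`,
#'   `"sine_fm"`.
#' @param f0 start frequency in Hz (linear kinds and first crossing
#'   branch).
#' @param slope chirp rate in Hz/s.
#' @param gap_start,gap_len start and length (seconds) of the silent gap
#'   for `kind = "interrupted"`. The default gap lasts 0.125 s, twice the
#'   standard interaction delay of 0.0625 s, and sits at mid-signal.
#' @param f1,slope2 start frequency (Hz) and slope (Hz/s) of the second
#'   branch for `kind = "crossing"`.
#' @param carrier,depth,m carrier frequency (Hz), modulation depth (Hz)
#'   and modulation rate (rad/s) for `kind = "sine_fm"`.
#' @param amplitude peak amplitude (dimensionless, > 0).
#' @param duration signal duration in seconds.
#' @param rate sample rate in Hz.
#' @return An object of class `chirp_spec`.
#' @export
chirp_spec <- function(kind = c("linear", "interrupted", "crossing", "sine_fm"),
                       f0 = 500, slope = 1000,
                       gap_start = NULL, gap_len = 0.125,
                       f1 = 2500, slope2 = -1000,
                       carrier = 1500, depth = 800, m = 2 * pi,
                       amplitude = 1, duration = 2, rate = 8000) {
  kind <- match.arg(kind)
  if (amplitude <= 0) stop("`amplitude` must be > 0")
  if (duration <= 0) stop("`duration` must be > 0")
  if (rate <= 0) stop("`rate` must be > 0")
  if (kind == "interrupted") {
    if (is.null(gap_start)) gap_start <- (duration - gap_len) / 2
    if (gap_len < 0) stop("`gap_len` must be >= 0")
    if (gap_start < 0 || gap_start + gap_len > duration)
      stop("gap interval must lie inside [0, duration]")
  }
  spec <- structure(
    list(kind = kind, f0 = f0, slope = slope,
         gap_start = gap_start, gap_len = gap_len,
         f1 = f1, slope2 = slope2,
         carrier = carrier, depth = depth, m = m,
         amplitude = amplitude, duration = duration, rate = rate),
    class = "chirp_spec")
  inst <- instantaneous_frequency(spec)
  if (max(inst) >= rate / 2)
    stop(sprintf(paste0("aliasing: maximum instantaneous frequency ",
                        "%.1f Hz reaches the Nyquist frequency %.1f Hz"),
                 max(inst), rate / 2))
  if (min(inst) <= 0)
    stop("instantaneous frequency must stay positive over the sweep")
  spec
}

#' Nominal instantaneous frequency of a chirp spec
#'
#' Frequency track (Hz) that the generated waveform follows, sampled at
#' the spec's rate. For the crossing kind both branches are returned as
#' columns.
#'
#' @param spec a `chirp_spec`.
#' @return numeric vector (or two-column matrix for `"crossing"`).
#' @export
instantaneous_frequency <- function(spec) {
  t <- seq(0, spec$duration, length.out = max(2L, round(spec$duration * spec$rate)))
  switch(spec$kind,
    linear      = spec$f0 + spec$slope * t,
    interrupted = spec$f0 + spec$slope * t,
    crossing    = cbind(spec$f0 + spec$slope * t, spec$f1 + spec$slope2 * t),
    sine_fm     = spec$carrier + spec$depth * sin(spec$m * t))
}

# Phase integral 2*pi*int_0^t f(u) du for one linear branch.
linear_phase <- function(t, f0, slope) 2 * pi * (f0 * t + slope * t^2 / 2)

#' Generate a synthetic chirp waveform
#'
#' Produces the waveform whose instantaneous frequency follows `spec`.
#' The phase is continuous except across an interruption gap, where the
#' samples are exactly zero; the crossing kind is the pointwise sum of
#' its two linear branches. Output is deterministic for a fixed spec;
#' `seed` only matters when additive white noise is requested.
#'
#' @param spec a [chirp_spec()].
#' @param seed optional integer seed for the additive noise.
#' @param noise_sd standard deviation of optional additive white
#'   Gaussian noise (default 0, no noise).
#' @return a [sound_signal()].
#' @export
make_chirp <- function(spec, seed = NULL, noise_sd = 0) {
  stopifnot(inherits(spec, "chirp_spec"))
  n <- round(spec$duration * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  A <- spec$amplitude
  x <- switch(spec$kind,
    linear = A * sin(linear_phase(t, spec$f0, spec$slope)),
    interrupted = {
      y <- A * sin(linear_phase(t, spec$f0, spec$slope))
      gap <- t >= spec$gap_start & t < spec$gap_start + spec$gap_len
      y[gap] <- 0
      y
    },
    crossing = A * sin(linear_phase(t, spec$f0, spec$slope)) +
               A * sin(linear_phase(t, spec$f1, spec$slope2)),
    sine_fm = {
      # int_0^t carrier + depth*sin(m u) du = carrier*t + depth*(1-cos(m t))/m
      phase <- 2 * pi * (spec$carrier * t +
                           spec$depth * (1 - cos(spec$m * t)) / spec$m)
      A * sin(phase)
    })
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    }
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  sound_signal(x, spec$rate)
}

# ---------------------------------------------------------------------------
# WAV I/O. Minimal RIFF/WAVE reader and writer supporting mono (or
# first-channel extraction) PCM16 and IEEE float32, which is all the
# package needs for lossless round trips of its own signals.

#' Write a sound signal to a WAV file
#'
#' @param s a `sound_signal`.
#' @param path output file path.
#' @param format `"float32"` (IEEE float, lossless for typical signals)
#'   or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(s, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(s, "sound_signal"))
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(s$samples)
  bits <- if (format == "float32") 32L else 16L
  bytes_per <- bits %/% 8L
  fmt_tag <- if (format == "float32") 3L else 1L
  data_len <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(s$rate), con, size = 4, endian = "little")
  writeBin(as.integer(s$rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(s$samples), con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(s$samples * 32767))))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file as a sound signal
#'
#' Supports mono PCM16 and IEEE float32 files; for multichannel input
#' only the first channel is kept.
#'
#' @param path file path.
#' @return a [sound_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stop("not a valid WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt_tag <- NULL; n_chan <- NULL; rate <- NULL; bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (length(len) == 0) break
    if (identical(id, "fmt ")) {
      fmt_tag <- readBin(con, integer(), size = 2, endian = "little")
      n_chan <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- len - 16L
      if (extra > 0) invisible(readBin(con, raw(), n = extra))
    } else if (identical(id, "data")) {
      if (is.null(fmt_tag)) stop("malformed WAV: data chunk before fmt")
      if (fmt_tag == 1L && bits == 16L) {
        raw_vals <- readBin(con, integer(), n = len %/% 2L, size = 2,
                            signed = TRUE, endian = "little")
        samples <- raw_vals / 32767
      } else if (fmt_tag == 3L && bits == 32L) {
        samples <- readBin(con, numeric(), n = len %/% 4L, size = 4,
                           endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                     fmt_tag, bits))
      }
      break
    } else {
      invisible(readBin(con, raw(), n = len + (len %% 2L)))
    }
  }
  if (is.null(samples) || length(samples) == 0)
    stop("malformed WAV: no data chunk found in ", path)
  if (n_chan > 1L)
    samples <- samples[seq(1, length(samples), by = n_chan)]
  sound_signal(samples, rate)
}
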