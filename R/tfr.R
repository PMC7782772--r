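#' STFT analysis configuration
#'
#' Geometry of the short-time Fourier analysis: a Hann window of
#' `window_len` seconds advanced by `hop` seconds, transformed on
#' `fft_size` points. Invertibility of the overlap-add synthesis is
#' guaranteed for `hop <= window_len / 2` (the constant-overlap-add
#' regime of the Hann window), which is enforced at construction.
#'
#' Defaults follow the time resolution the reconstruction needs: a 64 ms
#' window hopped by 16 ms gives roughly four analysis frames per 62.5 ms
#' interaction delay.
#'
#' @param rate sample rate in Hz of the signals to analyse.
#' @param window_len analysis window length in seconds.
#' @param hop hop between consecutive frames in seconds.
#' @param fft_size FFT length in samples; defaults to the next power of
#'   two at or above the window sample count.
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(rate, window_len = 0.064, hop = window_len / 4,
                        fft_size = NULL) {
  if (rate <= 0) stop("`rate` must be > 0")
  win_n <- round(window_len * rate)
  hop_n <- round(hop * rate)
  if (win_n < 2) stop("window must span at least 2 samples")
  if (hop_n < 1) stop("hop must span at least 1 sample")
  if (hop_n > win_n / 2)
    stop("`hop` must be <= window_len / 2 for invertible overlap-add")
  if (is.null(fft_size)) fft_size <- 2^ceiling(log2(win_n))
  fft_size <- as.integer(fft_size)
  if (fft_size < win_n) stop("`fft_size` must be >= window sample count")
  structure(list(rate = rate,
                 window_len = win_n / rate, hop = hop_n / rate,
                 win_n = as.integer(win_n), hop_n = as.integer(hop_n),
                 fft_size = fft_size),
            class = "stft_config")
}

#' Hann window samples
#'
#' Periodic Hann window `0.5 * (1 - cos(2*pi*n/L))`, `n = 0, ...,
#' L - 1`: the single zero endpoint is included once so that overlapped
#' squared windows sum to an exactly constant value at hops `L/2`,
#' `L/4`, ... The window equals `(1 + cos(2*pi*x/L)) / 2` for
#' `|x| < L/2` (and 0 outside) with `x` measured from the window
#' centre at index `L/2`.
#'
#' @param L_samples window length in samples (>= 2).
#' @return numeric vector of length `L_samples`, values in `[0, 1]`.
#' @export
hann_window <- function(L_samples) {
  L_samples <- as.integer(L_samples)
  if (is.na(L_samples) || L_samples < 2) stop("`L_samples` must be >= 2")
  n <- seq_len(L_samples) - 1
  0.5 * (1 - cos(2 * pi * n / L_samples))
}

#' Time-frequency image
#'
#' Complex STFT coefficients on a regular grid. Only the non-negative
#' frequency bins are stored; the negative half follows from Hermitian
#' symmetry of the spectrum of a real signal and is reinstated where
#' needed (inverse transform, interaction across the zero-frequency
#' edge).
#'
#' @param values complex matrix, rows = frames, cols = frequency bins.
#' @param times frame-centre times in seconds.
#' @param freqs bin frequencies in Hz (0 to Nyquist).
#' @param config the [stft_config()] that produced the image.
#' @param n_samples original signal length in samples (used by
#'   [istft()] to trim).
#' @return An object of class `tf_image`.
#' @export
tf_image <- function(values, times, freqs, config, n_samples = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) != length(times) || ncol(values) != length(freqs))
    stop("matrix shape must be length(times) x length(freqs)")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("`values` must be finite")
  structure(list(values = values, times = times, freqs = freqs,
                 config = config, n_samples = n_samples),
            class = "tf_image")
}

#' @export
print.tf_image <- function(x, ...) {
  cat(sprintf("<tf_image> %d frames x %d bins, t in [%.3g, %.3g] s, f in [0, %g] Hz\n",
              nrow(x$values), ncol(x$values),
              min(x$times), max(x$times), max(x$freqs)))
  invisible(x)
}

#' Short-time Fourier transform
#'
#' Windows the signal with a periodic Hann window, applies a
#' unitary-per-frame DFT (`fft(x) / sqrt(fft_size)`) and keeps the
#' non-negative frequency bins. The transform is linear in the signal.
#' The final partial frame is zero-padded.
#'
#' @param s a [sound_signal()].
#' @param cfg an [stft_config()]; its rate must match the signal.
#' @return a [tf_image()].
#' @export
stft <- function(s, cfg) {
  stopifnot(inherits(s, "sound_signal"), inherits(cfg, "stft_config"))
  if (abs(cfg$rate - s$rate) > 1e-9)
    stop("config rate does not match signal rate")
  n <- length(s$samples)
  if (n <= cfg$win_n) stop("signal must be longer than one window")
  w <- hann_window(cfg$win_n)
  n_frames <- ceiling((n - cfg$win_n) / cfg$hop_n) + 1L
  padded <- c(s$samples, rep(0, (n_frames - 1L) * cfg$hop_n + cfg$win_n - n))
  starts <- (seq_len(n_frames) - 1L) * cfg$hop_n
  frames <- matrix(0, nrow = cfg$fft_size, ncol = n_frames)
  idx <- seq_len(cfg$win_n)
  for (i in seq_len(n_frames))
    frames[idx, i] <- padded[starts[i] + idx] * w
  spec <- stats::mvfft(frames) / sqrt(cfg$fft_size)
  n_bins <- cfg$fft_size %/% 2L + 1L
  vals <- t(spec[seq_len(n_bins), , drop = FALSE])
  times <- (starts + cfg$win_n / 2) / cfg$rate
  freqs <- (seq_len(n_bins) - 1) * cfg$rate / cfg$fft_size
  tf_image(vals, times, freqs, cfg, n_samples = n)
}

# Hermitian extension of a half-spectrum matrix (frames x bins) to the
# full fft_size bins. DC and Nyquist are forced real (their imaginary
# parts are diagnostics of symmetry preservation, see istft()).
hermitian_full_spectrum <- function(vals, fft_size) {
  n_bins <- ncol(vals)
  stopifnot(n_bins == fft_size %/% 2L + 1L)
  full <- matrix(0i, nrow = nrow(vals), ncol = fft_size)
  full[, seq_len(n_bins)] <- vals
  full[, 1L] <- complex(real = Re(vals[, 1L]))
  full[, n_bins] <- complex(real = Re(vals[, n_bins]))
  if (n_bins > 2L)
    full[, fft_size:(n_bins + 1L)] <- Conj(vals[, 2L:(n_bins - 1L)])
  full
}

#' Inverse short-time Fourier transform
#'
#' Rebuilds the full Hermitian spectrum from the stored half, inverts
#' each frame, and overlap-adds with the analysis window, normalising
#' pointwise by the summed squared window. With matching analysis
#' geometry this makes `istft(stft(s))` the identity up to floating
#' round-off away from the first/last window, for any hop satisfying the
#' construction-time overlap condition.
#'
#' The imaginary residual of the frame inverses - which is zero in exact
#' arithmetic whenever the half-spectrum genuinely came from a real
#' signal - is measured before being discarded and reported in the
#' `"imag_ratio"` attribute (max |Im| / max |Re|).
#'
#' @param S a [tf_image()].
#' @param n_samples output length in samples; defaults to the length
#'   recorded at analysis time, else full overlap-add length.
#' @return a [sound_signal()] with attribute `"imag_ratio"`.
#' @export
istft <- function(S, n_samples = NULL) {
  stopifnot(inherits(S, "tf_image"))
  cfg <- S$config
  n_bins <- cfg$fft_size %/% 2L + 1L
  if (ncol(S$values) != n_bins)
    stop("bin count inconsistent with config fft_size")
  full <- hermitian_full_spectrum(S$values, cfg$fft_size)
  frames <- stats::mvfft(t(full), inverse = TRUE) / sqrt(cfg$fft_size)
  # DC/Nyquist bins of a real signal are real; any imaginary content
  # there is a symmetry defect and is charged to the residual too.
  im_dcny <- max(abs(Im(S$values[, c(1L, n_bins)])))
  im_max <- max(abs(Im(frames)), im_dcny)
  re_max <- max(abs(Re(frames)))
  imag_ratio <- if (re_max > 0) im_max / re_max else 0
  frames <- Re(frames)
  n_frames <- ncol(frames)
  w <- hann_window(cfg$win_n)
  total_n <- (n_frames - 1L) * cfg$hop_n + cfg$win_n
  acc <- numeric(total_n)
  wsq <- numeric(total_n)
  idx <- seq_len(cfg$win_n)
  for (i in seq_len(n_frames)) {
    off <- (i - 1L) * cfg$hop_n
    acc[off + idx] <- acc[off + idx] + frames[idx, i] * w
    wsq[off + idx] <- wsq[off + idx] + w^2
  }
  ok <- wsq > 1e-8 * max(wsq)
  acc[ok] <- acc[ok] / wsq[ok]
  acc[!ok] <- 0
  if (is.null(n_samples)) n_samples <- S$n_samples
  if (is.null(n_samples)) n_samples <- total_n
  out <- sound_signal(acc[seq_len(min(n_samples, total_n))], cfg$rate)
  attr(out, "imag_ratio") <- imag_ratio
  out
}
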