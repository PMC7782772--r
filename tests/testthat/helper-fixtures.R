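# Shared fixtures and independent oracles used across the suite.

# Instantaneous frequency (Hz) of a real signal via the analytic-signal
# phase: an FFT Hilbert transform followed by a finite difference of
# the unwrapped phase. Independent of the package's chirp generator.
analytic_inst_freq <- function(x, rate) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  dphi <- Arg(z[-1] * Conj(z[-n]))
  dphi * rate / (2 * pi)
}

# Random Hermitian field H(w, v) = Conj(H(-w, -v)) on a full symmetric
# frequency axis of odd length (centre index = zero frequency).
random_hermitian_field <- function(nf_full, nn) {
  M <- matrix(complex(real = stats::rnorm(nf_full * nn),
                      imaginary = stats::rnorm(nf_full * nn)),
              nf_full, nn)
  (M + Conj(M[rev(seq_len(nf_full)), rev(seq_len(nn))])) / 2
}

# Small half/full lattice pair for symmetry and mirror-operator tests.
small_lattice <- function(nf = 9, nn = 7, f_max = 0.4, nu_max = 0.3) {
  freqs_half <- seq(0, f_max, length.out = nf)
  dw <- freqs_half[2] - freqs_half[1]
  list(freqs_half = freqs_half,
       freqs_full = seq(-(nf - 1) * dw, (nf - 1) * dw, by = dw),
       nus = seq(-nu_max, nu_max, length.out = nn),
       nf = nf, nn = nn)
}

default_chirp_signal <- function(kind = "linear", ...) {
  make_chirp(chirp_spec(kind, ...))
}
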