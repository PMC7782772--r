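#' Wilson-Cowan evolution parameters
#'
#' Parameters of the delayed Wilson-Cowan equation
#' `da/dt = -alpha * a + beta * I +
#'  gamma * Int k_delta(.||.) sigma(a(t - delta, .)) `
#' integrated by forward Euler with step `dt`. The delay must be a whole
#' number of Euler steps; a `delta` that is not is snapped to the
#' nearest multiple of `dt` with a warning. Explicit-Euler stability of
#' the linear decay requires `alpha * dt < 1`.
#'
#' @param alpha decay rate, 1/s (> 0).
#' @param beta input gain (> 0).
#' @param gamma interaction gain (>= 0).
#' @param kappa sigmoid slope (> 0).
#' @param delta interaction delay, s (> 0).
#' @param dt Euler step, s (> 0, <= delta).
#' @return An object of class `wc_params`; `delay_steps` holds
#'   `delta / dt`.
#' @export
wc_params <- function(alpha, beta, gamma, kappa = 1, delta, dt) {
  if (alpha <= 0) stop("`alpha` must be > 0")
  if (beta <= 0) stop("`beta` must be > 0")
  if (gamma < 0) stop("`gamma` must be >= 0")
  if (kappa <= 0) stop("`kappa` must be > 0")
  if (delta <= 0 || dt <= 0) stop("`delta` and `dt` must be > 0")
  if (dt > delta + 1e-12) stop("`dt` must be <= `delta`")
  if (alpha * dt >= 1)
    stop(sprintf("alpha * dt = %.3g >= 1: forward Euler unstable; reduce dt",
                 alpha * dt))
  d_steps <- round(delta / dt)
  snapped <- d_steps * dt
  if (abs(snapped - delta) > 1e-9 * delta) {
    warning(sprintf("delay %.6g s is not a multiple of dt = %.6g s; snapped to %.6g s",
                    delta, dt, snapped))
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
                 delta = snapped, dt = dt, delay_steps = as.integer(d_steps)),
            class = "wc_params")
}

#' Phase-preserving saturating sigmoid
#'
#' `sigma(rho * exp(i theta)) = min(1, kappa * rho) * exp(i theta)`: the
#' modulus is passed through a ramp clipped at 1 while the phase is
#' untouched (and negative real inputs keep their sign). Acting on the
#' modulus only is what lets the evolution preserve the Hermitian
#' symmetry of fields coming from real signals, hence the reality of
#' the reconstructed sound.
#'
#' @param z complex (vector, matrix or array).
#' @param kappa slope of the ramp (> 0).
#' @return same shape as `z`, with `|out| <= 1`.
#' @export
wc_sigmoid <- function(z, kappa = 1) {
  rho <- Mod(z)
  fac <- ifelse(rho > 0, pmin(1, kappa * rho) / rho, 0)
  z * fac
}

#' One forward-Euler step of the delayed Wilson-Cowan equation
#'
#' `a_next = a_now + dt * (-alpha * a_now + beta * I_now +
#'  gamma * K sigma(a_delayed))`, where `K` is the sparse interaction
#' operator applied to the sigmoided field delayed by one interaction
#' delay. With `gamma = 0` the interaction (and `K`) is skipped.
#'
#' @param a_now complex matrix, current activation on the lattice.
#' @param a_delayed complex matrix, activation one delay earlier (zero
#'   matrix before the evolution start).
#' @param I_now complex matrix, external input at the current step.
#' @param params a [wc_params()].
#' @param K a [build_interaction()] operator (required when
#'   `gamma > 0`).
#' @return complex matrix `a_next`.
#' @export
wc_step <- function(a_now, a_delayed, I_now, params, K = NULL) {
  if (!all(is.finite(Re(a_now)), is.finite(Im(a_now)),
           is.finite(Re(a_delayed)), is.finite(Im(a_delayed)),
           is.finite(Re(I_now)), is.finite(Im(I_now))))
    stop("non-finite values in Wilson-Cowan state or input")
  inter <- 0
  if (params$gamma > 0) {
    if (is.null(K)) stop("`K` is required when gamma > 0")
    inter <- apply_interaction(K, wc_sigmoid(a_delayed, params$kappa))
  }
  a_now + params$dt * (-params$alpha * a_now + params$beta * I_now +
                         params$gamma * inter)
}

#' Evolve the Wilson-Cowan equation over a lifted image
#'
#' Integrates the delayed Wilson-Cowan equation with zero initial
#' history, consuming one input frame per Euler step (`dt` equals the
#' frame hop). The evolution is causal - the state after `n` steps
#' depends only on inputs up to frame `n` and on the state at least one
#' delay in the past - and fully deterministic.
#'
#' @param I a `lifted_image`, or a plain complex array
#'   (steps x frequency x chirpiness).
#' @param params a [wc_params()]; `params$dt` must match the frame
#'   spacing of `I` when `I` is a `lifted_image`.
#' @param K interaction operator on the matching lattice (needed when
#'   `gamma > 0`).
#' @return An object of class `activation_field`: complex array
#'   `values` of the same dimensions as the input (state after each
#'   step), plus axes and parameters.
#' @export
wc_evolve <- function(I, params, K = NULL) {
  if (inherits(I, "lifted_image")) {
    arr <- I$values
    frame_dt <- diff(I$times[1:2])
    if (abs(frame_dt - params$dt) > 1e-9)
      stop(sprintf("params$dt = %.6g s does not match the frame spacing %.6g s",
                   params$dt, frame_dt))
    axes <- list(times = I$times, freqs = I$freqs, nu_values = I$nu_values,
                 config = I$config, n_samples = I$n_samples)
  } else {
    arr <- I
    axes <- NULL
  }
  dm <- dim(arr)
  if (length(dm) != 3L) stop("input must be a 3D array (time x freq x nu)")
  nT <- dm[1]; nf <- dm[2]; nn <- dm[3]
  d <- params$delay_steps
  a <- array(0i, dim = dm)
  zero <- matrix(0i, nf, nn)
  a_prev <- zero
  for (n in seq_len(nT)) {
    a_del <- if (n - 1L - d >= 1L)
      matrix(a[n - 1L - d, , ], nf, nn) else zero
    a_prev <- wc_step(a_prev, a_del, matrix(arr[n, , ], nf, nn), params, K)
    a[n, , ] <- a_prev
  }
  structure(c(list(values = a, params = params), axes),
            class = "activation_field")
}

#' @export
print.activation_field <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("<activation_field> %d steps x %d bins x %d chirpiness, max |a| = %.4g\n",
              dm[1], dm[2], dm[3], max(Mod(x$values))))
  invisible(x)
}

#' Exact low-pass reference trajectory
#'
#' Solution of the interaction-free limit `da/dt = -alpha * a + beta *
#' I` for an input held constant over each frame: the causal
#' exponential filter `a_n = e^(-alpha dt) a_(n-1) + (beta / alpha) (1 -
#' e^(-alpha dt)) I_n`, i.e. the convolution of the input with `beta *
#' exp(-alpha t)` for `t > 0`. This is the exact zero-order-hold
#' solution, so it serves as the convergence oracle for the forward
#' Euler integrator as `dt` shrinks.
#'
#' @param I complex array (steps x ...) or vector of frame inputs.
#' @param alpha decay rate (> 0).
#' @param beta input gain.
#' @param dt frame duration in seconds.
#' @return trajectory of the same shape as `I`.
#' @export
lowpass_reference <- function(I, alpha, beta, dt) {
  decay <- exp(-alpha * dt)
  gain <- beta / alpha * (1 - decay)
  if (is.null(dim(I))) {
    out <- I * 0
    prev <- 0
    for (n in seq_along(I)) {
      prev <- decay * prev + gain * I[n]
      out[n] <- prev
    }
    return(out)
  }
  dm <- dim(I)
  out <- array(if (is.complex(I)) 0i else 0, dim = dm)
  nT <- dm[1]
  prev <- array(if (is.complex(I)) 0i else 0, dim = dm[-1])
  flat <- matrix(I, nrow = nT)
  oflat <- matrix(out, nrow = nT)
  pv <- rep(if (is.complex(I)) 0i else 0, ncol(flat))
  for (n in seq_len(nT)) {
    pv <- decay * pv + gain * flat[n, ]
    oflat[n, ] <- pv
  }
  array(oflat, dim = dm)
}
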