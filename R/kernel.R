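#' Interaction kernel parameters
#'
#' Parameters of the neuronal interaction kernel: the diffusion
#' strength `b` of the chirpiness variable, the interaction delay
#' `delta` (seconds) at which the transition density is evaluated, and
#' the truncation threshold `eps` below which kernel values are treated
#' as zero when building sparse interaction tables.
#'
#' The kernel attains its maximum `sqrt(3) / (2 * pi * b * delta^2)`;
#' thresholds above it give an empty support. The default threshold is
#' `1e-4` times the maximum, which keeps supports compact while
#' retaining essentially all of the unit transition mass.
#'
#' @param b diffusion strength (> 0), in squared chirpiness units per
#'   second of whatever axis scaling the kernel is evaluated in.
#' @param delta delay in seconds (> 0).
#' @param eps absolute truncation threshold (>= 0); default
#'   `1e-4 * kernel_max()`.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(b, delta, eps = NULL) {
  if (!is.finite(b) || b <= 0) stop("`b` must be > 0")
  if (!is.finite(delta) || delta <= 0) stop("`delta` must be > 0")
  kmax <- sqrt(3) / (2 * pi * b * delta^2)
  if (is.null(eps)) eps <- 1e-4 * kmax
  if (eps < 0) stop("`eps` must be >= 0")
  structure(list(b = b, delta = delta, eps = eps, kmax = kmax),
            class = "kernel_params")
}

#' Maximum of the interaction kernel
#'
#' `sqrt(3) / (2 * pi * b * delta^2)`, the value of the transition
#' density at its degenerate point (the pure drift endpoint).
#'
#' @param params a [kernel_params()].
#' @return positive scalar.
#' @export
kernel_max <- function(params) params$kmax

#' Quadratic form of the interaction kernel
#'
#' The positive-semidefinite quadratic form
#' `3*(w - wp)^2 - 3*delta*(w - wp)*(nu + nup) +
#'  delta^2*(nu^2 + nu*nup + nup^2)`
#' appearing in the exponent of the closed-form transition density.
#' Vectorised over all arguments.
#'
#' @param omega,nu arrival frequency and chirpiness.
#' @param omegap,nup departure frequency and chirpiness.
#' @param delta delay (> 0).
#' @return numeric, always >= 0.
#' @export
g_delta <- function(omega, nu, omegap, nup, delta) {
  dw <- omega - omegap
  3 * dw^2 - 3 * delta * dw * (nu + nup) +
    delta^2 * (nu^2 + nu * nup + nup^2)
}

#' Closed-form hypoelliptic transition density
#'
#' Density, after a delay `delta`, of the chirp diffusion
#' `d(omega) = nu dt`, `d(nu) = sqrt(2 b) dW` started at
#' `(omegap, nup)`, evaluated at `(omega, nu)`:
#' `kernel_value = kernel_max * exp(-g_delta / (b * delta^3))`.
#' Strictly positive, bounded by [kernel_max()], and integrating to one
#' over the arrival plane. Vectorised.
#'
#' @inheritParams g_delta
#' @param params a [kernel_params()].
#' @return numeric, in `(0, kernel_max]`.
#' @export
kernel_value <- function(omega, nu, omegap, nup, params) {
  params$kmax * exp(-g_delta(omega, nu, omegap, nup, params$delta) /
                      (params$b * params$delta^3))
}

#' Truncated support of the interaction kernel
#'
#' The set of departure points whose kernel value at `(omega, nu)` is at
#' least `eps` is the region
#' `|nu - nup|^2 <= C_eps` with
#' `C_eps = -4 * b * delta * log(2 * pi * b * delta^2 * eps / sqrt(3))`,
#' and, for each admissible `nup`,
#' `|omegap - omega + delta * (nu + nup) / 2| <=
#'  delta / (2 * sqrt(3)) * sqrt(C_eps - |nu - nup|^2)`.
#' At `eps = kernel_max` the region degenerates to the single point
#' `nup = nu`, `omegap = omega - delta * nu`; above the maximum it is
#' empty.
#'
#' @param omega,nu arrival point.
#' @param params a [kernel_params()].
#' @return list with `C_eps`, the chirpiness interval `nu_range`, the
#'   centre function `omega_center(nup)` and half-width function
#'   `omega_halfwidth(nup)` of the frequency interval, and a predicate
#'   `contains(omegap, nup)`. `C_eps < 0` encodes the empty region.
#' @export
support_bounds <- function(omega, nu, params) {
  b <- params$b; delta <- params$delta; eps <- params$eps
  # -4*b*delta*log(2*pi*b*delta^2*eps/sqrt(3)), written against the
  # kernel maximum so that eps equal to the maximum gives exactly 0
  C_eps <- if (eps == 0) Inf else -4 * b * delta * log(eps / params$kmax)
  half_nu <- if (C_eps >= 0) sqrt(C_eps) else NA_real_
  omega_center <- function(nup) omega - delta * (nu + nup) / 2
  omega_halfwidth <- function(nup) {
    d2 <- C_eps - (nu - nup)^2
    ifelse(d2 >= 0, delta / (2 * sqrt(3)) * sqrt(pmax(d2, 0)), NA_real_)
  }
  contains <- function(omegap, nup) {
    d2 <- C_eps - (nu - nup)^2
    ok <- d2 >= 0
    hw <- delta / (2 * sqrt(3)) * sqrt(pmax(d2, 0))
    ok & abs(omegap - omega_center(nup)) <= hw
  }
  list(C_eps = C_eps,
       nu_range = if (C_eps >= 0) c(nu - half_nu, nu + half_nu) else NULL,
       omega_center = omega_center,
       omega_halfwidth = omega_halfwidth,
       contains = contains)
}

#' Sparse interaction operator on a frequency-chirpiness lattice
#'
#' Tabulates, for every lattice point `(omega, nu)`, the kernel values
#' over its truncated support, scaled by the lattice cell area so that
#' applying the operator approximates the interaction integral by a
#' midpoint sum. Because the kernel depends on frequency only through
#' the difference `omega - omegap`, the table is assembled band-by-band
#' over chirpiness pairs.
#'
#' When `mirror = TRUE` (the default whenever the frequency axis starts
#' at zero) the lattice is understood as the non-negative half of a
#' frequency axis that extends symmetrically below zero. Support mass
#' falling at negative departure frequencies is then routed to the
#' mirrored stored bin `(-omegap, -nup)` and flagged so that the
#' operator is applied to the complex conjugate of the field there -
#' exactly the Hermitian-symmetry rule for fields arising from real
#' signals.
#'
#' @param freqs frequency axis (uniform, ascending).
#' @param nus chirpiness axis (uniform, symmetric about 0), a
#'   [chirpiness_grid()] or a numeric vector.
#' @param params a [kernel_params()] in the same units as the axes.
#' @param mirror route sub-zero-frequency support through the Hermitian
#'   mirror (requires `freqs[1] == 0`).
#' @param inert_top leave the top frequency row without arrivals
#'   (default follows `mirror`). In half-spectrum use the top row is the
#'   Nyquist bin, whose coefficient is shared between the two spectral
#'   halves and must stay real; evolving it as an interior row of the
#'   half-space model would leak an imaginary part into the
#'   reconstruction.
#' @return An object of class `sparse_interaction`: sparse matrices
#'   `direct` and `mirrored` of size `nG x nG` (`nG = length(freqs) *
#'   length(nus)`, frequency index fastest), row masses, axes and
#'   parameters.
#' @export
build_interaction <- function(freqs, nus, params, mirror = NULL,
                              inert_top = NULL) {
  if (inherits(nus, "chirpiness_grid")) nus <- nus$nu_values
  nf <- length(freqs); nn <- length(nus)
  if (nf < 1L || nn < 1L) stop("lattice must be non-empty")
  dw <- if (nf > 1L) freqs[2] - freqs[1] else 1
  dn <- if (nn > 1L) nus[2] - nus[1] else 1
  if (is.null(mirror)) mirror <- isTRUE(all.equal(freqs[1], 0))
  if (mirror && abs(freqs[1]) > 1e-12 * max(abs(freqs), 1))
    stop("`mirror = TRUE` requires a frequency axis starting at 0")
  cell <- dw * dn
  delta <- params$delta
  C_eps <- support_bounds(0, 0, params)$C_eps
  if (C_eps < 0) {
    warning("truncation threshold exceeds the kernel maximum: ",
            "all interaction tables are empty")
    empty <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                  x = numeric(), dims = c(nf * nn, nf * nn))
    return(structure(list(direct = empty, mirrored = empty,
                          row_mass = numeric(nf * nn),
                          freqs = freqs, nus = nus, params = params,
                          cell_area = cell, mirror = mirror),
                     class = "sparse_interaction"))
  }
  ti <- list(); tj <- list(); tx <- list()   # direct triplets
  mi <- list(); mj <- list(); mx <- list()   # mirrored triplets
  p <- 0L
  for (a_n in seq_len(nn)) {      # arrival chirpiness (row)
    nu_a <- nus[a_n]
    for (d_n in seq_len(nn)) {    # departure chirpiness (column, physical)
      nu_d <- nus[d_n]
      rem <- C_eps - (nu_a - nu_d)^2
      if (rem < 0) next
      hw <- delta / (2 * sqrt(3)) * sqrt(rem)
      shift <- delta * (nu_a + nu_d) / 2    # omegap center = omega - shift
      # departure offsets k: omegap = omega + k*dw with |k*dw + shift| <= hw
      k_lo <- ceiling((-shift - hw) / dw - 1e-12)
      k_hi <- floor((-shift + hw) / dw + 1e-12)
      if (k_lo > k_hi) next
      ks <- k_lo:k_hi
      kv <- kernel_value(0, nu_a, ks * dw, nu_d, params)
      keep <- kv >= params$eps * (1 - 1e-9)
      ks <- ks[keep]
      if (!length(ks)) next
      vals <- kv[keep] * cell
      for (ii in seq_along(ks)) {
        k <- ks[ii]
        # direct: columns at omegap = (i-1+k)*dw >= 0
        i0 <- max(1L, 1L - k); i1 <- min(nf, nf - k)
        if (i0 <= i1) {
          p <- p + 1L
          rows <- i0:i1
          ti[[p]] <- rows + (a_n - 1L) * nf
          tj[[p]] <- rows + k + (d_n - 1L) * nf
          tx[[p]] <- rep(vals[ii], length(rows))
        }
        if (mirror && k <= -1L) {
          # mirrored: omegap = (i-1+k)*dw <= -dw, stored at
          # (-omegap, -nu_d) i.e. column index 1-(i-1+k) = 2-i-k
          i0m <- max(1L, 2L - k - nf); i1m <- min(nf, -k)
          if (i0m <= i1m) {
            rows <- i0m:i1m
            mi[[length(mi) + 1L]] <- rows + (a_n - 1L) * nf
            mj[[length(mj) + 1L]] <- (2L - rows - k) + (nn - d_n) * nf
            mx[[length(mx) + 1L]] <- rep(vals[ii], length(rows))
          }
        }
      }
    }
  }
  nG <- nf * nn
  if (is.null(inert_top)) inert_top <- mirror
  tif <- unlist(ti); tjf <- unlist(tj); txf <- unlist(tx)
  mif <- unlist(mi); mjf <- unlist(mj); mxf <- unlist(mx)
  if (is.null(tif)) { tif <- integer(); tjf <- integer(); txf <- numeric() }
  if (inert_top && nf > 1L) {
    keep_d <- ((tif - 1L) %% nf) + 1L != nf
    tif <- tif[keep_d]; tjf <- tjf[keep_d]; txf <- txf[keep_d]
    if (length(mif)) {
      keep_m <- ((mif - 1L) %% nf) + 1L != nf
      mif <- mif[keep_m]; mjf <- mjf[keep_m]; mxf <- mxf[keep_m]
    }
  }
  direct <- Matrix::sparseMatrix(i = tif, j = tjf, x = txf,
                                 dims = c(nG, nG))
  mirrored <- if (length(mif))
    Matrix::sparseMatrix(i = mif, j = mjf, x = mxf, dims = c(nG, nG))
  else Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(nG, nG))
  structure(list(direct = direct, mirrored = mirrored,
                 row_mass = Matrix::rowSums(direct) +
                   Matrix::rowSums(mirrored),
                 freqs = freqs, nus = nus, params = params,
                 cell_area = cell, mirror = mirror),
            class = "sparse_interaction")
}

#' @export
print.sparse_interaction <- function(x, ...) {
  cat(sprintf(paste0("<sparse_interaction> %d x %d lattice, %d + %d ",
                     "nonzeros, row mass in [%.4g, %.4g]\n"),
              length(x$freqs), length(x$nus),
              length(x$direct@x), length(x$mirrored@x),
              min(x$row_mass), max(x$row_mass)))
  invisible(x)
}

#' Apply a sparse interaction operator to a field
#'
#' Computes the truncated interaction sum for every lattice point. The
#' mirrored part of the operator acts on the complex conjugate of the
#' field, implementing the reach of the interaction across the
#' zero-frequency edge for Hermitian fields. Linear in the field (over
#' the reals); a zero field maps to zero and the output magnitude is
#' bounded by the row mass times the maximum field magnitude.
#'
#' @param K a [build_interaction()] result.
#' @param field complex matrix, `length(freqs) x length(nus)`.
#' @return complex matrix of the same shape.
#' @export
apply_interaction <- function(K, field) {
  stopifnot(inherits(K, "sparse_interaction"))
  nf <- length(K$freqs); nn <- length(K$nus)
  if (!is.matrix(field) || nrow(field) != nf || ncol(field) != nn)
    stop("`field` must be a ", nf, " x ", nn, " matrix")
  fre <- as.vector(Re(field)); fim <- as.vector(Im(field))
  out_re <- as.vector(K$direct %*% fre + K$mirrored %*% fre)
  out_im <- as.vector(K$direct %*% fim - K$mirrored %*% fim)
  matrix(complex(real = out_re, imaginary = out_im), nf, nn)
}

#' Simulate the chirp diffusion underlying the kernel
#'
#' Euler-Maruyama sample paths of `d(omega) = nu dt`,
#' `d(nu) = sqrt(2 b) dW` over one delay, started at `(omegap, nup)`.
#' The endpoint cloud at time `delta` is distributed (up to
#' time-discretisation bias of order `1/n_steps`) according to the
#' closed-form density [kernel_value()], which the test-suite checks by
#' moment matching and a chi-square goodness of fit. With `b = 0` the
#' path is deterministic: the endpoint is `(omegap + nup * delta, nup)`.
#'
#' @param start numeric length-2 vector `(omegap, nup)`.
#' @param params a [kernel_params()] (`eps` is irrelevant here).
#' @param n_paths number of independent paths.
#' @param n_steps Euler steps per path.
#' @param seed optional integer seed.
#' @param b overrides `params$b`, e.g. `b = 0` for the drift-only check.
#' @return `n_paths x 2` matrix of endpoints, columns `omega`, `nu`.
#' @export
simulate_sde <- function(start, params, n_paths = 1e5, n_steps = 256,
                         seed = NULL, b = params$b) {
  stopifnot(length(start) == 2, n_paths >= 1, n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  dt <- params$delta / n_steps
  omega <- rep(start[1], n_paths)
  nu <- rep(start[2], n_paths)
  sig <- sqrt(2 * b * dt)
  for (k in seq_len(n_steps)) {
    omega <- omega + nu * dt
    nu <- if (sig > 0) nu + sig * stats::rnorm(n_paths) else nu
  }
  cbind(omega = omega, nu = nu)
}
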