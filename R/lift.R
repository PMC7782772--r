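#' Chirpiness grid
#'
#' Uniform discretisation of the admissible chirpiness interval
#' `[-nu_max, nu_max]` (Hz/s). The count is odd so that zero chirpiness
#' is a grid point: stationary tones then lift onto an exact bin.
#'
#' @param nu_max half-width of the chirpiness interval in Hz/s (> 0).
#' @param count odd number of grid points (>= 3).
#' @return An object of class `chirpiness_grid` with field `nu_values`.
#' @export
chirpiness_grid <- function(nu_max, count = 33L) {
  count <- as.integer(count)
  if (!is.finite(nu_max) || nu_max <= 0) stop("`nu_max` must be > 0")
  if (count < 3L || count %% 2L == 0L) stop("`count` must be odd and >= 3")
  structure(list(nu_values = seq(-nu_max, nu_max, length.out = count),
                 nu_max = nu_max, count = count),
            class = "chirpiness_grid")
}

#' Gradient of a spectrogram magnitude
#'
#' Central differences of `|S|` on interior points and one-sided
#' differences at the borders, scaled by the grid spacings, giving the
#' partial derivatives with respect to frame time (per second) and bin
#' frequency (per Hz).
#'
#' @param S a [tf_image()] (or a plain numeric matrix with attributes
#'   supplied via `dtau`/`domega`).
#' @param dtau,domega grid spacings; taken from `S` when it is a
#'   `tf_image`.
#' @return list with matrices `dtau` and `domega` of the same shape as
#'   the magnitude.
#' @export
spectrogram_gradient <- function(S, dtau = NULL, domega = NULL) {
  if (inherits(S, "tf_image")) {
    mag <- abs(S$values)
    dtau <- diff(S$times[1:2])
    domega <- diff(S$freqs[1:2])
  } else {
    mag <- abs(S)
    if (is.null(dtau) || is.null(domega))
      stop("`dtau` and `domega` must be given for plain matrices")
  }
  nr <- nrow(mag); nc <- ncol(mag)
  if (nr < 3L || nc < 3L) stop("grid must be at least 3 x 3")
  gt <- matrix(0, nr, nc)
  gw <- matrix(0, nr, nc)
  gt[2:(nr - 1), ] <- (mag[3:nr, ] - mag[1:(nr - 2), ]) / (2 * dtau)
  gt[1, ] <- (mag[2, ] - mag[1, ]) / dtau
  gt[nr, ] <- (mag[nr, ] - mag[nr - 1, ]) / dtau
  gw[, 2:(nc - 1)] <- (mag[, 3:nc] - mag[, 1:(nc - 2)]) / (2 * domega)
  gw[, 1] <- (mag[, 2] - mag[, 1]) / domega
  gw[, nc] <- (mag[, nc] - mag[, nc - 1]) / domega
  list(dtau = gt, domega = gw)
}

#' Chirpiness field from spectrogram gradients
#'
#' Solves the level-line condition `nu * d|S|/domega + d|S|/dtau = 0`
#' for the chirpiness `nu* = -dtau / domega` at every time-frequency
#' point. Where the frequency derivative is below `tol_grad` the contour
#' is (numerically) vertical, the chirpiness diverges, and the point is
#' marked undefined rather than assigned a value.
#'
#' @param gradients output of [spectrogram_gradient()].
#' @param tol_grad absolute threshold on `|domega|`; default `1e-3`
#'   times the maximum `|domega|` over the image. (The two gradient
#'   components carry different units - per second and per Hz - so the
#'   vertical-contour test is made against the frequency component
#'   alone.)
#' @return list with matrix `nu` (Hz/s, `NA` where undefined) and
#'   logical matrix `defined`.
#' @export
chirpiness_field <- function(gradients, tol_grad = NULL) {
  gt <- gradients$dtau
  gw <- gradients$domega
  if (is.null(tol_grad))
    tol_grad <- 1e-3 * max(abs(gw))
  defined <- abs(gw) > tol_grad
  nu <- matrix(NA_real_, nrow(gt), ncol(gt))
  nu[defined] <- -gt[defined] / gw[defined]
  list(nu = nu, defined = defined, tol_grad = tol_grad)
}

#' Automatic chirpiness bound
#'
#' Chooses the half-width of the admissible chirpiness interval from the
#' data: the 99th percentile of `|nu*|` over the bins carrying the top
#' 1% of spectrogram magnitudes, inflated by a small margin so the
#' diffusion has headroom around the strongest ridge slope.
#'
#' @param S a [tf_image()].
#' @param tol_grad passed to [chirpiness_field()].
#' @param margin multiplicative headroom (default 1.25).
#' @return positive scalar, Hz/s.
#' @export
auto_nu_max <- function(S, tol_grad = NULL, margin = 1.25) {
  grad <- spectrogram_gradient(S)
  cf <- chirpiness_field(grad, tol_grad)
  mag <- abs(S$values)
  thr <- stats::quantile(mag, 0.99)
  sel <- cf$defined & mag >= thr
  if (!any(sel)) sel <- cf$defined
  if (!any(sel)) return(1)
  nu_abs <- abs(cf$nu[sel])
  v <- stats::quantile(nu_abs, 0.99, names = FALSE)
  if (!is.finite(v) || v <= 0) v <- max(nu_abs, 1)
  margin * v
}

#' Lifted time-frequency image
#'
#' The spectrogram lifted to the augmented (time, frequency, chirpiness)
#' space: each time-frequency coefficient is carried, in full, by the
#' chirpiness bin nearest its level-line slope, so the field is a
#' discrete Dirac layer over the lift surface and summing over
#' chirpiness recovers the non-dropped coefficients exactly.
#'
#' Points whose chirpiness is undefined (vertical contour) or falls
#' outside the grid are dropped, not clamped: clamping would pile
#' spurious mass at the boundary and bias the transport direction. The
#' zero-frequency and Nyquist rows are always dropped - their content is
#' shared with the mirrored negative-frequency half, and keeping them
#' out preserves the Hermitian symmetry of the lifted field exactly.
#'
#' @param S a [tf_image()].
#' @param grid a [chirpiness_grid()], or `NULL` to choose the bound
#'   automatically via [auto_nu_max()].
#' @param tol_grad vertical-contour threshold, see [chirpiness_field()].
#' @param nu_count grid size used when `grid` is `NULL`.
#' @return An object of class `lifted_image` with the complex array
#'   `values` (frames x bins x chirpiness), the three axes, the bin
#'   assignment matrix `nu_index` (`NA` = dropped) and the fraction of
#'   magnitude mass dropped.
#' @export
lift <- function(S, grid = NULL, tol_grad = NULL, nu_count = 33L) {
  stopifnot(inherits(S, "tf_image"))
  if (is.null(grid))
    grid <- chirpiness_grid(auto_nu_max(S, tol_grad), nu_count)
  stopifnot(inherits(grid, "chirpiness_grid"))
  grad <- spectrogram_gradient(S)
  cf <- chirpiness_field(grad, tol_grad)
  nu_vals <- grid$nu_values
  dnu <- nu_vals[2] - nu_vals[1]
  nt <- nrow(S$values); nf <- ncol(S$values); nn <- grid$count
  idx <- matrix(NA_integer_, nt, nf)
  ok <- cf$defined
  ok[, 1L] <- FALSE          # zero-frequency row: shared with mirror half
  ok[, nf] <- FALSE          # Nyquist row
  bin <- round((cf$nu - nu_vals[1]) / dnu) + 1L
  inside <- ok & !is.na(bin) & bin >= 1L & bin <= nn
  idx[inside] <- as.integer(bin[inside])
  values <- array(0i, dim = c(nt, nf, nn))
  sel <- which(inside)
  if (length(sel)) {
    ti <- ((sel - 1L) %% nt) + 1L
    fi <- ((sel - 1L) %/% nt) + 1L
    values[cbind(ti, fi, idx[sel])] <- S$values[sel]
  }
  mass_total <- sum(abs(S$values))
  mass_kept <- sum(abs(S$values[inside]))
  structure(list(values = values, times = S$times, freqs = S$freqs,
                 nu_values = nu_vals, grid = grid, config = S$config,
                 n_samples = S$n_samples,
                 nu_index = idx, tol_grad = cf$tol_grad,
                 dropped_mass = if (mass_total > 0)
                   1 - mass_kept / mass_total else 0),
            class = "lifted_image")
}

#' @export
print.lifted_image <- function(x, ...) {
  cat(sprintf(paste0("<lifted_image> %d frames x %d bins x %d chirpiness ",
                     "(nu_max %.4g Hz/s), %.2f%% mass dropped\n"),
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$grid$nu_max, 100 * x$dropped_mass))
  invisible(x)
}

#' Project an augmented-space field back to time-frequency
#'
#' Plain summation over the chirpiness axis, the discrete counterpart of
#' integrating the activation in the chirpiness variable. Linear; the
#' projection of a lifted image equals the original image on all
#' non-dropped points.
#'
#' @param x a `lifted_image`, a 3D array (time x frequency x
#'   chirpiness), or a matrix (frequency x chirpiness) holding the field
#'   at a single time.
#' @return a [tf_image()] for a `lifted_image` input; otherwise an array
#'   with the chirpiness axis summed out.
#' @export
project <- function(x) {
  if (inherits(x, "lifted_image")) {
    vals <- rowSums(x$values, dims = 2L)
    return(tf_image(vals, x$times, x$freqs, x$config,
                    n_samples = x$n_samples))
  }
  if (is.array(x) && length(dim(x)) == 3L) return(rowSums(x, dims = 2L))
  if (is.matrix(x)) return(rowSums(x))
  stop("cannot project object of class ", paste(class(x), collapse = "/"))
}
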