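test_that("the sigmoid saturates the modulus and never touches the phase", {
  expect_equal(wc_sigmoid(2 * exp(1i * pi / 4)), exp(1i * pi / 4))
  expect_equal(wc_sigmoid(0.5 + 0i), 0.5 + 0i)
  expect_equal(wc_sigmoid(-3 + 0i), -1 + 0i)
  expect_equal(wc_sigmoid(0i), 0i)
  set.seed(2)
  z <- complex(real = stats::rnorm(100, sd = 2), imaginary = stats::rnorm(100, sd = 2))
  out <- wc_sigmoid(z, kappa = 0.7)
  expect_true(all(Mod(out) <= 1 + 1e-12))
  nz <- Mod(z) > 0
  expect_equal(Arg(out[nz]), Arg(z[nz]), tolerance = 1e-12)
  # conjugation commutes with the sigmoid (phase-only action)
  expect_equal(wc_sigmoid(Conj(z), 0.7), Conj(out), tolerance = 1e-14)
})

test_that("parameter invariants are enforced", {
  expect_error(wc_params(60, 1, 55, 1, delta = 0.064, dt = 0.02), "unstable")
  expect_error(wc_params(55, 1, 55, 1, delta = 0.01, dt = 0.016), "<=")
  expect_warning(wc_params(10, 1, 0, 1, delta = 0.05, dt = 0.016), "snapped")
  p <- wc_params(55, 1, 55, 1, delta = 0.064, dt = 0.016)
  expect_identical(p$delay_steps, 4L)
})

test_that("a single step reproduces the three-term right-hand side", {
  lat <- small_lattice(nf = 7, nn = 5)
  kp <- kernel_params(0.05, 0.064, eps = 1e-6)
  K <- build_interaction(lat$freqs_half, lat$nus, kp, mirror = TRUE)
  p <- wc_params(20, 2, 7, 0.8, delta = 0.064, dt = 0.016)
  set.seed(3)
  rmat <- function() matrix(complex(real = stats::rnorm(35),
                                    imaginary = stats::rnorm(35)), 7, 5)
  a_now <- rmat(); a_del <- rmat(); I_now <- rmat()
  got <- wc_step(a_now, a_del, I_now, p, K)
  # oracle: naive term-by-term recomputation
  inter <- apply_interaction(K, wc_sigmoid(a_del, 0.8))
  want <- a_now + 0.016 * (-20 * a_now + 2 * I_now + 7 * inter)
  expect_equal(got, want, tolerance = 1e-14)
  # pure decay when gamma = 0 and I = 0
  p0 <- wc_params(20, 2, 0, 1, delta = 0.064, dt = 0.016)
  expect_equal(wc_step(a_now, a_del * 0, I_now * 0, p0),
               a_now * (1 - 20 * 0.016), tolerance = 1e-14)
  # sigma(0) = 0 kills the interaction term
  got0 <- wc_step(a_now, a_del * 0, I_now, p, K)
  expect_equal(got0, a_now + 0.016 * (-20 * a_now + 2 * I_now),
               tolerance = 1e-14)
  expect_error(wc_step(a_now * NaN, a_del, I_now, p, K), "finite")
})

test_that("zero input yields the zero trajectory", {
  lat <- small_lattice()
  kp <- kernel_params(0.05, 0.064, eps = 1e-6)
  K <- build_interaction(lat$freqs_half, lat$nus, kp, mirror = TRUE)
  p <- wc_params(55, 1, 55, 1, delta = 0.064, dt = 0.016)
  a <- wc_evolve(array(0i, dim = c(20, lat$nf, lat$nn)), p, K)
  expect_true(all(a$values == 0))
})

test_that("evolution is causal: truncating future input leaves the past unchanged", {
  lat <- small_lattice()
  kp <- kernel_params(0.05, 0.064, eps = 1e-6)
  K <- build_interaction(lat$freqs_half, lat$nus, kp, mirror = TRUE)
  p <- wc_params(55, 1, 55, 1, delta = 0.064, dt = 0.016)
  set.seed(8)
  I_full <- array(complex(real = stats::rnorm(30 * lat$nf * lat$nn),
                          imaginary = stats::rnorm(30 * lat$nf * lat$nn)),
                  dim = c(30, lat$nf, lat$nn))
  I_trunc <- I_full
  I_trunc[21:30, , ] <- 0i
  a_full <- wc_evolve(I_full, p, K)$values
  a_trunc <- wc_evolve(I_trunc, p, K)$values
  expect_identical(a_full[1:20, , ], a_trunc[1:20, , ])
})

test_that("interaction term stays bounded by gamma times the row mass", {
  lat <- small_lattice()
  kp <- kernel_params(0.05, 0.064, eps = 1e-6)
  K <- build_interaction(lat$freqs_half, lat$nus, kp, mirror = TRUE)
  set.seed(12)
  big <- matrix(complex(real = 50 * stats::rnorm(lat$nf * lat$nn),
                        imaginary = 50 * stats::rnorm(lat$nf * lat$nn)),
                lat$nf, lat$nn)
  inter <- apply_interaction(K, wc_sigmoid(big, 1))
  expect_true(all(Mod(as.vector(inter)) <= K$row_mass + 1e-9))
})

test_that("the interaction-free evolution converges to the exponential filter at first order", {
  alpha <- 55; beta <- 1; Tend <- 0.5
  errs <- vapply(c(1 / 256, 1 / 512), function(dt) {
    nT <- round(Tend / dt)
    I <- array(1 + 0i, dim = c(nT, 1, 1))
    p <- wc_params(alpha, beta, 0, 1, delta = 16 * dt, dt = dt)
    a <- wc_evolve(I, p)$values[, 1, 1]
    exact <- lowpass_reference(rep(1 + 0i, nT), alpha, beta, dt)
    max(Mod(a - exact))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_gt(errs[1] / errs[2], 1.8)
  expect_lt(errs[1] / errs[2], 2.2)
})

test_that("the exponential filter reference has the right impulse response", {
  alpha <- 12; dt <- 0.01
  I <- c(1, rep(0, 49))
  tr <- lowpass_reference(I, alpha, beta = 1, dt = dt)
  # shape: exponential decay exp(-alpha t) step to step
  expect_equal(tr[-1] / tr[-50], rep(exp(-alpha * dt), 49), tolerance = 1e-12)
  expect_true(all(lowpass_reference(rep(0, 20), alpha, 1, dt) == 0))
  # closed form for a constant input
  trc <- lowpass_reference(rep(1, 300), alpha, beta = 2, dt = dt)
  t <- (1:300) * dt
  expect_equal(trc, 2 / alpha * (1 - exp(-alpha * t)), tolerance = 1e-12)
})

test_that("Hermitian inputs evolve Hermitianly; the half-lattice mirror operator agrees with the full lattice", {
  lat <- small_lattice()
  kp <- kernel_params(0.05, 0.064, eps = 1e-6)
  # the top row of this abstract lattice is a plain edge, not a shared
  # Nyquist coefficient, so it is evolved like any other row
  K_half <- build_interaction(lat$freqs_half, lat$nus, kp, mirror = TRUE,
                              inert_top = FALSE)
  K_full <- build_interaction(lat$freqs_full, lat$nus, kp, mirror = FALSE)
  nf_full <- 2 * lat$nf - 1
  set.seed(1)
  nT <- 12
  If <- array(0i, dim = c(nT, nf_full, lat$nn))
  for (tt in seq_len(nT))
    If[tt, , ] <- random_hermitian_field(nf_full, lat$nn)
  p <- wc_params(55, 1, 55, 1, delta = 0.064, dt = 0.016)
  af <- wc_evolve(If, p, K_full)$values
  flipped <- Conj(af[, rev(seq_len(nf_full)), rev(seq_len(lat$nn)), drop = FALSE])
  expect_lt(max(Mod(af - flipped)), 1e-13 * max(Mod(af)))
  ah <- wc_evolve(If[, lat$nf:nf_full, , drop = FALSE], p, K_half)$values
  expect_lt(max(Mod(ah - af[, lat$nf:nf_full, , drop = FALSE])),
            1e-13 * max(Mod(af)))
})
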