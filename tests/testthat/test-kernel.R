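test_that("the kernel quadratic form matches hand values and is non-negative", {
  expect_equal(g_delta(2, 0, 2, 0, 0.5), 0)
  expect_equal(g_delta(0, 1, 0, 1, 1), 3)     # delta^2 (1 + 1 + 1)
  expect_equal(g_delta(1, 0, 0, 0, 1), 3)     # 3 * 1^2
  set.seed(11)
  for (i in 1:200) {
    v <- stats::rnorm(4, sd = 5)
    expect_gte(g_delta(v[1], v[2], v[3], v[4], stats::runif(1, 0.01, 2)), 0)
  }
})

test_that("kernel peak value and location follow the closed form", {
  kp <- kernel_params(1, 1)
  expect_equal(kernel_value(0, 0, 0, 0, kp), sqrt(3) / (2 * pi),
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    b <- stats::runif(1, 0.01, 1); d <- stats::runif(1, 0.02, 0.5)
    kp <- kernel_params(b, d)
    om <- stats::rnorm(1); nu <- stats::rnorm(1)
    # degenerate point of the truncated support at eps = max
    expect_equal(kernel_value(om, nu, om - d * nu, nu, kp), kernel_max(kp),
                 tolerance = 1e-12)
    # bounded by the maximum everywhere
    pts <- matrix(stats::rnorm(40), ncol = 2)
    expect_true(all(kernel_value(om, nu, pts[, 1], pts[, 2], kp) <=
                      kernel_max(kp) * (1 + 1e-12)))
  }
})

test_that("kernel satisfies the mirror symmetry used for real signals", {
  set.seed(9)
  for (i in 1:50) {
    kp <- kernel_params(stats::runif(1, 0.01, 1), stats::runif(1, 0.02, 0.5))
    v <- stats::rnorm(4, sd = 2)
    expect_equal(kernel_value(-v[1], -v[2], v[3], v[4], kp),
                 kernel_value(v[1], v[2], -v[3], -v[4], kp),
                 tolerance = 1e-14)
  }
})

test_that("kernel integrates to one over the arrival plane", {
  for (b in c(0.01, 0.2)) for (d in c(0.03125, 0.125)) {
    kp <- kernel_params(b, d)
    sd_nu <- sqrt(2 * b * d); sd_om <- sqrt(2 * b * d^3 / 3)
    om <- seq(-8 * sd_om, 8 * sd_om, length.out = 401)
    nu <- seq(-8 * sd_nu, 8 * sd_nu, length.out = 401)
    kv <- outer(om, nu, function(o, v) kernel_value(o, v, 0, 0, kp))
    I <- sum(kv) * diff(om[1:2]) * diff(nu[1:2])
    expect_lt(abs(I - 1), 1e-6)
  }
})

test_that("support bounds reproduce the degenerate and analytic cases", {
  kp <- kernel_params(1, 1, eps = sqrt(3) / (2 * pi))    # eps = max
  sb <- support_bounds(2, 0.5, kp)
  expect_equal(sb$C_eps, 0, tolerance = 1e-12)
  expect_equal(sb$nu_range, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sb$omega_center(0.5), 2 - 1 * 0.5)
  kp2 <- kernel_params(1, 1, eps = sqrt(3) / (2 * pi) / exp(1))
  expect_equal(support_bounds(0, 0, kp2)$C_eps, 4, tolerance = 1e-12)
  # above the maximum: empty region
  kp3 <- kernel_params(1, 1, eps = 2 * sqrt(3) / (2 * pi))
  expect_lt(support_bounds(0, 0, kp3)$C_eps, 0)
})

test_that("support bounds equal brute-force kernel thresholding on lattices", {
  set.seed(21)
  for (i in 1:5) {
    b <- stats::runif(1, 0.01, 1); d <- stats::runif(1, 0.03, 0.2)
    om <- stats::rnorm(1); nu <- stats::rnorm(1)
    kp0 <- kernel_params(b, d)
    kp <- kernel_params(b, d, eps = kp0$kmax * 10^stats::runif(1, -6, -0.2))
    sb <- support_bounds(om, nu, kp)
    hw_nu <- sqrt(sb$C_eps)
    hw_om <- d / (2 * sqrt(3)) * hw_nu
    nug <- seq(nu - 1.3 * hw_nu, nu + 1.3 * hw_nu, length.out = 41)
    ctr <- sb$omega_center(nu)
    span <- 2 * hw_om + d * hw_nu
    omg <- seq(ctr - span, ctr + span, length.out = 41)
    brute <- outer(omg, nug,
                   function(o, v) kernel_value(om, nu, o, v, kp) >= kp$eps)
    pred <- outer(omg, nug, function(o, v) sb$contains(o, v))
    expect_identical(sum(brute != pred), 0L)
  }
})

test_that("sparse interaction tables hold unit-mass rows on ample lattices", {
  kp <- kernel_params(0.05, 0.0625, eps = 1e-6 * sqrt(3) / (2 * pi * 0.05 * 0.0625^2))
  freqs <- seq(-0.5, 0.5, length.out = 201)
  nus <- seq(-0.5, 0.5, length.out = 81)
  K <- build_interaction(freqs, nus, kp, mirror = FALSE)
  # interior rows: support fully inside the lattice
  centre_rows <- which(abs(rep(freqs, times = 81)) < 0.2 &
                         abs(rep(nus, each = 201)) < 0.2)
  expect_lt(max(abs(K$row_mass[centre_rows] - 1)), 0.02)
  expect_true(all(K$row_mass <= 1 + 0.02))
  expect_true(all(K$direct@x >= kp$eps * K$cell_area * (1 - 1e-9)))
})

test_that("an over-threshold truncation empties every table with a warning", {
  kp <- kernel_params(1, 1, eps = 1.5 * sqrt(3) / (2 * pi))
  expect_warning(
    K <- build_interaction(seq(0, 1, 0.1), seq(-1, 1, 0.25), kp),
    "empty")
  expect_identical(length(K$direct@x), 0L)
  expect_true(all(K$row_mass == 0))
})

test_that("interaction support is transported against the drift", {
  # for the row at (omega, nu), the column band evaluated at nu' = nu
  # is centred at omega - delta * nu
  kp <- kernel_params(0.05, 0.0625)
  freqs <- seq(0, 1, length.out = 401)
  nus <- seq(-0.5, 0.5, length.out = 41)
  K <- build_interaction(freqs, nus, kp, mirror = FALSE)
  nf <- length(freqs)
  i_f <- 200; i_n <- 36                     # nu = 0.375, away from edges
  row <- K$direct[i_f + (i_n - 1) * nf, ]
  cols <- which(row != 0)
  same_nu <- cols[((cols - 1) %/% nf) + 1 == i_n]
  expect_gt(length(same_nu), 0)
  centre <- mean(freqs[((same_nu - 1) %% nf) + 1])
  expect_equal(centre, freqs[i_f] - kp$delta * nus[i_n],
               tolerance = 2 * diff(freqs[1:2]))
})

test_that("applying the interaction matches a dense quadrature sum", {
  lat <- small_lattice(nf = 15, nn = 9, f_max = 0.6, nu_max = 0.4)
  kp <- kernel_params(0.05, 0.0625, eps = 1e-8)
  K <- build_interaction(lat$freqs_half, lat$nus, kp, mirror = FALSE)
  set.seed(5)
  f <- matrix(complex(real = stats::rnorm(15 * 9),
                      imaginary = stats::rnorm(15 * 9)), 15, 9)
  out <- apply_interaction(K, f)
  # dense oracle: full double sum over the lattice, no truncation
  dw <- diff(lat$freqs_half[1:2]); dn <- diff(lat$nus[1:2])
  dense <- matrix(0i, 15, 9)
  for (i in 1:15) for (j in 1:9) {
    kv <- outer(lat$freqs_half, lat$nus,
                function(o, v) kernel_value(lat$freqs_half[i], lat$nus[j],
                                            o, v, kp))
    dense[i, j] <- sum(kv * f) * dw * dn
  }
  expect_lt(max(Mod(out - dense)),
            kp$eps * (0.6 * 0.8) * max(Mod(f)) + 1e-12)
  # linearity and the zero/ones identities
  expect_true(all(apply_interaction(K, matrix(0i, 15, 9)) == 0))
  ones <- matrix(1 + 0i, 15, 9)
  expect_equal(as.vector(Re(apply_interaction(K, ones))),
               as.vector(K$row_mass), tolerance = 1e-12)
  expect_error(apply_interaction(K, matrix(0i, 3, 3)), "matrix")
})

test_that("drift-only stochastic paths land exactly at the transported point", {
  kp <- kernel_params(0.05, 0.0625)
  ep <- simulate_sde(c(0.2, -0.4), kp, n_paths = 10, n_steps = 64, b = 0)
  expect_equal(unname(ep[, 1]), rep(0.2 - 0.4 * 0.0625, 10), tolerance = 1e-14)
  expect_equal(unname(ep[, 2]), rep(-0.4, 10))
})

test_that("stochastic endpoint chirpiness variance matches the kernel variance", {
  kp <- kernel_params(0.05, 0.0625)
  ep <- simulate_sde(c(0.3, -0.5), kp, n_paths = 2e4, n_steps = 128, seed = 77)
  v <- stats::var(ep[, "nu"])
  tgt <- 2 * kp$b * kp$delta
  se <- tgt * sqrt(2 / (nrow(ep) - 1))
  expect_lt(abs(v - tgt), 3 * se)
  expect_identical(ep, simulate_sde(c(0.3, -0.5), kp, n_paths = 2e4,
                                    n_steps = 128, seed = 77))
})
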