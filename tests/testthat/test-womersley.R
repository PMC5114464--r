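test_that("Womersley number arithmetic and the physiological range", {
  st <- pulsatile_settings()
  expect_equal(st$omega, 2 * pi * 1.25)
  # r = 1 mm, omega = 2*pi*1.25, rho = 1060, mu = 0.0035
  expect_equal(womersley_alpha(1, st),
               1e-3 * sqrt(2 * pi * 1.25 * 1060 / 0.0035), tolerance = 1e-12)
  expect_equal(womersley_alpha(1, st), 1.54, tolerance = 1e-2)
  expect_equal(womersley_alpha(2, st), 2 * womersley_alpha(1, st))
  a <- womersley_alpha(c(0.05, 2.5), st)
  expect_true(all(a >= 0.01 & a <= 10))
  # harmonic index scales omega linearly
  st4 <- pulsatile_settings(harmonic = 4)
  expect_equal(womersley_alpha(1, st4), 2 * womersley_alpha(1, st))
  expect_error(pulsatile_settings(nu_poisson = 0.7), "nu_poisson")
  expect_error(womersley_alpha(-1), "positive")
})

test_that("oscillatory factors match an independent Bessel quadrature", {
  set.seed(5)
  alpha <- exp(runif(20, log(0.05), log(20)))
  got <- m0_eps(alpha)
  ref <- oracle_m0_eps(alpha)
  expect_lt(max(abs(got$M0p - Mod(ref)) / Mod(ref)), 1e-8)
  expect_lt(max(abs(got$eps0 - Arg(ref))), 1e-8)
})

test_that("oscillatory factors have the right limits and monotonicity", {
  lo <- m0_eps(0.01)
  expect_equal(lo$M0p / (0.01^2 / 8), 1, tolerance = 0.01)
  expect_equal(lo$eps0, pi / 2, tolerance = 1e-4)
  hi <- m0_eps(50)
  # large-alpha asymptotics: 1 - M0' ~ sqrt(2)/alpha
  expect_lt(1 - hi$M0p, 0.03)
  expect_lt(hi$eps0, 0.09)
  grid <- m0_eps(exp(seq(log(0.02), log(60), length.out = 200)))
  expect_true(all(diff(grid$M0p) > 0))
  expect_true(all(diff(grid$eps0) < 0))
  expect_true(all(grid$M0p > 0 & grid$M0p <= 1))
  expect_true(all(grid$eps0 >= 0 & grid$eps0 <= pi / 2))
})

test_that("daughter Womersley numbers follow the junction geometry", {
  d <- daughter_alphas(10, 1, 1)
  expect_equal(d$alpha_d1, 10 / sqrt(2), tolerance = 1e-12)
  expect_equal(d$alpha_d2, 10 / sqrt(2), tolerance = 1e-12)
  # continuation limit
  d0 <- daughter_alphas(10, 1, 1e-12)
  expect_equal(d0$alpha_d1, 10, tolerance = 1e-6)
  # consistency with alpha computed from the daughter radii
  st <- pulsatile_settings()
  r_m <- 0.8
  sig <- 1.15; g <- 0.6
  A_m <- pi * r_m^2
  r_d1 <- sqrt(A_m * sig / (1 + g) / pi)
  r_d2 <- sqrt(g * A_m * sig / (1 + g) / pi)
  am <- womersley_alpha(r_m, st)
  d2 <- daughter_alphas(am, sig, g)
  expect_equal(d2$alpha_d1, womersley_alpha(r_d1, st), tolerance = 1e-12)
  expect_equal(d2$alpha_d2, womersley_alpha(r_d2, st), tolerance = 1e-12)
})

test_that("complex impedance reduces to the inviscid form at high alpha", {
  f <- m0_eps(5000)
  z <- pulsatile_impedance(1, 20, rho = 1060, nu_poisson = 0.5, factors = f)
  expect_equal(Mod(z), 1060 * 20 / 1e-6 / sqrt(1 - 0.25), tolerance = 1e-3)
  expect_equal(Arg(z), 0, tolerance = 1e-3)
  # halving the area doubles the modulus
  f1 <- m0_eps(1.3)
  expect_equal(Mod(pulsatile_impedance(0.5, 20, factors = f1)),
               2 * Mod(pulsatile_impedance(1, 20, factors = f1)))
  # uniform Poisson factor cancels in impedance ratios
  za <- pulsatile_impedance(1, 20, nu_poisson = 0.5, factors = f1) /
    pulsatile_impedance(2, 18, nu_poisson = 0.5, factors = m0_eps(2))
  zb <- pulsatile_impedance(1, 20, nu_poisson = 0.2, factors = f1) /
    pulsatile_impedance(2, 18, nu_poisson = 0.2, factors = m0_eps(2))
  expect_equal(za, zb, tolerance = 1e-12)
})

test_that("pulsatile forward reflection reduces to steady at high alpha", {
  g <- seq(0.1, 1, length.out = 10)
  for (tau in c(2, 7 / 3, 3)) {
    rf <- pulsatile_forward_reflection(sigma_of_gamma(g, tau), g, tau,
                                       alpha_m = 50)
    expect_lt(max(Mod(rf)), 0.02)
  }
  # symmetric daughters see identical factors
  rf1 <- pulsatile_forward_reflection(1.2, 1, 7 / 3, alpha_m = 2)
  d <- daughter_alphas(2, 1.2, 1)
  expect_equal(d$alpha_d1, d$alpha_d2)
  # steady sigma under-matches at low alpha: Re(D) < 1
  sig <- sigma_of_gamma(0.6, 7 / 3)
  D <- (sig / 1.6)^(7 / 6) *
    corowave:::.pulsatile_S(sig, 0.6, 7 / 3, alpha_m = 0.1)
  expect_lt(Re(D), 1)
})

test_that("pulsatile well-matched area ratio: limits, monotonicity, residual", {
  g <- seq(0.05, 1, length.out = 12)
  for (tau in c(2, 7 / 3, 3)) {
    s_hi <- sigma_of_gamma_pulsatile(g, tau, 50)
    expect_lt(max(abs(s_hi / sigma_of_gamma(g, tau) - 1)), 0.01)
    # low-alpha limit equals the steady curve with exponent tau + 1
    # (independent closed-form oracle)
    s_lo <- sigma_of_gamma_pulsatile(g, tau, 0.01)
    expect_lt(max(abs(s_lo / sigma_of_gamma(g, tau + 1) - 1)), 1e-4)
  }
  # pulsatility always raises the required area ratio
  expect_gt(min(sigma_of_gamma_pulsatile(g, 7 / 3, 0.1) /
                sigma_of_gamma_pulsatile(g, 7 / 3, 10)), 1)
  # non-increasing in alpha
  alphas <- exp(seq(log(0.01), log(50), length.out = 15))
  for (gg in c(0.2, 0.6, 1)) {
    s <- sigma_of_gamma_pulsatile(rep(gg, 15), 7 / 3, alphas)
    expect_true(all(diff(s) <= 1e-12))
  }
  # defining condition Re(D) = 1 at the fixed point
  s <- sigma_of_gamma_pulsatile(g, 7 / 3, 0.7)
  D <- (s / (1 + g))^(7 / 6) * corowave:::.pulsatile_S(s, g, 7 / 3, 0.7)
  expect_lt(max(abs(Re(D) - 1)), 1e-8)
  # deterministic and idempotent to the solver tolerance
  expect_identical(s, sigma_of_gamma_pulsatile(g, 7 / 3, 0.7))
})

test_that("sigma-gamma band spans the Womersley range and contains steady", {
  band <- sigma_gamma_band(7 / 3, c(0.01, 10), n_gamma = 30, n_alpha = 8)
  steady <- sigma_of_gamma(band$gamma, 7 / 3)
  expect_true(all(in_band(band, band$gamma, steady)))
  # steady curve is the alpha -> infinity member: it is the lower edge
  expect_equal(band$sigma_min, steady, tolerance = 1e-12)
  expect_true(all(band$sigma_max >= band$sigma_min))
  # Murray and HK bands overlap partially
  mur <- sigma_gamma_band(3, c(0.01, 10), n_gamma = 30, n_alpha = 8)
  overlap <- mur$sigma_min <= band$sigma_max & band$sigma_min <= mur$sigma_max
  expect_true(any(overlap))
  expect_false(all(in_band(band, mur$gamma, mur$sigma_max)))
})
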