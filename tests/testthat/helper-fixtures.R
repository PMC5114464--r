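# Shared fixtures, built once per test run and memoized. The default-config
# tree is large (~9e5 segments, ~40 s to grow), so every test that needs the
# stated default world shares a single instance.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

default_tree <- function() {
  memo("default_tree", function() generate_tree(synthetic_config(seed = 101)))
}

default_bifurcations <- function() {
  memo("default_bif", function() extract_bifurcations(default_tree()))
}

# small steady-HK tree: fast, exact sigma-gamma curve, ~1e3 segments
hk_tree <- function(seed = 11, r_min = 0.15) {
  memo(paste0("hk_", seed, "_", r_min), function() {
    generate_tree(synthetic_config(
      seed = seed, r_min = r_min,
      matching_law = list(type = "steady", tau = 7 / 3)))
  })
}

# minimal hand-built 3-segment tree (one bifurcation)
tiny_tree <- function() {
  vascular_tree(data.frame(
    id = c("m", "a", "b"), parent = c(NA, "m", "m"),
    radius_mm = c(1, 0.8, 0.6), length_mm = c(10, 8, 6),
    stringsAsFactors = FALSE))
}

# independent oracle for the Womersley factors: J0 and J1 of complex argument
# by trapezoidal quadrature of the integral representations
#   J0(z) = (1/pi) int_0^pi cos(z sin t) dt
#   J1(z) = (1/pi) int_0^pi cos(t - z sin t) dt
# (spectrally accurate for these periodic analytic integrands), assembled
# into 1 - F10 without using any package code path.
oracle_m0_eps <- function(alpha, n_quad = 4000) {
  vapply(alpha, function(a) {
    z <- complex(modulus = a, argument = 3 * pi / 4)
    t <- seq(0, pi, length.out = n_quad + 1)
    w <- rep(1, n_quad + 1); w[c(1, n_quad + 1)] <- 0.5
    h <- pi / n_quad
    J0 <- sum(w * cos(z * sin(t))) * h / pi
    J1 <- sum(w * cos(t - z * sin(t))) * h / pi
    1 - 2 * J1 / (z * J0)
  }, complex(1))
}
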