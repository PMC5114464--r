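#' Settings for pulsatile (Womersley) analysis
#'
#' Bundles the fluid and wall parameters entering the oscillatory-flow
#' analysis. The default frequency is the heartbeat fundamental at 75 beats
#' per minute; `harmonic` scales the angular frequency for higher harmonics,
#' since the physiological Womersley-number range (0.01-10 in the coronary
#' tree) reflects several harmonics, not just the fundamental.
#'
#' @param heart_rate heart rate in min^-1 (default 75).
#' @param harmonic positive integer harmonic index (default 1).
#' @param mu dynamic viscosity of blood in Pa s (default 0.0035).
#' @param rho blood density in kg/m^3 (default 1060).
#' @param nu_poisson wall Poisson ratio in \[0, 0.5\]; 0.5 for a nearly
#'   incompressible biological wall.
#' @return list of class `pulsatile_settings` with the above plus `omega`
#'   (angular frequency, rad/s).
#' @export
pulsatile_settings <- function(heart_rate = 75, harmonic = 1, mu = 0.0035,
                               rho = 1060, nu_poisson = 0.5) {
  stopifnot(heart_rate > 0, harmonic >= 1, mu > 0, rho > 0,
            nu_poisson >= 0, nu_poisson <= 0.5)
  structure(list(heart_rate = heart_rate, harmonic = harmonic,
                 omega = 2 * pi * (heart_rate / 60) * harmonic,
                 mu = mu, rho = rho, nu_poisson = nu_poisson),
            class = "pulsatile_settings")
}

#' Womersley number of a vessel
#'
#' \eqn{\alpha = r \sqrt{\omega \rho / \mu}}: the ratio of oscillatory
#' inertia to viscous forces. With default settings, coronary radii between
#' 0.05 and 2.5 mm give alpha between roughly 0.08 and 3.9, inside the
#' physiological coronary range 0.01-10.
#'
#' @param radius_mm vessel radius in mm.
#' @param settings a [pulsatile_settings()] object.
#' @return Womersley number(s).
#' @export
womersley_alpha <- function(radius_mm, settings = pulsatile_settings()) {
  if (any(radius_mm <= 0)) stop("radius must be positive")
  (radius_mm * 1e-3) * sqrt(settings$omega * settings$rho / settings$mu)
}

# F10(z) = 2 J1(z) / (z J0(z)) for complex z, vectorized. Power series for
# |z| <= 9 (fixed term count reaches machine precision there; cancellation is
# mild for arg(z) = 3pi/4), Lentz continued fraction above.
.f10 <- function(z) {
  out <- complex(length(z))
  small <- Mod(z) <= 9
  if (any(small)) {
    # F10 = (J1(z)/(z/2)) / J0(z); both series in q = -z^2/4. Term count per
    # magnitude tier: the k-th term is ~ (|z|^2/4)^k / (k!)^2, so 10/20/40
    # terms reach machine precision for |z| <= 1.5 / 4 / 9.
    series <- function(zz, kmax) {
      q <- -zz^2 / 4
      j0 <- complex(real = rep(1, length(q)))
      j1h <- j0
      term0 <- j0
      term1 <- j0
      for (k in seq_len(kmax)) {
        term0 <- term0 * q / k^2            # J0 terms: q^k / (k!)^2
        term1 <- term1 * q / (k * (k + 1))  # J1/(z/2): q^k / (k!(k+1)!)
        j0 <- j0 + term0
        j1h <- j1h + term1
      }
      j1h / j0
    }
    mz <- Mod(z)
    for (tier in list(c(0, 1.5, 10), c(1.5, 4, 20), c(4, 9, 40))) {
      sel <- mz > tier[1] & mz <= tier[2]
      if (any(sel)) out[sel] <- series(z[sel], tier[3])
    }
  }
  if (any(!small)) {
    out[!small] <- (2 / z[!small]) * .besselj_ratio(z[!small])
  }
  out
}

# J1(z)/J0(z) by the modified Lentz continued fraction for the Bessel ratio
# (Gautschi minimal solution), vectorized over complex z. Converges for all z
# off the zeros of J0; iteration count grows like max |z|.
.besselj_ratio <- function(z) {
  n <- length(z)
  tiny <- 1e-30
  f <- rep(complex(real = tiny), n)
  C <- f
  D <- rep(complex(real = 0), n)
  active <- rep(TRUE, n)
  k <- 1
  while (any(active)) {
    if (k > 20000) stop("Bessel-ratio continued fraction failed to converge")
    b <- 2 * k / z[active]
    a <- if (k == 1) 1 else -1
    Da <- b + a * D[active]
    Da[Mod(Da) < tiny] <- tiny
    Ca <- b + a / C[active]
    Ca[Mod(Ca) < tiny] <- tiny
    Da <- 1 / Da
    delta <- Ca * Da
    f[active] <- f[active] * delta
    C[active] <- Ca
    D[active] <- Da
    active[active] <- Mod(delta - 1) >= 4 * .Machine$double.eps
    k <- k + 1
  }
  f
}

#' Womersley modulus and phase factors
#'
#' The oscillatory velocity profile enters the characteristic impedance
#' through \eqn{M_0' e^{i\epsilon_0} = 1 - F_{10}(\alpha)} with
#' \deqn{F_{10}(\alpha) = \frac{2 J_1(i^{3/2}\alpha)}
#'       {i^{3/2}\alpha\, J_0(i^{3/2}\alpha)}.}
#' Evaluated analytically with complex Bessel functions (continued-fraction
#' ratio), not by interpolating printed tables. Limits: \eqn{M_0' \to
#' \alpha^2/8}, \eqn{\epsilon_0 \to \pi/2} as \eqn{\alpha \to 0};
#' \eqn{M_0' \to 1}, \eqn{\epsilon_0 \to 0} as \eqn{\alpha \to \infty}.
#' `M0p` is strictly increasing and `eps0` strictly decreasing in alpha.
#'
#' @param alpha Womersley number(s), > 0.
#' @return data.frame with columns `alpha`, `M0p` (modulus, in (0, 1\])
#'   and `eps0` (phase, radians, in \[0, pi/2\]).
#' @export
m0_eps <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  w <- .m0_eps_w(alpha)
  data.frame(alpha = alpha, M0p = Mod(w), eps0 = Arg(w))
}

# complex M0' e^{i eps0} = 1 - F10(i^{3/2} alpha), no data.frame overhead
.m0_eps_w <- function(alpha) {
  z <- complex(modulus = alpha, argument = 3 * pi / 4)  # i^(3/2) * alpha
  1 - .f10(z)
}

#' Womersley numbers of the daughter vessels
#'
#' Given the mother's Womersley number and the junction's (sigma, gamma),
#' \deqn{\alpha_{d1} = \alpha_m \sqrt{\sigma/(1+\gamma)}, \qquad
#'       \alpha_{d2} = \alpha_m \sqrt{\sigma\gamma/(1+\gamma)},}
#' i.e. alpha scales with the daughter radius.
#'
#' @param alpha_m mother Womersley number, > 0.
#' @param sigma area ratio, > 0.
#' @param gamma symmetry ratio in (0, 1\].
#' @return data.frame with columns `alpha_d1`, `alpha_d2`.
#' @export
daughter_alphas <- function(alpha_m, sigma, gamma) {
  if (any(alpha_m <= 0) || any(sigma <= 0)) {
    stop("alpha_m and sigma must be positive")
  }
  if (any(gamma <= 0 | gamma > 1)) stop("gamma must lie in (0, 1]")
  data.frame(alpha_d1 = alpha_m * sqrt(sigma / (1 + gamma)),
             alpha_d2 = alpha_m * sqrt(sigma * gamma / (1 + gamma)))
}

#' Complex characteristic impedance with Womersley factors
#'
#' The general (finite-alpha) characteristic impedance
#' \deqn{Z_0 = \frac{\rho c_0}{A_0}\,
#'       \left[M_0'(1-\nu^2)\right]^{-1/2} e^{-i\epsilon_0/2}.}
#' Reduces to \eqn{\rho c_0/A_0 (1-\nu^2)^{-1/2}} with zero phase as
#' \eqn{\alpha \to \infty}. In reflection-coefficient ratios with uniform
#' Poisson ratio, the \eqn{(1-\nu^2)} factor cancels.
#'
#' @param A0_mm2 reference area in mm^2.
#' @param c0 pulse wave speed in m/s.
#' @param rho blood density, kg/m^3.
#' @param nu_poisson wall Poisson ratio.
#' @param factors one-row result of [m0_eps()] (or a list with `M0p`, `eps0`).
#' @return complex impedance in Pa s/m^3.
#' @export
pulsatile_impedance <- function(A0_mm2, c0, rho = 1060, nu_poisson = 0.5,
                                factors) {
  if (any(A0_mm2 <= 0) || any(c0 <= 0)) stop("A0 and c0 must be positive")
  (rho * c0 / (A0_mm2 * 1e-6)) *
    (factors$M0p * (1 - nu_poisson^2))^(-1 / 2) *
    exp(complex(imaginary = -factors$eps0 / 2))
}

# complex admittance-sum factor of the pulsatile junction condition:
# S = sqrt(M'_d1/M'_m) e^{-i(eps_d1 - eps_m)/2}
#   + gamma^{tau/2} sqrt(M'_d2/M'_m) e^{-i(eps_d2 - eps_m)/2}
# Only Re(S) enters the well-matchedness condition; uniform Poisson-ratio
# factors cancel. `wm` allows the (sigma-independent) mother factors to be
# precomputed across fixed-point iterations.
.pulsatile_S <- function(sigma, gamma, tau, alpha_m, wm = .m0_eps_w(alpha_m)) {
  a_d1 <- alpha_m * sqrt(sigma / (1 + gamma))
  a_d2 <- alpha_m * sqrt(sigma * gamma / (1 + gamma))
  w1 <- .m0_eps_w(a_d1)
  w2 <- .m0_eps_w(a_d2)
  Mm <- Mod(wm); em <- Arg(wm)
  sqrt(Mod(w1) / Mm) * exp(complex(imaginary = -(Arg(w1) - em) / 2)) +
    gamma^(tau / 2) * sqrt(Mod(w2) / Mm) *
      exp(complex(imaginary = -(Arg(w2) - em) / 2))
}

#' Complex forward reflection coefficient under pulsatile flow
#'
#' Generalizes the steady (sigma, gamma) reflection formula to finite
#' Womersley number: \eqn{R_f = (1 - D)/(1 + D)} with
#' \deqn{D = \left(\frac{\sigma}{1+\gamma}\right)^{\tau/2} S(\alpha_m, \sigma,
#'       \gamma, \tau)} where `S` carries the daughter/mother ratios of the
#' Womersley modulus and phase factors. No reflection occurs when
#' \eqn{Re(D) = 1}. As \eqn{\alpha_m \to \infty} this reduces to the steady
#' formula.
#'
#' @inheritParams daughter_alphas
#' @param tau scaling exponent coupling wave speed to area.
#' @param settings a [pulsatile_settings()] object; with a uniform Poisson
#'   ratio it does not affect the ratio and is accepted for interface
#'   symmetry.
#' @return complex reflection coefficient(s).
#' @export
pulsatile_forward_reflection <- function(sigma, gamma, tau, alpha_m,
                                         settings = pulsatile_settings()) {
  D <- (sigma / (1 + gamma))^(tau / 2) *
    .pulsatile_S(sigma, gamma, tau, alpha_m)
  (1 - D) / (1 + D)
}

#' Pulsatile well-matched area ratio
#'
#' Solves the finite-alpha well-matchedness condition \eqn{Re(D) = 1} for the
#' area ratio:
#' \deqn{\sigma = (1+\gamma)\,\left[Re\, S(\sigma)\right]^{-2/\tau},}
#' a fixed-point problem because the daughter Womersley numbers depend on
#' sigma. Iteration starts from the steady solution [sigma_of_gamma()] and
#' uses deterministic Steffensen acceleration (equivalent to the plain damped
#' iteration but shorter); convergence is declared when successive iterates
#' and the plain-update residual are both below `tol`. The result is
#' non-increasing in alpha: lower Womersley numbers (smaller vessels) need
#' larger area ratios to stay reflection-free.
#'
#' @inheritParams pulsatile_forward_reflection
#' @param tol convergence tolerance on successive iterates.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   iterate trace.
#' @return area ratio(s) sigma (vectorized over `gamma`).
#' @export
sigma_of_gamma_pulsatile <- function(gamma, tau, alpha_m,
                                     settings = pulsatile_settings(),
                                     tol = 1e-10, max_iter = 200) {
  if (any(alpha_m <= 0)) stop("alpha_m must be positive")
  if (any(gamma <= 0 | gamma > 1)) stop("gamma must lie in (0, 1]")
  n <- max(length(gamma), length(tau), length(alpha_m))
  g <- rep_len(gamma, n)
  tt <- rep_len(tau, n)
  am <- rep_len(alpha_m, n)
  sig <- sigma_of_gamma(g, tt)
  active <- rep(TRUE, n)
  last <- sig
  wm <- .m0_eps_w(am)
  fp_step <- function(s, idx) {
    S <- Re(.pulsatile_S(s, g[idx], tt[idx], am[idx], wm[idx]))
    if (any(!is.finite(S) | S <= 0)) {
      stop("pulsatile fixed point: nonpositive Re(S) at sigma = ",
           s[which(!is.finite(S) | S <= 0)[1]])
    }
    (1 + g[idx]) * S^(-2 / tt[idx])
  }
  # Steffensen-accelerated fixed point: two plain updates, then the Aitken
  # extrapolate (falling back to the plain update if degenerate). The plain
  # map is a damped contraction here, so acceleration only shortens the
  # deterministic path to the same fixed point.
  for (k in seq_len(max_iter)) {
    idx <- which(active)
    s0 <- sig[idx]
    s1 <- fp_step(s0, idx)
    s2 <- fp_step(s1, idx)
    den <- s2 - 2 * s1 + s0
    acc <- s0 - (s1 - s0)^2 / den
    bad <- !is.finite(acc) | abs(den) < 1e-300 | acc <= 0
    acc[bad] <- s2[bad]
    conv <- abs(acc - s0) < tol & abs(s2 - s1) < tol
    last[idx] <- s0
    sig[idx] <- acc
    active[idx] <- !conv
    if (!any(active)) break
  }
  if (any(active)) {
    i <- which(active)[1]
    stop("pulsatile sigma fixed point did not converge in ", max_iter,
         " iterations (gamma = ", g[i], ", alpha_m = ", am[i],
         "); last iterates: ", signif(last[i], 12), ", ", signif(sig[i], 12))
  }
  sig
}

#' Sigma-gamma band over a Womersley-number range
#'
#' Pointwise envelope of the pulsatile well-matched curve
#' [sigma_of_gamma_pulsatile()] over a log-spaced alpha grid. Because
#' alpha > 10 is conventionally treated as the non-pulsatile regime, the
#' steady curve (the alpha -> infinity member) is included in the envelope
#' whenever the upper end of `alpha_range` is at least 10, so the band always
#' contains the steady scaling-law curve in that case.
#'
#' @param tau scaling exponent.
#' @param alpha_range length-2 numeric, physiological range of the mother
#'   Womersley number (default `c(0.01, 10)`).
#' @param n_gamma number of gamma grid points in (0, 1\].
#' @param n_alpha number of log-spaced alpha grid points.
#' @param settings a [pulsatile_settings()] object.
#' @return data.frame of class `sigma_gamma_band` with columns `gamma`,
#'   `sigma_min`, `sigma_max`.
#' @export
sigma_gamma_band <- function(tau, alpha_range = c(0.01, 10), n_gamma = 50,
                             n_alpha = 25, settings = pulsatile_settings()) {
  stopifnot(length(alpha_range) == 2, all(alpha_range > 0),
            alpha_range[1] < alpha_range[2], n_gamma >= 2, n_alpha >= 2)
  gamma <- seq(1 / n_gamma, 1, length.out = n_gamma)
  alphas <- exp(seq(log(alpha_range[1]), log(alpha_range[2]),
                    length.out = n_alpha))
  curves <- vapply(alphas, function(a) {
    sigma_of_gamma_pulsatile(gamma, tau, a, settings)
  }, numeric(n_gamma))
  if (alpha_range[2] >= 10) {
    curves <- cbind(curves, sigma_of_gamma(gamma, tau))
  }
  band <- data.frame(gamma = gamma,
                     sigma_min = apply(curves, 1, min),
                     sigma_max = apply(curves, 1, max))
  class(band) <- c("sigma_gamma_band", "data.frame")
  attr(band, "tau") <- tau
  attr(band, "alpha_range") <- alpha_range
  band
}

#' Test whether (gamma, sigma) points fall inside a band
#'
#' Linear interpolation of the band edges at the query gamma values, with a
#' small numerical tolerance so points generated exactly on an edge curve
#' count as inside.
#'
#' @param band a [sigma_gamma_band()] result.
#' @param gamma,sigma coordinates of query points.
#' @param tol edge tolerance (default `1e-9` relative).
#' @return logical vector.
#' @export
in_band <- function(band, gamma, sigma, tol = 1e-9) {
  lo <- stats::approx(band$gamma, band$sigma_min, xout = gamma, rule = 2)$y
  hi <- stats::approx(band$gamma, band$sigma_max, xout = gamma, rule = 2)$y
  sigma >= lo * (1 - tol) & sigma <= hi * (1 + tol)
}
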