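#' Area ratio implied by a scaling law (steady regime)
#'
#' Under a generic branching law \eqn{(d_{d1}/d_m)^\tau + (d_{d2}/d_m)^\tau = 1}
#' the area ratio at a bifurcation is fully determined by the symmetry ratio:
#' \deqn{\sigma(\gamma; \tau) = (1+\gamma)\,(1+\gamma^{\tau/2})^{-2/\tau}.}
#' This is also the locus of zero forward reflection ("well-matchedness")
#' when pulse wave speed scales with area as \eqn{c \propto A^{\tau/2 - 1}}.
#' Murray's law is \eqn{\tau = 3}; the Huo-Kassab law is \eqn{\tau = 7/3};
#' \eqn{\tau = 2} gives \eqn{\sigma \equiv 1}.
#'
#' @param gamma symmetry ratio(s) in \[0, 1\] (smaller/larger daughter area).
#' @param tau scaling exponent, > 0.
#' @return area ratio(s) \eqn{\sigma}.
#' @examples
#' sigma_of_gamma(1, 3)       # 2^(1/3), symmetric Murray bifurcation
#' sigma_of_gamma(0.5, 7/3)   # asymmetric Huo-Kassab
#' @export
sigma_of_gamma <- function(gamma, tau) {
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]")
  if (any(tau <= 0)) stop("tau must be positive")
  (1 + gamma) * (1 + gamma^(tau / 2))^(-2 / tau)
}

#' Forward reflection coefficient in (sigma, gamma) form
#'
#' Linearized forward reflection coefficient at a bifurcation expressed in
#' terms of area ratio and symmetry ratio, assuming the wave-speed/area
#' coupling of the scaling law with exponent `tau`:
#' \deqn{R_f = \frac{1 - X}{1 + X}, \quad
#'       X = \left(\frac{\sigma}{1+\gamma}\right)^{\tau/2}(1+\gamma^{\tau/2}).}
#' `Rf = 0` exactly when `sigma == sigma_of_gamma(gamma, tau)`.
#'
#' @param sigma area ratio(s), > 0.
#' @param gamma symmetry ratio(s) in \[0, 1\].
#' @param tau scaling exponent.
#' @return forward reflection coefficient(s) in \[-1, 1\].
#' @export
forward_reflection_sigma_gamma <- function(sigma, gamma, tau) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]")
  X <- (sigma / (1 + gamma))^(tau / 2) * (1 + gamma^(tau / 2))
  (1 - X) / (1 + X)
}

#' Reflection coefficients at a junction from areas and wave speeds
#'
#' Linearized (high Womersley number) reflection coefficients at a
#' mother/daughter junction, assuming constant blood density so that the
#' admittance of each vessel is proportional to \eqn{A c}:
#' \deqn{R_f = \frac{Y_m - Y_{d1} - Y_{d2}}{Y_m + Y_{d1} + Y_{d2}},}
#' with the backward coefficients \eqn{R_{d1}}, \eqn{R_{d2}} obtained by
#' swapping the leading (incident-vessel) term. All three lie in \[-1, 1\].
#'
#' @param A_m,A_d1,A_d2 cross-sectional areas (any common unit), > 0.
#' @param c_m,c_d1,c_d2 pulse wave speeds (any common unit), > 0.
#' @return data.frame with columns `Rf`, `Rd1`, `Rd2` (vectorized).
#' @examples
#' reflection_triple(2, 1, 1, 1, 1, 1)  # Rf = 0, Rd1 = Rd2 = -0.5
#' @export
reflection_triple <- function(A_m, A_d1, A_d2, c_m, c_d1, c_d2) {
  Ym <- A_m * c_m
  Y1 <- A_d1 * c_d1
  Y2 <- A_d2 * c_d2
  if (any(Ym <= 0 | Y1 <= 0 | Y2 <= 0)) {
    stop("admittances (A * c) must all be positive")
  }
  tot <- Ym + Y1 + Y2
  data.frame(Rf = (Ym - Y1 - Y2) / tot,
             Rd1 = (Y1 - Ym - Y2) / tot,
             Rd2 = (Y2 - Ym - Y1) / tot)
}

#' Backward reflection coefficients of a well-matched bifurcation
#'
#' Closed forms obtained by substituting the zero-forward-reflection area
#' ratio into the admittance formula:
#' \deqn{R_{d1} = -\frac{\gamma^{\tau/2}}{1+\gamma^{\tau/2}}, \qquad
#'       R_{d2} = -\frac{1}{1+\gamma^{\tau/2}}.}
#' Always \eqn{R_{d1} \ge R_{d2}} with equality only at \eqn{\gamma = 1}:
#' asymmetric junctions pass backward waves from the larger daughter but
#' strongly damp those from the smaller one, and as \eqn{\gamma \to 0} the
#' pair tends to (0, -1).
#'
#' @inheritParams sigma_of_gamma
#' @return data.frame with columns `Rd1`, `Rd2`.
#' @export
matched_backward_reflections <- function(gamma, tau) {
  g <- gamma^(tau / 2)
  data.frame(Rd1 = -g / (1 + g), Rd2 = -1 / (1 + g))
}

#' Pulse wave speed from area-independent wall stiffness (and inverse)
#'
#' The linear tube law gives the reference-state pulse wave speed
#' \deqn{c_0 = \sqrt{\beta^* / (2\rho)}\; A_0^{-1/4}}
#' where \eqn{\beta^* = \beta A_0} is the area-independent stiffness
#' (units Pa m, i.e. N/m). A uniform \eqn{\beta^*} across a tree implies the
#' wave speed increases distally as the area shrinks.
#'
#' @param beta_star wall stiffness \eqn{\beta^*} in Pa m (kg/s^2).
#' @param A0_mm2 reference cross-sectional area in mm^2.
#' @param rho blood density in kg/m^3 (default 1060).
#' @return `pws_from_beta_star`: wave speed in m/s.
#' @export
pws_from_beta_star <- function(beta_star, A0_mm2, rho = 1060) {
  if (any(beta_star <= 0) || any(A0_mm2 <= 0) || any(rho <= 0)) {
    stop("beta_star, A0_mm2 and rho must be positive")
  }
  sqrt(beta_star / (2 * rho)) * (A0_mm2 * 1e-6)^(-1 / 4)
}

#' @rdname pws_from_beta_star
#' @param c0 pulse wave speed in m/s.
#' @return `beta_star_from_pws`: stiffness \eqn{\beta^*} in Pa m.
#' @export
beta_star_from_pws <- function(c0, A0_mm2, rho = 1060) {
  if (any(c0 <= 0) || any(A0_mm2 <= 0) || any(rho <= 0)) {
    stop("c0, A0_mm2 and rho must be positive")
  }
  2 * rho * c0^2 * sqrt(A0_mm2 * 1e-6)
}

#' Characteristic impedance of a segment (high-alpha limit)
#'
#' \eqn{Z_0 = \rho c_0 / A_0}, the ratio of pulsatile pressure to flow for a
#' unidirectional wave when viscous effects are negligible.
#'
#' @inheritParams pws_from_beta_star
#' @param c0 pulse wave speed in m/s.
#' @return impedance in Pa s/m^3.
#' @export
characteristic_impedance <- function(A0_mm2, c0, rho = 1060) {
  if (any(A0_mm2 <= 0) || any(c0 <= 0)) stop("A0 and c0 must be positive")
  rho * c0 / (A0_mm2 * 1e-6)
}

#' Scaling-law residual of a measured bifurcation
#'
#' \eqn{(d_{d1}/d_m)^\tau + (d_{d2}/d_m)^\tau - 1}; zero iff the diameter
#' triple obeys the scaling law with exponent `tau`, equivalently iff its
#' \eqn{(\sigma, \gamma)} pair lies on `sigma_of_gamma(gamma, tau)`.
#'
#' @param d_m,d_d1,d_d2 mother and daughter diameters (any common unit), > 0.
#' @param tau scaling exponent.
#' @return residual(s).
#' @export
scaling_residual <- function(d_m, d_d1, d_d2, tau) {
  if (any(d_m <= 0 | d_d1 <= 0 | d_d2 <= 0)) {
    stop("diameters must be positive")
  }
  (d_d1 / d_m)^tau + (d_d2 / d_m)^tau - 1
}

#' Transmitted fraction of a wave crossing a junction
#'
#' A wave meeting a reflection coefficient `R` continues with amplitude
#' fraction `1 + R`; e.g. a backward wave seeing `R = -0.3` retains 70% of
#' its amplitude at each such junction.
#'
#' @param R reflection coefficient(s) in \[-1, 1\].
#' @return transmitted amplitude fraction(s).
#' @export
wave_transmission <- function(R) {
  if (any(R < -1 | R > 1)) stop("reflection coefficients must lie in [-1, 1]")
  1 + R
}

#' Wave transit time along a segment
#'
#' @param length_mm segment length in mm.
#' @param c_m_per_s pulse wave speed in m/s.
#' @return transit time in seconds.
#' @export
transit_time <- function(length_mm, c_m_per_s) {
  if (any(length_mm <= 0) || any(c_m_per_s <= 0)) {
    stop("length and wave speed must be positive")
  }
  (length_mm * 1e-3) / c_m_per_s
}
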