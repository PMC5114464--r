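#' Empirical exponential wall-stiffness law
#'
#' The empirical fit of wall elasticity to vessel radius,
#' \deqn{\frac{Eh}{r_0} = k_1 e^{k_2 r_0} + k_3,}
#' with constants in cgs units as published
#' (`k1 = 2e7 g s^-2 cm^-1`, `k2 = -22.53 cm^-1`, `k3 = 8.65e5 g s^-2 cm^-1`;
#' 1 g s^-2 cm^-1 = 0.1 Pa). Only the product `Eh` is ever needed: it is
#' converted to the area-independent stiffness
#' \eqn{\beta^* = \sqrt{\pi}\, Eh / (1-\nu^2)} (SI: Pa m), from which the
#' pulse wave speed follows via [pws_from_beta_star()].
#'
#' @param r0_mm vessel radius in mm.
#' @param k1,k2,k3 constants in cgs units (see above).
#' @param nu_poisson wall Poisson ratio (default 0.5).
#' @return data.frame with columns `Eh` (kg/s^2, SI) and `beta_star` (Pa m).
#' @export
olufsen_wall_law <- function(r0_mm, k1 = 2e7, k2 = -22.53, k3 = 8.65e5,
                             nu_poisson = 0.5) {
  if (any(r0_mm <= 0)) stop("radius must be positive")
  r0_cm <- r0_mm / 10
  Eh_cgs <- r0_cm * (k1 * exp(k2 * r0_cm) + k3)  # g/s^2
  Eh <- Eh_cgs * 1e-3                            # kg/s^2
  data.frame(Eh = Eh, beta_star = sqrt(pi) * Eh / (1 - nu_poisson^2))
}

#' Assign pulse wave speed and wall stiffness across a tree
#'
#' Fills every segment with a pulse wave speed `c0` and area-independent
#' stiffness `beta_star` under one of four hypotheses:
#' \describe{
#'   \item{`uniform_pws`}{constant wave speed everywhere (param `c0`,
#'     default 20 m/s, the scale of recent intracoronary estimates); implies
#'     `beta_star` decreasing distally.}
#'   \item{`uniform_beta_star`}{constant `beta_star` (param `beta_star`,
#'     default 1500 Pa m, tuned to give ~20 m/s at a 1 mm radius); implies
#'     \eqn{c_0 \propto A^{-1/4}}, i.e. wave speed increasing distally.}
#'   \item{`uniform_beta`}{constant non-normalized stiffness \eqn{\beta}
#'     of the tube law, \eqn{c_0 \propto A^{1/4}} (params `c0_ref`,
#'     `r_ref_mm`: the speed at a reference radius; defaults 20 m/s at
#'     1 mm). This is the reading under which a constant-stiffness network
#'     corresponds to scaling exponent tau = 2.5.}
#'   \item{`olufsen`}{the empirical exponential wall law
#'     [olufsen_wall_law()] (params `k1`, `k2`, `k3`, `nu_poisson`).}
#' }
#'
#' @param tree a `vascular_tree`.
#' @param hypothesis one of `"uniform_pws"`, `"uniform_beta_star"`,
#'   `"uniform_beta"`, `"olufsen"`.
#' @param params named list of hypothesis parameters (see above); `rho`
#'   (kg/m^3, default 1060) is common to all.
#' @return object of class `material_assignment`: list with `hypothesis`,
#'   `rho`, `params` and `segments` (data.frame `id`, `c0` m/s,
#'   `beta_star` Pa m).
#' @export
assign_material <- function(tree,
                            hypothesis = c("uniform_pws", "uniform_beta_star",
                                           "uniform_beta", "olufsen"),
                            params = list()) {
  hypothesis <- match.arg(hypothesis)
  validate_tree(tree)
  rho <- params$rho %||% 1060
  A <- segment_areas(tree)  # mm^2
  if (hypothesis == "uniform_pws") {
    c0 <- rep(params$c0 %||% 20, length(A))
    beta_star <- beta_star_from_pws(c0, A, rho)
  } else if (hypothesis == "uniform_beta_star") {
    beta_star <- rep(params$beta_star %||% 1500, length(A))
    c0 <- pws_from_beta_star(beta_star, A, rho)
  } else if (hypothesis == "uniform_beta") {
    c0_ref <- params$c0_ref %||% 20
    r_ref <- params$r_ref_mm %||% 1
    A_ref <- pi * r_ref^2
    c0 <- c0_ref * (A / A_ref)^(1 / 4)
    beta_star <- beta_star_from_pws(c0, A, rho)
  } else {  # olufsen
    wl <- olufsen_wall_law(tree$segments$radius_mm,
                           k1 = params$k1 %||% 2e7,
                           k2 = params$k2 %||% -22.53,
                           k3 = params$k3 %||% 8.65e5,
                           nu_poisson = params$nu_poisson %||% 0.5)
    beta_star <- wl$beta_star
    c0 <- pws_from_beta_star(beta_star, A, rho)
  }
  structure(list(hypothesis = hypothesis, rho = rho, params = params,
                 segments = data.frame(id = tree$segments$id, c0 = c0,
                                       beta_star = beta_star,
                                       stringsAsFactors = FALSE)),
            class = "material_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.material_assignment <- function(x, ...) {
  cat("<material_assignment> hypothesis:", x$hypothesis, "\n")
  cat(sprintf("  %d segments, c0 range %.3g - %.3g m/s\n",
              nrow(x$segments), min(x$segments$c0), max(x$segments$c0)))
  invisible(x)
}

#' Export a material assignment as a delimited table
#'
#' Writes `id,c0_m_per_s,beta_star_Pa_m`, one row per segment.
#'
#' @param assignment a `material_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_material <- function(assignment, path) {
  out <- data.frame(id = assignment$segments$id,
                    c0_m_per_s = sprintf("%.17g", assignment$segments$c0),
                    beta_star_Pa_m = sprintf("%.17g",
                                             assignment$segments$beta_star))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reflection coefficients at every bifurcation of a tree
#'
#' Evaluates the linearized admittance formula ([reflection_triple()]) at
#' each bifurcation using the areas of the tree and the wave speeds of a
#' material assignment. The linearized (steady) formula is used deliberately:
#' it requires only the assumed wave-speed distribution, not an additional
#' Womersley-number distribution.
#'
#' @param tree a `vascular_tree`.
#' @param assignment a [assign_material()] result covering all segments.
#' @return the [extract_bifurcations()] records with added columns `Rf`,
#'   `Rd1`, `Rd2`, plus the census as attribute `census`.
#' @export
tree_reflection_coefficients <- function(tree, assignment) {
  bs <- extract_bifurcations(tree)
  rec <- bs$records
  if (nrow(rec) == 0) return(rec)
  c_of <- assignment$segments$c0[match(
    c(rec$mother_id, rec$d1_id, rec$d2_id), assignment$segments$id)]
  if (anyNA(c_of)) {
    missing_ids <- unique(c(rec$mother_id, rec$d1_id,
                            rec$d2_id)[is.na(c_of)])
    stop("material assignment missing segment(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  n <- nrow(rec)
  cc <- matrix(c_of, ncol = 3)
  rt <- reflection_triple(rec$A_m, rec$A_d1, rec$A_d2,
                          cc[, 1], cc[, 2], cc[, 3])
  rec$Rf <- rt$Rf
  rec$Rd1 <- rt$Rd1
  rec$Rd2 <- rt$Rd2
  attr(rec, "census") <- bs$census
  rec
}
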