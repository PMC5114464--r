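# run expr with a local RNG state so generators are reproducible without
# clobbering the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration of the synthetic coronary-tree generator
#'
#' The generator emulates the branching statistics measured in ex vivo
#' coronary networks: mother radii spanning about 0.05-2.5 mm, a symmetry
#' ratio gamma rising from ~0.3 in the large epicardial vessels to ~0.7 in
#' the arterioles, area ratios in ~\[1.0, 1.5\] with a distal plateau near
#' 1.4, ~95% bifurcations / ~4% higher-order junctions, and a fraction of
#' asymmetric bifurcations (gamma < 0.5) falling from ~80% proximally to
#' ~15% distally.
#'
#' @param root_radius root radius in mm (default 2.5, large epicardial
#'   calibre).
#' @param r_min terminal radius in mm (default 0.05, the resolution floor of
#'   high-resolution casting data).
#' @param gamma_law list: `mean_proximal`, `mean_distal` (Beta mean at the
#'   root radius and at `r_min`, interpolated linearly in log radius) and
#'   `concentration` of the Beta distribution (defaults 0.3, 0.7, 10); or
#'   `fixed` for a degenerate law with the same gamma at every junction.
#' @param matching_law list: `type` (`"steady"` or `"pulsatile"`), `tau`
#'   (scalar, or length-2 `c(proximal, distal)` interpolated in log radius)
#'   and, for pulsatile matching, `settings` (a [pulsatile_settings()]).
#'   Default: pulsatile Huo-Kassab matching (tau = 7/3 with alpha from the
#'   mother radius), the combination that reproduces the measured rise of
#'   the area ratio toward a distal plateau; steady matching keeps sigma
#'   on the closed-form curve instead.
#' @param length_ratio segment length / radius (default 10).
#' @param noise_cv coefficient of variation of multiplicative radius noise
#'   applied after growth (default 0 = ideal tree).
#' @param trifurcation_rate probability that a junction is converted to a
#'   trifurcation by splitting the smaller daughter (default 0.04).
#' @param n_territories number of perfused-territory labels (default 3:
#'   LAD, LCx, RCA).
#' @param seed integer RNG seed.
#' @param max_segments safety cap on tree size.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(root_radius = 2.5, r_min = 0.05,
                             gamma_law = list(), matching_law = list(),
                             length_ratio = 10, noise_cv = 0,
                             trifurcation_rate = 0.04, n_territories = 3,
                             seed = 1L, max_segments = 1e6) {
  gamma_law <- utils::modifyList(
    list(mean_proximal = 0.3, mean_distal = 0.7, concentration = 10),
    gamma_law)
  matching_law <- utils::modifyList(
    list(type = "pulsatile", tau = 7 / 3, settings = pulsatile_settings()),
    matching_law)
  stopifnot(r_min > 0, root_radius > r_min, noise_cv >= 0,
            trifurcation_rate >= 0, trifurcation_rate <= 0.1,
            n_territories >= 1, length_ratio > 0,
            matching_law$type %in% c("steady", "pulsatile"),
            all(matching_law$tau > 1), all(matching_law$tau < 6))
  structure(list(root_radius = root_radius, r_min = r_min,
                 gamma_law = gamma_law, matching_law = matching_law,
                 length_ratio = length_ratio, noise_cv = noise_cv,
                 trifurcation_rate = trifurcation_rate,
                 n_territories = n_territories, seed = as.integer(seed),
                 max_segments = as.integer(max_segments)),
            class = "synthetic_config")
}

# linear interpolation in log radius between a proximal value (at the root
# radius) and a distal value (at r_min)
.log_radius_ramp <- function(r, root_radius, r_min, v_prox, v_dist) {
  t <- (log(root_radius) - log(r)) / (log(root_radius) - log(r_min))
  t <- pmin(pmax(t, 0), 1)
  v_prox + (v_dist - v_prox) * t
}

# tau at radius r: scalar tau, or c(proximal, distal) ramp
.tau_at <- function(r, cfg) {
  tau <- cfg$matching_law$tau
  if (length(tau) == 1) rep(tau, length(r))
  else .log_radius_ramp(r, cfg$root_radius, cfg$r_min, tau[1], tau[2])
}

#' Generate a synthetic coronary tree
#'
#' Recursive growth from the root: at each junction a symmetry ratio gamma is
#' drawn from a radius-conditioned Beta distribution (mean ramping from
#' `mean_proximal` at the root to `mean_distal` at `r_min` in log radius),
#' the area ratio sigma is set by the configured matching law (steady
#' closed form, or the pulsatile fixed point with alpha from the mother
#' radius), and daughter areas follow as \eqn{A_{d1} = A_m \sigma/(1+\gamma)},
#' \eqn{A_{d2} = \gamma A_{d1}}. Branches stop below `r_min`. With
#' probability `trifurcation_rate` the smaller daughter is split into two
#' symmetric grand-daughters attached to the mother, producing a
#' trifurcation. Lengths are `length_ratio * radius`; territories label the
#' proximal subtrees round-robin; transmural depth accumulates a
#' Uniform(0, 0.15) increment per generation, clipped at 1. Radii decrease
#' strictly along every path before noise; if `noise_cv > 0`, multiplicative
#' lognormal radius noise is applied at the end.
#'
#' @param config a [synthetic_config()].
#' @return a `vascular_tree` with `territory`, `transmural_depth` and
#'   `weibel_generation` labels.
#' @export
generate_tree <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$root_radius < config$r_min) stop("root radius below r_min")
  cfg <- config
  .with_seed(cfg$seed, {
    ids <- "s1"
    parent <- NA_character_
    radius <- cfg$root_radius
    depth <- 0
    next_id <- 2L
    frontier <- 1L  # row indices of segments whose children are pending
    while (length(frontier) > 0) {
      r_m <- radius[frontier]
      grow <- r_m >= cfg$r_min
      frontier <- frontier[grow]
      if (length(frontier) == 0) break
      r_m <- r_m[grow]
      n <- length(frontier)
      if (!is.null(cfg$gamma_law$fixed)) {
        g <- rep(cfg$gamma_law$fixed, n)
      } else {
        m <- .log_radius_ramp(r_m, cfg$root_radius, cfg$r_min,
                              cfg$gamma_law$mean_proximal,
                              cfg$gamma_law$mean_distal)
        m <- pmin(pmax(m, 0.05), 0.95)
        kappa <- cfg$gamma_law$concentration
        g <- stats::rbeta(n, m * kappa, (1 - m) * kappa)
        g <- pmin(pmax(g, 1e-6), 1)
      }
      tau <- .tau_at(r_m, cfg)
      if (cfg$matching_law$type == "steady") {
        sig <- sigma_of_gamma(g, tau)
      } else {
        a_m <- womersley_alpha(r_m, cfg$matching_law$settings)
        sig <- sigma_of_gamma_pulsatile(g, tau, a_m,
                                        cfg$matching_law$settings)
      }
      A_m <- pi * r_m^2
      A_d1 <- A_m * sig / (1 + g)
      A_d2 <- g * A_d1
      trif <- stats::runif(n) < cfg$trifurcation_rate
      # with probability trifurcation_rate the smaller daughter is split into
      # two symmetric vessels attached to the mother (a trifurcation)
      A_split <- A_d2 * sigma_of_gamma(1, tau) / 2
      nchild <- ifelse(trif, 3L, 2L)
      jx <- rep(seq_len(n), nchild)       # junction index per child
      pos <- sequence(nchild)             # child slot within junction
      r_child <- numeric(length(jx))
      r_child[pos == 1] <- sqrt(A_d1 / pi)
      second <- pos == 2 & !trif[jx]
      r_child[second] <- sqrt(A_d2[jx[second]] / pi)
      splitkid <- pos >= 2 & trif[jx]
      r_child[splitkid] <- sqrt(A_split[jx[splitkid]] / pi)
      new_parent <- ids[frontier][jx]
      new_radius <- r_child
      new_depth <- pmin(1, depth[frontier][jx] +
                          stats::runif(length(jx), 0, 0.15))
      k <- length(new_parent)
      new_rows <- seq(length(ids) + 1L, length(ids) + k)
      ids <- c(ids, paste0("s", seq(next_id, next_id + k - 1L)))
      next_id <- next_id + k
      parent <- c(parent, new_parent)
      radius <- c(radius, new_radius)
      depth <- c(depth, new_depth)
      if (length(ids) > cfg$max_segments) {
        stop("tree exceeded max_segments = ", cfg$max_segments,
             "; raise the cap or r_min")
      }
      frontier <- new_rows
    }
    seg <- data.frame(id = ids, parent = parent, radius_mm = radius,
                      length_mm = cfg$length_ratio * radius,
                      transmural_depth = depth, stringsAsFactors = FALSE)
    tree <- vascular_tree(seg)
    tree <- assign_weibel_generations(tree)
    tree <- .assign_territories(tree, cfg$n_territories)
    if (cfg$noise_cv > 0) {
      tree <- add_radius_noise(tree, cfg$noise_cv,
                               seed = cfg$seed + 1000003L)
    }
    attr(tree, "config") <- cfg
    tree
  })
}

# label proximal subtrees round-robin with territory names. Branch roots are
# the children of the first junction; the largest branch is repeatedly
# expanded until there are at least n_territories branch roots (or no more
# junctions), so that three labels can be placed on a binary root.
.assign_territories <- function(tree, n_territories) {
  seg <- tree$segments
  kids <- .children_index(tree)
  node <- match(tree$root_id, seg$id)
  repeat {
    ch <- kids[[seg$id[node]]]
    if (length(ch) != 1) break
    node <- ch
  }
  branches <- kids[[seg$id[node]]]
  while (length(branches) < n_territories) {
    sizes <- seg$radius_mm[branches]
    expandable <- vapply(branches,
                         function(b) length(kids[[seg$id[b]]]) > 0,
                         logical(1))
    if (!any(expandable)) break
    pick <- branches[expandable][which.max(sizes[expandable])]
    branches <- c(setdiff(branches, pick), kids[[seg$id[pick]]])
  }
  names_pool <- c("LAD", "LCx", "RCA",
                  paste0("T", seq_len(max(0, length(branches) - 3))))
  territory <- rep(NA_character_, nrow(seg))
  idx <- match(seg$parent, seg$id)
  for (i in seq_along(branches)) {
    lab <- names_pool[((i - 1) %% n_territories) + 1]
    members <- branches[i]
    frontier <- branches[i]
    while (length(frontier) > 0) {
      nxt <- which(idx %in% frontier)
      members <- c(members, nxt)
      frontier <- nxt
    }
    territory[members] <- lab
  }
  # segments proximal to the branch roots carry the first label
  territory[is.na(territory)] <- names_pool[1]
  tree$segments$territory <- territory
  tree
}

#' Multiplicative radius noise
#'
#' Multiplies every radius by an independent lognormal factor with unit
#' median and the stated coefficient of variation, emulating segmentation
#' radius error. Topology, lengths and labels are untouched.
#'
#' @param tree a `vascular_tree`.
#' @param cv coefficient of variation (>= 0; 0 is the identity).
#' @param seed optional integer seed for reproducibility.
#' @return the perturbed tree.
#' @export
add_radius_noise <- function(tree, cv, seed = NULL) {
  stopifnot(cv >= 0)
  if (cv == 0) return(tree)
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function() stats::rlnorm(nrow(tree$segments), 0, sdlog)
  f <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  tree$segments$radius_mm <- tree$segments$radius_mm * f
  tree
}

#' Generate a well-matched (sigma, gamma) point cloud
#'
#' For gamma evenly spaced in (0, 1\], finds the area ratio giving zero
#' forward reflection when pulse wave speed scales with area as
#' \eqn{c \propto A^s}. The steady construction solves the admittance
#' formula ([reflection_triple()]) by root finding in sigma, so it is an
#' independent route to the closed-form curve with exponent
#' \eqn{\tau = 2(1+s)}: `s = 0` (uniform speed) gives sigma = 1 for all
#' gamma (tau = 2), `s = 1/4` (constant tube-law stiffness) the tau = 2.5
#' curve, `s = 1/6` the Huo-Kassab curve, `s = 1/2` Murray's. With
#' `alpha_m` given, the pulsatile fixed point is used instead.
#'
#' @param exponent_s wave-speed/area exponent `s`.
#' @param n number of gamma points (>= 2).
#' @param alpha_m optional mother Womersley number for pulsatile matching.
#' @param settings a [pulsatile_settings()] (pulsatile case only).
#' @return data.frame with columns `gamma`, `sigma`.
#' @export
generate_matched_cloud <- function(exponent_s, n, alpha_m = NULL,
                                   settings = pulsatile_settings()) {
  stopifnot(n >= 2)
  gamma <- seq(1 / n, 1, length.out = n)
  tau <- 2 * (1 + exponent_s)
  if (is.null(alpha_m)) {
    s <- exponent_s
    sigma <- vapply(gamma, function(g) {
      f <- function(sig) {
        A_m <- 1
        A_d1 <- sig / (1 + g)
        A_d2 <- g * A_d1
        reflection_triple(A_m, A_d1, A_d2,
                          A_m^s, A_d1^s, A_d2^s)$Rf
      }
      stats::uniroot(f, c(0.2, 5), tol = 1e-14)$root
    }, numeric(1))
  } else {
    sigma <- sigma_of_gamma_pulsatile(gamma, tau, alpha_m, settings)
  }
  data.frame(gamma = gamma, sigma = sigma)
}
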