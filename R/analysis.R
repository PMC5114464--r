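#' Clustering specification for bifurcation records
#'
#' @param mode `"radius_bins"` (mother radius), `"territory"`,
#'   `"transmural_layer"` or `"weibel_generation"`.
#' @param bin_edges strictly increasing radius bin edges in mm (radius mode).
#'   The defaults are declared, not inferred from any published figure.
#' @param n_layers number of transmural layers (transmural mode).
#' @return list of class `cluster_spec`.
#' @export
cluster_spec <- function(mode = c("radius_bins", "territory",
                                  "transmural_layer", "weibel_generation"),
                         bin_edges = c(0.05, 0.1, 0.3, 0.5, 1.0, 3.0),
                         n_layers = 3) {
  mode <- match.arg(mode)
  if (mode == "radius_bins" && any(diff(bin_edges) <= 0)) {
    stop("bin edges must be strictly increasing")
  }
  structure(list(mode = mode, bin_edges = bin_edges, n_layers = n_layers),
            class = "cluster_spec")
}

#' Assign bifurcation records to clusters
#'
#' Every record falls in exactly one cluster; empty clusters are retained as
#' factor levels so downstream summaries report them with n = 0. Radius bins
#' are left-open/right-closed; records outside the edges are dropped with a
#' warning.
#'
#' @param records the `records` data.frame of [extract_bifurcations()] (or
#'   a `bifurcation_set`).
#' @param spec a [cluster_spec()].
#' @return the records with an added `cluster` factor column.
#' @export
cluster_bifurcations <- function(records, spec = cluster_spec()) {
  if (inherits(records, "bifurcation_set")) records <- records$records
  if (nrow(records) == 0) stop("no bifurcation records to cluster")
  if (spec$mode == "radius_bins") {
    cl <- cut(records$r_m, breaks = spec$bin_edges, include.lowest = TRUE)
    if (anyNA(cl)) {
      warning(sum(is.na(cl)), " record(s) outside the radius bin edges; dropped")
      records <- records[!is.na(cl), , drop = FALSE]
      cl <- cl[!is.na(cl)]
    }
  } else if (spec$mode == "territory") {
    if (is.null(records$territory) || all(is.na(records$territory))) {
      stop("records have no territory labels")
    }
    cl <- factor(records$territory)
  } else if (spec$mode == "transmural_layer") {
    if (!is.null(records$transmural_layer)) {
      lay <- records$transmural_layer
    } else if (!is.null(records$transmural_depth)) {
      lay <- .bin_depth(records$transmural_depth, spec$n_layers)
    } else {
      stop("records have neither transmural_layer nor transmural_depth")
    }
    cl <- factor(lay, levels = seq_len(spec$n_layers),
                 labels = paste0("layer", seq_len(spec$n_layers)))
  } else {  # weibel_generation
    if (is.null(records$weibel_generation)) {
      stop("records have no weibel_generation labels")
    }
    cl <- factor(records$weibel_generation)
  }
  records$cluster <- cl
  records
}

#' Fit the scaling exponent tau to a (sigma, gamma) cloud
#'
#' Least-squares fit of the closed-form curve [sigma_of_gamma()] to observed
#' (gamma, sigma) pairs: minimizes the mean squared vertical residual in
#' sigma over `tau` within `tau_bounds`, using `n_starts` random
#' initializations (bounded quasi-Newton from each) and keeping the minimum-
#' MSE solution. Deterministic given `seed`. Groups in which all gamma are
#' identical cannot constrain tau and are flagged `low_confidence`.
#'
#' @param group data.frame with columns `gamma` and `sigma` (e.g. clustered
#'   bifurcation records or a [generate_matched_cloud()] result).
#' @param n_starts number of random restarts (default 50).
#' @param tau_bounds length-2 search bounds (default `c(1, 6)`).
#' @param seed integer seed for the restart draws.
#' @return list with `tau_hat`, `mse`, `n`, `low_confidence`.
#' @export
fit_tau <- function(group, n_starts = 50, tau_bounds = c(1, 6), seed = 1L) {
  if (inherits(group, "bifurcation_set")) group <- group$records
  if (nrow(group) < 3) stop("need at least 3 records to fit tau")
  g <- group$gamma
  s <- group$sigma
  low_confidence <- stats::sd(g) < 1e-12
  mse <- function(tau) mean((s - sigma_of_gamma(g, tau))^2)
  fits <- .with_seed(seed, {
    starts <- stats::runif(n_starts, tau_bounds[1], tau_bounds[2])
    lapply(starts, function(t0) {
      stats::optim(t0, mse, method = "L-BFGS-B",
                   lower = tau_bounds[1], upper = tau_bounds[2],
                   control = list(factr = 1))
    })
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  if (low_confidence) {
    warning("all gamma identical; tau fit is low-confidence")
  }
  list(tau_hat = best$par, mse = best$value, n = length(g),
       low_confidence = low_confidence)
}

#' Per-cluster summary statistics
#'
#' Means and standard errors of sigma and gamma, the fraction of asymmetric
#' bifurcations (gamma < 0.5), and optionally the fitted scaling exponent,
#' for each cluster of a clustered record set. Empty clusters are reported
#' with n = 0. The input is not modified.
#'
#' @param records output of [cluster_bifurcations()].
#' @param fit logical; also run [fit_tau()] per cluster (clusters with < 3
#'   records get NA).
#' @param n_starts,tau_bounds,seed passed to [fit_tau()].
#' @return data.frame of class `cluster_summary`, one row per cluster:
#'   `cluster`, `n`, `mean_sigma`, `sem_sigma`, `mean_gamma`, `sem_gamma`,
#'   `frac_asymmetric`, and if `fit` also `tau_hat`, `mse`.
#' @export
summarize_clusters <- function(records, fit = FALSE, n_starts = 50,
                               tau_bounds = c(1, 6), seed = 1L) {
  if (is.null(records$cluster)) stop("records are not clustered")
  lev <- levels(records$cluster)
  rows <- lapply(lev, function(lv) {
    sub <- records[records$cluster == lv, , drop = FALSE]
    n <- nrow(sub)
    out <- data.frame(
      cluster = lv, n = n,
      mean_sigma = if (n > 0) mean(sub$sigma) else NA_real_,
      sem_sigma = if (n > 1) stats::sd(sub$sigma) / sqrt(n) else
        if (n == 1) 0 else NA_real_,
      mean_gamma = if (n > 0) mean(sub$gamma) else NA_real_,
      sem_gamma = if (n > 1) stats::sd(sub$gamma) / sqrt(n) else
        if (n == 1) 0 else NA_real_,
      frac_asymmetric = if (n > 0) mean(sub$gamma < 0.5) else NA_real_,
      stringsAsFactors = FALSE)
    if (fit) {
      if (n >= 3) {
        ft <- fit_tau(sub, n_starts = n_starts, tau_bounds = tau_bounds,
                      seed = seed)
        out$tau_hat <- ft$tau_hat
        out$mse <- ft$mse
      } else {
        out$tau_hat <- NA_real_
        out$mse <- NA_real_
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_summary", "data.frame")
  out
}

#' Pairwise rank-based comparison of clusters
#'
#' Compares sigma or gamma between every pair of clusters with a rank-based
#' test and reports raw p-values alongside the conventional significance
#' threshold P < 0.01. The default is the unpaired Wilcoxon rank-sum test,
#' the appropriate choice for unpaired cluster samples; `paired = TRUE`
#' selects the signed-rank variant for equal-sized paired designs.
#'
#' @param records output of [cluster_bifurcations()].
#' @param variable `"sigma"` or `"gamma"`.
#' @param paired use the signed-rank (paired) variant.
#' @param threshold significance threshold reported alongside p (default
#'   0.01).
#' @return data.frame: `cluster_a`, `cluster_b`, `n_a`, `n_b`, `p_value`,
#'   `significant`. Pairs with a group of n < 2 are skipped with a warning.
#' @export
compare_clusters <- function(records, variable = c("sigma", "gamma"),
                             paired = FALSE, threshold = 0.01) {
  variable <- match.arg(variable)
  if (is.null(records$cluster)) stop("records are not clustered")
  lev <- levels(droplevels(records$cluster))
  if (length(lev) < 2) stop("need at least 2 non-empty clusters")
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- records[[variable]][records$cluster == pairs[1, j]]
    b <- records[[variable]][records$cluster == pairs[2, j]]
    if (length(a) < 2 || length(b) < 2) {
      warning("cluster pair (", pairs[1, j], ", ", pairs[2, j],
              ") has a group with n < 2; skipped")
      return(NULL)
    }
    p <- if (paired && length(a) == length(b)) {
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
    } else {
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    }
    data.frame(cluster_a = pairs[1, j], cluster_b = pairs[2, j],
               n_a = length(a), n_b = length(b), p_value = p,
               significant = p < threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "test") <- if (paired) "wilcoxon_signed_rank"
                       else "wilcoxon_rank_sum"
  out
}

#' Per-cluster distributions of reflection coefficients
#'
#' Computes the reflection triple at every bifurcation under a material
#' assignment and summarizes mean and quantiles per cluster.
#'
#' @param tree a `vascular_tree`.
#' @param assignment a [assign_material()] result.
#' @param spec a [cluster_spec()].
#' @param probs quantile probabilities (default quartiles).
#' @return data.frame with one row per cluster and columns
#'   `<coef>_mean`, `<coef>_q<p>` for each of Rf, Rd1, Rd2.
#' @export
reflection_summary <- function(tree, assignment, spec = cluster_spec(),
                               probs = c(0.25, 0.5, 0.75)) {
  rec <- tree_reflection_coefficients(tree, assignment)
  rec <- cluster_bifurcations(rec, spec)
  lev <- levels(rec$cluster)
  rows <- lapply(lev, function(lv) {
    sub <- rec[rec$cluster == lv, , drop = FALSE]
    out <- data.frame(cluster = lv, n = nrow(sub), stringsAsFactors = FALSE)
    for (cf in c("Rf", "Rd1", "Rd2")) {
      x <- sub[[cf]]
      out[[paste0(cf, "_mean")]] <- if (length(x) > 0) mean(x) else NA_real_
      qs <- if (length(x) > 0) stats::quantile(x, probs, names = FALSE)
            else rep(NA_real_, length(probs))
      for (k in seq_along(probs)) {
        out[[sprintf("%s_q%02d", cf, round(100 * probs[k]))]] <- qs[k]
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Sensitivity of cluster summaries to radius-bin placement
#'
#' Scales each internal bin edge in turn by `(1 - perturbation)` and
#' `(1 + perturbation)`, recomputes the per-cluster mean sigma, mean gamma
#' and asymmetric fraction, and reports the maximum relative change of each
#' metric across clusters. Perturbations that break the edge ordering are
#' skipped.
#'
#' @param records the `records` of [extract_bifurcations()] (unclustered).
#' @param spec a radius-bin [cluster_spec()].
#' @param perturbation relative edge shift (default 0.2).
#' @return list with `shifts` (one row per perturbation and metric) and
#'   `max_shift` (named vector of the worst relative change per metric,
#'   NA-safe). Zero perturbation or a single-bin spec yields empty shifts.
#' @export
bin_sensitivity <- function(records, spec = cluster_spec(),
                            perturbation = 0.2) {
  if (inherits(records, "bifurcation_set")) records <- records$records
  if (spec$mode != "radius_bins") stop("bin_sensitivity needs radius-bin mode")
  metrics <- c("mean_sigma", "mean_gamma", "frac_asymmetric")
  base <- summarize_clusters(cluster_bifurcations(records, spec))
  internal <- seq_along(spec$bin_edges)[-c(1, length(spec$bin_edges))]
  rows <- list()
  if (perturbation > 0) {
    for (i in internal) {
      for (fac in c(1 - perturbation, 1 + perturbation)) {
        edges <- spec$bin_edges
        edges[i] <- edges[i] * fac
        if (any(diff(edges) <= 0)) next
        sp <- cluster_spec("radius_bins", bin_edges = edges)
        pert <- suppressWarnings(
          summarize_clusters(cluster_bifurcations(records, sp)))
        for (m in metrics) {
          rel <- abs(pert[[m]] - base[[m]]) / pmax(abs(base[[m]]), 1e-12)
          rows[[length(rows) + 1]] <- data.frame(
            edge_index = i, factor = fac, metric = m,
            max_rel_change = max(rel, na.rm = TRUE))
        }
      }
    }
  }
  shifts <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(edge_index = integer(), factor = numeric(),
               metric = character(), max_rel_change = numeric())
  max_shift <- vapply(metrics, function(m) {
    v <- shifts$max_rel_change[shifts$metric == m]
    if (length(v) == 0) 0 else max(v)
  }, numeric(1))
  list(shifts = shifts, max_shift = max_shift)
}

#' Fraction of measured points inside the pulsatile sigma-gamma band
#'
#' @param records bifurcation records (need `gamma`, `sigma`).
#' @param tau scaling exponent of the band.
#' @param alpha_range Womersley-number range of the band.
#' @param n_gamma,n_alpha band grid resolution.
#' @param settings a [pulsatile_settings()].
#' @return fraction in \[0, 1\] of records whose (gamma, sigma) lies within
#'   the band envelope.
#' @export
band_coverage <- function(records, tau, alpha_range = c(0.01, 10),
                          n_gamma = 50, n_alpha = 25,
                          settings = pulsatile_settings()) {
  if (inherits(records, "bifurcation_set")) records <- records$records
  band <- sigma_gamma_band(tau, alpha_range, n_gamma = n_gamma,
                           n_alpha = n_alpha, settings = settings)
  mean(in_band(band, records$gamma, records$sigma))
}
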