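test_that("clustering partitions records under every mode", {
  rec <- extract_bifurcations(hk_tree())$records
  cl <- cluster_bifurcations(rec, cluster_spec(bin_edges = c(0.1, 0.3, 3)))
  expect_equal(sum(table(cl$cluster)), nrow(rec))
  # bin arithmetic: a 0.2 mm mother falls in the first bin (0.1 to 0.3],
  # a 0.4 mm mother in the second
  one <- data.frame(gamma = c(0.5, 0.5), sigma = 1.1, r_m = c(0.2, 0.4))
  lab <- cluster_bifurcations(one, cluster_spec(bin_edges = c(0.1, 0.3, 0.5)))
  expect_equal(as.integer(lab$cluster), c(1L, 2L))
  expect_equal(levels(lab$cluster), c("[0.1,0.3]", "(0.3,0.5]"))
  # records outside the edges are dropped with a warning
  expect_warning(
    cluster_bifurcations(rbind(one, data.frame(gamma = 1, sigma = 1,
                                               r_m = 9)),
                         cluster_spec(bin_edges = c(0.1, 0.3, 0.5))),
    "outside")

  # territory mode partitions all records
  clt <- cluster_bifurcations(rec, cluster_spec("territory"))
  expect_equal(sum(table(clt$cluster)), nrow(rec))
  expect_setequal(levels(clt$cluster), c("LAD", "LCx", "RCA"))

  # transmural mode agrees with the layer assignment on the tree
  tr3 <- assign_transmural_layer(hk_tree(), 3)
  rec3 <- extract_bifurcations(tr3)$records
  cl3 <- cluster_bifurcations(rec3, cluster_spec("transmural_layer"))
  expect_equal(as.integer(cl3$cluster), rec3$transmural_layer)

  clw <- cluster_bifurcations(rec, cluster_spec("weibel_generation"))
  expect_equal(sum(table(clw$cluster)), nrow(rec))
  expect_error(cluster_bifurcations(data.frame(gamma = 1, sigma = 1,
                                               r_m = 1),
                                    cluster_spec("territory")),
               "territory")
})

test_that("tau fitting recovers generating exponents deterministically", {
  f <- fit_tau(generate_matched_cloud(1 / 6, 50), seed = 9)
  expect_equal(f$tau_hat, 7 / 3, tolerance = 1e-6)
  f2 <- fit_tau(generate_matched_cloud(0, 50), seed = 9)
  expect_equal(f2$tau_hat, 2, tolerance = 1e-6)
  # determinism in (group, seed, n_starts)
  g <- extract_bifurcations(hk_tree())$records
  expect_identical(fit_tau(g, seed = 5), fit_tau(g, seed = 5))
  expect_error(fit_tau(g[1:2, ]), "at least 3")
  # degenerate gamma is flagged, not silent
  deg <- data.frame(gamma = rep(0.5, 5), sigma = c(1, 1.1, 1.2, 1.05, 1.3))
  expect_warning(fd <- fit_tau(deg), "low-confidence")
  expect_true(fd$low_confidence)
})

test_that("noisy recovery stays within the Monte-Carlo tolerance", {
  taus <- vapply(1:20, function(s) {
    tr <- generate_tree(synthetic_config(seed = s, r_min = 0.15,
      matching_law = list(type = "steady", tau = 7 / 3)))
    tr <- add_radius_noise(tr, 0.03, seed = s + 500)
    rec <- extract_bifurcations(tr)$records
    if (nrow(rec) > 500) rec <- rec[seq_len(500), ]
    fit_tau(rec, seed = s)$tau_hat
  }, numeric(1))
  expect_lt(abs(mean(taus) - 7 / 3), 0.05)
  expect_lt(sd(taus), 0.1)
})

test_that("fitted exponents track a radius-dependent generating exponent", {
  tr <- generate_tree(synthetic_config(seed = 5, r_min = 0.1,
    matching_law = list(type = "steady", tau = c(2.25, 3.5))))
  rec <- cluster_bifurcations(extract_bifurcations(tr)$records,
                              cluster_spec(bin_edges = c(0.1, 0.3, 0.5, 1, 3)))
  s <- summarize_clusters(rec, fit = TRUE, seed = 2)
  s <- s[!is.na(s$tau_hat) & s$n >= 30, ]
  expect_gte(nrow(s), 3)
  # clusters are ordered small to large radius: tau_hat must decrease
  expect_true(all(diff(s$tau_hat) < 0))
})

test_that("cluster summaries compute means, SEMs and asymmetric fractions", {
  rec <- data.frame(gamma = c(0.2, 0.4, 0.6, 0.8),
                    sigma = c(1.1, 1.1, 1.2, 1.2),
                    cluster = factor(rep("all", 4)))
  s <- summarize_clusters(rec)
  expect_equal(s$frac_asymmetric, 0.5)
  expect_equal(s$mean_gamma, 0.5)
  expect_equal(s$sem_gamma, sd(rec$gamma) / 2)
  ident <- data.frame(gamma = rep(0.3, 5), sigma = rep(1.05, 5),
                      cluster = factor(rep("a", 5)))
  s2 <- summarize_clusters(ident)
  expect_equal(s2$sem_sigma, 0)
  expect_equal(s2$sem_gamma, 0)
  # empty clusters retained with n = 0; inputs not mutated
  rec$cluster <- factor("all", levels = c("all", "empty"))
  before <- rec
  s3 <- summarize_clusters(rec)
  expect_equal(s3$n, c(4, 0))
  expect_identical(rec, before)
})

test_that("rank-based cluster comparison behaves as a two-sample test", {
  set.seed(31)
  a <- data.frame(gamma = rbeta(200, 3, 7), sigma = 1.1)
  b <- data.frame(gamma = rbeta(200, 7, 3), sigma = 1.1)
  rec <- rbind(cbind(a, cluster = "prox"), cbind(b, cluster = "dist"))
  rec$cluster <- factor(rec$cluster)
  cmp <- compare_clusters(rec, "gamma")
  expect_lt(cmp$p_value, 0.01)
  expect_true(cmp$significant)
  expect_identical(attr(cmp, "test"), "wilcoxon_rank_sum")
  # identical groups: no significance
  rec2 <- rec
  rec2$gamma <- rep(a$gamma, 2)
  cmp2 <- compare_clusters(rec2, "gamma")
  expect_gt(cmp2$p_value, 0.5)
  # order of the pair does not change the p-value
  rec3 <- rec
  rec3$cluster <- factor(rec3$cluster, levels = rev(levels(rec$cluster)))
  expect_equal(compare_clusters(rec3, "gamma")$p_value, cmp$p_value)
  # paired variant is available
  cmp4 <- compare_clusters(rec, "gamma", paired = TRUE)
  expect_identical(attr(cmp4, "test"), "wilcoxon_signed_rank")
})

test_that("reflection summaries respect bounds and distal trends", {
  tr <- generate_tree(synthetic_config(seed = 2, r_min = 0.3,
    matching_law = list(type = "steady", tau = 2), trifurcation_rate = 0))
  rs <- reflection_summary(tr, assign_material(tr, "uniform_pws"),
                           cluster_spec(bin_edges = c(0.3, 1, 3)))
  expect_true(all(abs(rs$Rf_mean[rs$n > 0]) < 1e-12))
  qcols <- grep("_q", names(rs), value = TRUE)
  expect_true(all(abs(as.matrix(rs[rs$n > 0, qcols])) <= 1))

  # rising symmetry toward the periphery drives Rd1 down and Rd2 up
  tr2 <- hk_tree(seed = 11, r_min = 0.1)
  rs2 <- reflection_summary(tr2, assign_material(tr2, "uniform_pws"),
                            cluster_spec(bin_edges = c(0.1, 0.3, 1, 3)))
  rs2 <- rs2[rs2$n > 10, ]  # small to large radius
  expect_true(all(diff(rs2$Rd1_mean) > 0))
  expect_true(all(diff(rs2$Rd2_mean) < 0))
})

test_that("bin sensitivity reports no shift for null perturbations", {
  rec <- extract_bifurcations(hk_tree())$records
  z <- bin_sensitivity(rec, cluster_spec(bin_edges = c(0.1, 0.3, 0.5, 3)),
                       perturbation = 0)
  expect_equal(unname(z$max_shift), c(0, 0, 0))
  # single bin: no internal edges, empty report
  z1 <- bin_sensitivity(rec, cluster_spec(bin_edges = c(0.1, 3)))
  expect_equal(nrow(z1$shifts), 0)
  expect_error(bin_sensitivity(rec, cluster_spec("territory")), "radius-bin")
})

test_that("band coverage counts points inside the pulsatile envelope", {
  hk <- generate_matched_cloud(1 / 6, 40)
  expect_equal(band_coverage(hk, 7 / 3, n_gamma = 40, n_alpha = 6), 1)
  # the Murray steady curve lies wholly inside the pulsatile Huo-Kassab
  # band (its low-alpha edge is the steady curve with exponent 7/3 + 1)
  mur <- generate_matched_cloud(1 / 2, 40)
  expect_equal(band_coverage(mur, 7 / 3, n_gamma = 40, n_alpha = 6), 1)
  # a steeper-exponent curve leaves the band; a half-displaced cloud gives
  # fractional coverage
  tau4 <- generate_matched_cloud(1, 40)
  expect_equal(band_coverage(tau4, 7 / 3, n_gamma = 40, n_alpha = 6), 0)
  mixed <- hk
  mixed$sigma[seq(2, 40, by = 2)] <- mixed$sigma[seq(2, 40, by = 2)] + 0.5
  cov_m <- band_coverage(mixed, 7 / 3, n_gamma = 40, n_alpha = 6)
  expect_equal(cov_m, 0.5)
})
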