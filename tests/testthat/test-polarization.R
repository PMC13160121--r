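test_that("axial separation: perfect split, null case, brute-force toys", {
  set.seed(51)
  P <- rbind(cbind(rnorm(50) - 20, rnorm(50), rnorm(50)),
             cbind(rnorm(50) + 20, rnorm(50), rnorm(50)))
  tab <- toy_table(P, types = rep(c("A", "B"), each = 50))
  ax <- find_separation_axis(tab, "true_type")
  s <- axial_separation(tab, ax)
  expect_equal(s$axial_auc, 1.0)
  expect_equal(s$segregation_pct, 100)

  # both groups from the identical distribution: near-chance scores
  null <- generate_aggregate(synthetic_params(pattern = "mixed", seed = 52))
  axn <- find_separation_axis(null, "true_type")
  sn <- axial_separation(null, axn)
  expect_lt(sn$axial_auc, 0.68)
  expect_lt(sn$segregation_pct, 68)
  expect_gte(sn$segregation_pct, 50)

  # toys: folded AUC equals all-pairs enumeration along the same axis
  set.seed(53)
  for (i in 1:10) {
    n <- sample(9:12, 1)
    Pt <- matrix(rnorm(3 * n), ncol = 3)
    ty <- rep(c("A", "B"), c(5, n - 5))
    tt <- toy_table(Pt, types = ty)
    axt <- find_separation_axis(tt, "true_type", min_group = 4)
    z <- drop(sweep(Pt, 2, axt$origin) %*% axt$direction)
    expect_equal(axial_separation(tt, axt, min_group = 4)$axial_auc,
                 fold(auc_bruteforce(z, factor(ty))))
  }
})

test_that("permutation test: sharp hemisphere hits the minimal p-value", {
  a <- hemi_table(seed = 61)
  pt <- permutation_test(a, "true_type", n_perm = 199, seed = 62)
  expect_equal(pt$p, 1 / 200)
  expect_true(pt$polarized)
  expect_gte(pt$p, 1 / (pt$n_perm + 1))
  expect_error(permutation_test(a, "true_type", n_perm = 50), "n_perm")
})

test_that("exact permutation p matches exhaustive enumeration on a toy", {
  set.seed(63)
  P <- rbind(matrix(rnorm(12, sd = 2), 4, 3) - 3,
             matrix(rnorm(12, sd = 2), 4, 3) + 3)
  ty <- rep(c("A", "B"), each = 4)
  tab <- toy_table(P, types = ty)
  pt <- permutation_test(tab, "true_type", exact = TRUE, min_group = 4)
  expect_equal(pt$n_perm, choose(8, 4))

  # oracle: enumerate every distinct assignment through the public axis API
  idx <- combn(8, 4)
  stats <- apply(idx, 2, function(ii) {
    ty2 <- ifelse(seq_len(8) %in% ii, "A", "B")
    t2 <- toy_table(P, types = ty2)
    find_separation_axis(t2, "true_type", min_group = 4)$statistic
  })
  obs <- find_separation_axis(tab, "true_type", min_group = 4)$statistic
  expect_equal(pt$p, mean(stats >= obs - 1e-12))
})

test_that("radial separation: core-shell vs hemisphere, brute-force radii", {
  # radii are measured to the estimated centroid, which sits ~R/sqrt(n) off
  # the true center, so a sharp core-shell splits almost (not exactly) cleanly
  core <- generate_aggregate(synthetic_params(pattern = "radial",
                                              interface_width = 0, seed = 71))
  expect_gte(radial_separation(core, "true_type")$radial_auc, 0.99)

  hemi <- hemi_table(seed = 72)
  expect_lt(radial_separation(hemi, "true_type")$radial_auc, 0.65)

  # toy with symmetric pairs: centroid at origin, radii known exactly
  r <- c(1, 2, 3, 4, 5, 6)
  P <- rbind(cbind(r, 0, 0), cbind(-r, 0, 0))
  ty <- rep(c("A", "B"), 6)
  tab <- toy_table(P, types = ty)
  rs <- radial_separation(tab, "true_type")
  expect_equal(rs$radial_auc,
               fold(auc_bruteforce(c(r, r), factor(ty))))
  expect_s3_class(rs$trace, "line_trace")
  expect_equal(sum(rs$trace$counts), 12)
})

test_that("mixing score: sorted, random, and the hand-computed 3x3 grid", {
  # sharp hemispheres at n = 200, k = 10: the k-NN radius is ~15 um, so the
  # ~40% of nuclei within one neighbourhood of the plane see some mixing and
  # the expected score is ~0.8, well clear of the ~0 mixed baseline
  sorted <- hemi_table(seed = 81)
  expect_gte(neighbor_mixing_score(sorted, "true_type", k = 10), 0.7)

  scores <- sapply(82:86, function(s)
    neighbor_mixing_score(generate_aggregate(
      synthetic_params(pattern = "mixed", seed = s)), "true_type", k = 10))
  expect_true(all(abs(scores) <= 0.1))

  # 3x3 grid, 2x2 type-A patch, k = 2, ties by distance then nucleus order:
  # hand enumeration gives M = 13/18, M0 = 41/81, score = 35/80
  g <- expand.grid(x = 0:2, y = 0:2)
  ty <- ifelse(g$x <= 1 & g$y <= 1, "A", "B")
  tab <- toy_table(cbind(g$x, g$y), types = ty)
  expect_equal(neighbor_mixing_score(tab, "true_type", k = 2), 35 / 80)

  expect_error(neighbor_mixing_score(tab, "true_type", k = 9), "k must be")
})

test_that("pattern rules follow the threshold decision order", {
  thr <- pattern_thresholds()
  expect_equal(classify_pattern(0.95, 0.55, 0.8, TRUE, thr), "hemispherical")
  expect_equal(classify_pattern(0.6, 0.95, 0.5, FALSE, thr), "radial")
  expect_equal(classify_pattern(0.7, 0.6, 0.5, TRUE, thr), "fragmented")
  expect_equal(classify_pattern(0.55, 0.52, 0.02, FALSE, thr), "mixed")
  # hemispherical requires the permutation call
  expect_equal(classify_pattern(0.95, 0.55, 0.1, FALSE, thr), "mixed")
  expect_error(pattern_thresholds(tau_ax = 0.3), "tau_ax")
  expect_error(pattern_thresholds(tau_mix = 2), "tau_mix")
})

test_that("generator patterns are recovered by the full polarization fit", {
  fits <- list(
    mixed = polarize(generate_aggregate(synthetic_params(
      pattern = "mixed", seed = 91)), seed = 191),
    hemispherical = polarize(generate_aggregate(synthetic_params(
      pattern = "hemispherical", interface_width = 0, seed = 92)), seed = 192),
    radial = polarize(generate_aggregate(synthetic_params(
      pattern = "radial", interface_width = 0, seed = 93)), seed = 193))
  for (nm in names(fits)) expect_equal(fits[[nm]]$pattern, nm, info = nm)
  df <- as.data.frame(fits$hemispherical)
  expect_identical(df$pattern, "hemispherical")
  expect_true(df$polarized)
  expect_gte(df$axial_auc, 0.99)
})

test_that("permutation p-values are super-uniform under the mixed null", {
  ps <- sapply(1:300, function(s)
    permutation_test(generate_aggregate(synthetic_params(
      pattern = "mixed", n_cells = 60, seed = 300 + s)),
      "true_type", n_perm = 99, seed = 700 + s)$p)
  expect_gte(min(ps), 1 / 100)
  # one-sided KS against anti-conservatism (ecdf above uniform)
  ks <- suppressWarnings(ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("separation strengthens monotonically as the interface sharpens", {
  mean_auc <- sapply(c(0.3, 0.1, 0), function(w) {
    mean(sapply(1:12, function(s) {
      a <- hemi_table(seed = s, width = w, n = 100)
      find_separation_axis(a, "true_type")$statistic
    }))
  })
  expect_true(all(diff(mean_auc) >= 0))
})
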