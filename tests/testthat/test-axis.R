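test_that("two clouds offset along z give the z axis, reference on the left", {
  set.seed(31)
  n <- 2000
  P <- rbind(cbind(rnorm(n), rnorm(n), rnorm(n) - 4),
             cbind(rnorm(n), rnorm(n), rnorm(n) + 4))
  tab <- toy_table(P, types = rep(c("A", "B"), each = n))
  ax <- find_separation_axis(tab, "true_type")
  expect_gte(abs(ax$direction[[3]]), 0.999)
  # orientation: reference (first level, "A") projects lower
  z <- drop(sweep(nucleus_positions(tab), 2, ax$origin) %*% ax$direction)
  expect_lt(mean(z[tab$true_type == "A"]), mean(z[tab$true_type == "B"]))
})

test_that("the axis is rotation-equivariant and outputs translation-invariant", {
  a <- hemi_table(seed = 23, width = 0.1)
  ax <- find_separation_axis(a, "true_type")
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
       rbind(c(1, 0, 0), c(0, cos(1.1), -sin(1.1)), c(0, sin(1.1), cos(1.1)))
  Pr <- nucleus_positions(a) %*% t(R)
  rot <- toy_table(Pr, types = a$true_type)
  axr <- find_separation_axis(rot, "true_type")
  expect_equal(axr$direction, drop(R %*% ax$direction), tolerance = 1e-6)

  shift <- toy_table(sweep(nucleus_positions(a), 2, c(100, -50, 7), "+"),
                     types = a$true_type)
  axs <- find_separation_axis(shift, "true_type")
  expect_equal(axs$direction, ax$direction, tolerance = 1e-9)
  expect_equal(axs$statistic, ax$statistic)
})

test_that("fisher and exhaustive direction search agree on sharp hemispheres", {
  angs <- vapply(41:45, function(s) {
    a <- hemi_table(seed = s, width = 0, n = 100)
    f <- find_separation_axis(a, "true_type", method = "fisher")
    g <- find_separation_axis(a, "true_type", method = "search")
    acos(pmin(1, abs(sum(f$direction * g$direction)))) * 180 / pi
  }, 0)
  expect_lte(mean(angs), 5)
})

test_that("projected AUC equals the brute-force Mann-Whitney statistic", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    z <- sample(c(rnorm(n), round(rnorm(2), 0)))[1:n]  # include ties sometimes
    g <- factor(sample(rep(c("u", "v"), c(2, n - 2))))
    expect_equal(gastrupol:::projected_auc(z, g), auc_bruteforce(z, g))
  }
})

test_that("line trace matches the hand-computed 3-bin example", {
  coords <- c(0.05, 0.15, 0.45, 0.55, 0.85, 0.95)
  tab <- toy_table(cbind(coords, 0, 0),
                   intensities = list(M = rep(1, 6)))
  tab$call_M <- c(0L, 0L, 0L, 1L, 1L, 1L)
  ax <- structure(list(direction = c(1, 0, 0), origin = c(0, 0, 0),
                       method = "fisher", statistic = 1,
                       dichotomy = "call_M", levels = c("M-", "M+"), n = 6),
                  class = "separation_axis")
  tr <- compute_line_trace(tab, ax, marker = "M", n_bins = 3)
  expect_equal(tr$fraction_positive, c(0, 0.5, 1))
  expect_equal(tr$counts, c(2, 2, 2))
  expect_equal(sum(tr$counts), 6)
  expect_error(compute_line_trace(tab, ax, marker = "M", n_bins = 2), "n_bins")
})

test_that("width-0 hemisphere gives a step profile with one interface bin", {
  a <- hemi_table(seed = 9)
  ax <- find_separation_axis(a, "true_type", method = "search")
  tr <- compute_line_trace(a, ax, marker = NULL, n_bins = 20)
  f <- tr$fraction_positive[!is.na(tr$fraction_positive)]
  expect_lte(sum(f > 0 & f < 1), 1)
  expect_true(!is.unsorted(f))
})

test_that("mixed-aggregate bin fractions stay inside exact binomial bounds", {
  a <- generate_aggregate(synthetic_params(pattern = "mixed", seed = 33))
  a$call_mCherry <- as.integer(a$true_type == "A")
  ax <- find_separation_axis(a, "true_type")
  tr <- compute_line_trace(a, ax, marker = "mCherry", n_bins = 10)
  for (b in which(tr$counts > 0)) {
    k <- tr$fraction_positive[b] * tr$counts[b]
    expect_gte(k, qbinom(0.005, tr$counts[b], 0.5))
    expect_lte(k, qbinom(0.995, tr$counts[b], 0.5))
  }
})

test_that("traces are scale-invariant and flip with the dichotomy", {
  a <- hemi_table(seed = 15, width = 0.1)
  a$call_mCherry <- as.integer(a$true_type == "A")
  ax <- find_separation_axis(a, "true_type")
  tr <- compute_line_trace(a, ax, marker = "mCherry")

  scaled <- toy_table(nucleus_positions(a) * 3.7, types = a$true_type)
  scaled$call_marker <- a$call_mCherry
  axs <- find_separation_axis(scaled, "true_type")
  trs <- compute_line_trace(scaled, axs, marker = "marker")
  expect_equal(trs$fraction_positive, tr$fraction_positive)
  expect_equal(trs$counts, tr$counts)

  flipped <- factor(ifelse(a$true_type == "A", "B", "A"), levels = c("A", "B"))
  axf <- find_separation_axis(a, flipped)
  trf <- compute_line_trace(a, axf, marker = "mCherry")
  expect_equal(trf$fraction_positive, rev(tr$fraction_positive))
  expect_equal(trf$counts, rev(tr$counts))
})

test_that("pooling: identical traces, the {0,1} SD case, and recomputation", {
  a <- hemi_table(seed = 3, width = 0.2)
  ax <- find_separation_axis(a, "true_type")
  tr <- compute_line_trace(a, ax)
  pp <- pool_line_traces(list(tr, tr, tr))
  expect_equal(pp$mean, tr$fraction_positive)
  expect_equal(unname(pp$sd[pp$n_contributing == 3]),
               rep(0, sum(pp$n_contributing == 3)))

  t0 <- tr; t1 <- tr
  t0$fraction_positive <- rep(0, tr$n_bins)
  t1$fraction_positive <- rep(1, tr$n_bins)
  p2 <- pool_line_traces(list(t0, t1))
  expect_equal(unname(p2$mean), rep(0.5, tr$n_bins))
  expect_equal(unname(p2$sd), rep(sqrt(0.5), tr$n_bins), tolerance = 1e-12)

  traces <- lapply(c(5, 6, 8), function(s) {
    b <- hemi_table(seed = s, width = 0.2)
    compute_line_trace(b, find_separation_axis(b, "true_type"))
  })
  pool <- pool_line_traces(traces)
  M <- do.call(rbind, lapply(traces, `[[`, "fraction_positive"))
  expect_equal(pool$mean, colMeans(M, na.rm = TRUE))

  short <- compute_line_trace(a, ax, n_bins = 10)
  expect_error(pool_line_traces(list(tr, short)), "binning")
})
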