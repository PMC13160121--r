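#' Axial separation scores along a fitted axis
#'
#' `axial_auc` is the projected-coordinate AUC of the dichotomy along the
#' axis, folded to [0.5, 1] (axis sign is a convention, so separation is
#' reported sign-free). `segregation_pct` is 100 x the best balanced accuracy
#' over all single split points along the axis, each group scored on its
#' majority side — balanced so unequal group sizes do not inflate the score.
#'
#' @param table an [aggregate_table()].
#' @param axis a `separation_axis` fitted on this aggregate's dichotomy.
#' @param dichotomy see [dichotomy_labels()]; defaults to the axis dichotomy.
#' @param min_group group-size floor.
#' @return list with `axial_auc` and `segregation_pct`.
#' @export
axial_separation <- function(table, axis, dichotomy = axis$dichotomy,
                             min_group = 5L) {
  g <- dichotomy_labels(table, dichotomy, min_group = min_group)
  P <- nucleus_positions(table)
  z <- drop(sweep(P, 2, axis$origin) %*% axis$direction)
  list(axial_auc = fold_auc(projected_auc(z, g)),
       segregation_pct = 100 * best_balanced_accuracy(z, g))
}

# max over all 1D split points (and side assignments) of balanced accuracy
best_balanced_accuracy <- function(z, g) {
  ord <- order(z)
  i1 <- (as.integer(g) == 1L)[ord]
  n1 <- sum(i1); n2 <- sum(!i1)
  # split after position k (k = 0..n): group1 on the left
  c1 <- c(0, cumsum(i1))
  c2 <- c(0, cumsum(!i1))
  bacc <- (c1 / n1 + (n2 - c2) / n2) / 2
  max(pmax(bacc, 1 - bacc))
}

#' Permutation test for spatial polarization
#'
#' Tests an aggregate's dichotomy against the well-mixed null: labels are
#' permuted over the fixed nucleus positions and, for every permutation, the
#' separation axis is refit and the folded axial AUC recomputed. Refitting
#' inside the null is essential — the observed statistic is a maximum over
#' directions, so a null that skips the maximization is anti-conservative.
#' The Monte-Carlo p-value is `(1 + #(null >= observed)) / (n_perm + 1)`.
#' With `exact = TRUE` all distinct label assignments are enumerated instead
#' (small n only) and `p = #(stat >= observed) / N`.
#'
#' @param table an [aggregate_table()].
#' @param dichotomy see [dichotomy_labels()].
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @param method axis-fitting method used for observed and null statistics.
#' @param alpha significance level for the `polarized` call.
#' @param exact enumerate all distinct assignments (requires
#'   `choose(n, n1) <= max_exact`).
#' @param max_exact guard for exact enumeration.
#' @param min_group group-size floor.
#' @return object of class `polarization_test`: `p`, `observed`, `null`
#'   (vector of null statistics), `n_perm`, `alpha`, `polarized`.
#' @export
permutation_test <- function(table, dichotomy = NULL, n_perm = 199L,
                             seed = NULL, method = "fisher", alpha = 0.05,
                             exact = FALSE, max_exact = 50000L,
                             min_group = 5L) {
  g <- dichotomy_labels(table, dichotomy, min_group = min_group)
  P <- nucleus_positions(table)
  Pc <- sweep(P, 2, colMeans(P))
  stat <- function(gg) {
    w <- if (method == "fisher") fisher_direction(Pc, gg)
         else stop("permutation_test supports method 'fisher'")
    fold_auc(projected_auc(drop(Pc %*% w), gg))
  }
  observed <- stat(g)
  n <- length(g)
  if (exact) {
    n1 <- sum(as.integer(g) == 1L)
    N <- choose(n, n1)
    if (N > max_exact)
      stop("exact enumeration infeasible: choose(", n, ",", n1, ") = ", N)
    idx <- utils::combn(n, n1)
    null <- apply(idx, 2, function(ii) {
      gg <- factor(ifelse(seq_len(n) %in% ii, levels(g)[1L], levels(g)[2L]),
                   levels = levels(g))
      stat(gg)
    })
    p <- mean(null >= observed - 1e-12)
    n_perm <- as.integer(N)
  } else {
    if (n_perm < 99) stop("n_perm must be >= 99")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    null <- vapply(seq_len(n_perm), function(i) stat(sample(g)), 0)
    p <- (1 + sum(null >= observed - 1e-12)) / (n_perm + 1)
  }
  structure(list(p = p, observed = observed, null = null,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 polarized = p < alpha, exact = exact),
            class = "polarization_test")
}

#' @export
print.polarization_test <- function(x, ...) {
  cat("<polarization_test> observed axial AUC = ", signif(x$observed, 4),
      ", p = ", signif(x$p, 4), " (", x$n_perm,
      if (x$exact) " exact assignments" else " permutations",
      ") -> ", if (x$polarized) "polarized" else "not polarized",
      " at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Radial (core-shell) separation
#'
#' AUC of classifying the dichotomy from each nucleus's distance to the
#' aggregate centroid, folded to [0.5, 1]; high values indicate one
#' population forming a core inside a shell of the other. A radial line
#' trace (fraction positive vs normalized radius) is returned alongside.
#'
#' @inheritParams axial_separation
#' @param n_bins bins for the radial trace.
#' @return list with `radial_auc` and `trace` (a `line_trace` over
#'   normalized radius).
#' @export
radial_separation <- function(table, dichotomy = NULL, n_bins = 20L,
                              min_group = 5L) {
  g <- dichotomy_labels(table, dichotomy, min_group = min_group)
  P <- nucleus_positions(table)
  r <- sqrt(rowSums(sweep(P, 2, colMeans(P))^2))
  auc <- fold_auc(projected_auc(r, g))
  rn <- r / max(r)
  bin <- pmin(floor(rn * n_bins) + 1L, n_bins)
  pos <- as.integer(g) == 2L
  counts <- tabulate(bin, n_bins)
  frac <- ifelse(counts > 0, tabulate(bin[pos], n_bins) / counts, NA_real_)
  trace <- structure(list(label = paste0("radial:", levels(g)[2L]),
                          n_bins = as.integer(n_bins),
                          bin_centers = (seq_len(n_bins) - 0.5) / n_bins,
                          fraction_positive = frac, counts = counts,
                          n = length(r),
                          aggregate_id = attr(table, "aggregate_id")),
                     class = "line_trace")
  list(radial_auc = auc, trace = trace)
}

#' k-nearest-neighbour mixing score
#'
#' `M` is the mean, over nuclei, of the fraction of each nucleus's `k`
#' nearest neighbours sharing its type; `M0 = sum(p_t^2)` is its expectation
#' under random labelling at the observed type fractions. The score
#' `(M - M0) / (1 - M0)` is ~0 for well-mixed aggregates and approaches 1
#' for fully sorted ones, detecting local patchiness without any global
#' symmetry. Neighbour ties are broken by distance, then nucleus order.
#'
#' @param table an [aggregate_table()].
#' @param dichotomy see [dichotomy_labels()] (any 2-level labelling).
#' @param k number of neighbours (default 10; must be < n).
#' @return mixing score in [-1, 1].
#' @export
neighbor_mixing_score <- function(table, dichotomy = NULL, k = 10L) {
  g <- dichotomy_labels(table, dichotomy, min_group = 1L)
  P <- nucleus_positions(table)
  n <- nrow(P)
  if (k >= n) stop("k must be smaller than the number of nuclei (", n, ")")
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  same <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    mean(g[nb] == g[i])
  }, 0)
  M <- mean(same)
  p <- as.vector(table(g)) / n
  M0 <- sum(p^2)
  (M - M0) / (1 - M0)
}

#' Default thresholds for pattern classification
#'
#' @param tau_ax minimum folded axial AUC for the hemispherical call.
#' @param tau_rad minimum folded radial AUC for the radial call.
#' @param tau_mix minimum mixing score for the fragmented call.
#' @param alpha significance level of the polarization test.
#' @return named list, validated.
#' @export
pattern_thresholds <- function(tau_ax = 0.8, tau_rad = 0.8, tau_mix = 0.3,
                               alpha = 0.05) {
  if (tau_ax < 0.5 || tau_ax > 1 || tau_rad < 0.5 || tau_rad > 1)
    stop("tau_ax and tau_rad must lie in [0.5, 1]")
  if (tau_mix < 0 || tau_mix > 1) stop("tau_mix must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  list(tau_ax = tau_ax, tau_rad = tau_rad, tau_mix = tau_mix, alpha = alpha)
}

#' Classify the spatial pattern of an aggregate
#'
#' Decision rules, evaluated in order on the component scores:
#' hemispherical iff polarized and `axial_auc >= tau_ax` and
#' `radial_auc < tau_rad`; radial iff `radial_auc >= tau_rad` and
#' `axial_auc < tau_ax`; fragmented iff neither and
#' `mixing_score >= tau_mix`; else mixed.
#'
#' @param axial_auc,radial_auc folded AUCs in [0.5, 1].
#' @param mixing_score k-NN mixing score.
#' @param polarized logical, from the permutation test.
#' @param thresholds a [pattern_thresholds()] list.
#' @return one of `"mixed"`, `"hemispherical"`, `"radial"`, `"fragmented"`.
#' @export
classify_pattern <- function(axial_auc, radial_auc, mixing_score, polarized,
                             thresholds = pattern_thresholds()) {
  thresholds <- do.call(pattern_thresholds, thresholds[c("tau_ax", "tau_rad",
                                                         "tau_mix", "alpha")])
  if (isTRUE(polarized) && axial_auc >= thresholds$tau_ax &&
      radial_auc < thresholds$tau_rad) return("hemispherical")
  if (radial_auc >= thresholds$tau_rad && axial_auc < thresholds$tau_ax)
    return("radial")
  if (mixing_score >= thresholds$tau_mix) return("fragmented")
  "mixed"
}

#' Score an aggregate's polarization and classify its pattern
#'
#' The central fit of the package: given one aggregate and a two-population
#' dichotomy it (i) fits the maximal-separation axis, (ii) computes the folded
#' axial AUC and the best-split segregation percentage, (iii) runs the
#' axis-refitting permutation test against the well-mixed null, (iv) computes
#' the radial AUC and the k-NN mixing score, and (v) classifies the aggregate
#' as mixed, hemispherical, radial or fragmented.
#'
#' @param table an [aggregate_table()].
#' @param dichotomy see [dichotomy_labels()].
#' @param axis_method `"fisher"` (default) or `"search"` for the reported
#'   axis (the permutation null always refits with `"fisher"`).
#' @param n_perm,alpha permutation test parameters.
#' @param k neighbours for the mixing score.
#' @param n_bins bins for the dichotomy line trace.
#' @param thresholds [pattern_thresholds()] for classification.
#' @param seed RNG seed for the permutation draw.
#' @param min_group group-size floor for the dichotomy.
#' @return object of class `polarization` with components `aggregate_id`,
#'   `axis`, `axial_auc`, `segregation_pct`, `perm` (`polarization_test`),
#'   `perm_p`, `polarized`, `radial_auc`, `radial_trace`, `mixing_score`,
#'   `pattern`, `trace`, `thresholds_used`, `n`.
#' @export
polarize <- function(table, dichotomy = NULL, axis_method = "fisher",
                     n_perm = 199L, alpha = 0.05, k = 10L, n_bins = 20L,
                     thresholds = pattern_thresholds(alpha = alpha),
                     seed = NULL, min_group = 5L) {
  g <- dichotomy_labels(table, dichotomy, min_group = min_group)
  axis <- find_separation_axis(table, dichotomy, method = axis_method,
                               min_group = min_group)
  ax <- axial_separation(table, axis, dichotomy, min_group = min_group)
  perm <- permutation_test(table, dichotomy, n_perm = n_perm, seed = seed,
                           alpha = thresholds$alpha, min_group = min_group)
  rad <- radial_separation(table, dichotomy, n_bins = n_bins,
                           min_group = min_group)
  mix <- neighbor_mixing_score(table, dichotomy, k = k)
  pattern <- classify_pattern(ax$axial_auc, rad$radial_auc, mix,
                              perm$polarized, thresholds)
  trace <- compute_line_trace(table, axis, marker = NULL, n_bins = n_bins)
  structure(list(aggregate_id = attr(table, "aggregate_id"),
                 dichotomy = attr(g, "dichotomy_label"), levels = levels(g),
                 axis = axis, axial_auc = ax$axial_auc,
                 segregation_pct = ax$segregation_pct,
                 perm = perm, perm_p = perm$p, polarized = perm$polarized,
                 radial_auc = rad$radial_auc, radial_trace = rad$trace,
                 mixing_score = mix, pattern = pattern, trace = trace,
                 thresholds_used = thresholds, n = nrow(table)),
            class = "polarization")
}

#' @export
print.polarization <- function(x, ...) {
  cat("<polarization> ", x$aggregate_id, " (", x$n, " nuclei, ",
      x$dichotomy, ": ", paste(x$levels, collapse = " vs "), ")\n",
      "  axial AUC ", signif(x$axial_auc, 4),
      " | segregation ", signif(x$segregation_pct, 4), "%",
      " | perm p ", signif(x$perm_p, 4),
      " | radial AUC ", signif(x$radial_auc, 4),
      " | mixing ", signif(x$mixing_score, 3), "\n",
      "  pattern: ", x$pattern,
      if (x$polarized) " (polarized)" else " (not polarized)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.polarization <- function(object, ...) {
  print(object)
  cat("  thresholds: ",
      paste(names(object$thresholds_used),
            unlist(object$thresholds_used), sep = "=", collapse = ", "),
      "\n  axis: ", object$axis$method, " (",
      paste(signif(object$axis$direction, 3), collapse = ", "), ")\n", sep = "")
  invisible(object)
}

#' @export
as.data.frame.polarization <- function(x, ...) {
  data.frame(aggregate_id = x$aggregate_id, n_nuclei = x$n,
             dichotomy = x$dichotomy,
             axial_auc = x$axial_auc, segregation_pct = x$segregation_pct,
             perm_p = x$perm_p, polarized = x$polarized,
             radial_auc = x$radial_auc, mixing_score = x$mixing_score,
             pattern = x$pattern, stringsAsFactors = FALSE)
}

#' @export
plot.polarization <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$trace, main = paste0(x$aggregate_id, ": axial profile"))
  graphics::hist(x$perm$null, breaks = 20,
                 xlim = range(c(x$perm$null, x$perm$observed)),
                 main = "permutation null", xlab = "folded axial AUC")
  graphics::abline(v = x$perm$observed, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Cohort-calibrated polarization threshold
#'
#' Literal analogue of declaring polarization by deviation from a dark
#' (unilluminated, well-mixed) cohort: the threshold is the `q`-th quantile
#' of the dark cohort's folded axial AUCs, and an aggregate is polarized if
#' its own score exceeds it. Provided as an alternative to the per-aggregate
#' permutation test when a dark cohort is available.
#'
#' @param dark_scores folded axial AUCs of the dark/control cohort.
#' @param q quantile (default 0.95).
#' @return threshold (numeric scalar).
#' @export
calibration_threshold <- function(dark_scores, q = 0.95) {
  stats::quantile(dark_scores, q, names = FALSE, type = 7)
}
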