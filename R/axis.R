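# AUC of classifying `g` (second level = "positive") from scalar scores,
# tie-aware (midranks): equals the Mann-Whitney U statistic / (n1*n2)
projected_auc <- function(z, g) {
  i2 <- as.integer(g) == 2L
  n1 <- sum(!i2); n2 <- sum(i2)
  r <- rank(z)
  (sum(r[i2]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

fold_auc <- function(auc) 0.5 + abs(auc - 0.5)

# near-uniform directions on the sphere (Fibonacci lattice) or circle
direction_grid <- function(n, d) {
  if (d == 2L) {
    th <- pi * (seq_len(n) - 0.5) / n      # half circle; sign handled by folding
    cbind(cos(th), sin(th))
  } else {
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    th <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  }
}

fisher_direction <- function(P, g, lambda = 1e-3) {
  d <- ncol(P)
  i2 <- as.integer(g) == 2L
  m1 <- colMeans(P[!i2, , drop = FALSE])
  m2 <- colMeans(P[i2, , drop = FALSE])
  diff <- m2 - m1
  n <- nrow(P); n1 <- sum(!i2); n2 <- sum(i2)
  Pc <- sweep(P, 2, colMeans(P))
  St <- crossprod(Pc)                       # total scatter
  Sw <- St - (n1 * n2 / n) * tcrossprod(diff)   # pooled within-class scatter
  Sw <- Sw / max(n - 2, 1)
  tr <- sum(diag(Sw))
  if (tr <= 0) stop("all points coincident; no separation axis exists")
  w <- solve(Sw + lambda * (tr / d) * diag(d), diff)
  unname(w / sqrt(sum(w^2)))
}

orient_direction <- function(w, P, g) {
  z <- drop(P %*% w)
  ref <- as.integer(g) == 1L
  dm <- mean(z[ref]) - mean(z[!ref])
  if (dm > 0) return(-w)
  if (dm < 0) return(w)
  # exact tie: deterministic lexicographic rule
  cmp <- w - (-w)
  nz <- which(cmp != 0)
  if (!length(nz) || cmp[nz[[1L]]] > 0) w else -w
}

#' Maximal-separation axis between two cell populations
#'
#' Finds the spatial direction along which the two groups of a dichotomy
#' (e.g. WT vs optoWnt genotype, or marker-positive vs -negative) are best
#' resolved, the coordinate system for all line traces. `method = "fisher"`
#' (default) takes the two-class linear discriminant direction — the group
#' centroid difference whitened by the pooled within-class covariance,
#' regularized by `lambda * trace/d` on the diagonal. `method = "search"`
#' maximizes the projected AUC directly over >= `n_dir` near-uniform
#' directions plus one local cone refinement. The direction is oriented so
#' the reference (first) group's mean projection is the lower one; exact
#' ties are broken lexicographically.
#'
#' @param table an [aggregate_table()].
#' @param dichotomy see [dichotomy_labels()].
#' @param method `"fisher"` or `"search"`.
#' @param lambda ridge regularization for the pooled covariance.
#' @param n_dir number of grid directions for `"search"`.
#' @param min_group group-size floor (default 5).
#' @return object of class `separation_axis`: unit `direction`, `origin`
#'   (centroid of all nuclei), `method`, `statistic` (projected AUC at the
#'   optimum, folded to [0.5, 1]) and the dichotomy used.
#' @export
find_separation_axis <- function(table, dichotomy = NULL,
                                 method = c("fisher", "search"),
                                 lambda = 1e-3, n_dir = 10000L,
                                 min_group = 5L) {
  method <- match.arg(method)
  g <- dichotomy_labels(table, dichotomy, min_group = min_group)
  P <- nucleus_positions(table)
  origin <- colMeans(P)
  Pc <- sweep(P, 2, origin)
  if (method == "fisher") {
    w <- fisher_direction(Pc, g, lambda = lambda)
  } else {
    d <- ncol(Pc)
    grid <- direction_grid(n_dir, d)
    best <- plateau_argmax(Pc, g, grid)
    # local refinement: fine grid in a small cone around the best direction
    w <- refine_direction(Pc, g, best, n_local = 2000L, cone = 5 * pi / 180)
  }
  w <- orient_direction(w, Pc, g)
  stat <- fold_auc(projected_auc(drop(Pc %*% w), g))
  structure(list(direction = w, origin = origin, method = method,
                 statistic = stat,
                 dichotomy = attr(g, "dichotomy_label"),
                 levels = levels(g), n = nrow(P)),
            class = "separation_axis")
}

# argmax of folded AUC over a direction set; the AUC is piecewise constant,
# so exact ties are the rule near the optimum — return the (sign-aligned)
# centroid of the tied plateau rather than an arbitrary member
plateau_argmax <- function(Pc, g, dirs) {
  Z <- Pc %*% t(dirs)
  aucs <- vapply(seq_len(ncol(Z)), function(j) fold_auc(projected_auc(Z[, j], g)), 0)
  top <- which(aucs >= max(aucs) - 1e-12)
  if (length(top) == 1L) return(dirs[top, ])
  # secondary criterion: projected two-sample t statistic (continuous, so it
  # breaks the ties deterministically and picks the plateau's best-resolved
  # member)
  i2 <- as.integer(g) == 2L
  tstat <- vapply(top, function(j) {
    z <- Z[, j]
    sp <- sqrt((stats::var(z[i2]) * (sum(i2) - 1) +
                stats::var(z[!i2]) * (sum(!i2) - 1)) / (length(z) - 2))
    if (sp <= 0) return(Inf)
    abs(mean(z[i2]) - mean(z[!i2])) / sp
  }, 0)
  dirs[top[which.max(tstat)], ]
}

refine_direction <- function(Pc, g, w0, n_local = 2000L, cone = 5 * pi / 180) {
  d <- length(w0)
  # deterministic tangent perturbations on a spiral inside the cone
  basis <- qr.Q(qr(cbind(w0, diag(d))))[, -1L, drop = FALSE]
  i <- seq_len(n_local)
  ang <- cone * sqrt(i / n_local)
  if (d == 2L) {
    tang <- outer(cos(pi * i), 1)          # +/- side alternation
    cand <- t(vapply(i, function(k)
      cos(ang[k]) * w0 + sin(ang[k]) * sign(tang[k]) * basis[, 1L], w0))
  } else {
    th <- pi * (1 + sqrt(5)) * i
    cand <- t(vapply(i, function(k)
      cos(ang[k]) * w0 + sin(ang[k]) * (cos(th[k]) * basis[, 1L] +
                                        sin(th[k]) * basis[, 2L]), w0))
  }
  cand <- rbind(w0, cand)
  cand <- cand / sqrt(rowSums(cand^2))
  plateau_argmax(Pc, g, cand)
}

#' @export
print.separation_axis <- function(x, ...) {
  cat("<separation_axis> method=", x$method,
      ", dichotomy=", x$dichotomy,
      " (", paste(x$levels, collapse = " vs "), ")\n",
      "  direction: (", paste(signif(x$direction, 4), collapse = ", "),
      "),  axial AUC: ", signif(x$statistic, 4), "\n", sep = "")
  invisible(x)
}

#' Normalized line trace along a separation axis
#'
#' Projects every nucleus onto the axis, min-max normalizes the projected
#' coordinates to [0, 1] over the aggregate's own projected extent (the
#' "normalized diameter"), and reports the fraction of marker-positive nuclei
#' per equal-width bin. Empty bins are reported as missing, never
#' interpolated.
#'
#' @param table an [aggregate_table()] with calls for `marker` (or a
#'   dichotomy when `marker` is `NULL`).
#' @param axis a `separation_axis` fitted on this aggregate.
#' @param marker channel name whose `call_<marker>` column defines
#'   positivity; `NULL` uses the axis dichotomy (second level = positive).
#' @param n_bins number of bins (default 20, minimum 3).
#' @return object of class `line_trace`: `bin_centers`, `fraction_positive`
#'   (NA for empty bins), `counts`, `label`, `n`.
#' @export
compute_line_trace <- function(table, axis, marker = NULL, n_bins = 20L) {
  stopifnot(inherits(axis, "separation_axis"))
  if (n_bins < 3) stop("n_bins must be >= 3")
  P <- nucleus_positions(table)
  if (ncol(P) != length(axis$direction))
    stop("axis dimensionality does not match table positions")
  z <- drop(sweep(P, 2, axis$origin) %*% axis$direction)
  rng <- range(z)
  if (diff(rng) <= 0) stop("zero projected extent; cannot normalize")
  t01 <- (z - rng[1]) / diff(rng)
  if (is.null(marker)) {
    g <- dichotomy_labels(table, axis$dichotomy, min_group = 1L)
    pos <- as.integer(g) == 2L
    label <- paste0(axis$dichotomy, ":", levels(g)[2L])
  } else {
    cc <- paste0("call_", marker)
    if (!cc %in% names(table))
      stop("no calls for marker ", marker, "; run call_marker_positive() first")
    pos <- as.logical(as.data.frame(table)[[cc]])
    label <- marker
  }
  bin <- pmin(floor(t01 * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, n_bins)
  pos_counts <- tabulate(bin[pos], n_bins)
  frac <- ifelse(counts > 0, pos_counts / counts, NA_real_)
  structure(list(label = label, n_bins = as.integer(n_bins),
                 bin_centers = (seq_len(n_bins) - 0.5) / n_bins,
                 fraction_positive = frac, counts = counts,
                 n = length(z), aggregate_id = attr(table, "aggregate_id")),
            class = "line_trace")
}

#' @export
print.line_trace <- function(x, ...) {
  cat("<line_trace> ", x$label, ": ", x$n, " nuclei in ", x$n_bins,
      " bins (", sum(x$counts == 0), " empty)\n", sep = "")
  invisible(x)
}

#' @export
plot.line_trace <- function(x, ..., col = "steelblue") {
  graphics::plot(x$bin_centers, 100 * x$fraction_positive, type = "b",
                 pch = 16, col = col, ylim = c(0, 100),
                 xlab = "normalized position along axis",
                 ylab = paste0("% ", x$label, " positive"), ...)
  invisible(x)
}

#' Pool line traces across aggregates
#'
#' The aggregate is the unit of replication: per bin, the mean, sample SD and
#' SEM are taken over the per-aggregate bin fractions. Bins that are empty in
#' a given aggregate are excluded pairwise, with the exclusion count
#' reported.
#'
#' @param traces list of [compute_line_trace()] results with identical
#'   binning.
#' @return object of class `pooled_profile`: `bin_centers`, `mean`, `sd`,
#'   `sem`, `n_contributing` (traces per bin), `n_aggregates`.
#' @export
pool_line_traces <- function(traces) {
  if (!length(traces)) stop("need at least one trace")
  stopifnot(all(vapply(traces, inherits, TRUE, "line_trace")))
  nb <- unique(vapply(traces, function(t) t$n_bins, 0L))
  if (length(nb) != 1L)
    stop("mismatched binning across traces: ", paste(nb, collapse = ", "))
  M <- do.call(rbind, lapply(traces, function(t) t$fraction_positive))
  k <- colSums(!is.na(M))
  mu <- ifelse(k > 0, colMeans(M, na.rm = TRUE), NA_real_)
  sd <- apply(M, 2, function(v) if (sum(!is.na(v)) >= 2) stats::sd(v, na.rm = TRUE) else NA_real_)
  structure(list(label = traces[[1L]]$label, n_bins = nb,
                 bin_centers = traces[[1L]]$bin_centers,
                 mean = mu, sd = sd, sem = sd / sqrt(k),
                 n_contributing = k,
                 n_excluded = length(traces) - k,
                 n_aggregates = length(traces)),
            class = "pooled_profile")
}

#' @export
print.pooled_profile <- function(x, ...) {
  cat("<pooled_profile> ", x$label, ": ", x$n_aggregates, " aggregates, ",
      x$n_bins, " bins\n", sep = "")
  invisible(x)
}

#' @export
plot.pooled_profile <- function(x, ..., col = "steelblue") {
  ok <- !is.na(x$mean)
  m <- 100 * x$mean
  s <- 100 * ifelse(is.na(x$sd), 0, x$sd)
  graphics::plot(x$bin_centers[ok], m[ok], type = "n", ylim = c(0, 100),
                 xlab = "normalized position along axis",
                 ylab = paste0("% ", x$label, " positive (mean +/- SD)"), ...)
  graphics::polygon(c(x$bin_centers[ok], rev(x$bin_centers[ok])),
                    c(pmin(m[ok] + s[ok], 100), rev(pmax(m[ok] - s[ok], 0))),
                    col = grDevices::adjustcolor(col, 0.25), border = NA)
  graphics::lines(x$bin_centers[ok], m[ok], type = "b", pch = 16, col = col)
  invisible(x)
}
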