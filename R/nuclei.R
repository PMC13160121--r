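#' @importFrom mclust Mclust mclustBIC
NULL

# -- separable array filters ------------------------------------------------

# apply FUN over the `axis`-th dimension of a 2D/3D array by rotating that
# dimension to the front and working on a (n_axis x rest) matrix
along_axis <- function(arr, axis, fun) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = d[[axis]])
  m <- fun(m)
  dim(m) <- dm
  aperm(m, order(perm))
}

# column-wise Gaussian smoothing with edge replication
gauss_filter_cols <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                  m[rep(nrow(m), r), , drop = FALSE])
  f <- stats::filter(padded, k, sides = 2)
  matrix(f[(r + 1L):(r + nrow(m)), ], nrow = nrow(m))
}

gauss_smooth <- function(arr, sigma_vox) {
  for (axis in seq_along(dim(arr))) {
    s <- sigma_vox[[axis]]
    if (s > 0) arr <- along_axis(arr, axis, function(m) gauss_filter_cols(m, s))
  }
  arr
}

# column-wise running max with radius w (box max filter)
max_filter_cols <- function(m, w) {
  out <- m
  n <- nrow(m)
  for (s in seq_len(w)) {
    out[seq_len(n - s), ] <- pmax(out[seq_len(n - s), , drop = FALSE],
                                  m[(s + 1L):n, , drop = FALSE])
    out[(s + 1L):n, ] <- pmax(out[(s + 1L):n, , drop = FALSE],
                              m[seq_len(n - s), , drop = FALSE])
  }
  out
}

max_filter <- function(arr, radius_vox) {
  for (axis in seq_along(dim(arr))) {
    w <- radius_vox[[axis]]
    if (w >= 1L) arr <- along_axis(arr, axis, function(m) max_filter_cols(m, w))
  }
  arr
}

#' Detect nuclei on the nuclear channel of a stack or MIP
#'
#' Blob-style detection: the nuclear channel is Gaussian-smoothed at the
#' expected nucleus scale, local intensity maxima above a relative threshold
#' are collected, and maxima closer than the expected nucleus diameter are
#' merged by greedy non-maximum suppression (brightest first). Works on 3D
#' stacks and 2D maximum-intensity projections; deterministic for fixed input
#' and parameters.
#'
#' @param image an `aggregate_image`.
#' @param nuclear_channel channel to detect on (default `"DAPI"`).
#' @param sigma smoothing scale in um (roughly the nucleus radius).
#' @param min_separation minimum center-to-center distance in um between
#'   detections (roughly the nucleus diameter).
#' @param threshold_rel candidate threshold as a fraction of the smoothed
#'   dynamic range above the median background level.
#' @return numeric matrix of centroid positions in image-frame um with
#'   columns `x`, `y` (and `z` for stacks); zero rows when nothing exceeds
#'   the threshold.
#' @export
detect_nuclei <- function(image, nuclear_channel = "DAPI", sigma = 3,
                          min_separation = 6, threshold_rel = 0.1) {
  stopifnot(inherits(image, "aggregate_image"))
  if (!nuclear_channel %in% image$channels)
    stop("channel not present in image: ", nuclear_channel)
  arr <- image$data[[nuclear_channel]]
  d <- dim(arr)
  is3d <- length(d) == 3
  vox <- image$voxel_size          # named z,y,x or y,x
  sig_vox <- sigma / vox
  if (any(sig_vox < 0.5))
    stop("smoothing kernel collapses below one voxel on axis ",
         paste(names(vox)[sig_vox < 0.5], collapse = ","),
         "; increase sigma or reduce voxel size")

  sm <- gauss_smooth(arr, sig_vox)
  bg <- stats::median(sm)
  rng <- max(sm) - bg
  if (rng <= 0) {
    out <- matrix(numeric(0), ncol = if (is3d) 3L else 2L)
    colnames(out) <- if (is3d) c("x", "y", "z") else c("x", "y")
    return(out)
  }
  thr <- bg + threshold_rel * rng
  rad_vox <- pmax(1L, floor(min_separation / (2 * vox)))
  peaks <- which(sm >= thr & sm >= max_filter(sm, rad_vox), arr.ind = TRUE)
  if (!nrow(peaks)) {
    out <- matrix(numeric(0), ncol = if (is3d) 3L else 2L)
    colnames(out) <- if (is3d) c("x", "y", "z") else c("x", "y")
    return(out)
  }
  vals <- sm[peaks]
  ord <- order(-vals)
  peaks <- peaks[ord, , drop = FALSE]

  # voxel indices -> physical um (voxel centers), x,y(,z) columns
  if (is3d) {
    pts <- cbind(x = (peaks[, 3] - 0.5) * vox[["x"]],
                 y = (peaks[, 2] - 0.5) * vox[["y"]],
                 z = (peaks[, 1] - 0.5) * vox[["z"]])
  } else {
    pts <- cbind(x = (peaks[, 2] - 0.5) * vox[["x"]],
                 y = (peaks[, 1] - 0.5) * vox[["y"]])
  }
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    sel <- pts[keep, , drop = FALSE]
    d2 <- colSums((t(sel) - pts[i, ])^2)
    if (min(d2) >= min_separation^2) keep[i] <- TRUE
  }
  pts[keep, , drop = FALSE]
}

#' Measure per-nucleus channel intensities
#'
#' For each position and channel, the mean intensity inside a spherical (disc
#' for MIPs) aperture, background-subtracted at the channel's lower-percentile
#' level and clamped at zero. Apertures are clipped at image borders.
#'
#' @param image an `aggregate_image`.
#' @param positions matrix of positions in image-frame um (columns `x`, `y`
#'   and `z` for stacks), e.g. from [detect_nuclei()].
#' @param aperture_radius aperture radius in um; must cover >= 1 voxel.
#' @param background_quantile per-channel background level (default 0.05).
#' @param channels channels to measure (default: all but the nuclear stain is
#'   kept too — every channel in the image).
#' @param aggregate_id,metadata passed to [aggregate_table()].
#' @return an [aggregate_table()] with one intensity column per measured
#'   channel; empty `positions` yield an empty table.
#' @export
measure_intensities <- function(image, positions, aperture_radius = 3,
                                background_quantile = 0.05, channels = NULL,
                                aggregate_id = image$aggregate_id %||% "agg1",
                                metadata = list()) {
  stopifnot(inherits(image, "aggregate_image"))
  if (is.null(channels)) channels <- image$channels
  d <- dim(image$data[[1L]])
  is3d <- length(d) == 3
  vox <- image$voxel_size
  if (aperture_radius < min(vox))
    stop("aperture_radius smaller than one voxel (", min(vox), " um)")
  positions <- as.matrix(positions)
  n <- nrow(positions)
  df <- data.frame(nucleus_id = seq_len(n),
                   x = as.numeric(positions[, "x"]),
                   y = as.numeric(positions[, "y"]))
  if (is3d) df$z <- as.numeric(positions[, "z"])
  if (n == 0) {
    for (ch in channels) df[[ch]] <- numeric(0)
    return(aggregate_table(df, aggregate_id = aggregate_id,
                           channels = channels, metadata = metadata))
  }

  centers <- if (is3d)
    lapply(c(z = "z", y = "y", x = "x"), function(a) (seq_len(d[[match(a, c("z", "y", "x"))]]) - 0.5) * vox[[a]])
  else
    lapply(c(y = "y", x = "x"), function(a) (seq_len(d[[match(a, c("y", "x"))]]) - 0.5) * vox[[a]])

  bg <- if (is.null(background_quantile)) {
    stats::setNames(rep(0, length(channels)), channels)
  } else {
    stats::setNames(vapply(channels, function(ch)
      stats::quantile(image$data[[ch]], background_quantile, names = FALSE), 0),
      channels)
  }
  vals <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
  for (i in seq_len(n)) {
    if (is3d) {
      zr <- which(abs(centers$z - positions[i, "z"]) <= aperture_radius)
      yr <- which(abs(centers$y - positions[i, "y"]) <= aperture_radius)
      xr <- which(abs(centers$x - positions[i, "x"]) <= aperture_radius)
      if (!length(zr) || !length(yr) || !length(xr)) next
      dz2 <- (centers$z[zr] - positions[i, "z"])^2
      dy2 <- (centers$y[yr] - positions[i, "y"])^2
      dx2 <- (centers$x[xr] - positions[i, "x"])^2
      mask <- outer(dz2, outer(dy2, dx2, "+"), "+") <= aperture_radius^2
      if (!any(mask)) next
      for (ch in channels)
        vals[i, ch] <- mean(image$data[[ch]][zr, yr, xr][mask])
    } else {
      yr <- which(abs(centers$y - positions[i, "y"]) <= aperture_radius)
      xr <- which(abs(centers$x - positions[i, "x"]) <= aperture_radius)
      if (!length(yr) || !length(xr)) next
      dy2 <- (centers$y[yr] - positions[i, "y"])^2
      dx2 <- (centers$x[xr] - positions[i, "x"])^2
      mask <- outer(dy2, dx2, "+") <= aperture_radius^2
      if (!any(mask)) next
      for (ch in channels)
        vals[i, ch] <- mean(image$data[[ch]][yr, xr][mask])
    }
  }
  for (ch in channels) df[[ch]] <- pmax(vals[, ch] - bg[[ch]], 0)
  aggregate_table(df, aggregate_id = aggregate_id, channels = channels,
                  metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# histogram Otsu threshold on a numeric vector; returns NA when degenerate
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) return(NA_real_)
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  if (max(between) <= 0) return(NA_real_)
  mids[which.max(between)]
}

#' Call marker-positive nuclei
#'
#' Adds a boolean `call_<marker>` column by thresholding the marker's
#' intensity. `otsu` (default) thresholds the log intensities with a
#' histogram Otsu rule; `gmm2` fits a two-component Gaussian mixture on the
#' log scale (via mclust) and calls posterior membership of the high-mean
#' component; `fixed` applies a user threshold on the raw intensity scale.
#' Thresholds are computed per aggregate; for a cohort-level rule compute one
#' with [cohort_threshold()] and apply it as `method = "fixed"`.
#'
#' Degenerate intensity distributions (constant, or no resolvable split) give
#' all-negative calls and a warning rather than an error: unstained control
#' aggregates are legitimately all-negative.
#'
#' @param table an [aggregate_table()].
#' @param marker channel name to call.
#' @param method `"otsu"`, `"gmm2"` or `"fixed"`.
#' @param threshold raw-intensity threshold, required for `method = "fixed"`.
#' @return the table with a `call_<marker>` column (0/1); calling details
#'   (method, threshold on the scale it was applied, degeneracy flag) are
#'   recorded in the `call_info` attribute.
#' @export
call_marker_positive <- function(table, marker,
                                 method = c("otsu", "gmm2", "fixed"),
                                 threshold = NULL) {
  method <- match.arg(method)
  if (!marker %in% attr(table, "channels"))
    stop("marker channel not present: ", marker)
  x <- as.data.frame(table)[[marker]]
  degenerate <- FALSE
  if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold value")
    calls <- x > threshold
    info <- list(method = method, threshold = threshold, scale = "linear",
                 degenerate = FALSE)
  } else {
    eps <- if (any(x > 0)) min(x[x > 0]) / 2 else .Machine$double.eps
    lx <- log(x + eps)
    thr <- NA_real_
    if (method == "otsu") {
      thr <- otsu_threshold(lx)
    } else {
      if (stats::sd(lx) > 1e-9) {
        fit <- tryCatch(
          Mclust(lx, G = 2, verbose = FALSE),
          error = function(e) NULL)
        if (!is.null(fit) && length(unique(fit$parameters$mean)) == 2L) {
          hi <- which.max(fit$parameters$mean)
          post_hi <- fit$z[, hi]
          calls <- post_hi > 0.5
          # record the implied boundary: midpoint between the extreme members
          thr <- if (any(calls) && any(!calls))
            (max(lx[!calls]) + min(lx[calls])) / 2 else NA_real_
          if (any(calls) && any(!calls)) {
            info <- list(method = method, threshold = thr, scale = "log",
                         degenerate = FALSE)
            return(finish_call(table, marker, calls, info))
          }
        }
      }
      thr <- NA_real_
    }
    if (is.na(thr)) {
      degenerate <- TRUE
      calls <- rep(FALSE, length(x))
      warning("degenerate intensity distribution for marker ", marker,
              "; all nuclei called negative")
    } else {
      calls <- lx > thr
    }
    info <- list(method = method, threshold = thr, scale = "log",
                 degenerate = degenerate)
  }
  finish_call(table, marker, calls, info)
}

finish_call <- function(table, marker, calls, info) {
  a <- attributes(table)
  table[[paste0("call_", marker)]] <- as.integer(calls)
  ci <- a$call_info %||% list()
  ci[[marker]] <- info
  attr(table, "call_info") <- ci
  for (nm in c("aggregate_id", "channels", "metadata", "truth", "synthetic_params"))
    if (!is.null(a[[nm]])) attr(table, nm) <- a[[nm]]
  class(table) <- c("aggregate_table", "data.frame")
  table
}

#' Cohort-level calling threshold
#'
#' Pools a marker's intensities across aggregates and returns one raw-scale
#' threshold (Otsu on log intensities or 2-component GMM boundary), for use
#' with `call_marker_positive(method = "fixed")` on low-count aggregates.
#'
#' @param tables list of [aggregate_table()]s.
#' @param marker channel name.
#' @param method `"otsu"` or `"gmm2"`.
#' @return raw-intensity threshold (numeric scalar, `NA` if degenerate).
#' @export
cohort_threshold <- function(tables, marker, method = c("otsu", "gmm2")) {
  method <- match.arg(method)
  x <- unlist(lapply(tables, function(t) as.data.frame(t)[[marker]]))
  if (is.null(x) || !length(x)) stop("marker channel not present: ", marker)
  eps <- if (any(x > 0)) min(x[x > 0]) / 2 else .Machine$double.eps
  lx <- log(x + eps)
  lthr <- if (method == "otsu") {
    otsu_threshold(lx)
  } else {
    fit <- tryCatch(Mclust(lx, G = 2, verbose = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else {
      hi <- which.max(fit$parameters$mean)
      calls <- fit$z[, hi] > 0.5
      if (any(calls) && any(!calls)) (max(lx[!calls]) + min(lx[calls])) / 2
      else NA_real_
    }
  }
  if (is.na(lthr)) NA_real_ else exp(lthr) - eps
}
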