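#' Imaging parameters for the synthetic rasterizer
#'
#' Describes the virtual microscope used by [rasterize_aggregate()]: voxel
#' size, Gaussian nucleus footprint, image extent, background level and
#' Poisson-Gaussian noise. Defaults emulate a 20X confocal acquisition
#' (anisotropic 2 um z step, 1 um xy sampling, ~8 um nuclei).
#'
#' @param voxel_size voxel edge lengths in um, named `z`, `y`, `x` (2D images
#'   carry `y`, `x` only).
#' @param blob_sigma isotropic Gaussian nucleus footprint SD in um.
#' @param image_shape integer voxel counts `c(z, y, x)`; `NULL` auto-fits the
#'   aggregate bounding box plus a `3 * blob_sigma` margin.
#' @param background constant background intensity added to every channel.
#' @param noise `NULL` for noise-free images, else a list with `poisson`
#'   (logical, shot noise with the voxel value as mean) and `gaussian_sd`
#'   (read-noise SD).
#' @param project_mip also emit a maximum-intensity projection.
#' @param nuclear_channel name of the synthesized nuclear stain channel.
#' @param nuclear_peak peak amplitude of each nuclear blob.
#' @return list of class `imaging_params`.
#' @export
imaging_params <- function(voxel_size = c(z = 2, y = 1, x = 1), blob_sigma = 3,
                           image_shape = NULL, background = 10,
                           noise = list(poisson = TRUE, gaussian_sd = 2),
                           project_mip = FALSE, nuclear_channel = "DAPI",
                           nuclear_peak = 1000) {
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  if (is.null(names(voxel_size)) && length(voxel_size) == 3)
    names(voxel_size) <- c("z", "y", "x")
  if (!all(c("z", "y", "x") %in% names(voxel_size)))
    stop("voxel_size must be named z, y, x")
  if (blob_sigma <= 0) stop("blob_sigma must be positive")
  structure(list(voxel_size = voxel_size[c("z", "y", "x")],
                 blob_sigma = blob_sigma, image_shape = image_shape,
                 background = background, noise = noise,
                 project_mip = project_mip,
                 nuclear_channel = nuclear_channel,
                 nuclear_peak = nuclear_peak),
            class = "imaging_params")
}

new_aggregate_image <- function(data, voxel_size, offset,
                                aggregate_id = NULL, mip = NULL) {
  structure(list(data = data, channels = names(data),
                 voxel_size = voxel_size, offset = offset,
                 aggregate_id = aggregate_id, mip = mip),
            class = "aggregate_image")
}

#' @export
print.aggregate_image <- function(x, ...) {
  d <- dim(x$data[[1L]])
  cat("<aggregate_image> ", length(x$data), " channel(s): ",
      paste(x$channels, collapse = ", "), "\n  shape (",
      if (length(d) == 3) "z,y,x" else "y,x", "): ",
      paste(d, collapse = " x "), ", voxel ",
      paste(signif(x$voxel_size, 3), collapse = " x "), " um\n", sep = "")
  invisible(x)
}

#' Rasterize an aggregate into a multichannel microscopy-like stack
#'
#' Renders each nucleus as an isotropic Gaussian blob. The nuclear channel
#' gets a constant peak per nucleus; every intensity channel of the table gets
#' blobs whose amplitude is that nucleus's channel intensity, so the
#' background-subtracted integrated signal is linear in the table intensity.
#' Background and Poisson-Gaussian noise are applied last.
#'
#' @param agg an [aggregate_table()] with 3D positions.
#' @param imaging an [imaging_params()].
#' @param seed optional RNG seed for the noise draw.
#' @return an `aggregate_image`: named channel arrays in `(z, y, x)` voxel
#'   order, voxel sizes, and `offset` — the um translation added to table
#'   coordinates to place the aggregate in the image frame (voxel centers sit
#'   at `(index - 0.5) * voxel_size`).
#' @export
rasterize_aggregate <- function(agg, imaging = imaging_params(), seed = NULL) {
  stopifnot(inherits(imaging, "imaging_params"))
  if (!"z" %in% names(agg)) stop("rasterization needs 3D nucleus positions")
  pos <- nucleus_positions(agg)               # n x (x, y, z)
  vox <- imaging$voxel_size                   # z, y, x
  sig <- imaging$blob_sigma
  margin <- 3 * sig

  lo <- apply(pos, 2, min) - margin           # x, y, z order
  hi <- apply(pos, 2, max) + margin
  if (is.null(imaging$image_shape)) {
    shape <- ceiling((hi - lo)[c(3, 2, 1)] / vox)   # z, y, x
    offset <- -lo                                    # maps table coords into [0, extent]
  } else {
    shape <- imaging$image_shape
    extent <- shape * vox                            # z, y, x um
    need <- (hi - lo)[c(3, 2, 1)]
    if (any(need > extent))
      stop("aggregate (plus 3*sigma margin) exceeds image volume: needs ",
           paste(signif(need, 4), collapse = " x "), " um, volume is ",
           paste(signif(extent, 4), collapse = " x "), " um")
    offset <- -lo + (extent[c(3, 2, 1)] - (hi - lo)) / 2   # center it
  }
  shape <- as.integer(shape)
  names(shape) <- c("z", "y", "x")

  ppix <- sweep(pos, 2, offset, "+")          # image-frame um, cols x,y,z
  centers <- lapply(c(z = "z", y = "y", x = "x"),
                    function(a) (seq_len(shape[[a]]) - 0.5) * vox[[a]])

  blank <- array(0, dim = shape)
  chans <- c(imaging$nuclear_channel, attr(agg, "channels"))
  imgs <- stats::setNames(lapply(chans, function(ch) blank), chans)

  amp <- cbind(rep(imaging$nuclear_peak, nrow(ppix)),
               as.matrix(as.data.frame(agg)[, attr(agg, "channels"), drop = FALSE]))
  colnames(amp) <- chans
  half <- 4 * sig
  for (i in seq_len(nrow(ppix))) {
    px <- ppix[i, "x"]; py <- ppix[i, "y"]; pz <- ppix[i, "z"]
    zr <- which(abs(centers$z - pz) <= half)
    yr <- which(abs(centers$y - py) <= half)
    xr <- which(abs(centers$x - px) <= half)
    if (!length(zr) || !length(yr) || !length(xr)) next
    gz <- exp(-(centers$z[zr] - pz)^2 / (2 * sig^2))
    gy <- exp(-(centers$y[yr] - py)^2 / (2 * sig^2))
    gx <- exp(-(centers$x[xr] - px)^2 / (2 * sig^2))
    blob <- outer(gz, outer(gy, gx))
    for (ch in chans)
      imgs[[ch]][zr, yr, xr] <- imgs[[ch]][zr, yr, xr] + amp[i, ch] * blob
  }

  if (imaging$background != 0)
    imgs <- lapply(imgs, function(a) a + imaging$background)
  if (!is.null(imaging$noise)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    imgs <- lapply(imgs, function(a) {
      v <- as.vector(a)
      if (isTRUE(imaging$noise$poisson)) v <- stats::rpois(length(v), pmax(v, 0))
      gs <- imaging$noise$gaussian_sd
      if (!is.null(gs) && gs > 0) v <- v + stats::rnorm(length(v), 0, gs)
      array(pmax(v, 0), dim = dim(a))
    })
  }

  img <- new_aggregate_image(imgs, voxel_size = vox,
                             offset = offset,
                             aggregate_id = attr(agg, "aggregate_id"))
  if (isTRUE(imaging$project_mip)) img$mip <- project_mip(img)
  img
}

#' Maximum-intensity projection of a 3D stack
#'
#' @param image an `aggregate_image` with 3D channels.
#' @return a 2D `aggregate_image` (axes y, x), z collapsed by max.
#' @export
project_mip <- function(image) {
  stopifnot(inherits(image, "aggregate_image"))
  d <- dim(image$data[[1L]])
  if (length(d) != 3) stop("image is already 2D")
  data2 <- lapply(image$data, function(a) apply(a, c(2, 3), max))
  new_aggregate_image(data2, voxel_size = image$voxel_size[c("y", "x")],
                      offset = image$offset[c("x", "y")],
                      aggregate_id = image$aggregate_id)
}

#' Write / read a multichannel stack as TIFF plus sidecar metadata
#'
#' Frames are stored channel-first (all z slices of channel 1, then channel
#' 2, ...), each frame a y-by-x plane, 16-bit, intensities scaled by the global
#' maximum. Channel names, voxel size, shape, axis order and the intensity
#' scale are echoed in a `<path>.yaml` sidecar so the round trip is lossless
#' up to 16-bit quantization.
#'
#' @param image an `aggregate_image`.
#' @param path output TIFF path.
#' @return `write_aggregate_tiff` returns `path` invisibly;
#'   `read_aggregate_tiff` returns an `aggregate_image`.
#' @export
write_aggregate_tiff <- function(image, path) {
  stopifnot(inherits(image, "aggregate_image"))
  d <- dim(image$data[[1L]])
  is3d <- length(d) == 3
  scale <- max(1e-12, max(vapply(image$data, max, 0)))
  frames <- list()
  for (ch in image$channels) {
    a <- image$data[[ch]] / scale
    if (is3d) for (z in seq_len(d[[1L]])) frames[[length(frames) + 1L]] <- a[z, , ]
    else frames[[length(frames) + 1L]] <- a
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  meta <- list(aggregate_id = image$aggregate_id,
               channels = as.list(image$channels),
               axis_order = if (is3d) "CZYX" else "CYX",
               shape = as.list(unname(d)),
               voxel_size_um = as.list(image$voxel_size),
               offset_um = as.list(image$offset),
               intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_aggregate_tiff
#' @export
read_aggregate_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  shape <- unlist(meta$shape)
  chans <- unlist(meta$channels)
  is3d <- identical(meta$axis_order, "CZYX")
  nz <- if (is3d) shape[[1L]] else 1L
  data <- stats::setNames(vector("list", length(chans)), chans)
  k <- 1L
  for (ch in chans) {
    if (is3d) {
      a <- array(0, dim = shape)
      for (z in seq_len(nz)) { a[z, , ] <- frames[[k]]; k <- k + 1L }
    } else {
      a <- frames[[k]]; k <- k + 1L
    }
    data[[ch]] <- a * meta$intensity_scale
  }
  vs <- unlist(meta$voxel_size_um)
  new_aggregate_image(data, voxel_size = vs,
                      offset = unlist(meta$offset_um),
                      aggregate_id = meta$aggregate_id)
}
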