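#' Parameters for the synthetic aggregate generator
#'
#' Defines one simulated 3D aggregate: `n_cells` nuclei placed uniformly in a
#' ball of radius `radius` (um), assigned to two cell types ("A", the
#' signal-activated/optoWnt-like population, and "B", the wild-type-like
#' population) according to a spatial `pattern`, with per-channel log-normal
#' fluorescence intensities conditioned on the true type.
#'
#' Patterns:
#' \describe{
#'   \item{mixed}{independent Bernoulli(`frac_type_a`) labels — the dark /
#'     unilluminated control regime.}
#'   \item{hemispherical}{type probability is a logistic function of the
#'     signed distance to a plane with a uniformly random normal; the plane
#'     offset is set so the expected type-A volume fraction equals
#'     `frac_type_a` (it passes through the centroid when `frac_type_a` is
#'     0.5). The logistic scale is `interface_width * 2 * radius`;
#'     `interface_width = 0` is the deterministic sharp-boundary limit.}
#'   \item{radial}{core-shell: type-A probability is a logistic function of
#'     `radius_of_nucleus - core_fraction * radius`, same scale rule.}
#'   \item{fragmented}{nuclei take the type of the nearest of `n_patches`
#'     uniformly placed patch seeds; each patch is type A with probability
#'     `frac_type_a` (re-flipped if a single type swallowed every patch).}
#' }
#'
#' @param n_cells nuclei per aggregate (default 200, the experimental seeding
#'   density for these aggregates).
#' @param radius aggregate radius in um (default 40).
#' @param frac_type_a expected fraction of type-A cells, in (0, 1).
#' @param pattern one of `"mixed"`, `"hemispherical"`, `"radial"`,
#'   `"fragmented"`.
#' @param interface_width boundary softness as a fraction of the diameter
#'   (>= 0); 0 gives a deterministic assignment given positions.
#' @param core_fraction radial pattern: core radius / aggregate radius.
#' @param n_patches fragmented pattern: number of patch seeds (>= 2).
#' @param marker_model per-channel intensity model, see [marker_model()].
#' @param min_spacing optional minimum nucleus spacing in um (0 = off);
#'   enforced by greedy thinning of uniform candidates.
#' @param seed integer RNG seed; identical parameters (including seed) give
#'   bit-identical tables.
#' @return a validated list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_cells = 200L, radius = 40, frac_type_a = 0.5,
                             pattern = c("mixed", "hemispherical", "radial",
                                         "fragmented"),
                             interface_width = 0.05, core_fraction = 0.5,
                             n_patches = 8L, marker_model = NULL,
                             min_spacing = 0, seed = 1L) {
  pattern <- match.arg(pattern)
  if (!is.numeric(n_cells) || n_cells < 20)
    stop("n_cells must be >= 20")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  if (!(frac_type_a > 0 && frac_type_a < 1))
    stop("frac_type_a must lie strictly in (0, 1)")
  if (interface_width < 0) stop("interface_width must be >= 0")
  if (!(core_fraction > 0 && core_fraction < 1))
    stop("core_fraction must lie strictly in (0, 1)")
  if (pattern == "fragmented" && n_patches < 2)
    stop("fragmented pattern needs n_patches >= 2")
  if (is.null(marker_model)) marker_model <- marker_model()
  validate_marker_model(marker_model)
  structure(list(n_cells = as.integer(n_cells), radius = radius,
                 frac_type_a = frac_type_a, pattern = pattern,
                 interface_width = interface_width,
                 core_fraction = core_fraction,
                 n_patches = as.integer(n_patches),
                 marker_model = marker_model,
                 min_spacing = min_spacing, seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Log-normal per-type intensity model
#'
#' One entry per channel giving the log-intensity mean for nuclei of type A
#' and type B and a common log-scale SD. The default emulates the two
#' genotype reporters (mCherry marking the activated type-A population, GFP
#' marking type B) with a 3-SD separation between positive and negative
#' log-intensity modes — right-skewed on the linear scale, cleanly bimodal on
#' the log scale.
#'
#' @param channels channel names.
#' @param meanlog_a,meanlog_b per-channel log-intensity means for type A / B
#'   nuclei (recycled to `length(channels)`).
#' @param sdlog per-channel log-intensity SD.
#' @return data.frame with columns channel, meanlog_a, meanlog_b, sdlog.
#' @export
marker_model <- function(channels = c("mCherry", "GFP"),
                         meanlog_a = c(6, 4.5), meanlog_b = c(4.5, 6),
                         sdlog = 0.5) {
  data.frame(channel = channels,
             meanlog_a = rep_len(meanlog_a, length(channels)),
             meanlog_b = rep_len(meanlog_b, length(channels)),
             sdlog = rep_len(sdlog, length(channels)),
             stringsAsFactors = FALSE)
}

validate_marker_model <- function(mm) {
  if (!is.data.frame(mm) ||
      !all(c("channel", "meanlog_a", "meanlog_b", "sdlog") %in% names(mm)))
    stop("marker_model must be a data.frame with columns channel, meanlog_a, meanlog_b, sdlog")
  if (any(mm$sdlog <= 0)) stop("marker_model sdlog must be positive")
  if (anyDuplicated(mm$channel)) stop("duplicated channel in marker_model")
  invisible(mm)
}

# uniform points in the ball of given radius (n x 3)
runif_ball <- function(n, radius) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * stats::runif(n)^(1 / 3)
  u * r
}

# uniformly random unit vector
runif_sphere <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# signed plane offset t in [-1,1] (units of radius) such that the volume
# fraction of the unit ball with coordinate <= t equals f
cap_offset <- function(f) {
  if (abs(f - 0.5) < 1e-12) return(0)
  stats::uniroot(function(t) (2 + 3 * t - t^3) / 4 - f,
                 c(-1, 1), tol = 1e-12)$root
}

# logistic type probability with deterministic width-0 limit
interface_prob <- function(s, scale) {
  if (scale <= 0) as.numeric(s < 0) else stats::plogis(-s / scale)
}

#' Generate one ground-truthed synthetic aggregate
#'
#' Draws nucleus positions uniformly in a ball, assigns true cell types
#' according to the configured spatial pattern, and draws per-channel
#' intensities log-normally from the type-conditional [marker_model()]. The
#' generating pattern parameters (hemisphere plane normal and offset, patch
#' seeds, ...) are stored in the `truth` attribute for axis-recovery and
#' classification tests.
#'
#' @param params a [synthetic_params()] object.
#' @param aggregate_id identifier stored on the table.
#' @return an [aggregate_table()] with a `true_type` column (`"A"`/`"B"`) and
#'   attributes `truth` (list: pattern, parameters, plane axis/offset or patch
#'   seeds) and the generator parameters under `synthetic_params`.
#' @export
generate_aggregate <- function(params = synthetic_params(),
                               aggregate_id = paste0("agg", params$seed)) {
  stopifnot(inherits(params, "synthetic_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)

  n <- params$n_cells
  R <- params$radius
  pos <- if (params$min_spacing > 0)
    thinned_ball(n, R, params$min_spacing) else runif_ball(n, R)

  scale <- params$interface_width * 2 * R
  truth <- list(pattern = params$pattern, radius = R,
                frac_type_a = params$frac_type_a,
                interface_width = params$interface_width)
  p_a <- switch(params$pattern,
    mixed = rep(params$frac_type_a, n),
    hemispherical = {
      axis <- runif_sphere()
      off <- cap_offset(params$frac_type_a) * R
      s <- drop(pos %*% axis) - off
      truth$plane_normal <- axis
      truth$plane_offset <- off
      interface_prob(s, scale)
    },
    radial = {
      r <- sqrt(rowSums(pos^2))
      truth$core_fraction <- params$core_fraction
      interface_prob(r - params$core_fraction * R, scale)
    },
    fragmented = {
      seeds <- runif_ball(params$n_patches, R)
      patch_a <- stats::rbinom(params$n_patches, 1L, params$frac_type_a)
      if (all(patch_a == patch_a[[1L]]))
        patch_a[sample.int(params$n_patches, 1L)] <- 1L - patch_a[[1L]]
      d2 <- outer(rowSums(pos^2), rep(1, params$n_patches)) +
        outer(rep(1, n), rowSums(seeds^2)) - 2 * pos %*% t(seeds)
      nearest <- max.col(-d2, ties.method = "first")
      truth$patch_seeds <- seeds
      truth$patch_type_a <- patch_a
      patch_a[nearest]
    })
  # p_a is 0/1 for fragmented and for width-0 interfaces, so the Bernoulli
  # draw degenerates to a deterministic assignment exactly where required
  type <- ifelse(stats::runif(n) < p_a, "A", "B")

  mm <- params$marker_model
  nuclei <- data.frame(nucleus_id = seq_len(n),
                       x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mm))) {
    ml <- ifelse(type == "A", mm$meanlog_a[[i]], mm$meanlog_b[[i]])
    nuclei[[mm$channel[[i]]]] <- stats::rlnorm(n, meanlog = ml, sdlog = mm$sdlog[[i]])
  }
  nuclei$true_type <- type

  tab <- aggregate_table(nuclei, aggregate_id = aggregate_id,
                         channels = mm$channel,
                         metadata = list(condition = "synthetic",
                                         pattern = params$pattern,
                                         seed = params$seed))
  attr(tab, "truth") <- truth
  attr(tab, "synthetic_params") <- params
  tab
}

# greedy minimum-spacing thinning of uniform ball candidates
thinned_ball <- function(n, radius, min_spacing, max_tries = 200L) {
  acc <- matrix(NA_real_, n, 3)
  got <- 0L
  for (try in seq_len(max_tries)) {
    cand <- runif_ball(2L * n, radius)
    for (i in seq_len(nrow(cand))) {
      if (got == 0L ||
          min(colSums((t(acc[seq_len(got), , drop = FALSE]) - cand[i, ])^2)) >=
          min_spacing^2) {
        got <- got + 1L
        acc[got, ] <- cand[i, ]
        if (got == n) return(acc)
      }
    }
  }
  stop("could not place ", n, " nuclei at min_spacing ", min_spacing,
       " in radius ", radius)
}

#' Generate a cohort of synthetic aggregates
#'
#' @param n_aggregates number of aggregates.
#' @param params template [synthetic_params()]; each aggregate gets seed
#'   `base_seed + i - 1`.
#' @param base_seed seed of the first aggregate (default `params$seed`).
#' @param id_prefix prefix for aggregate ids.
#' @return list of [aggregate_table()]s.
#' @export
generate_cohort <- function(n_aggregates, params = synthetic_params(),
                            base_seed = params$seed, id_prefix = params$pattern) {
  lapply(seq_len(n_aggregates), function(i) {
    p <- params
    p$seed <- as.integer(base_seed + i - 1L)
    generate_aggregate(p, aggregate_id = sprintf("%s_%03d", id_prefix, i))
  })
}
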