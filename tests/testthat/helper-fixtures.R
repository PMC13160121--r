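# shared fixtures and independent oracles

# build an aggregate_table from a position matrix and optional labels
toy_table <- function(pos, types = NULL, intensities = NULL, id = "toy") {
  pos <- as.matrix(pos)
  colnames(pos) <- c("x", "y", "z")[seq_len(ncol(pos))]
  df <- data.frame(nucleus_id = seq_len(nrow(pos)), pos)
  channels <- character(0)
  if (!is.null(intensities)) {
    for (ch in names(intensities)) df[[ch]] <- intensities[[ch]]
    channels <- names(intensities)
  }
  if (is.null(intensities)) {
    df$marker <- 1  # placeholder channel so the table validates
    channels <- "marker"
  }
  if (!is.null(types)) df$true_type <- as.character(types)
  aggregate_table(df, aggregate_id = id, channels = channels)
}

# brute-force AUC: all-pairs concordance count (ties count 1/2)
auc_bruteforce <- function(z, g) {
  g <- factor(g)
  z1 <- z[as.integer(g) == 1L]
  z2 <- z[as.integer(g) == 2L]
  s <- 0
  for (a in z1) for (b in z2) s <- s + (b > a) + 0.5 * (a == b)
  s / (length(z1) * length(z2))
}

fold <- function(a) 0.5 + abs(a - 0.5)

# nearest-neighbour matching of detections to ground truth positions
match_detections <- function(truth, detected) {
  nt <- nrow(truth)
  D <- as.matrix(stats::dist(rbind(truth, detected)))[seq_len(nt), -seq_len(nt),
                                                      drop = FALSE]
  list(nn_dist = apply(D, 1, min),          # truth -> closest detection
       nearest_truth = apply(D, 2, which.min))
}

# deterministic positions in a ball
runif_ball_fixture <- function(n, radius, seed = 42) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u * radius * runif(n)^(1 / 3)
}

# constant-valued 3D image with DAPI and one marker channel
new_image_fixture <- function(value = 7, shape = c(8, 24, 32),
                              voxel = c(z = 2, y = 1, x = 1)) {
  arr <- array(value, dim = shape)
  structure(list(data = list(DAPI = arr, M = arr),
                 channels = c("DAPI", "M"),
                 voxel_size = voxel, offset = c(x = 0, y = 0, z = 0),
                 aggregate_id = "fixture", mip = NULL),
            class = "aggregate_image")
}

# cohort used by several hemisphere tests
hemi_table <- function(seed, width = 0, n = 200) {
  generate_aggregate(synthetic_params(pattern = "hemispherical",
                                      interface_width = width,
                                      n_cells = n, seed = seed))
}
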