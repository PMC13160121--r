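#' Load and validate a run configuration
#'
#' Configurations are named lists, typically read from a YAML file. Common
#' fields: `mode` (`"synthetic"`, `"point_tables"` or `"images"`), `seed`
#' (mandatory for any stochastic step), `out_dir`, plus mode-specific fields
#' documented in [run_synthesize()] and [run_quantify()].
#'
#' @param config a named list or the path to a YAML file.
#' @return the configuration list, with the source path (if any) attached.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    path <- config
    if (!file.exists(path)) stop("config file not found: ", path)
    config <- yaml::read_yaml(path)
    attr(config, "source") <- path
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

cfg_get <- function(config, name, default = NULL, required = FALSE) {
  v <- config[[name]]
  if (is.null(v)) {
    if (required) stop("config field missing: ", name)
    v <- default
  }
  v
}

params_from_config <- function(config, pattern, seed) {
  synthetic_params(
    n_cells = cfg_get(config, "n_cells", 200L),
    radius = cfg_get(config, "radius", 40),
    frac_type_a = cfg_get(config, "frac_type_a", 0.5),
    pattern = pattern,
    interface_width = cfg_get(config, "interface_width", 0.05),
    core_fraction = cfg_get(config, "core_fraction", 0.5),
    n_patches = cfg_get(config, "n_patches", 8L),
    min_spacing = cfg_get(config, "min_spacing", 0),
    seed = seed)
}

write_manifest <- function(out_dir, config, extra = list()) {
  src <- attr(config, "source")
  manifest <- c(list(
    package = "gastrupol",
    version = as.character(utils::packageVersion("gastrupol")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_md5 = if (!is.null(src)) unname(tools::md5sum(src)) else
      unname(tools::md5sum(textConnection_md5(config)))),
    extra)
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# hash an in-memory config by serializing it to a temp YAML
textConnection_md5 <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, tf)
  tf
}

#' Synthesize a cohort of ground-truthed aggregates to disk
#'
#' Writes one point-table CSV per aggregate, a truth manifest CSV
#' (aggregate id, pattern, seed, observed type-A fraction, generating-plane
#' axis where applicable), optionally rasterized TIFF stacks or MIPs, and a
#' machine-readable run manifest.
#'
#' Config fields: `out_dir`; `seed`; `patterns` — named list of per-pattern
#' aggregate counts (e.g. `list(mixed = 10, hemispherical = 10)`) or a single
#' `pattern`/`n_aggregates` pair; generator overrides (`n_cells`, `radius`,
#' `frac_type_a`, `interface_width`, `core_fraction`, `n_patches`); imaging:
#' `write_images` (logical), `mip_only` (logical, write 2D projections and
#' 2D point tables with no z column).
#'
#' @param config list or YAML path, see [load_config()].
#' @return (invisibly) list with `tables`, `truth` (data.frame) and
#'   `out_dir`.
#' @export
run_synthesize <- function(config) {
  config <- load_config(config)
  out_dir <- cfg_get(config, "out_dir", required = TRUE)
  seed <- cfg_get(config, "seed", required = TRUE)
  patterns <- cfg_get(config, "patterns",
                      stats::setNames(list(cfg_get(config, "n_aggregates", 3L)),
                                      cfg_get(config, "pattern", "mixed")))
  write_images <- isTRUE(cfg_get(config, "write_images", FALSE))
  mip_only <- isTRUE(cfg_get(config, "mip_only", FALSE))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- list()
  truth_rows <- list()
  offset <- 0L
  for (pat in names(patterns)) {
    n_agg <- patterns[[pat]]
    for (i in seq_len(n_agg)) {
      p <- params_from_config(config, pat, seed = as.integer(seed + offset))
      offset <- offset + 1L
      id <- sprintf("%s_%03d", pat, i)
      tab <- generate_aggregate(p, aggregate_id = id)
      if (mip_only) {
        img <- rasterize_aggregate(tab, rasterization_params(config),
                                   seed = p$seed)
        mip <- project_mip(img)
        if (write_images)
          write_aggregate_tiff(mip, file.path(out_dir, paste0(id, "_mip.tif")))
        df <- as.data.frame(tab)
        df$z <- NULL
        tab2 <- aggregate_table(df, aggregate_id = id,
                                channels = attr(tab, "channels"),
                                metadata = attr(tab, "metadata"))
        attr(tab2, "truth") <- attr(tab, "truth")
        tab <- tab2
      } else if (write_images) {
        img <- rasterize_aggregate(tab, rasterization_params(config),
                                   seed = p$seed)
        write_aggregate_tiff(img, file.path(out_dir, paste0(id, ".tif")))
      }
      write_aggregate_csv(tab, file.path(out_dir, paste0(id, ".csv")))
      tables[[id]] <- tab
      tr <- attr(tab, "truth")
      truth_rows[[id]] <- data.frame(
        aggregate_id = id, pattern = pat, seed = p$seed,
        n_cells = nrow(tab),
        frac_type_a_observed = mean(tab$true_type == "A"),
        plane_x = tr$plane_normal[1] %||% NA_real_,
        plane_y = tr$plane_normal[2] %||% NA_real_,
        plane_z = tr$plane_normal[3] %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  utils::write.csv(truth, file.path(out_dir, "truth_manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, config,
                 extra = list(n_aggregates = length(tables),
                              files = paste0(names(tables), ".csv")))
  invisible(list(tables = tables, truth = truth, out_dir = out_dir))
}

rasterization_params <- function(config) {
  imaging_params(
    voxel_size = unlist(cfg_get(config, "voxel_size",
                                c(z = 2, y = 1, x = 1))),
    blob_sigma = cfg_get(config, "blob_sigma", 3),
    background = cfg_get(config, "background", 10),
    noise = cfg_get(config, "noise", list(poisson = TRUE, gaussian_sd = 2)))
}

#' Quantify a cohort: polarization scores, traces, pattern summary, plots
#'
#' Wires the full pipeline over a cohort of aggregates and writes:
#' `polarization_results.csv` (one row per aggregate), per-marker line-trace
#' CSVs, pooled-profile CSVs per condition, `pattern_summary.csv` (counts and
#' percentages per condition and class), diagnostic plots (PDF) and a run
#' manifest. The configuration is validated before any output is written;
#' validation failures raise errors and leave no partial outputs.
#'
#' Config fields: `mode` — `"synthetic"` (generator settings as in
#' [run_synthesize()]), `"point_tables"` (`input_glob` of CSVs in the
#' package's dialect) or `"images"` (`input_glob` of TIFFs written by
#' [write_aggregate_tiff()], plus `nuclear_channel`, `detection`
#' (`sigma`, `min_separation`, `threshold_rel`), `aperture_radius`);
#' `markers` — channels to call and trace (default: all non-nuclear
#' channels); `call_method`; `dichotomy`; `axis_method`; `n_bins`; `n_perm`;
#' `alpha`; `k`; thresholds (`tau_ax`, `tau_rad`, `tau_mix`); `min_nuclei`
#' floor (aggregates below it are skipped with a warning); `seed`;
#' `out_dir`; `plots` (logical).
#'
#' @param config list or YAML path.
#' @return (invisibly) list with `results` (data.frame), `summary`
#'   (data.frame), `profiles`, `out_dir`.
#' @export
run_quantify <- function(config) {
  config <- load_config(config)
  out_dir <- cfg_get(config, "out_dir", required = TRUE)
  seed <- cfg_get(config, "seed", required = TRUE)
  mode <- match.arg(cfg_get(config, "mode", required = TRUE),
                    c("synthetic", "point_tables", "images"))
  min_nuclei <- cfg_get(config, "min_nuclei", 20L)
  n_bins <- cfg_get(config, "n_bins", 20L)
  n_perm <- cfg_get(config, "n_perm", 199L)
  alpha <- cfg_get(config, "alpha", 0.05)
  k <- cfg_get(config, "k", 10L)
  thresholds <- pattern_thresholds(
    tau_ax = cfg_get(config, "tau_ax", 0.8),
    tau_rad = cfg_get(config, "tau_rad", 0.8),
    tau_mix = cfg_get(config, "tau_mix", 0.3),
    alpha = alpha)
  axis_method <- cfg_get(config, "axis_method", "fisher")
  call_method <- cfg_get(config, "call_method", "otsu")
  dichotomy <- cfg_get(config, "dichotomy", NULL)

  # fail fast on marker names before anything is written (synthetic channels
  # are known ahead of generation)
  if (mode == "synthetic") {
    synth_channels <- marker_model()$channel
    bad <- setdiff(cfg_get(config, "markers", synth_channels), synth_channels)
    if (length(bad))
      stop("configured marker channel(s) not present in inputs: ",
           paste(bad, collapse = ", "),
           " (available: ", paste(synth_channels, collapse = ", "), ")")
  }

  tables <- switch(mode,
    synthetic = {
      res <- run_synthesize(utils::modifyList(
        config, list(out_dir = file.path(out_dir, "synthetic"))))
      res$tables
    },
    point_tables = {
      files <- Sys.glob(cfg_get(config, "input_glob", required = TRUE))
      files <- files[!grepl("truth_manifest", files)]
      if (!length(files)) stop("no point tables match input_glob")
      stats::setNames(lapply(files, read_aggregate_csv),
                      sub("\\.csv$", "", basename(files)))
    },
    images = {
      files <- Sys.glob(cfg_get(config, "input_glob", required = TRUE))
      files <- files[!grepl("\\.yaml$", files)]
      if (!length(files)) stop("no images match input_glob")
      nuclear <- cfg_get(config, "nuclear_channel", "DAPI")
      det <- cfg_get(config, "detection", list())
      ap <- cfg_get(config, "aperture_radius", 3)
      lapply_named <- function(fs, f) stats::setNames(lapply(fs, f),
        sub("\\.tiff?$", "", basename(fs)))
      lapply_named(files, function(f) {
        img <- read_aggregate_tiff(f)
        if (!nuclear %in% img$channels)
          stop("nuclear channel '", nuclear, "' not in image ", basename(f),
               " (has: ", paste(img$channels, collapse = ", "), ")")
        pos <- detect_nuclei(img, nuclear_channel = nuclear,
                             sigma = det$sigma %||% 3,
                             min_separation = det$min_separation %||% 6,
                             threshold_rel = det$threshold_rel %||% 0.1)
        measure_intensities(img, pos, aperture_radius = ap,
                            channels = setdiff(img$channels, nuclear))
      })
    })

  if (!length(tables)) stop("no aggregates to quantify")
  all_channels <- attr(tables[[1L]], "channels")
  markers <- cfg_get(config, "markers", all_channels)
  bad <- setdiff(markers, all_channels)
  if (length(bad))
    stop("configured marker channel(s) not present in inputs: ",
         paste(bad, collapse = ", "),
         " (available: ", paste(all_channels, collapse = ", "), ")")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  traces <- stats::setNames(vector("list", length(markers)), markers)
  skipped <- character(0)
  agg_seed <- as.integer(seed)
  fits <- list()
  for (id in names(tables)) {
    tab <- tables[[id]]
    if (nrow(tab) < min_nuclei) {
      warning("aggregate ", id, " skipped: ", nrow(tab),
              " nuclei below floor of ", min_nuclei)
      skipped <- c(skipped, id)
      next
    }
    for (m in markers)
      tab <- suppressWarnings(call_marker_positive(tab, m, method = call_method))
    agg_seed <- agg_seed + 1L
    fit <- polarize(tab, dichotomy = dichotomy, axis_method = axis_method,
                    n_perm = n_perm, alpha = alpha, k = k, n_bins = n_bins,
                    thresholds = thresholds, seed = agg_seed)
    fits[[id]] <- fit
    row <- as.data.frame(fit)
    row$condition <- attr(tab, "metadata")$pattern %||%
      attr(tab, "metadata")$condition %||% "all"
    results[[id]] <- row
    for (m in markers) {
      tr <- compute_line_trace(tab, fit$axis, marker = m, n_bins = n_bins)
      traces[[m]][[id]] <- tr
    }
  }
  if (!length(results)) stop("all aggregates were below the nucleus floor")
  results <- do.call(rbind, results)
  utils::write.csv(results, file.path(out_dir, "polarization_results.csv"),
                   row.names = FALSE, quote = FALSE)

  profiles <- list()
  for (m in markers) {
    df <- do.call(rbind, lapply(traces[[m]], function(t)
      data.frame(aggregate_id = t$aggregate_id, bin_center = t$bin_centers,
                 fraction_positive = t$fraction_positive, count = t$counts)))
    utils::write.csv(df, file.path(out_dir, paste0("line_traces_", m, ".csv")),
                     row.names = FALSE, quote = FALSE)
    for (cond in unique(results$condition)) {
      ids <- results$aggregate_id[results$condition == cond]
      pp <- pool_line_traces(traces[[m]][names(traces[[m]]) %in% ids])
      profiles[[paste(m, cond, sep = "_")]] <- pp
      utils::write.csv(
        data.frame(bin_center = pp$bin_centers, mean = pp$mean, sd = pp$sd,
                   sem = pp$sem, n_contributing = pp$n_contributing),
        file.path(out_dir, paste0("pooled_profile_", m, "_", cond, ".csv")),
        row.names = FALSE, quote = FALSE)
    }
  }

  summary_tab <- as.data.frame(table(condition = results$condition,
                                     pattern = results$pattern))
  names(summary_tab)[3] <- "count"
  tot <- stats::ave(summary_tab$count, summary_tab$condition, FUN = sum)
  summary_tab$percent <- ifelse(tot > 0, 100 * summary_tab$count / tot, 0)
  utils::write.csv(summary_tab, file.path(out_dir, "pattern_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  if (isTRUE(cfg_get(config, "plots", TRUE))) {
    grDevices::pdf(file.path(out_dir, "quantification_plots.pdf"),
                   width = 9, height = 4.5)
    for (nm in names(profiles))
      plot(profiles[[nm]], main = nm)
    pol_rate <- tapply(results$polarized, results$condition, mean) * 100
    graphics::barplot(pol_rate, ylim = c(0, 100),
                      ylab = "% aggregates polarized", xlab = "condition")
    grDevices::dev.off()
  }

  write_manifest(out_dir, config, extra = list(
    n_aggregates = nrow(results), skipped = skipped,
    thresholds = thresholds, n_perm = n_perm, seed = seed))
  invisible(list(results = results, summary = summary_tab,
                 profiles = profiles, fits = fits, out_dir = out_dir))
}

#' Run the ddCt computation from a config
#'
#' Config fields: `ct_csv` (long-format Ct table), `housekeeping`,
#' `control`, optional `gene_order`, `sample_order`, `out_dir`.
#'
#' @param config list or YAML path.
#' @return (invisibly) the `fold_change_matrix`.
#' @export
run_ddct <- function(config) {
  config <- load_config(config)
  ct <- read_ct_csv(cfg_get(config, "ct_csv", required = TRUE),
                    housekeeping = cfg_get(config, "housekeeping", required = TRUE),
                    control = cfg_get(config, "control", required = TRUE))
  fc <- compute_log2fc(ct,
                       gene_order = cfg_get(config, "gene_order", NULL),
                       sample_order = cfg_get(config, "sample_order", NULL))
  out_dir <- cfg_get(config, "out_dir", NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_log2fc_csv(fc, file.path(out_dir, "log2fc.csv"))
    write_manifest(out_dir, config)
  }
  invisible(fc)
}
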