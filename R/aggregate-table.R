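#' Per-nucleus table for one aggregate
#'
#' An `aggregate_table` is the unit of every downstream computation: one row
#' per detected (or simulated) nucleus, with physical coordinates in
#' micrometres, one intensity column per fluorescence channel, optional
#' ground-truth type (synthetic data only) and optional boolean marker calls
#' in `call_<marker>` columns.
#'
#' @param nuclei data.frame with columns `nucleus_id`, `x`, `y` (and `z` for
#'   3D data), one numeric column per channel, optionally `true_type` and
#'   `call_<marker>` columns.
#' @param aggregate_id identifier for the aggregate.
#' @param channels character vector of channel column names, in display order.
#' @param metadata named list of condition metadata (condition, timepoint,
#'   illumination, ...).
#' @param min_nuclei minimum nucleus count required for downstream scoring.
#'   Tables below the floor are still representable; scoring functions refuse
#'   them.
#' @return an object of class `aggregate_table` (a data.frame with
#'   attributes `aggregate_id`, `channels`, `metadata`).
#' @export
aggregate_table <- function(nuclei, aggregate_id = "agg1", channels = NULL,
                            metadata = list(), min_nuclei = 0L) {
  stopifnot(is.data.frame(nuclei))
  nuclei <- as.data.frame(nuclei, stringsAsFactors = FALSE)
  req <- c("nucleus_id", "x", "y")
  missing_cols <- setdiff(req, names(nuclei))
  if (length(missing_cols))
    stop("nuclei table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(nuclei$nucleus_id))
    stop("nucleus_id values must be unique within an aggregate")
  coord_cols <- intersect(c("x", "y", "z"), names(nuclei))
  if (!all(vapply(nuclei[coord_cols], function(v) all(is.finite(v)), TRUE)))
    stop("nucleus positions must be finite")
  if (is.null(channels)) {
    reserved <- c("nucleus_id", "x", "y", "z", "true_type")
    channels <- setdiff(names(nuclei)[vapply(nuclei, is.numeric, TRUE)],
                        c(reserved, grep("^call_", names(nuclei), value = TRUE)))
  }
  for (ch in channels) {
    if (!ch %in% names(nuclei)) stop("declared channel not in table: ", ch)
    if (any(nuclei[[ch]] < 0, na.rm = TRUE))
      stop("channel intensities must be non-negative: ", ch)
  }
  for (cc in grep("^call_", names(nuclei), value = TRUE)) {
    m <- sub("^call_", "", cc)
    if (!m %in% channels)
      stop("call column ", cc, " refers to an undeclared channel")
  }
  if (nrow(nuclei) < min_nuclei)
    stop("aggregate has ", nrow(nuclei), " nuclei, below floor of ", min_nuclei)
  structure(nuclei,
            aggregate_id = aggregate_id,
            channels = channels,
            metadata = metadata,
            class = c("aggregate_table", "data.frame"))
}

#' @export
print.aggregate_table <- function(x, ...) {
  cat("<aggregate_table> ", attr(x, "aggregate_id"),
      ": ", nrow(x), " nuclei, ",
      if ("z" %in% names(x)) "3D" else "2D (MIP)",
      ", channels: ", paste(attr(x, "channels"), collapse = ", "), "\n", sep = "")
  md <- attr(x, "metadata")
  if (length(md))
    cat("  metadata: ",
        paste(names(md), unlist(lapply(md, format)), sep = "=", collapse = ", "),
        "\n", sep = "")
  calls <- grep("^call_", names(x), value = TRUE)
  if (length(calls))
    cat("  calls: ", paste(sub("^call_", "", calls), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Positions matrix of an aggregate table
#'
#' @param table an `aggregate_table`.
#' @return numeric matrix with columns x, y (and z when present), in um.
#' @export
nucleus_positions <- function(table) {
  cols <- intersect(c("x", "y", "z"), names(table))
  as.matrix(as.data.frame(table)[, cols, drop = FALSE])
}

#' Resolve a two-group dichotomy on an aggregate table
#'
#' The dichotomy used for axis fitting and polarization scoring can be the
#' synthetic/genotype ground truth (`true_type`, e.g. WT vs optoWnt), a marker
#' call (`"SOX2"` or `"call_SOX2"`), or an explicit per-nucleus vector. The
#' first factor level is the reference population (plotted on the left of line
#' traces). When `dichotomy` is `NULL` the genotype column `true_type` is used
#' if present, else the first available marker call.
#'
#' @param table an `aggregate_table`.
#' @param dichotomy `NULL`, a column/marker name, or a vector of length
#'   `nrow(table)` with exactly two distinct values.
#' @param min_group minimum size of each group (default 5).
#' @return factor of length `nrow(table)` with two levels; attribute
#'   `dichotomy_label` names the grouping used.
#' @export
dichotomy_labels <- function(table, dichotomy = NULL, min_group = 5L) {
  n <- nrow(table)
  label <- NULL
  if (is.null(dichotomy)) {
    if ("true_type" %in% names(table)) {
      dichotomy <- "true_type"
    } else {
      cc <- grep("^call_", names(table), value = TRUE)
      if (!length(cc))
        stop("no dichotomy available: table has neither true_type nor marker calls")
      dichotomy <- cc[[1L]]
    }
  }
  if (length(dichotomy) == 1L && is.character(dichotomy)) {
    # a marker name resolves to its call column, never the raw intensities
    col <- if (paste0("call_", dichotomy) %in% names(table)) paste0("call_", dichotomy)
           else if (dichotomy %in% names(table) &&
                    !dichotomy %in% attr(table, "channels")) dichotomy
           else stop("dichotomy column not found (or marker has no calls): ",
                     dichotomy)
    label <- col
    v <- as.data.frame(table)[[col]]
    if (startsWith(col, "call_")) {
      m <- sub("^call_", "", col)
      v <- factor(ifelse(as.logical(v), paste0(m, "+"), paste0(m, "-")),
                  levels = c(paste0(m, "-"), paste0(m, "+")))
    }
  } else {
    if (length(dichotomy) != n)
      stop("dichotomy vector length ", length(dichotomy), " != ", n, " nuclei")
    v <- dichotomy
    label <- "custom"
  }
  if (is.logical(v)) v <- factor(v, levels = c(FALSE, TRUE))
  g <- droplevels(factor(v))
  if (nlevels(g) != 2L)
    stop("dichotomy must split nuclei into exactly two groups, got ",
         nlevels(g), " (", label, ")")
  tab <- table(g)
  if (any(tab < min_group))
    stop("dichotomy group below size floor (", min_group, "): ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  attr(g, "dichotomy_label") <- label
  g
}

#' Read / write aggregate point tables
#'
#' CSV dialect: columns `aggregate_id`, `nucleus_id`, `x`, `y` (and `z` in
#' um), one column per channel, optional `true_type` and `call_<marker>`
#' columns.
#'
#' @param table an `aggregate_table`.
#' @param path CSV file path.
#' @return `read_aggregate_csv` returns an `aggregate_table`;
#'   `write_aggregate_csv` returns `path` invisibly.
#' @export
write_aggregate_csv <- function(table, path) {
  df <- as.data.frame(table)
  df <- cbind(aggregate_id = attr(table, "aggregate_id"), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_aggregate_csv
#' @param channels optional explicit channel names (default: inferred).
#' @export
read_aggregate_csv <- function(path, channels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  id <- if ("aggregate_id" %in% names(df)) as.character(df$aggregate_id[[1L]]) else
    sub("\\.csv$", "", basename(path))
  df$aggregate_id <- NULL
  aggregate_table(df, aggregate_id = id, channels = channels)
}
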